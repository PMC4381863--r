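#' Kernel specifications
#'
#' Construct a kernel specification used by all learners in the package.
#' `gaussian_kernel(h)` is the radial basis kernel
#' \deqn{\kappa(x, y) = \exp(-\|x - y\|^2 / (2 h^2)),}
#' a universal, strictly positive definite kernel; `linear_kernel()` is the
#' plain inner product \eqn{\kappa(x, y) = x^\top y}, whose induced feature
#' map is the identity.  The linear kernel makes kernel TD collapse onto
#' ordinary linear TD and is used as an exact cross-check.
#'
#' @param h Kernel size (bandwidth), a positive scalar.
#' @return An object of class `kernel_spec`.
#' @examples
#' k <- gaussian_kernel(0.2)
#' kernel_eval(k, c(1, 0), c(1, 0))  # always 1 at zero distance
#' @export
gaussian_kernel <- function(h) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("gaussian kernel requires a positive scalar bandwidth `h`")
  structure(list(family = "gaussian", h = as.numeric(h)), class = "kernel_spec")
}

#' @rdname gaussian_kernel
#' @export
linear_kernel <- function() {
  structure(list(family = "linear", h = NA_real_), class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  if (x$family == "gaussian")
    cat(sprintf("Gaussian kernel, h = %g\n", x$h))
  else
    cat("Linear kernel (inner product)\n")
  invisible(x)
}

#' Evaluate a kernel between two vectors
#'
#' @param spec A [kernel_spec][gaussian_kernel].
#' @param x,y Numeric vectors of equal length.
#' @param h Optional bandwidth override (used when centers carry their own
#'   frozen bandwidths in auto-kernel-size mode); ignored for the linear
#'   kernel.
#' @return The scalar kernel value.
#' @export
kernel_eval <- function(spec, x, y, h = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(x) != length(y))
    stop("kernel_eval: `x` and `y` must have the same dimension")
  if (spec$family == "linear") return(sum(x * y))
  hh <- if (is.null(h)) spec$h else h
  if (!is.finite(hh) || hh <= 0) stop("kernel_eval: nonpositive bandwidth")
  d2 <- sum((x - y)^2)
  exp(-d2 / (2 * hh^2))
}

## Row-wise kernel between a matrix of centers and one point.  `h` may be a
## per-center vector (frozen bandwidths).  Hot path: vectorized, no checks.
kernel_cross <- function(spec, centers, x, h = NULL) {
  if (nrow(centers) == 0L) return(numeric(0))
  if (spec$family == "linear") return(as.numeric(centers %*% x))
  hh <- if (is.null(h)) spec$h else h
  d2 <- rowSums(centers * centers) - 2 * as.numeric(centers %*% x) + sum(x * x)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * hh^2))
}

#' Gram matrix of a set of states
#'
#' @param spec A [kernel_spec][gaussian_kernel].
#' @param X Numeric matrix, one state per row.
#' @return The symmetric kernel matrix \eqn{K_{ij} = \kappa(x_i, x_j)}.
#' @export
gram_matrix <- function(spec, X) {
  stopifnot(inherits(spec, "kernel_spec"), is.matrix(X))
  if (spec$family == "linear") return(X %*% t(X))
  d2 <- as.matrix(stats::dist(X))^2
  exp(-d2 / (2 * spec$h^2))
}

#' Stepsize stability bound from the kernel least-mean-squares analysis
#'
#' The mean-square stability analysis of kernel LMS bounds the usable
#' stepsize by \eqn{\eta < N / \mathrm{tr}(G_\phi)} where \eqn{G_\phi} is the
#' Gram matrix of the \eqn{N} training states.  For any unit-norm kernel
#' (e.g. Gaussian, \eqn{\kappa(x,x) = 1}) the bound is exactly 1.
#'
#' @param X Numeric matrix of states, one per row (at least one row).
#' @param spec A [kernel_spec][gaussian_kernel].
#' @return The scalar bound \eqn{N / \sum_j \kappa(x_j, x_j)}.
#' @export
stepsize_bound <- function(X, spec) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (nrow(X) == 0L) stop("stepsize_bound: empty state list")
  diag_k <- if (spec$family == "gaussian") rep(1, nrow(X)) else rowSums(X * X)
  nrow(X) / sum(diag_k)
}

#' Online kernel-size selection from the history of inputs
#'
#' Maintains the running bandwidth heuristic used in closed-loop decoding,
#' where the dynamic range of the neural states is unknown beforehand.  On
#' the n-th input the tracker computes the half mean squared distance to all
#' previously seen states,
#' \deqn{h_{temp}(n) = \frac{1}{2(n-1)} \sum_{i<n} \|x_i - x_n\|^2,}
#' and averages it with the past kernel sizes,
#' \deqn{h(n) = \frac{1}{n}\Big(\sum_{i=1}^{n-1} h(i) + h_{temp}(n)\Big).}
#' The very first input has no history; `h_init` is recorded as h(1) so the
#' recursion is well posed (any positive constant is progressively washed
#' out by the averaging).
#'
#' @param h_init Fallback bandwidth recorded for the first input.
#' @return `kernel_size_tracker()` returns a fresh tracker (class
#'   `kernel_size_tracker`); `auto_kernel_size()` returns the updated
#'   tracker, with the bandwidth in force available as `$h`.
#' @examples
#' tr <- kernel_size_tracker(h_init = 1)
#' tr <- auto_kernel_size(tr, c(0, 0))   # h(1) = 1 (fallback)
#' tr <- auto_kernel_size(tr, c(2, 0))   # h(2) = (1 + 4/2) / 2
#' tr$h
#' @export
kernel_size_tracker <- function(h_init = 1.0) {
  stopifnot(is.numeric(h_init), h_init > 0)
  structure(list(n = 0L, history = numeric(0), states = NULL,
                 h = h_init, h_init = h_init),
            class = "kernel_size_tracker")
}

#' @rdname kernel_size_tracker
#' @param tracker A `kernel_size_tracker`.
#' @param x_new The incoming state vector.
#' @export
auto_kernel_size <- function(tracker, x_new) {
  stopifnot(inherits(tracker, "kernel_size_tracker"))
  x_new <- as.numeric(x_new)
  n <- tracker$n + 1L
  if (n == 1L) {
    h_n <- tracker$h_init
  } else {
    d2 <- colSums((t(tracker$states) - x_new)^2)
    h_temp <- sum(d2) / (2 * (n - 1L))
    h_n <- (sum(tracker$history) + h_temp) / n
  }
  tracker$states  <- rbind(tracker$states, x_new)
  tracker$history <- c(tracker$history, h_n)
  tracker$n <- n
  tracker$h <- h_n
  tracker
}

#' Offline kernel-size heuristic from pairwise squared distances
#'
#' The batch counterpart of [auto_kernel_size()]: with
#' \eqn{s = E[\|x_i - x_j\|^2]} over all pairs of training states, take
#' \eqn{h = \sqrt{s/2}}.  Used to pick a fixed bandwidth for open-loop
#' decoding where the whole batch is available up front.
#'
#' @param X Numeric matrix of states, one per row (at least two rows).
#' @return The scalar bandwidth.
#' @export
offline_kernel_size <- function(X) {
  stopifnot(is.matrix(X), nrow(X) >= 2L)
  s <- mean(stats::dist(X)^2)
  sqrt(s / 2)
}
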