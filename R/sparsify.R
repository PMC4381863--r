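#' Online dictionary sparsification criteria
#'
#' Growth control for kernel expansions.  Each incoming state is either
#' admitted as a new center or absorbed ("merged") into the closest existing
#' center, in which case the learner routes the same coefficient update to
#' that center instead of growing the dictionary.
#'
#' \describe{
#'   \item{`quantization`}{admit iff the input-space distance to the closest
#'     dictionary element exceeds the quantization size:
#'     \eqn{\min_i \|x - x_i\| > \epsilon_U}.}
#'   \item{`kernel_distance`}{admit iff the squared RKHS distance exceeds a
#'     threshold: \eqn{\min_i\, \kappa(x,x) + \kappa(x_i,x_i) -
#'     2\kappa(x,x_i) > \mu_1}.  For the Gaussian kernel this is equivalent
#'     to quantization under the monotone map
#'     \eqn{\mu_1 = 2 - 2\exp(-\epsilon_U^2 / 2h^2)}.}
#'   \item{`none`}{always admit; the dictionary grows by one center per
#'     observed state.}
#' }
#'
#' Equality with the threshold does not admit (the printed criteria use a
#' strict inequality for admission).  Distance ties between existing centers
#' are broken by the first index.
#'
#' @param method One of `"none"`, `"quantization"`, `"kernel_distance"`.
#' @param eps_u Quantization size (input-space distance threshold), >= 0.
#' @param mu1 Squared RKHS distance threshold, >= 0.
#' @return An object of class `sparsifier`.
#' @examples
#' sp <- sparsifier("quantization", eps_u = 1)
#' admit(sp, matrix(c(0, 0), 1), c(0.5, 0), gaussian_kernel(1))  # merge
#' @export
sparsifier <- function(method = c("none", "quantization", "kernel_distance"),
                       eps_u = 0, mu1 = 0) {
  method <- match.arg(method)
  if (eps_u < 0 || mu1 < 0) stop("sparsifier thresholds must be nonnegative")
  structure(list(method = method, eps_u = eps_u, mu1 = mu1),
            class = "sparsifier")
}

#' @rdname sparsifier
#' @param config A `sparsifier`.
#' @param centers Matrix of current dictionary centers (possibly 0 rows).
#' @param x_new Incoming state vector.
#' @param spec [kernel_spec][gaussian_kernel] (used by `kernel_distance`).
#' @param h Optional per-center bandwidth vector for `kernel_distance` with
#'   frozen per-center kernel sizes.
#' @return A list: `action` (`"add"` or `"merge"`) and, for merges, `index`
#'   of the absorbing center.
#' @export
admit <- function(config, centers, x_new, spec, h = NULL) {
  stopifnot(inherits(config, "sparsifier"))
  if (is.null(centers) || nrow(centers) == 0L)
    return(list(action = "add", index = NA_integer_))
  if (config$method == "none") return(list(action = "add", index = NA_integer_))
  d2 <- colSums((t(centers) - as.numeric(x_new))^2)
  if (config$method == "quantization") {
    i <- which.min(d2)                       # first index wins ties
    if (sqrt(d2[i]) > config$eps_u) list(action = "add", index = NA_integer_)
    else list(action = "merge", index = unname(i))
  } else {
    kxx <- if (spec$family == "gaussian") 1 else sum(x_new^2)
    kcc <- if (spec$family == "gaussian") rep(1, nrow(centers)) else rowSums(centers^2)
    kxc <- kernel_cross(spec, centers, as.numeric(x_new), h = h)
    rk2 <- kxx + kcc - 2 * kxc
    i <- which.min(rk2)
    if (rk2[i] > config$mu1) list(action = "add", index = NA_integer_)
    else list(action = "merge", index = unname(i))
  }
}
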