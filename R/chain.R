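#' Absorbing 13-state Markov reward chains
#'
#' Builds the classic 13-state absorbing chain used as a policy-evaluation
#' benchmark.  States are numbered 12 down to 0; every episode starts at
#' state 12 and ends at the absorbing state 0.  From states 2..12 the chain
#' moves to the two next-lower states with probability 0.5 each; state 1
#' moves to the terminal state 0 with probability 1.  Each state is
#' represented by a 4-dimensional feature vector: states 12, 8, 4 and 0 are
#' the four unit vectors and intermediate states interpolate linearly
#' between their bracketing anchors.
#'
#' Two reward assignments are provided:
#' \describe{
#'   \item{`linear`}{reward -3 on leaving states 2..12 and -2 on leaving
#'     state 1, which makes the true value function linear in the features:
#'     V* = (0, -2, -4, ..., -24) at states 0..12, i.e. V*(x) = w*ᵀx with
#'     w* = (-24, -16, -8, 0).}
#'   \item{`nonlinear`}{per-state rewards reconstructed by Bellman inversion
#'     ([bellman_invert()]) of the nonlinear target value vector
#'     V* = (0, -0.2, -0.6, -1.4, -3, -6.2, -12.6, -13.4, -13.5, -14.45,
#'     -15.975, -19.2125, -25.5938) at states 0..12, which no linear
#'     function of the features can represent.}
#' }
#'
#' @param variant `"linear"` or `"nonlinear"`.
#' @return An object of class `chain_mdp` with components
#'   `n_states` (13), `Q` (12x12 transition matrix between nonterminal
#'   states 1..12), `absorb` (per-state probability of entering the terminal
#'   state), `rewards` (length-12, reward emitted on leaving each
#'   nonterminal state), `features` (13x4 matrix, rows are states 0..12),
#'   `start` (start distribution over nonterminal states; all mass on 12),
#'   and `variant`.
#' @examples
#' ch <- build_chain("linear")
#' exact_values(ch)       # 0, -2, ..., -24
#' @export
build_chain <- function(variant = c("linear", "nonlinear")) {
  variant <- match.arg(variant)
  n_nt <- 12L                       # nonterminal states 1..12
  Q <- matrix(0, n_nt, n_nt, dimnames = list(1:12, 1:12))
  absorb <- numeric(n_nt)
  for (i in 2:12) {
    Q[i, i - 1L] <- 0.5
    if (i - 2L >= 1L) Q[i, i - 2L] <- 0.5 else absorb[i] <- 0.5
  }
  absorb[1L] <- 1
  rewards <- switch(variant,
    linear = c(-2, rep(-3, 11)),
    nonlinear = bellman_invert(nonlinear_values()))
  start <- c(rep(0, 11), 1)
  structure(list(n_states = 13L, Q = Q, absorb = absorb, rewards = rewards,
                 features = chain_features(), start = start,
                 variant = variant),
            class = "chain_mdp")
}

## The published nonlinear target values at states 0..12.
nonlinear_values <- function() {
  c(0, -0.2, -0.6, -1.4, -3, -6.2, -12.6, -13.4, -13.5,
    -14.45, -15.975, -19.2125, -25.5938)
}

## 13x4 feature matrix, row s+1 = state s.  Anchors: 12 -> e1, 8 -> e2,
## 4 -> e3, 0 -> e4; linear interpolation in between.
chain_features <- function() {
  X <- matrix(0, 13L, 4L, dimnames = list(0:12, NULL))
  for (s in 0:12) {
    if (s >= 8) {
      w <- (s - 8) / 4; X[s + 1L, 1:2] <- c(w, 1 - w)
    } else if (s >= 4) {
      w <- (s - 4) / 4; X[s + 1L, 2:3] <- c(w, 1 - w)
    } else {
      w <- s / 4;       X[s + 1L, 3:4] <- c(w, 1 - w)
    }
  }
  X
}

#' @export
print.chain_mdp <- function(x, ...) {
  cat(sprintf("Absorbing 13-state chain (%s value function)\n", x$variant))
  cat("rewards on leaving states 1..12:\n")
  print(round(x$rewards, 6))
  invisible(x)
}

#' Recover per-state rewards from a target value function
#'
#' Inverts the Bellman equation of the chain (gamma = 1): for states 2..12,
#' \eqn{r_i = V(i) - 0.5\,(V(i-1) + V(i-2))}, and \eqn{r_1 = V(1) - V(0)}.
#' This reconstructs the reward assignment that makes an arbitrary target
#' vector the chain's exact value function, and acts as the independent
#' oracle for the nonlinear benchmark's rewards.
#'
#' @param values Numeric vector of length 13, target values at states 0..12
#'   with `values[1]` (state 0) equal to 0.
#' @return Numeric vector of length 12: rewards on leaving states 1..12.
#' @export
bellman_invert <- function(values) {
  if (length(values) != 13L)
    stop("bellman_invert: `values` must have length 13 (states 0..12)")
  v <- as.numeric(values)           # v[s + 1] = V(s)
  r <- numeric(12L)
  r[1L] <- v[2L] - v[1L]
  for (i in 2:12) r[i] <- v[i + 1L] - 0.5 * (v[i] + v[i - 1L])
  r
}

#' Exact chain values by matrix inversion
#'
#' Solves the absorbing-chain value equation \eqn{V = (I - Q)^{-1} h} over
#' the nonterminal states, where \eqn{h} is the expected one-step reward
#' vector, and fixes the terminal value at 0.
#'
#' @param chain A [chain_mdp][build_chain].
#' @return Numeric vector of length 13: exact values at states 0..12.
#' @export
exact_values <- function(chain) {
  stopifnot(inherits(chain, "chain_mdp"))
  A <- diag(12L) - chain$Q
  v_nt <- tryCatch(solve(A, chain$rewards),
                   error = function(e) stop("exact_values: (I - Q) is singular; chain is not absorbing"))
  c(0, v_nt)
}

#' Sample one episode from the chain
#'
#' Starts from the start distribution (state 12) and follows the transition
#' law until absorption.  Uses R's global random number stream.
#'
#' @param chain A [chain_mdp][build_chain].
#' @return A list of class `chain_trajectory` with `states` (visited state
#'   indices, ending at 0), `rewards` (one per transition), and `features`
#'   (matrix of visited-state representations, including the terminal one).
#' @export
sample_episode <- function(chain) {
  stopifnot(inherits(chain, "chain_mdp"))
  s <- sample.int(12L, 1L, prob = chain$start)
  states <- s
  rewards <- numeric(0)
  while (s != 0L) {
    rewards <- c(rewards, chain$rewards[s])
    if (s == 1L) {
      s_next <- 0L
    } else {
      s_next <- if (stats::runif(1) < 0.5) s - 1L else s - 2L
    }
    states <- c(states, s_next)
    s <- s_next
  }
  structure(list(states = states, rewards = rewards,
                 features = chain$features[states + 1L, , drop = FALSE]),
            class = "chain_trajectory")
}

#' RMS error of a value estimate over all 13 chain states
#'
#' \deqn{RMS = \sqrt{\frac{1}{13} \sum_{x} (V^*(x) - \tilde V(x))^2}}
#' scored over all 13 states including the terminal one (true value 0).
#'
#' @param estimates,truth Numeric vectors of length 13 (states 0..12).
#' @return The scalar RMS error.
#' @export
rms_error <- function(estimates, truth) {
  if (length(estimates) != 13L || length(truth) != 13L)
    stop("rms_error: both vectors must have length 13")
  sqrt(mean((truth - estimates)^2))
}

#' Expected-update matrix and convergence diagnostic
#'
#' For policy evaluation with eligibility rate lambda the mean update of the
#' learner's state-value estimates is governed by
#' \deqn{H = -K D [I - (1 - \lambda) Q (I - \lambda Q)^{-1}]}
#' where K is the kernel Gram matrix of the nonterminal state features and
#' D is diagonal with the expected number of visits to each state per
#' episode.  Mean estimates converge when all eigenvalues of H have negative
#' real part, which requires K to be full rank — guaranteed for a strictly
#' positive definite kernel on distinct representations.
#'
#' @param chain A [chain_mdp][build_chain].
#' @param spec A strictly positive definite [kernel_spec][gaussian_kernel].
#' @param lambda Eligibility rate in \[0, 1).
#' @return A list with `H`, `eigenvalues` (of H), `K`, and `D` (the visit
#'   count vector).
#' @export
expected_update_matrix <- function(chain, spec, lambda) {
  stopifnot(inherits(chain, "chain_mdp"), inherits(spec, "kernel_spec"))
  if (lambda < 0 || lambda >= 1)
    stop("expected_update_matrix: this diagnostic requires 0 <= lambda < 1")
  X <- chain$features[-1L, , drop = FALSE]   # nonterminal states 1..12
  K <- gram_matrix(spec, X)
  Q <- chain$Q
  visits <- as.numeric(chain$start %*% solve(diag(12L) - Q))
  M <- diag(12L) - (1 - lambda) * Q %*% solve(diag(12L) - lambda * Q)
  H <- -K %*% diag(visits) %*% M
  list(H = H, eigenvalues = eigen(H, only.values = TRUE)$values,
       K = K, D = visits)
}
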