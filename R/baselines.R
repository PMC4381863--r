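#' Linear TD(lambda) baseline on a chain
#'
#' Conventional temporal-difference learning with a linearly parametrized
#' value function \eqn{V(x) = w^\top x} on the 4-dimensional chain features,
#' with accumulating eligibility traces (traces decay by lambda, matching
#' the kernel learner's accumulation) and the same annealed stepsize
#' schedule and RMS scoring protocol as [ktd_policy_eval()].  With the
#' linear kernel, KTD(lambda) reproduces this learner step for step.
#'
#' @inheritParams ktd_policy_eval
#' @return A [learning_curve]; `$fits` holds each run's final weight vector.
#' @export
linear_td <- function(chain, lambda, eta0, a0 = 100, gamma = 1,
                      n_trials = 1000, n_runs = 10, seed = 1,
                      anneal = c("per_step", "per_trial")) {
  stopifnot(inherits(chain, "chain_mdp"))
  anneal <- match.arg(anneal)
  truth <- exact_values(chain)
  sched <- stepsize_schedule(eta0, a0)
  rms <- matrix(NA_real_, n_runs, n_trials)
  fits <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    set.seed(derive_seed(seed, run))
    w <- numeric(4L)
    step_count <- 0L
    for (trial in seq_len(n_trials)) {
      traj <- sample_episode(chain)
      z <- numeric(4L)
      m <- length(traj$rewards)
      for (n in seq_len(m)) {
        step_count <- step_count + 1L
        eta <- if (anneal == "per_trial") stepsize(sched, trial)
               else stepsize(sched, step_count)
        x <- traj$features[n, ]
        v_next <- if (n == m) 0 else sum(w * traj$features[n + 1L, ])
        delta <- traj$rewards[n] + gamma * v_next - sum(w * x)
        z <- z * lambda
        z <- z + x
        w <- w + eta * delta * z
      }
      est <- c(0, as.numeric(chain$features[-1L, , drop = FALSE] %*% w))
      rms[run, trial] <- rms_error(est, truth)
    }
    fits[[run]] <- w
  }
  learning_curve(rms, metric = "rms",
                 params = list(algorithm = "td", variant = chain$variant,
                               lambda = lambda, eta0 = eta0, a0 = a0,
                               gamma = gamma, seed = seed),
                 fits = fits)
}

#' Monte-Carlo Gaussian-process TD baseline on a chain
#'
#' Gaussian-process temporal difference learning in its Monte-Carlo form
#' (lambda = 1): the value function has a GP prior with covariance given by
#' the kernel on the state features, and the observed rewards follow
#' \eqn{r = H V + N} with the episode's bidiagonal (1, -gamma) structure H
#' and intra-episode correlated noise \eqn{N \sim N(0, \sigma^2 H H^\top)}.
#' Left-multiplying by \eqn{H^{-1}} shows this model is exactly GP
#' regression of the per-visit returns-to-go: each visit to a state
#' contributes its observed remaining discounted return with independent
#' \eqn{N(0, \sigma^2)} noise.  Because the chains have at most 12 distinct
#' nonterminal states, observations are compressed exactly onto that
#' dictionary and the posterior is accumulated in information form, so each
#' trial costs one 12 x 12 solve.  The posterior mean is scored by RMS
#' against the exact values after every trial.
#'
#' @inheritParams ktd_policy_eval
#' @param sigma2 Observation noise variance, > 0.
#' @return A [learning_curve]; `$fits` holds each run's final posterior mean
#'   expansion coefficients (over the 12 nonterminal state features).
#' @export
gptd <- function(chain, sigma2 = 0.5, kernel = gaussian_kernel(0.2),
                 gamma = 1, n_trials = 1000, n_runs = 10, seed = 1) {
  stopifnot(inherits(chain, "chain_mdp"), sigma2 > 0)
  truth <- exact_values(chain)
  X <- chain$features[-1L, , drop = FALSE]       # states 1..12
  K <- gram_matrix(kernel, X)
  Kinv <- solve(K)
  # kernel between all 13 state features and the dictionary
  K13 <- t(apply(chain$features, 1L, function(x) kernel_cross(kernel, X, x)))
  B <- K13 %*% Kinv                              # maps m_X -> estimates
  rms <- matrix(NA_real_, n_runs, n_trials)
  fits <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    set.seed(derive_seed(seed, run))
    visits <- numeric(12L)                       # per-state observation counts
    gsum <- numeric(12L)                         # per-state summed returns
    for (trial in seq_len(n_trials)) {
      traj <- sample_episode(chain)
      m <- length(traj$rewards)
      # discounted returns-to-go along the episode
      G <- numeric(m)
      G[m] <- traj$rewards[m]
      if (m > 1L) for (n in (m - 1L):1L) G[n] <- traj$rewards[n] + gamma * G[n + 1L]
      for (n in seq_len(m)) {
        s <- traj$states[n]
        visits[s] <- visits[s] + 1
        gsum[s] <- gsum[s] + G[n]
      }
      m_X <- tryCatch(solve(Kinv + diag(visits / sigma2), gsum / sigma2),
                      error = function(e)
                        stop(sprintf("gptd: posterior solve failed at trial %d", trial)))
      rms[run, trial] <- rms_error(c(0, m_X), truth)
    }
    fits[[run]] <- as.numeric(Kinv %*% m_X)
  }
  learning_curve(rms, metric = "rms",
                 params = list(algorithm = "gptd", variant = chain$variant,
                               sigma2 = sigma2, gamma = gamma,
                               kernel = kernel$family, h = kernel$h,
                               seed = seed),
                 fits = fits)
}
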