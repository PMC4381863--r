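#' Kernel expansions (the learned value function)
#'
#' A kernel expansion is the function \eqn{f(x) = \sum_i \alpha_i
#' \kappa(c_i, x)} defined by a list of centers \eqn{c_i}, their
#' coefficients \eqn{\alpha_i} and a kernel.  All learners in the package
#' represent their value estimates this way; the empty expansion evaluates
#' to 0 everywhere.
#'
#' @param kernel A [kernel_spec][gaussian_kernel].
#' @param dim Dimension of the input states.
#' @return An object of class `kernel_expansion`.
#' @export
kernel_expansion <- function(kernel, dim) {
  stopifnot(inherits(kernel, "kernel_spec"), dim >= 1)
  structure(list(kernel = kernel, centers = matrix(numeric(0), 0L, dim),
                 coef = numeric(0), bw = NULL),
            class = "kernel_expansion")
}

#' @rdname kernel_expansion
#' @param object A `kernel_expansion`.
#' @param newdata A state vector, or a matrix with one state per row.
#' @param ... Unused.
#' @return Numeric vector of function values.
#' @export
predict.kernel_expansion <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- matrix(newdata, nrow = 1L)
  if (length(object$coef) == 0L) return(numeric(nrow(newdata)))
  apply(newdata, 1L, function(x)
    sum(object$coef * kernel_cross(object$kernel, object$centers, x,
                                   h = object$bw)))
}

#' @export
print.kernel_expansion <- function(x, ...) {
  cat(sprintf("Kernel expansion: %d centers (dim %d), %s kernel\n",
              length(x$coef), ncol(x$centers), x$kernel$family))
  invisible(x)
}

#' Temporal-difference error
#'
#' \deqn{\delta = r + \gamma V(x') - V(x)}
#' At an absorbing transition the bootstrapped next value is 0 by
#' definition, so the caller passes `v_next = 0`.
#'
#' @param r Observed reward.
#' @param v_next Value estimate at the next state (0 at terminal).
#' @param v_cur Value estimate at the current state.
#' @param gamma Discount factor in (0, 1].
#' @return The scalar TD error.
#' @export
td_error <- function(r, v_next, v_cur, gamma = 1) {
  stopifnot(gamma > 0, gamma <= 1)
  r + gamma * v_next - v_cur
}

#' Eligibility trace state
#'
#' Per-center eligibilities with decay rate lambda.  Within an episode the
#' trace of a center observed at step k carries weight \eqn{\lambda^{n-k}}
#' at step n; traces are reset at episode start.
#'
#' @param lambda Trace decay rate in \[0, 1\].
#' @return An object of class `trace_state`.
#' @export
trace_state <- function(lambda) {
  stopifnot(lambda >= 0, lambda <= 1)
  structure(list(e = numeric(0), lambda = lambda), class = "trace_state")
}

#' Annealed stepsize schedule
#'
#' \deqn{\eta_n = \eta_0 \frac{a_0 + 1}{a_0 + n}}
#' so that \eqn{\eta_1 = \eta_0} and the stepsize decays hyperbolically at a
#' rate controlled by the annealing factor \eqn{a_0}.
#'
#' @param eta0 Initial stepsize, > 0 (0 allowed to freeze learning).
#' @param a0 Annealing factor, > 0.
#' @return An object of class `stepsize_schedule`.
#' @export
stepsize_schedule <- function(eta0, a0 = 100) {
  stopifnot(eta0 >= 0, a0 > 0)
  structure(list(eta0 = eta0, a0 = a0), class = "stepsize_schedule")
}

#' @rdname stepsize_schedule
#' @param schedule A `stepsize_schedule`.
#' @param n Step index, >= 1.
#' @export
stepsize <- function(schedule, n) {
  stopifnot(inherits(schedule, "stepsize_schedule"), all(n >= 1))
  schedule$eta0 * (schedule$a0 + 1) / (schedule$a0 + n)
}

#' One online KTD(lambda) update
#'
#' Performs a single kernel temporal-difference update.  The current state
#' is admitted as a new center (or merged into its nearest neighbour by the
#' sparsifier), all traces are decayed by lambda and the current state's
#' trace incremented by 1, and every center's coefficient is incremented by
#' \eqn{\eta\,\delta\,e_i} where \eqn{\delta = r + \gamma v_{next} -
#' f(x_{cur})}.
#'
#' The TD error uses the expansion as it stands when the step is applied
#' (online realization).  For per-sequence updates, pass `v_cur` (and
#' `v_next`) evaluated on a frozen copy of the expansion.
#'
#' @param expansion A [kernel_expansion].
#' @param traces A [trace_state].
#' @param x_cur Current state vector.
#' @param v_next Value bootstrap at the next state (0 at terminal).
#' @param r Observed reward.
#' @param eta Stepsize for this update.
#' @param gamma Discount factor.
#' @param sp A [sparsifier] controlling dictionary growth.
#' @param v_cur Optional override of the current-state value (frozen-
#'   function variants); default is the expansion's own evaluation.
#' @param bw Optional bandwidth to freeze onto a newly created center
#'   (auto-kernel-size mode).
#' @return A list with the updated `expansion`, `traces`, and the TD error
#'   `delta`.
#' @export
ktd_step <- function(expansion, traces, x_cur, v_next, r, eta, gamma = 1,
                     sp = sparsifier("none"), v_cur = NULL, bw = NULL) {
  x_cur <- as.numeric(x_cur)
  dec <- admit(sp, expansion$centers, x_cur, expansion$kernel,
               h = expansion$bw)
  if (dec$action == "add") {
    expansion$centers <- rbind(expansion$centers, x_cur)
    expansion$coef <- c(expansion$coef, 0)
    if (!is.null(bw)) expansion$bw <- c(expansion$bw, bw)
    idx <- length(expansion$coef)
  } else {
    idx <- dec$index
  }
  # pre-existing centers (e.g. a warm-started expansion) carry zero trace
  if (length(traces$e) < length(expansion$coef))
    traces$e <- c(traces$e, numeric(length(expansion$coef) - length(traces$e)))
  if (is.null(v_cur))
    v_cur <- sum(expansion$coef *
                 kernel_cross(expansion$kernel, expansion$centers, x_cur,
                              h = expansion$bw))
  delta <- r + gamma * v_next - v_cur
  traces$e <- traces$e * traces$lambda
  traces$e[idx] <- traces$e[idx] + 1
  expansion$coef <- expansion$coef + eta * delta * traces$e
  list(expansion = expansion, traces = traces, delta = delta)
}

## Run one episode of KTD(lambda) along a sampled trajectory, returning the
## updated expansion.  timing = "per_sequence" evaluates all TD errors on
## the expansion frozen at episode start (the per-sequence sum of the
## update rule); "online" uses the running expansion.
ktd_episode <- function(expansion, traj, lambda, eta, gamma = 1,
                        sp = sparsifier("none"),
                        timing = c("online", "per_sequence")) {
  timing <- match.arg(timing)
  traces <- trace_state(lambda)
  frozen <- if (timing == "per_sequence") expansion else NULL
  m <- length(traj$rewards)
  for (n in seq_len(m)) {
    x_cur <- traj$features[n, ]
    terminal <- (n == m) && traj$states[length(traj$states)] == 0L
    if (!is.null(frozen)) {
      v_cur <- predict(frozen, x_cur)
      v_next <- if (terminal) 0 else predict(frozen, traj$features[n + 1L, ])
    } else {
      v_cur <- NULL
      v_next <- if (terminal) 0 else predict(expansion, traj$features[n + 1L, ])
    }
    st <- ktd_step(expansion, traces, x_cur, v_next, traj$rewards[n], eta,
                   gamma = gamma, sp = sp, v_cur = v_cur)
    expansion <- st$expansion
    traces <- st$traces
  }
  expansion
}

#' KTD(lambda) policy evaluation on an absorbing chain
#'
#' Runs online kernel temporal-difference learning of the state-value
#' function under the chain's fixed policy, scoring the RMS error against
#' the exact values after every trial and averaging over independent Monte
#' Carlo runs.  The annealed stepsize ([stepsize_schedule]) advances once
#' per transition by default (`anneal = "per_trial"` advances it once per
#' episode instead); exact-duplicate centers are aggregated, so the
#' dictionary never exceeds the number of distinct chain states.  The value
#' estimate is scored over all 13 states, the absorbing state entering at
#' its defined value 0.
#'
#' @param chain A [chain_mdp][build_chain].
#' @param lambda Eligibility trace rate in \[0, 1\].
#' @param eta0 Initial stepsize.
#' @param a0 Annealing factor.
#' @param gamma Discount factor (1 for the absorbing chains).
#' @param kernel A [kernel_spec][gaussian_kernel].
#' @param n_trials Trials (episodes) per run.
#' @param n_runs Independent Monte Carlo runs.
#' @param seed Master seed; per-run seeds are derived with [derive_seed()].
#' @param timing Update timing, `"online"` (default) or `"per_sequence"`.
#' @param anneal `"per_trial"` (default) or `"per_step"` stepsize advance.
#' @param sp Sparsifier; default merges exact duplicates.
#' @return A [learning_curve] with the per-trial RMS matrix (runs x trials)
#'   and, in `$fits`, the final expansion of each run.
#' @examples
#' \donttest{
#' ch <- build_chain("linear")
#' lc <- ktd_policy_eval(ch, lambda = 0.6, eta0 = 0.3,
#'                       kernel = gaussian_kernel(0.2),
#'                       n_trials = 200, n_runs = 2, seed = 1)
#' summary(lc)
#' }
#' @export
ktd_policy_eval <- function(chain, lambda, eta0, a0 = 100, gamma = 1,
                            kernel = gaussian_kernel(0.2),
                            n_trials = 1000, n_runs = 10, seed = 1,
                            timing = c("online", "per_sequence"),
                            anneal = c("per_step", "per_trial"),
                            sp = sparsifier("quantization", eps_u = 0)) {
  stopifnot(inherits(chain, "chain_mdp"))
  timing <- match.arg(timing)
  anneal <- match.arg(anneal)
  truth <- exact_values(chain)
  sched <- stepsize_schedule(eta0, a0)
  rms <- matrix(NA_real_, n_runs, n_trials)
  fits <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    set.seed(derive_seed(seed, run))
    f <- kernel_expansion(kernel, ncol(chain$features))
    step_count <- 0L
    for (trial in seq_len(n_trials)) {
      traj <- sample_episode(chain)
      if (anneal == "per_trial") {
        eta <- stepsize(sched, trial)
        f <- ktd_episode(f, traj, lambda, eta, gamma, sp, timing)
      } else {
        # advance the schedule on every transition
        traces <- trace_state(lambda)
        frozen <- if (timing == "per_sequence") f else NULL
        m <- length(traj$rewards)
        for (n in seq_len(m)) {
          step_count <- step_count + 1L
          eta <- stepsize(sched, step_count)
          terminal <- (n == m)
          v_cur <- if (is.null(frozen)) NULL else predict(frozen, traj$features[n, ])
          v_next <- if (terminal) 0 else
            predict(if (is.null(frozen)) f else frozen, traj$features[n + 1L, ])
          st <- ktd_step(f, traces, traj$features[n, ], v_next,
                         traj$rewards[n], eta, gamma, sp, v_cur = v_cur)
          f <- st$expansion; traces <- st$traces
        }
      }
      est <- c(0, predict(f, chain$features[-1L, , drop = FALSE]))
      rms[run, trial] <- rms_error(est, truth)
    }
    fits[[run]] <- f
  }
  learning_curve(rms, metric = "rms",
                 params = list(algorithm = "ktd", variant = chain$variant,
                               lambda = lambda, eta0 = eta0, a0 = a0,
                               gamma = gamma, kernel = kernel$family,
                               h = kernel$h, seed = seed),
                 fits = fits)
}
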