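#' Q-learning agent via kernel temporal differences
#'
#' Creates a Q-KTD(lambda) agent: a multi-output kernel expansion sharing
#' one set of centers across actions, with one coefficient column per
#' action.  Each update touches only the executed action's column (the
#' indicator structure of the single-step update rule), so untouched action
#' columns stay exactly zero.  Optionally the kernel size is selected
#' automatically from the history of inputs ([auto_kernel_size()]); each
#' center then permanently keeps the bandwidth in force when it was created.
#'
#' @param n_actions Number of discrete actions (>= 2).
#' @param dim State dimension.
#' @param kernel A [kernel_spec][gaussian_kernel]; ignored when
#'   `auto_kernel = TRUE` except for the family (Gaussian).
#' @param epsilon Exploration rate in \[0, 1\].
#' @param gamma Discount factor in (0, 1\].
#' @param lambda Eligibility trace rate (0 for single-step tasks).
#' @param sp A [sparsifier] controlling dictionary growth.
#' @param auto_kernel If `TRUE`, bandwidths are selected online from the
#'   input history.
#' @param h_init Fallback bandwidth for the first input in auto mode.
#' @return An object of class `qktd_agent`.
#' @export
qktd_agent <- function(n_actions, dim, kernel = gaussian_kernel(1),
                       epsilon = 0.01, gamma = 0.9, lambda = 0,
                       sp = sparsifier("none"),
                       auto_kernel = FALSE, h_init = 1) {
  stopifnot(n_actions >= 2, dim >= 1, epsilon >= 0, epsilon <= 1,
            gamma > 0, gamma <= 1, lambda >= 0, lambda <= 1)
  structure(list(n_actions = as.integer(n_actions), dim = as.integer(dim),
                 kernel = kernel, epsilon = epsilon, gamma = gamma,
                 lambda = lambda, sp = sp,
                 auto_kernel = auto_kernel,
                 tracker = if (auto_kernel) kernel_size_tracker(h_init) else NULL,
                 centers = matrix(numeric(0), 0L, dim),
                 coef = matrix(numeric(0), 0L, n_actions),
                 bw = if (auto_kernel) numeric(0) else NULL,
                 tr_idx = integer(0), tr_act = integer(0), tr_e = numeric(0)),
            class = "qktd_agent")
}

#' @export
print.qktd_agent <- function(x, ...) {
  cat(sprintf("Q-KTD agent: %d actions, %d centers (dim %d), eps=%g, gamma=%g, lambda=%g%s\n",
              x$n_actions, nrow(x$centers), x$dim, x$epsilon, x$gamma,
              x$lambda, if (x$auto_kernel) ", auto kernel size" else ""))
  invisible(x)
}

#' Action values of a Q-KTD agent
#'
#' Evaluates all action-value outputs \eqn{Q_i(x) = \sum_j
#' \alpha_{ji}\,\kappa(c_j, x)} at a state.  An agent with no centers
#' returns all zeros.
#'
#' @param agent A [qktd_agent].
#' @param x State vector.
#' @return Numeric vector of length `n_actions`.
#' @export
q_values <- function(agent, x) {
  stopifnot(inherits(agent, "qktd_agent"))
  if (length(x) != agent$dim) stop("q_values: state dimension mismatch")
  if (nrow(agent$centers) == 0L) return(numeric(agent$n_actions))
  k <- kernel_cross(agent$kernel, agent$centers, as.numeric(x), h = agent$bw)
  as.numeric(crossprod(agent$coef, k))
}

#' Epsilon-greedy action selection
#'
#' Selects the highest-valued action with probability 1 - epsilon; otherwise
#' one of the remaining actions uniformly at random.  Argmax ties are broken
#' uniformly at random.  Uses R's global random number stream.
#'
#' @param q Numeric vector of action values.
#' @param epsilon Exploration rate in \[0, 1\].
#' @return The selected action index.
#' @export
select_action <- function(q, epsilon = 0) {
  if (length(q) == 0L) stop("select_action: empty action-value vector")
  stopifnot(epsilon >= 0, epsilon <= 1)
  g <- which(q == max(q))
  greedy <- if (length(g) > 1L) g[sample.int(length(g), 1L)] else g
  if (epsilon > 0 && length(q) > 1L && stats::runif(1) < epsilon) {
    others <- setdiff(seq_along(q), greedy)
    others[sample.int(length(others), 1L)]
  } else greedy
}

#' One Q-KTD update
#'
#' Applies the kernel temporal-difference Q-learning update
#' \deqn{\delta = r + \gamma \max_a Q(x', a) - Q(x, a_{exec})}
#' (the max term is 0 at a terminal transition).  The current state becomes
#' a new center, receiving coefficient \eqn{\eta\delta} in the executed
#' action's column only — unless the sparsifier absorbs it into its nearest
#' existing center, which then receives the increment instead.  With
#' lambda > 0, centers visited earlier in the current episode also receive
#' \eqn{\eta\,\delta\,\lambda^{age}} in their own recorded action columns.
#'
#' @param agent A [qktd_agent].
#' @param x_cur Current state.
#' @param action Executed action index.
#' @param r Observed reward.
#' @param x_next Next state, or `NULL` at a terminal transition.
#' @param eta Stepsize.
#' @return A list with the updated `agent` and the TD error `delta`.
#' @export
q_update <- function(agent, x_cur, action, r, x_next = NULL, eta) {
  stopifnot(inherits(agent, "qktd_agent"))
  x_cur <- as.numeric(x_cur)
  q_next <- if (is.null(x_next)) 0 else max(q_values(agent, x_next))
  q_cur <- q_values(agent, x_cur)[action]
  delta <- r + agent$gamma * q_next - q_cur
  h_new <- NULL
  if (agent$auto_kernel) {
    agent$tracker <- auto_kernel_size(agent$tracker, x_cur)
    h_new <- agent$tracker$h
  }
  dec <- admit(agent$sp, agent$centers, x_cur, agent$kernel, h = agent$bw)
  if (dec$action == "add") {
    agent$centers <- rbind(agent$centers, x_cur)
    agent$coef <- rbind(agent$coef, numeric(agent$n_actions))
    if (agent$auto_kernel) agent$bw <- c(agent$bw, h_new)
    idx <- nrow(agent$centers)
  } else idx <- dec$index
  # decay episode traces, then add the current (center, action) credit
  agent$tr_e <- agent$tr_e * agent$lambda
  agent$tr_idx <- c(agent$tr_idx, idx)
  agent$tr_act <- c(agent$tr_act, action)
  agent$tr_e <- c(agent$tr_e, 1)
  keep <- agent$tr_e > 1e-12
  agent$tr_idx <- agent$tr_idx[keep]
  agent$tr_act <- agent$tr_act[keep]
  agent$tr_e <- agent$tr_e[keep]
  # entry-wise loop: the same (center, action) pair may appear several
  # times in the traces and its increments must accumulate
  for (j in seq_along(agent$tr_e)) {
    i <- agent$tr_idx[j]; a <- agent$tr_act[j]
    agent$coef[i, a] <- agent$coef[i, a] + eta * delta * agent$tr_e[j]
  }
  list(agent = agent, delta = delta)
}

## Clear episode-local eligibility traces.
reset_traces <- function(agent) {
  agent$tr_idx <- integer(0); agent$tr_act <- integer(0)
  agent$tr_e <- numeric(0)
  agent
}

#' Run one interaction episode
#'
#' Interacts with an environment until a terminal flag or the environment's
#' step cap, applying [q_update()] after every transition and logging the
#' per-step TD errors and greedy Q-values.
#'
#' The environment is a list of closures: `reset()` returning
#' `list(state, target)` and `step(action)` returning
#' `list(state, reward, done, success)`.
#'
#' @param agent A [qktd_agent].
#' @param env An environment object (see [reaching_env()]).
#' @param eta Stepsize used for every update in the episode.
#' @return A list with the updated `agent`, the `target` index, vectors
#'   `actions`, `rewards`, `deltas`, `q_max` (greedy value at each step),
#'   and the logical `success` flag.
#' @export
run_episode <- function(agent, env, eta) {
  stopifnot(inherits(agent, "qktd_agent"))
  agent <- reset_traces(agent)
  obs <- env$reset()
  x <- obs$state
  actions <- integer(0); rewards <- numeric(0); deltas <- numeric(0)
  q_max <- numeric(0)
  success <- FALSE
  repeat {
    q <- q_values(agent, x)
    a <- select_action(q, agent$epsilon)
    res <- env$step(a)
    upd <- q_update(agent, x, a, res$reward,
                    if (res$done) NULL else res$state, eta)
    agent <- upd$agent
    actions <- c(actions, a); rewards <- c(rewards, res$reward)
    deltas <- c(deltas, upd$delta); q_max <- c(q_max, max(q))
    if (res$done) { success <- isTRUE(res$success); break }
    x <- res$state
  }
  list(agent = agent, target = obs$target, actions = actions,
       rewards = rewards, deltas = deltas, q_max = q_max,
       success = success)
}

#' Train a Q-KTD agent over epochs of an episodic environment
#'
#' Runs `epochs` complete passes over the environment's trial set, applying
#' [run_episode()] per trial, and records per-trial success.
#'
#' @param agent A [qktd_agent].
#' @param env An environment object exposing `n_trials`.
#' @param epochs Number of passes over the trial set.
#' @param eta Stepsize.
#' @return A list with the trained `agent`, the epochs x trials logical
#'   `success` matrix, per-epoch `success_rate`, and the per-trial
#'   dictionary size trace `filter_size`.
#' @export
qktd_train <- function(agent, env, epochs, eta) {
  n_trials <- env$n_trials
  success <- matrix(NA, epochs, n_trials)
  filter_size <- integer(0)
  for (ep in seq_len(epochs)) {
    for (tr in seq_len(n_trials)) {
      out <- run_episode(agent, env, eta)
      agent <- out$agent
      success[ep, tr] <- out$success
      filter_size <- c(filter_size, nrow(agent$centers))
    }
  }
  list(agent = agent, success = success,
       success_rate = rowMeans(success), filter_size = filter_size)
}
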