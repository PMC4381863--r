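#' Center-out target layout
#'
#' Geometry of the center-out reaching task: 2, 4 or 8 targets on a circle
#' of radius 4 cm around the origin, with a 1 cm capture radius.  The eight
#' possible action directions sit at multiples of 45 degrees; target
#' direction indices are 1 (right), 3 (up), 5 (left), 7 (down) for the
#' 4-target task, \{1, 5\} for the 2-target task, and 1..8 for the 8-target
#' task.  Each direction index also carries the orientation angle theta of
#' the elongated reward field: indices 1 and 5 map to 0, 2 and 6 to -pi/4,
#' 3 and 7 to pi/2, and 4 and 8 to pi/4.
#'
#' @param n_targets 2, 4 or 8.
#' @param distance Center-to-target distance in cm.
#' @param radius Capture radius in cm.
#' @return An object of class `target_layout` with `directions` (direction
#'   index per target), `positions` (n_targets x 2 matrix, cm), `theta`
#'   (field angle per target), `distance` and `radius`.
#' @export
target_layout <- function(n_targets = 2, distance = 4, radius = 1) {
  if (!n_targets %in% c(2L, 4L, 8L))
    stop("target_layout: `n_targets` must be 2, 4 or 8")
  directions <- switch(as.character(n_targets),
                       "2" = c(1L, 5L), "4" = c(1L, 3L, 5L, 7L), "8" = 1:8)
  ang <- (directions - 1L) * pi / 4
  positions <- distance * cbind(cos(ang), sin(ang))
  theta_table <- c(0, -pi / 4, pi / 2, pi / 4, 0, -pi / 4, pi / 2, pi / 4)
  structure(list(n_targets = as.integer(n_targets), directions = directions,
                 positions = positions, theta = theta_table[directions],
                 distance = distance, radius = radius),
            class = "target_layout")
}

#' Continuous reward field around a target
#'
#' The shaped reward used in multistep reaching:
#' \deqn{r(s) = p_{reward}\,G(s) \;\mathrm{if}\; G(s) > 0.1, \quad
#'       n_{reward} \;\mathrm{otherwise},}
#' with \eqn{G(s) = \exp[-(s-\mu)^\top C_\theta^{-1} (s-\mu)]},
#' \eqn{p_{reward} = 1}, \eqn{n_{reward} = -0.6}, and the anisotropic
#' covariance \eqn{C_\theta = R_\theta\,\mathrm{diag}(7.5, 0.1)\,
#' R_\theta^\top} oriented along the target's approach axis.  G is at most
#' 1, attained exactly at the target center, so the maximum attainable
#' reward is +1.
#'
#' @param layout A [target_layout].
#' @param s Cursor position (2-vector, cm).
#' @param target Target index (into the layout).
#' @param p_reward,n_reward Positive-region scale and far-field penalty.
#' @return The scalar reward.
#' @export
reward_continuous <- function(layout, s, target, p_reward = 1,
                              n_reward = -0.6) {
  stopifnot(inherits(layout, "target_layout"),
            target >= 1, target <= layout$n_targets)
  mu <- layout$positions[target, ]
  th <- layout$theta[target]
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2L, 2L)
  C <- R %*% diag(c(7.5, 0.1)) %*% t(R)
  d <- as.numeric(s) - mu
  G <- exp(-as.numeric(d %*% solve(C, d)))
  if (G > 0.1) p_reward * G else n_reward
}

#' Discrete reward of the single-step reaching task
#'
#' +0.6 when the position is within the capture radius of the assigned
#' target, -0.6 otherwise.
#'
#' @inheritParams reward_continuous
#' @param position Cursor position (2-vector, cm).
#' @return +0.6 or -0.6.
#' @export
reward_discrete <- function(position, layout, target) {
  stopifnot(inherits(layout, "target_layout"))
  d <- sqrt(sum((as.numeric(position) - layout$positions[target, ])^2))
  if (d <= layout$radius) 0.6 else -0.6
}

#' Move the cursor one step along an action direction
#'
#' Actions are the eight 45-degree directions; each step moves
#' `distance / steps_per_trial` cm, so a single-step trial jumps the full
#' center-to-target distance and multistep trials make proportionally
#' smaller jumps.
#'
#' @param position Current cursor position (2-vector, cm).
#' @param action Direction index in 1..8.
#' @param layout A [target_layout].
#' @param steps_per_trial Number of steps allowed per trial.
#' @return The new position.
#' @export
step_cursor <- function(position, action, layout, steps_per_trial = 1) {
  stopifnot(action >= 1, action <= 8, steps_per_trial >= 1)
  ang <- (action - 1) * pi / 4
  as.numeric(position) +
    (layout$distance / steps_per_trial) * c(cos(ang), sin(ang))
}

#' Synthetic neural-state trial generator
#'
#' Generates class-structured surrogate neural states emulating the shape
#' of center-out reaching recordings.  Each target class k has a
#' nonnegative mean firing-rate vector over `units` channels; a trial's
#' state is the class mean plus Gaussian noise, tap-delay embedded by
#' replicating the window across `taps + 1` lags with independent per-lag
#' noise.
#'
#' \describe{
#'   \item{`open_loop`}{`units = 185`, `taps = 6` (1295-dimensional states,
#'     the 100 ms firing-rate windows of the offline recordings); states
#'     are min-max normalized to \[-1, 1\] per dimension over the batch.}
#'   \item{`closed_loop`}{`units = 14`, `taps = 0` (2 s firing-rate windows
#'     of the online sessions); no normalization; class means drift as a
#'     random walk across trials (per-session nonstationarity) and with
#'     probability `distraction` a trial's state is generated around
#'     another class's mean (the subject attending away from the task)
#'     while keeping its intended label.}
#' }
#'
#' Class means are separated so that the minimum pairwise distance between
#' base means is `separation * noise_sd * sqrt(units)`: the separation
#' parameter is the per-channel class contrast in units of the noise sd
#' (the default 4 emulates strongly tuned, well-sorted units whose firing
#' rates differ clearly between movement intentions).
#'
#' @param n_trials Number of trials.
#' @param n_targets 2, 4 or 8.
#' @param mode `"open_loop"` or `"closed_loop"`.
#' @param units,taps Channel count and tap-delay order (defaults set by
#'   `mode`).
#' @param separation Class separation / noise ratio (>= 0).
#' @param noise_sd Per-unit, per-lag firing-rate noise sd (> 0 unless 0 for
#'   a noiseless batch).
#' @param drift Random-walk sd of the class means per trial; default 0.05
#'   in closed-loop mode, 0 in open-loop mode.
#' @param distraction Probability of a distracted trial (closed loop).
#' @return An object of class `neural_trial_batch`: `states` (n_trials x
#'   dim matrix), `labels` (intended target per trial), `means` (class base
#'   means), `distracted` (logical per trial), and `params`.
#' @examples
#' b <- local({set.seed(1); generate_trials(10, 2, "open_loop")})
#' dim(b$states)  # 10 x 1295
#' @export
generate_trials <- function(n_trials, n_targets = 2,
                            mode = c("open_loop", "closed_loop"),
                            units = NULL, taps = NULL,
                            separation = 4, noise_sd = 1,
                            drift = NULL, distraction = 0) {
  mode <- match.arg(mode)
  if (!n_targets %in% c(2L, 4L, 8L))
    stop("generate_trials: `n_targets` must be 2, 4 or 8")
  if (is.null(drift)) drift <- if (mode == "closed_loop") 0.05 else 0
  stopifnot(separation >= 0, noise_sd >= 0, drift >= 0,
            distraction >= 0, distraction < 1)
  if (is.null(units)) units <- if (mode == "open_loop") 185L else 14L
  if (is.null(taps)) taps <- if (mode == "open_loop") 6L else 0L
  dim_out <- units * (taps + 1L)
  # nonnegative base firing means, offsets rescaled to the target separation
  base <- stats::runif(units, 2, 8)
  offs <- matrix(stats::rnorm(n_targets * units), n_targets, units)
  dmin <- min(stats::dist(offs))
  if (dmin > 0 && separation > 0)
    offs <- offs * (separation * max(noise_sd, 1e-8) * sqrt(units) / dmin)
  means <- sweep(offs, 2L, base, "+")
  means[means < 0] <- 0
  labels <- rep_len(seq_len(n_targets), n_trials)
  states <- matrix(NA_real_, n_trials, dim_out)
  distracted <- logical(n_trials)
  m_cur <- means
  for (i in seq_len(n_trials)) {
    if (mode == "closed_loop" && drift > 0)
      m_cur <- m_cur + matrix(stats::rnorm(n_targets * units, 0, drift),
                              n_targets, units)
    k <- labels[i]
    k_gen <- k
    if (distraction > 0 && stats::runif(1) < distraction) {
      others <- setdiff(seq_len(n_targets), k)
      k_gen <- others[sample.int(length(others), 1L)]
      distracted[i] <- TRUE
    }
    lags <- vapply(seq_len(taps + 1L), function(l)
      m_cur[k_gen, ] + stats::rnorm(units, 0, noise_sd), numeric(units))
    states[i, ] <- as.numeric(lags)
  }
  if (mode == "open_loop") {
    rng_lo <- apply(states, 2L, min)
    rng_hi <- apply(states, 2L, max)
    span <- pmax(rng_hi - rng_lo, 1e-12)
    states <- sweep(sweep(states, 2L, rng_lo, "-"), 2L, span / 2, "/") - 1
  }
  structure(list(states = states, labels = labels, means = means,
                 distracted = distracted,
                 params = list(mode = mode, n_targets = n_targets,
                               units = units, taps = taps,
                               separation = separation, noise_sd = noise_sd,
                               drift = drift, distraction = distraction)),
            class = "neural_trial_batch")
}

#' @export
print.neural_trial_batch <- function(x, ...) {
  cat(sprintf("Neural trial batch (%s): %d trials x %d dims, %d targets\n",
              x$params$mode, nrow(x$states), ncol(x$states),
              x$params$n_targets))
  invisible(x)
}

#' Reaching-task environment over a trial batch
#'
#' Wraps a [neural_trial_batch] and a [target_layout] as an episodic
#' environment for [run_episode()].  Trials are presented in batch order,
#' cycling across epochs.  Each episode starts with the cursor at the
#' origin; the agent's action moves the cursor by
#' `distance / steps_per_trial` cm.  A trial succeeds when the cursor
#' enters the capture radius (earning the maximum reward: +0.6 discrete,
#' +1 continuous); otherwise the discrete scheme pays -0.6 and the
#' continuous scheme pays the shaped field value, and the trial fails when
#' the step cap is reached.
#'
#' @param batch A [neural_trial_batch].
#' @param layout A [target_layout] (must match the batch's target count).
#' @param steps_per_trial Step cap per trial (1 = single-step task).
#' @param reward `"discrete"` or `"continuous"`.
#' @return An environment object (list of closures `reset`, `step`, plus
#'   `n_trials`).
#' @export
reaching_env <- function(batch, layout = target_layout(batch$params$n_targets),
                         steps_per_trial = 1,
                         reward = c("discrete", "continuous")) {
  stopifnot(inherits(batch, "neural_trial_batch"),
            inherits(layout, "target_layout"),
            layout$n_targets == batch$params$n_targets)
  reward <- match.arg(reward)
  e <- new.env(parent = emptyenv())
  e$trial <- 0L
  e$pos <- c(0, 0)
  e$steps <- 0L
  e$target <- NA_integer_
  n_trials <- nrow(batch$states)
  reset <- function() {
    e$trial <- (e$trial %% n_trials) + 1L
    e$pos <- c(0, 0)
    e$steps <- 0L
    e$target <- batch$labels[e$trial]
    list(state = batch$states[e$trial, ], target = e$target)
  }
  step <- function(action) {
    e$steps <- e$steps + 1L
    e$pos <- step_cursor(e$pos, action, layout, steps_per_trial)
    hit <- sqrt(sum((e$pos - layout$positions[e$target, ])^2)) <= layout$radius
    r <- if (reward == "discrete") {
      reward_discrete(e$pos, layout, e$target)
    } else {
      if (hit) 1 else reward_continuous(layout, e$pos, e$target)
    }
    done <- hit || e$steps >= steps_per_trial
    list(state = batch$states[e$trial, ], reward = r, done = done,
         success = hit)
  }
  list(reset = reset, step = step, n_trials = n_trials, layout = layout,
       reward = reward, steps_per_trial = steps_per_trial)
}

#' Principal-component policy map
#'
#' Projects the neural states onto their first two principal components and
#' evaluates the agent's greedy action on a grid of points in that plane,
#' reconstructed back into state space as mean plus component combination.
#' This visualizes the learned decoding policy next to the observed states
#' during coadaptation.
#'
#' @param batch A [neural_trial_batch] (at least 2 distinct states).
#' @param agent A trained [qktd_agent] of matching dimension.
#' @param grid_n Grid resolution per axis.
#' @return A list with `scores` (trials x 2 projections), `labels`
#'   (intended targets), and `grid` (data frame with `pc1`, `pc2`, and the
#'   greedy `action` at each node).
#' @export
pca_policy_map <- function(batch, agent, grid_n = 20) {
  stopifnot(inherits(batch, "neural_trial_batch"),
            inherits(agent, "qktd_agent"))
  X <- batch$states
  if (nrow(unique(X)) < 2L)
    stop("pca_policy_map: fewer than 2 distinct states; projection is degenerate")
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  if (length(pr$sdev) < 2L || pr$sdev[2L] < 1e-10)
    stop("pca_policy_map: fewer than 2 distinct states; projection is degenerate")
  scores <- pr$x[, 1:2, drop = FALSE]
  g1 <- seq(min(scores[, 1]), max(scores[, 1]), length.out = grid_n)
  g2 <- seq(min(scores[, 2]), max(scores[, 2]), length.out = grid_n)
  grid <- expand.grid(pc1 = g1, pc2 = g2)
  V <- pr$rotation[, 1:2, drop = FALSE]
  grid$action <- apply(as.matrix(grid), 1L, function(u) {
    x <- pr$center + V %*% u
    which.max(q_values(agent, as.numeric(x)))
  })
  list(scores = scores, labels = batch$labels, grid = grid)
}
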