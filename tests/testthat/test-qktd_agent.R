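test_that("action values evaluate the multi-output expansion", {
  ag <- qktd_agent(4, dim = 3, kernel = gaussian_kernel(1))
  expect_equal(q_values(ag, c(0, 0, 0)), rep(0, 4))
  # one center with coefficient on action 2 only
  ag$centers <- matrix(c(1, 2, 3), 1)
  ag$coef <- matrix(0, 1, 4); ag$coef[1, 2] <- 0.7
  q <- q_values(ag, c(1, 2, 3))
  expect_equal(q, c(0, 0.7, 0, 0))
  # duplicate centers aggregate additively
  ag2 <- ag
  ag2$centers <- rbind(ag$centers, ag$centers)
  ag2$coef <- rbind(ag$coef, ag$coef)
  ag3 <- ag
  ag3$coef[1, 2] <- 1.4
  x <- c(0.5, 2.5, 3)
  expect_equal(q_values(ag2, x), q_values(ag3, x))
  expect_error(q_values(ag, c(1, 2)), "dimension")
})

test_that("epsilon-greedy selection has the stated exploration law", {
  expect_error(select_action(numeric(0)), "empty")
  set.seed(1)
  expect_equal(replicate(20, select_action(c(0, 3, 1), epsilon = 0)),
               rep(2L, 20))
  # epsilon = 1 with 8 actions: each non-greedy action ~ 1/7
  q <- c(9, 1:7)
  set.seed(123)
  draws <- replicate(3e4, select_action(q, epsilon = 1))
  expect_true(all(draws != 1L))
  freq <- tabulate(draws, 8)[2:8] / 3e4
  expect_true(all(abs(freq - 1 / 7) < 0.01))
  # all-equal values, epsilon = 0: uniform over the tied set
  set.seed(9)
  ties <- replicate(2e4, select_action(rep(0, 4), epsilon = 0))
  expect_true(all(abs(tabulate(ties, 4) / 2e4 - 0.25) < 0.02))
})

test_that("Q updates write eta*delta into the executed action column only", {
  ag <- qktd_agent(8, dim = 2, kernel = gaussian_kernel(1), gamma = 0.9,
                   lambda = 0)
  up <- q_update(ag, c(0, 0), action = 3, r = 0.6, x_next = NULL, eta = 0.3)
  expect_equal(up$delta, 0.6)                       # empty agent, terminal
  expect_equal(up$agent$coef[1, ], c(0, 0, 0.18, rep(0, 5)))
  # single-step task: delta = r - Q_action(x)
  up2 <- q_update(up$agent, c(0, 0), action = 3, r = 0.6, x_next = NULL,
                  eta = 0.3)
  expect_equal(up2$delta, 0.6 - 0.18)
})

test_that("repeated presentation converges Q of the greedy action to the reward", {
  ag <- qktd_agent(2, dim = 2, kernel = gaussian_kernel(1), epsilon = 0,
                   lambda = 0, sp = sparsifier("quantization", eps_u = 0))
  x <- c(1, 1)
  for (i in 1:300) ag <- q_update(ag, x, 1, r = 0.6, NULL, eta = 0.3)$agent
  expect_equal(q_values(ag, x)[1], 0.6, tolerance = 1e-10)
  expect_equal(q_values(ag, x)[2], 0)
  expect_equal(nrow(ag$centers), 1L)                # merged every revisit
})

test_that("eligibility traces credit earlier centers in their own action columns", {
  ag <- qktd_agent(3, dim = 2, kernel = gaussian_kernel(0.1), gamma = 1,
                   lambda = 0.5)
  x1 <- c(0, 0); x2 <- c(100, 100)                  # no kernel overlap
  u1 <- q_update(ag, x1, action = 1, r = 0, x_next = x2, eta = 0.1)
  u2 <- q_update(u1$agent, x2, action = 2, r = 1, x_next = NULL, eta = 0.1)
  a <- u2$agent
  # center 1 received eta*(d1 + 0.5*d2) on action 1; center 2 eta*d2 on action 2
  expect_equal(a$coef[1, 1], 0.1 * (u1$delta + 0.5 * u2$delta))
  expect_equal(a$coef[2, 2], 0.1 * u2$delta)
  expect_equal(a$coef[1, 2], 0)
  expect_equal(a$coef[2, 1], 0)
})

test_that("episodes log success, failure and the TD-error sign at misses", {
  set.seed(31)
  batch <- generate_trials(8, 2, "open_loop", separation = 8, noise_sd = 0.5)
  env <- reaching_env(batch, steps_per_trial = 1, reward = "discrete")
  ag <- qktd_agent(8, dim = ncol(batch$states),
                   kernel = gaussian_kernel(offline_kernel_size(batch$states)),
                   epsilon = 0, gamma = 0.9, lambda = 0)
  out <- run_episode(ag, env, eta = 0.3)
  expect_length(out$actions, 1L)
  expect_identical(out$success, out$rewards[1] > 0)
  # force a miss with positive predicted Q: delta must be <= -penalty
  ag2 <- out$agent
  obs <- env$reset()
  wrong <- (ag2$n_actions + which.max(q_values(ag2, obs$state))) %% 8 + 1
  upd <- q_update(ag2, obs$state, wrong, r = -0.6, NULL, eta = 0.3)
  q_wrong <- q_values(ag2, obs$state)[wrong]
  if (q_wrong > 0) expect_lte(upd$delta, -0.6)
  expect_equal(upd$delta, -0.6 - q_wrong)
})

test_that("training is reproducible and the filter grows one center per step", {
  run_once <- function() {
    set.seed(77)
    batch <- generate_trials(10, 2, "open_loop")
    env <- reaching_env(batch)
    ag <- qktd_agent(8, ncol(batch$states),
                     kernel = gaussian_kernel(offline_kernel_size(batch$states)),
                     epsilon = 0.01)
    qktd_train(ag, env, epochs = 2, eta = 0.3)
  }
  r1 <- run_once(); r2 <- run_once()
  expect_identical(r1$agent$coef, r2$agent$coef)
  expect_identical(r1$success, r2$success)
  expect_equal(r1$filter_size, seq_len(20))         # one center per trial-step
})

test_that("auto kernel mode freezes the creation-time bandwidth on each center", {
  ag <- qktd_agent(2, dim = 1, auto_kernel = TRUE, h_init = 1, lambda = 0)
  a1 <- q_update(ag, 0, 1, r = 1, NULL, eta = 0.5)$agent
  a2 <- q_update(a1, 2, 1, r = 1, NULL, eta = 0.5)$agent
  expect_equal(a2$bw[1], 1)                         # h(1) fallback, frozen
  expect_equal(a2$bw[2], (1 + 4 / 2) / 2)           # h(2) from the recursion
  a3 <- q_update(a2, 1, 1, r = 1, NULL, eta = 0.5)$agent
  expect_equal(a3$bw[1:2], a2$bw[1:2])              # never recomputed
  expect_equal(a3$tracker$n, 3L)
})
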