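test_that("TD error composes reward, bootstrap and current value", {
  expect_equal(td_error(-3, -4, -7, gamma = 1), 0)
  expect_equal(td_error(-2, 0, -5), 3)            # terminal: delta = r - v_cur
  expect_equal(td_error(0, 1, 0, gamma = 0.9), 0.9)
})

test_that("stepsize schedule anneals hyperbolically", {
  s <- stepsize_schedule(0.5, a0 = 100)
  expect_equal(stepsize(s, 1), 0.5)
  expect_equal(stepsize(s, 101), 0.5 * 101 / 201)
  expect_lt(stepsize(s, 1e7), 1e-4)
  expect_true(all(diff(stepsize(s, 1:50)) < 0))
})

test_that("a single KTD step updates coefficients via eta * delta * eligibility", {
  k <- gaussian_kernel(0.5)
  f <- kernel_expansion(k, 2)
  tr <- trace_state(0)
  # empty expansion: delta = r, new center gets eta * r
  st <- ktd_step(f, tr, c(0, 0), v_next = 0, r = -3, eta = 0.1)
  expect_equal(st$expansion$coef, -0.3)
  expect_equal(st$delta, -3)
  # lambda = 0: a second step touches only the new center
  st2 <- ktd_step(st$expansion, st$traces, c(5, 5), v_next = 0, r = 1,
                  eta = 0.1)
  expect_equal(st2$expansion$coef[1], -0.3)
  expect_equal(length(st2$expansion$coef), 2L)
})

test_that("with lambda = 0.5 the first center accumulates eta*(d1 + 0.5*d2)", {
  k <- gaussian_kernel(0.2)
  f <- kernel_expansion(k, 2)
  tr <- trace_state(0.5)
  eta <- 0.25
  x1 <- c(0, 0); x2 <- c(10, 0)                   # far apart: no kernel overlap
  st1 <- ktd_step(f, tr, x1, v_next = 0, r = 2, eta = eta)
  d1 <- st1$delta
  st2 <- ktd_step(st1$expansion, st1$traces, x2, v_next = 0, r = -1, eta = eta)
  d2 <- st2$delta
  expect_equal(st2$expansion$coef[1], eta * (d1 + 0.5 * d2))
  expect_equal(st2$expansion$coef[2], eta * d2)
})

test_that("KTD(1) per-sequence episode equals kernel LMS toward observed returns", {
  ch <- build_chain("nonlinear")
  k <- gaussian_kernel(0.2)
  eta <- 0.2
  set.seed(3)
  for (rep in 1:3) {
    traj <- sample_episode(ch)
    X <- traj$features[seq_along(traj$rewards), , drop = FALSE]
    # start from a nontrivial expansion
    f0 <- kernel_expansion(k, 4)
    f0$centers <- ch$features[c(3, 8), ]
    f0$coef <- c(-1, 2)
    f1 <- kerneltd:::ktd_episode(f0, traj, lambda = 1, eta = eta,
                                 timing = "per_sequence")
    d <- oracle_returns(traj$rewards)
    f_oracle <- oracle_klms(f0, X, d, eta)
    grid <- ch$features
    expect_equal(predict(f1, grid), predict(f_oracle, grid),
                 tolerance = 1e-10)
  }
})

test_that("linear-kernel KTD reproduces linear TD(lambda) trace for trace", {
  ch <- build_chain("linear")
  for (lam in c(0, 0.6, 1)) {
    lc_k <- ktd_policy_eval(ch, lambda = lam, eta0 = 0.1,
                            kernel = linear_kernel(),
                            n_trials = 40, n_runs = 2, seed = 99)
    lc_t <- linear_td(ch, lambda = lam, eta0 = 0.1,
                      n_trials = 40, n_runs = 2, seed = 99)
    expect_equal(lc_k$values, lc_t$values, tolerance = 1e-10)
    # the expansion is exactly w expressed as sum alpha_i x_i
    w_k <- as.numeric(crossprod(lc_k$fits[[1]]$centers, lc_k$fits[[1]]$coef))
    expect_equal(w_k, lc_t$fits[[1]], tolerance = 1e-10)
  }
})

test_that("zero stepsize freezes the learner at the zero function", {
  ch <- build_chain("linear")
  lc <- ktd_policy_eval(ch, lambda = 0.6, eta0 = 0, n_trials = 20,
                        n_runs = 1, seed = 1)
  expect_equal(unname(lc$values[1, ]), rep(sqrt(200), 20))
})

test_that("mean RMS improves between early and late trials", {
  ch <- build_chain("linear")
  for (prm in list(c(0, 0.3), c(0.6, 0.3), c(1, 0.1))) {
    lc <- ktd_policy_eval(ch, lambda = prm[1], eta0 = prm[2],
                          kernel = gaussian_kernel(0.2),
                          n_trials = 300, n_runs = 3, seed = 4)
    expect_lt(lc$mean[300], lc$mean[10])
  }
})

test_that("duplicate-center aggregation keeps the chain dictionary at 12", {
  ch <- build_chain("linear")
  lc <- ktd_policy_eval(ch, lambda = 0.4, eta0 = 0.3, n_trials = 50,
                        n_runs = 1, seed = 2)
  expect_lte(nrow(lc$fits[[1]]$centers), 12L)
  # without sparsification the dictionary grows by one center per visit
  set.seed(2)
  f <- kernel_expansion(gaussian_kernel(0.2), 4)
  traj <- sample_episode(ch)
  f2 <- kerneltd:::ktd_episode(f, traj, lambda = 0, eta = 0.1,
                               sp = sparsifier("none"))
  expect_equal(nrow(f2$centers), length(traj$rewards))
})
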