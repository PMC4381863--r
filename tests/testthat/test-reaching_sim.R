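test_that("target layouts place equidistant targets with the published angle table", {
  for (nt in c(2, 4, 8)) {
    lay <- target_layout(nt)
    expect_equal(sqrt(rowSums(lay$positions^2)), rep(4, nt))
    expect_equal(lay$radius, 1)
  }
  lay8 <- target_layout(8)
  expect_equal(lay8$theta, c(0, -pi / 4, pi / 2, pi / 4,
                             0, -pi / 4, pi / 2, pi / 4))
  expect_equal(unname(lay8$positions[1, ]), c(4, 0))
  expect_equal(unname(lay8$positions[5, ]), c(-4, 0), tolerance = 1e-12)
  expect_error(target_layout(3), "2, 4 or 8")
})

test_that("the continuous reward field peaks at 1 on target and floors at -0.6", {
  lay <- target_layout(8)
  for (tg in c(1, 3, 6)) {
    mu <- lay$positions[tg, ]
    expect_equal(reward_continuous(lay, mu, tg), 1)
    expect_equal(reward_continuous(lay, mu + c(30, 30), tg), -0.6)
  }
  # nonincreasing along the long axis away from the target
  mu <- lay$positions[1, ]                       # theta = 0: long axis = x
  r_line <- vapply(seq(0, 4, by = 0.25),
                   function(d) reward_continuous(lay, mu - c(d, 0), 1), 0)
  expect_true(all(diff(r_line) <= 1e-12))
  expect_true(all(r_line <= 1))
})

test_that("the reward field is congruent across targets sharing an angle", {
  lay <- target_layout(8)
  offsets <- list(c(0.5, 0.2), c(-1, 0.7), c(2, -1.5))
  for (d in offsets) {
    expect_equal(reward_continuous(lay, lay$positions[4, ] + unlist(d), 4),
                 reward_continuous(lay, lay$positions[8, ] + unlist(d), 8))
    expect_equal(reward_continuous(lay, lay$positions[2, ] + unlist(d), 2),
                 reward_continuous(lay, lay$positions[6, ] + unlist(d), 6))
  }
})

test_that("discrete reward and cursor stepping follow the task geometry", {
  lay <- target_layout(2)
  expect_equal(reward_discrete(lay$positions[1, ], lay, 1), 0.6)
  expect_equal(reward_discrete(c(0, 0), lay, 1), -0.6)
  near <- lay$positions[1, ] + c(0.99, 0)
  expect_equal(reward_discrete(near, lay, 1), 0.6)
  # single-step jump along the correct direction lands on the target
  p <- step_cursor(c(0, 0), 1, lay, steps_per_trial = 1)
  expect_equal(p, unname(lay$positions[1, ]))
  # two half-steps accumulate the same displacement
  p2 <- step_cursor(step_cursor(c(0, 0), 1, lay, 2), 1, lay, 2)
  expect_equal(p2, unname(lay$positions[1, ]))
  # a wasted step under a 4-step cap leaves the target unreachable in line
  lay4 <- target_layout(4)
  p <- step_cursor(c(0, 0), 5, lay4, 4)          # step away first
  for (i in 1:3) p <- step_cursor(p, 1, lay4, 4)
  expect_gt(sqrt(sum((p - lay4$positions[1, ])^2)), lay4$radius)
})

test_that("the generator produces the open-loop data shape", {
  set.seed(12)
  b <- generate_trials(43, 2, "open_loop")
  expect_equal(dim(b$states), c(43L, 1295L))
  expect_gte(min(b$states), -1)
  expect_lte(max(b$states), 1)
  expect_equal(sort(unique(b$labels)), 1:2)
  expect_error(generate_trials(10, 3), "2, 4 or 8")
  # noiseless batch: all trials of a class identical, 1-NN separates fully
  set.seed(13)
  b0 <- generate_trials(12, 4, "open_loop", noise_sd = 0)
  for (k in 1:4) {
    rows <- b0$states[b0$labels == k, , drop = FALSE]
    expect_equal(max(dist(rows)), 0)
  }
  expect_gt(min(dist(unique(b0$states))), 0)
})

test_that("closed-loop batches have 14 dims, drift and the stated distraction rate", {
  set.seed(14)
  b <- generate_trials(4000, 2, "closed_loop", drift = 0, distraction = 0.2)
  expect_equal(ncol(b$states), 14L)
  expect_equal(mean(b$distracted), 0.2, tolerance = 0.1)
  # distracted trials sit nearer the opposite class mean
  d_own <- sqrt(rowSums((b$states - b$means[b$labels, ])^2))
  d_opp <- sqrt(rowSums((b$states - b$means[3 - b$labels, ])^2))
  nearer_opp <- mean(d_opp < d_own)
  expect_equal(nearer_opp, 0.2, tolerance = 0.15)
  # drifting means: late trials stray farther from the base means
  set.seed(14)
  bd <- generate_trials(4000, 2, "closed_loop", drift = 0.05)
  dd <- sqrt(rowSums((bd$states - bd$means[bd$labels, ])^2))
  expect_gt(mean(dd[3601:4000]), mean(dd[1:400]))
})

test_that("the PCA policy map separates a trained two-class decoder", {
  set.seed(15)
  b <- generate_trials(40, 2, "open_loop", separation = 8, noise_sd = 0.5)
  ag <- qktd_agent(8, ncol(b$states),
                   kernel = gaussian_kernel(offline_kernel_size(b$states)),
                   epsilon = 0)
  env <- reaching_env(b)
  ag <- qktd_train(ag, env, epochs = 2, eta = 0.3)$agent
  pm <- pca_policy_map(b, ag, grid_n = 15)
  expect_equal(dim(pm$scores), c(40L, 2L))
  expect_equal(nrow(pm$grid), 225L)
  # both greedy regions appear, and class means project to distinct labels
  lay <- target_layout(2)
  acts <- unique(pm$grid$action)
  expect_true(all(lay$directions %in% acts))
  # degenerate projection is reported
  b1 <- b
  b1$states <- b$states[rep(1, 5), ]
  expect_error(pca_policy_map(b1, ag), "degenerate")
})
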