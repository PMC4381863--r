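#' Q-KTD on the synthetic center-out reaching task
#'
#' High-level runner for the decoding experiment: per Monte Carlo run it
#' generates a fresh trial batch, fixes the kernel size by the offline
#' \eqn{h = \sqrt{s/2}} heuristic on that batch (or uses the supplied
#' kernel), trains a Q-KTD agent for the requested epochs and records the
#' per-epoch success rate.  All 8 action directions are available
#' regardless of the number of targets.
#'
#' @param n_targets 2, 4 or 8.
#' @param n_trials Trials per epoch.
#' @param epochs Passes over the trial set.
#' @param n_runs Independent Monte Carlo runs (fresh batch and agent each).
#' @param seed Master seed.
#' @param eta Stepsize.
#' @param epsilon,gamma,lambda Agent parameters.
#' @param sp A [sparsifier].
#' @param kernel Optional fixed [kernel_spec][gaussian_kernel]; default is
#'   the per-batch offline bandwidth heuristic.
#' @param steps_per_trial Step cap (1 = single-step task).
#' @param reward `"discrete"` or `"continuous"`.
#' @param separation,noise_sd,mode,distraction Generator settings, see
#'   [generate_trials()].
#' @return A [learning_curve] (metric `"success"`, runs x epochs) with the
#'   final dictionary sizes in `$params$filter_size`.
#' @export
qktd_reaching <- function(n_targets = 2, n_trials = 43, epochs = 5,
                          n_runs = 10, seed = 1, eta = 0.3,
                          epsilon = 0.01, gamma = 0.9, lambda = 0,
                          sp = sparsifier("none"), kernel = NULL,
                          steps_per_trial = 1,
                          reward = c("discrete", "continuous"),
                          separation = 4, noise_sd = 1,
                          mode = "open_loop", distraction = 0) {
  reward <- match.arg(reward)
  succ <- matrix(NA_real_, n_runs, epochs)
  sizes <- integer(n_runs)
  for (run in seq_len(n_runs)) {
    set.seed(derive_seed(seed, run))
    batch <- generate_trials(n_trials, n_targets, mode = mode,
                             separation = separation, noise_sd = noise_sd,
                             distraction = distraction)
    kern <- if (is.null(kernel)) gaussian_kernel(offline_kernel_size(batch$states))
            else kernel
    agent <- qktd_agent(8L, ncol(batch$states), kernel = kern,
                        epsilon = epsilon, gamma = gamma, lambda = lambda,
                        sp = sp)
    env <- reaching_env(batch, steps_per_trial = steps_per_trial,
                        reward = reward)
    res <- qktd_train(agent, env, epochs, eta)
    succ[run, ] <- res$success_rate
    sizes[run] <- nrow(res$agent$centers)
  }
  learning_curve(succ, metric = "success",
                 params = list(algorithm = "qktd", n_targets = n_targets,
                               n_trials = n_trials, eta = eta,
                               epsilon = epsilon, gamma = gamma,
                               lambda = lambda, sparsifier = sp$method,
                               eps_u = sp$eps_u, seed = seed,
                               filter_size = sizes))
}

cfg_get <- function(config, path, default = NULL) {
  x <- config
  for (k in strsplit(path, ".", fixed = TRUE)[[1L]]) {
    if (!is.list(x) || is.null(x[[k]])) {
      if (!is.null(default)) return(default)
      stop(sprintf("config: missing key `%s`", path))
    }
    x <- x[[k]]
  }
  x
}

cfg_kernel <- function(config) {
  fam <- cfg_get(config, "kernel.family", "gaussian")
  if (fam == "linear") linear_kernel()
  else gaussian_kernel(cfg_get(config, "kernel.h", 0.2))
}

cfg_sparsifier <- function(config) {
  sparsifier(cfg_get(config, "sparsifier.method", "none"),
             eps_u = cfg_get(config, "sparsifier.eps_u", 0),
             mu1 = cfg_get(config, "sparsifier.mu1", 0))
}

#' Run a configured experiment
#'
#' Dispatches a configuration (a nested list, or the path of a YAML file)
#' to the matching learner — `ktd`, `td`, `gptd` on a chain variant, or
#' `qktd` on the synthetic reaching task — and optionally serializes the
#' learning curve as CSV plus a JSON summary embedding the resolved
#' configuration.  Identical configurations and master seeds yield
#' bit-identical artifacts.
#'
#' Keys: `env.variant` (chains) or `env.n_targets`/`env.n_trials`
#' (reaching); `algorithm.learner`, `algorithm.lambda`, `algorithm.eta0`,
#' `algorithm.a0`, `algorithm.gamma`, `algorithm.epsilon`,
#' `algorithm.sigma2`; `kernel.family`, `kernel.h`; `sparsifier.method`,
#' `sparsifier.eps_u`, `sparsifier.mu1`; `run.trials`, `run.epochs`,
#' `run.runs`, `run.seed`.
#'
#' @param config Nested list or YAML file path.
#' @param outdir Optional output directory for `curve.csv` and
#'   `summary.json`.
#' @return The [learning_curve], invisibly carrying the resolved config in
#'   `$params$config`.
#' @export
run_experiment <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config: must be a list or a YAML file path")
  learner <- cfg_get(config, "algorithm.learner")
  seed <- cfg_get(config, "run.seed", 1)
  runs <- cfg_get(config, "run.runs", 10)
  t0 <- proc.time()[["elapsed"]]
  lc <- switch(learner,
    ktd = {
      chain <- build_chain(cfg_get(config, "env.variant"))
      ktd_policy_eval(chain,
                      lambda = cfg_get(config, "algorithm.lambda"),
                      eta0 = cfg_get(config, "algorithm.eta0"),
                      a0 = cfg_get(config, "algorithm.a0", 100),
                      gamma = cfg_get(config, "algorithm.gamma", 1),
                      kernel = cfg_kernel(config),
                      n_trials = cfg_get(config, "run.trials", 1000),
                      n_runs = runs, seed = seed)
    },
    td = {
      chain <- build_chain(cfg_get(config, "env.variant"))
      linear_td(chain,
                lambda = cfg_get(config, "algorithm.lambda"),
                eta0 = cfg_get(config, "algorithm.eta0"),
                a0 = cfg_get(config, "algorithm.a0", 100),
                gamma = cfg_get(config, "algorithm.gamma", 1),
                n_trials = cfg_get(config, "run.trials", 1000),
                n_runs = runs, seed = seed)
    },
    gptd = {
      chain <- build_chain(cfg_get(config, "env.variant"))
      gptd(chain,
           sigma2 = cfg_get(config, "algorithm.sigma2", 0.5),
           kernel = cfg_kernel(config),
           gamma = cfg_get(config, "algorithm.gamma", 1),
           n_trials = cfg_get(config, "run.trials", 1000),
           n_runs = runs, seed = seed)
    },
    qktd = {
      qktd_reaching(n_targets = cfg_get(config, "env.n_targets", 2),
                    n_trials = cfg_get(config, "env.n_trials", 43),
                    epochs = cfg_get(config, "run.epochs", 5),
                    n_runs = runs, seed = seed,
                    eta = cfg_get(config, "algorithm.eta", 0.3),
                    epsilon = cfg_get(config, "algorithm.epsilon", 0.01),
                    gamma = cfg_get(config, "algorithm.gamma", 0.9),
                    lambda = cfg_get(config, "algorithm.lambda", 0),
                    sp = cfg_sparsifier(config),
                    steps_per_trial = cfg_get(config, "env.steps_per_trial", 1),
                    reward = cfg_get(config, "env.reward", "discrete"),
                    separation = cfg_get(config, "env.separation", 4),
                    noise_sd = cfg_get(config, "env.noise_sd", 1))
    },
    stop(sprintf("config: unknown learner `%s` at key `algorithm.learner`",
                 learner)))
  lc$params$config <- config
  lc$params$runtime_s <- proc.time()[["elapsed"]] - t0
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_curve_csv(lc, file.path(outdir, "curve.csv"))
    write_summary_json(lc, file.path(outdir, "summary.json"))
  }
  invisible(lc)
}

#' Serialize a learning curve
#'
#' `write_curve_csv()` writes the fixed column contract
#' `trial, mean, sd, run1..runN`; `write_summary_json()` writes the final
#' mean and sd, per-run final values, and the resolved parameters.
#'
#' @param lc A [learning_curve].
#' @param path Output file path.
#' @export
write_curve_csv <- function(lc, path) {
  utils::write.csv(as.data.frame(lc), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
write_summary_json <- function(lc, path) {
  nt <- ncol(lc$values)
  drop <- c("config", "runtime_s")   # runtime would break bit-identity
  out <- list(metric = lc$metric, trials = nt, runs = nrow(lc$values),
              final_mean = lc$mean[nt], final_sd = lc$sd[nt],
              final_by_run = as.numeric(lc$values[, nt]),
              params = lc$params[setdiff(names(lc$params), drop)],
              config = lc$params$config)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Sweep eligibility rate and initial stepsize
#'
#' Runs the configured experiment over a lambda x eta0 grid and tabulates
#' the mean metric at the requested checkpoints (the marker structure of
#' the parameter-sweep figures: after 100, 500 and 1000 trials).
#'
#' @param config Base configuration (list or YAML path) for
#'   [run_experiment()].
#' @param lambdas,etas Grid values (nonempty).
#' @param checkpoints Trial indices to report.
#' @return A data frame with one row per (lambda, eta0) pair.
#' @export
sweep_grid <- function(config, lambdas, etas,
                       checkpoints = c(100, 500, 1000)) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(length(lambdas) >= 1, length(etas) >= 1)
  rows <- list()
  for (lam in lambdas) for (eta in etas) {
    cfg <- config
    cfg$algorithm$lambda <- lam
    cfg$algorithm$eta0 <- eta
    lc <- run_experiment(cfg)
    cp <- pmin(checkpoints, ncol(lc$values))
    row <- c(lambda = lam, eta0 = eta,
             stats::setNames(lc$mean[cp], paste0("rms", checkpoints)))
    rows[[length(rows) + 1L]] <- row
  }
  as.data.frame(do.call(rbind, rows))
}
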