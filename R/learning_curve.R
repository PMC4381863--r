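#' Learning curves
#'
#' Container for per-trial performance traces of a learner: a runs x trials
#' metric matrix plus per-trial mean and standard deviation, with the
#' resolved run parameters attached.
#'
#' @param metric_matrix Numeric matrix, one row per Monte Carlo run, one
#'   column per trial (or epoch).
#' @param metric Name of the metric (`"rms"` or `"success"`).
#' @param params Named list of resolved run parameters (embedded in every
#'   serialized artifact).
#' @param fits Optional list of per-run fitted objects.
#' @return An object of class `learning_curve`.
#' @export
learning_curve <- function(metric_matrix, metric = "rms", params = list(),
                           fits = NULL) {
  stopifnot(is.matrix(metric_matrix))
  sds <- if (nrow(metric_matrix) > 1L) apply(metric_matrix, 2L, stats::sd)
         else rep(0, ncol(metric_matrix))        # single run: no dispersion
  structure(list(metric = metric, values = metric_matrix,
                 mean = colMeans(metric_matrix),
                 sd = sds,
                 params = params, fits = fits),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  nt <- ncol(x$values)
  cat(sprintf("Learning curve (%s): %d runs x %d trials\n",
              x$metric, nrow(x$values), nt))
  if (length(x$params))
    cat("  ", paste(names(x$params),
                    vapply(x$params, function(p) format(p)[1], ""),
                    sep = "=", collapse = ", "), "\n")
  cat(sprintf("  final mean %s = %.4f (sd %.4f)\n",
              x$metric, x$mean[nt], x$sd[nt]))
  invisible(x)
}

#' @export
summary.learning_curve <- function(object, checkpoints = NULL, ...) {
  nt <- ncol(object$values)
  if (is.null(checkpoints)) checkpoints <- unique(pmin(c(100, 500, nt), nt))
  data.frame(trial = checkpoints,
             mean = object$mean[checkpoints],
             sd = object$sd[checkpoints])
}

#' @export
plot.learning_curve <- function(x, ...) {
  nt <- ncol(x$values)
  graphics::plot(seq_len(nt), x$mean, type = "l",
                 xlab = "trial", ylab = paste("mean", x$metric), ...)
  graphics::lines(seq_len(nt), x$mean + x$sd, lty = 2)
  graphics::lines(seq_len(nt), pmax(x$mean - x$sd, 0), lty = 2)
  invisible(x)
}

#' @export
as.data.frame.learning_curve <- function(x, ...) {
  df <- data.frame(trial = seq_len(ncol(x$values)), mean = x$mean, sd = x$sd)
  runs <- t(x$values)
  colnames(runs) <- paste0("run", seq_len(nrow(x$values)))
  cbind(df, runs)
}

#' Deterministic per-run seed derivation
#'
#' Counter-based fan-out of a master seed: run `i` always gets the same
#' stream regardless of how many runs are requested, so adding runs never
#' perturbs earlier runs.  Kept within the 32-bit signed integer range.
#'
#' @param master Master seed (integer).
#' @param i Run counter, >= 1.
#' @return An integer seed.
#' @export
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 7919 + i * 104729) %% 2147483647)
}
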