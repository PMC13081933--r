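#' Trapezoidal area under a per-iteration series
#'
#' Area under `series` over unit-spaced iterations (trapezoid rule). A
#' constant `c` over `n` points gives `(n - 1) * c`; a linear ramp 0 to 1
#' over 21 points gives 10.
#'
#' @param series Numeric vector of length >= 2.
#' @return Scalar area.
#' @export
auc <- function(series) {
  n <- length(series)
  if (n < 2L) stop("series must have length >= 2", call. = FALSE)
  sum((series[-1] + series[-n]) / 2)
}

#' Percent elevation of a value over a reference
#'
#' `(a - b) / b * 100`: positive when `a` exceeds the reference, negative for
#' a gradient inversion.
#'
#' @param a Value.
#' @param b Reference (non-zero).
#' @return Percent elevation.
#' @examples
#' percent_elevation(7.40, 3.61)  # ~105%
#' @export
percent_elevation <- function(a, b) {
  if (any(b == 0)) stop("reference must be non-zero", call. = FALSE)
  (a - b) / b * 100
}

#' Compare two levels' per-trial values
#'
#' Paired (one-sample t on within-trial differences) or independent (Welch)
#' two-sided t-test. Degenerate inputs — fewer than two observations, or a
#' paired comparison with zero-variance differences — are flagged rather than
#' producing spurious statistics: identical vectors give `t = 0`, `p = 1`
#' with `zero_variance = TRUE`; constant non-zero differences give an
#' infinite t with `p = 0`, also flagged.
#'
#' @param x,y Per-trial values (equal length when `paired`).
#' @param paired Paired comparison?
#' @return List with `t`, `p`, `df`, `zero_variance`.
#' @export
compare_levels <- function(x, y, paired = TRUE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least two observations per group", call. = FALSE)
  }
  if (paired) {
    if (length(x) != length(y)) {
      stop("paired comparison requires equal lengths", call. = FALSE)
    }
    d <- x - y
    if (stats::sd(d) == 0) {
      m <- mean(d)
      return(list(t = if (m == 0) 0 else Inf * sign(m),
                  p = if (m == 0) 1 else 0,
                  df = length(d) - 1L, zero_variance = TRUE))
    }
    tt <- stats::t.test(d)
  } else {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      eq <- isTRUE(all.equal(mean(x), mean(y)))
      return(list(t = if (eq) 0 else Inf * sign(mean(x) - mean(y)),
                  p = if (eq) 1 else 0, df = NA_real_, zero_variance = TRUE))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
  }
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), zero_variance = FALSE)
}

#' Run a seeded Monte-Carlo ensemble of network trials
#'
#' Runs `n_trials` independent trials (trial `k` seeded with
#' `base_seed + k`), and aggregates the tracked-node traces: per-iteration
#' across-trial means and SDs of every measure, per-trial AUCs of the
#' cumulative-work and Lyapunov series with across-trial summaries, Level-3
#' vs Level-1 work elevation, and paired t-tests between all level pairs on
#' the per-trial cumulative-work AUCs.
#'
#' @param config A [network_config()].
#' @param stimulus A [stimulus_config()].
#' @param n_trials Number of trials (>= 2); 2000 for reference runs.
#' @param base_seed Base seed; the full seed list is `base_seed + 1:n_trials`.
#' @return An object of class `tier_ensemble`: list with
#'   `per_iteration` (data.frame: level, iteration, mean/sd per measure),
#'   `auc_work` / `auc_lyapunov` (per-trial AUC matrices, trials x levels),
#'   `auc_summary` (data.frame of across-trial AUC means and SDs),
#'   `elevation` (Level-3 over Level-1, percent, on mean cumulative-work
#'   AUCs), `tests` (pairwise paired t-tests), `n_trials`, `base_seed`,
#'   `config`, `stimulus`.
#' @examples
#' es <- run_ensemble(network_config(), stimulus_config("random"),
#'                    n_trials = 25, base_seed = 1)
#' es$elevation
#' @export
run_ensemble <- function(config, stimulus, n_trials = 2000L, base_seed = 0L) {
  stopifnot(n_trials >= 2L)
  nit <- config$n_iterations
  traces <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    traces[[k]] <- run_trial(config, stimulus, seed = base_seed + k,
                             trial_id = k)
  }
  all_tr <- do.call(rbind, traces)
  measures <- c("delta_sum", "delta_sq", "delta_max", "work_cum",
                "entropy_norm", "lyapunov")
  per_iter <- expand.grid(level = 1:3, iteration = seq_len(nit),
                          KEEP.OUT.ATTRS = FALSE)
  per_iter <- per_iter[order(per_iter$level, per_iter$iteration), ,
                       drop = FALSE]
  rownames(per_iter) <- NULL
  key <- interaction(all_tr$level, all_tr$iteration, drop = TRUE)
  okey <- interaction(per_iter$level, per_iter$iteration, drop = TRUE)
  for (m in measures) {
    mu <- tapply(all_tr[[m]], key, mean)
    sdv <- tapply(all_tr[[m]], key, stats::sd)
    per_iter[[paste0(m, "_mean")]] <- as.numeric(mu[as.character(okey)])
    per_iter[[paste0(m, "_sd")]] <- as.numeric(sdv[as.character(okey)])
  }
  trial_auc <- function(col) {
    t(vapply(traces, function(tr) {
      vapply(1:3, function(l) auc(tr[[col]][tr$level == l]), numeric(1))
    }, numeric(3)))
  }
  auc_work <- trial_auc("work_cum")
  auc_lyap <- trial_auc("lyapunov")
  colnames(auc_work) <- colnames(auc_lyap) <- paste0("level", 1:3)
  auc_summary <- data.frame(
    level = rep(1:3, 2),
    measure = rep(c("work_cum", "lyapunov"), each = 3),
    auc_mean = c(colMeans(auc_work), colMeans(auc_lyap)),
    auc_sd = c(apply(auc_work, 2, stats::sd), apply(auc_lyap, 2, stats::sd))
  )
  tests <- list(
    l3_vs_l1 = compare_levels(auc_work[, 3], auc_work[, 1], paired = TRUE),
    l3_vs_l2 = compare_levels(auc_work[, 3], auc_work[, 2], paired = TRUE),
    l2_vs_l1 = compare_levels(auc_work[, 2], auc_work[, 1], paired = TRUE)
  )
  structure(
    list(per_iteration = per_iter,
         auc_work = auc_work, auc_lyapunov = auc_lyap,
         auc_summary = auc_summary,
         elevation = percent_elevation(mean(auc_work[, 3]),
                                       mean(auc_work[, 1])),
         tests = tests,
         n_trials = n_trials, base_seed = base_seed,
         config = config, stimulus = stimulus),
    class = "tier_ensemble"
  )
}

#' @export
print.tier_ensemble <- function(x, ...) {
  cat(sprintf("<tier_ensemble> %d trials, %s stimuli (base seed %d)\n",
              x$n_trials, x$stimulus$regime, x$base_seed))
  w <- x$auc_summary[x$auc_summary$measure == "work_cum", ]
  cat(sprintf("  cumulative-work AUC: L1 %.3f, L2 %.3f, L3 %.3f\n",
              w$auc_mean[1], w$auc_mean[2], w$auc_mean[3]))
  cat(sprintf("  Level-3 over Level-1 elevation: %.1f%% (paired t = %.1f, p = %.3g)\n",
              x$elevation, x$tests$l3_vs_l1$t, x$tests$l3_vs_l1$p))
  invisible(x)
}
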