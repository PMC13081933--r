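#' @title Sensitivity-analysis sweep drivers
#' @description The six prespecified sensitivity analyses: alternative work
#'   metrics, alternative input regimes, the FFE parameter grid, the
#'   compensation-factor sweep, alternative activation functions, and the
#'   three-factor factorial interaction design. Every sweep records its axis
#'   values and seeds so it is reproducible from its manifest.
#' @name sweeps
NULL

.new_sweep <- function(sweep, results, ...) {
  structure(list(sweep = sweep, results = results, ...),
            class = "tier_sweep")
}

#' @export
print.tier_sweep <- function(x, ...) {
  cat("<tier_sweep>", x$sweep, "-", nrow(x$results), "rows\n")
  print(utils::head(x$results, 10))
  invisible(x)
}

# per-trial AUC of a tracked-node work series (cumulative accumulation for
# sum/sum_sq/max; the instantaneous series itself for rate)
.metric_auc <- function(trace, level, metric) {
  s <- switch(metric,
    sum = trace$delta_sum[trace$level == level],
    sum_sq = trace$delta_sq[trace$level == level],
    max = trace$delta_max[trace$level == level],
    rate = trace$delta_sum[trace$level == level]
  )
  if (metric == "rate") auc(s) else auc(cumsum(s))
}

#' Work-metric sensitivity sweep
#'
#' Runs one ensemble and evaluates all four work-accumulation metrics in
#' parallel on the same trajectories, reporting the Level-3 vs Level-1 AUC
#' elevation per metric (cumulative accumulation for `sum`, `sum_sq`, `max`;
#' the instantaneous demand series for `rate`). With `eta = 0` all metrics
#' are identically zero and the elevation is flagged as undefined (`NA`).
#'
#' @param config A [network_config()].
#' @param stimulus A [stimulus_config()].
#' @param n_trials Trials per ensemble.
#' @param base_seed Base seed (trial k uses `base_seed + k`).
#' @return A `tier_sweep` whose `results` has one row per metric with mean
#'   Level-1/Level-3 AUCs, percent elevation and the paired-t p-value.
#' @export
metric_sweep <- function(config, stimulus, n_trials = 2000L, base_seed = 0L) {
  metrics <- c("sum", "sum_sq", "max", "rate")
  aucs <- array(NA_real_, c(n_trials, 2L, 4L),
                dimnames = list(NULL, c("L1", "L3"), metrics))
  for (k in seq_len(n_trials)) {
    tr <- run_trial(config, stimulus, seed = base_seed + k, trial_id = k)
    for (m in metrics) {
      aucs[k, 1L, m] <- .metric_auc(tr, 1L, m)
      aucs[k, 2L, m] <- .metric_auc(tr, 3L, m)
    }
  }
  rows <- lapply(metrics, function(m) {
    a1 <- mean(aucs[, "L1", m])
    a3 <- mean(aucs[, "L3", m])
    degenerate <- a1 == 0 && a3 == 0
    p <- if (degenerate) NA_real_ else
      compare_levels(aucs[, "L3", m], aucs[, "L1", m], paired = TRUE)$p
    data.frame(metric = m, auc_l1 = a1, auc_l3 = a3,
               elevation_pct = if (degenerate) NA_real_ else
                 percent_elevation(a3, a1),
               p_value = p, degenerate = degenerate)
  })
  .new_sweep("metric", do.call(rbind, rows),
             n_trials = n_trials, base_seed = base_seed,
             config = config, stimulus = stimulus)
}

#' Input-regime sensitivity sweep
#'
#' Runs one ensemble per input regime (bounded random, equicorrelated
#' Gaussian, sinusoidal) and reports the Level-3 vs Level-1 cumulative-work
#' AUC elevation per regime.
#'
#' @param config A [network_config()].
#' @param n_trials Trials per ensemble.
#' @param base_seed Base seed, shared across regimes.
#' @param regimes Regimes to run.
#' @return A `tier_sweep` with one row per regime.
#' @export
input_regime_sweep <- function(config, n_trials = 2000L, base_seed = 0L,
                               regimes = c("random", "correlated_gaussian",
                                           "sinusoidal")) {
  rows <- lapply(regimes, function(r) {
    es <- run_ensemble(config, stimulus_config(r,
                         n_channels = config$nodes_per_level),
                       n_trials = n_trials, base_seed = base_seed)
    w <- es$auc_summary[es$auc_summary$measure == "work_cum", ]
    data.frame(regime = r, auc_l1 = w$auc_mean[1], auc_l3 = w$auc_mean[3],
               elevation_pct = es$elevation, p_value = es$tests$l3_vs_l1$p)
  })
  .new_sweep("inputs", do.call(rbind, rows),
             n_trials = n_trials, base_seed = base_seed, config = config)
}

#' FFE parameter-grid sweep
#'
#' Runs the siphon model over every combination of the cortical and support
#' fracture-fatigue-entropy thresholds (by default the 6 x 5 reference grid)
#' and records the failure order, both t50 milestones and the lead time.
#'
#' @param cfg Base [siphon_config()]; each cell overrides the FFE pair.
#' @param ffe_cortex,ffe_support Grid axis values.
#' @return A `tier_sweep` with one row per combination.
#' @export
ffe_grid_sweep <- function(cfg = reference_siphon_config(),
                           ffe_cortex = c(3, 4, 5, 6, 7, 8),
                           ffe_support = c(1, 1.5, 2, 2.5, 3)) {
  grid <- expand.grid(ffe_cortex = ffe_cortex, ffe_support = ffe_support,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg$ffe_cortex <- grid$ffe_cortex[i]
    cfg$ffe_support <- grid$ffe_support[i]
    m <- run_siphon(cfg)$milestones
    data.frame(ffe_cortex = grid$ffe_cortex[i],
               ffe_support = grid$ffe_support[i],
               ffe_differential = grid$ffe_cortex[i] - grid$ffe_support[i],
               t50_cortex = m$t50_cortex, t50_support = m$t50_support,
               lead_time = m$lead_time, failure_order = m$failure_order)
  })
  .new_sweep("ffe_grid", do.call(rbind, rows), config = cfg)
}

#' Compensation-factor sweep
#'
#' Varies the compensation intensity with all other parameters fixed and
#' records failure order and milestones per value.
#'
#' @param cfg Base [siphon_config()].
#' @param values Compensation factors (default the prespecified seven).
#' @return A `tier_sweep` with one row per value.
#' @export
compensation_sweep <- function(cfg = reference_siphon_config(),
                               values = c(0.5, 1, 1.5, 2, 2.5, 3, 4)) {
  stopifnot(all(values >= 0))
  rows <- lapply(values, function(v) {
    cfg$comp_factor <- v
    m <- run_siphon(cfg)$milestones
    data.frame(comp_factor = v, t50_cortex = m$t50_cortex,
               t50_support = m$t50_support, lead_time = m$lead_time,
               failure_order = m$failure_order)
  })
  .new_sweep("compensation", do.call(rbind, rows), config = cfg)
}

#' Activation-function sensitivity sweep
#'
#' Runs one ensemble per activation kind (tanh, sigmoid, ReLU, linear) and
#' reports the Level-3 vs Level-1 cumulative-work elevation per kind.
#'
#' @param config Base [network_config()]; each row overrides the activation.
#' @param stimulus A [stimulus_config()].
#' @param n_trials Trials per ensemble.
#' @param base_seed Base seed, shared across activation kinds.
#' @return A `tier_sweep` with one row per activation.
#' @export
activation_sweep <- function(config, stimulus, n_trials = 2000L,
                             base_seed = 0L) {
  kinds <- c("tanh", "sigmoid", "relu", "linear")
  rows <- lapply(kinds, function(kind) {
    cfg <- config
    cfg$activation <- kind
    es <- run_ensemble(cfg, stimulus, n_trials = n_trials,
                       base_seed = base_seed)
    data.frame(activation = kind, elevation_pct = es$elevation,
               p_value = es$tests$l3_vs_l1$p)
  })
  res <- do.call(rbind, rows)
  .new_sweep("activation", res,
             spread_points = diff(range(res$elevation_pct)),
             n_trials = n_trials, base_seed = base_seed, config = config,
             stimulus = stimulus)
}

#' Factorial interaction sweep
#'
#' Full factorial design over FFE ratio (support threshold anchored at 2.0,
#' cortical = ratio x 2.0), compensation factor, and cortical network size
#' (support population scaled as 0.3 x cortical; demand scaled at 3.0 work
#' units per cortical cell and baseline support work at 0.5 per cortical
#' cell, keeping per-cell load comparable across sizes). Records the lead
#' time per cell, marginal means (main effects) per factor, and pairwise
#' cell-mean interaction tables; the interaction assessment is descriptive,
#' as crossover is judged from the sign stability of simple effects.
#'
#' @param cfg Base [siphon_config()].
#' @param ffe_ratio,comp_factor,size Factor levels (defaults give the 27
#'   prespecified combinations).
#' @return A `tier_sweep` with `results` (27 rows), `main_effects` (marginal
#'   mean lead time per factor level, with per-factor effect ranges) and
#'   `interactions` (cell-mean tables per factor pair plus a `crossover`
#'   flag).
#' @export
factorial_interaction_sweep <- function(cfg = reference_siphon_config(),
                                        ffe_ratio = c(2, 3, 4),
                                        comp_factor = c(1, 2, 3),
                                        size = c(500, 1000, 2000)) {
  grid <- expand.grid(ffe_ratio = ffe_ratio, comp_factor = comp_factor,
                      size = size, KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cell <- cfg
    cell$ffe_support <- 2.0
    cell$ffe_cortex <- g$ffe_ratio * 2.0
    cell$comp_factor <- g$comp_factor
    cell$n_cortex0 <- g$size
    cell$n_support0 <- 0.3 * g$size
    cell$w_required <- 3.0 * g$size
    cell$w_baseline <- 0.5 * g$size
    m <- run_siphon(cell)$milestones
    data.frame(ffe_ratio = g$ffe_ratio, comp_factor = g$comp_factor,
               size = g$size, t50_cortex = m$t50_cortex,
               t50_support = m$t50_support, lead_time = m$lead_time,
               failure_order = m$failure_order)
  })
  res <- do.call(rbind, rows)
  factors <- c("ffe_ratio", "comp_factor", "size")
  main_effects <- lapply(factors, function(f) {
    mm <- tapply(res$lead_time, res[[f]], mean)
    data.frame(factor = f, level = as.numeric(names(mm)),
               mean_lead_time = as.numeric(mm))
  })
  main_effects <- do.call(rbind, main_effects)
  effect_range <- vapply(factors, function(f) {
    mm <- main_effects$mean_lead_time[main_effects$factor == f]
    diff(range(mm))
  }, numeric(1))
  pairs <- utils::combn(factors, 2, simplify = FALSE)
  interactions <- lapply(pairs, function(pr) {
    cell_means <- tapply(res$lead_time, res[pr], mean)
    # simple effects of pr[1] at each level of pr[2]: crossover iff the sign
    # of any adjacent-level difference flips across columns
    d <- apply(cell_means, 2, diff)
    d <- matrix(d, ncol = ncol(cell_means))
    crossover <- any(apply(d, 1, function(r) {
      s <- sign(r[r != 0])
      length(unique(s)) > 1
    }))
    list(factors = pr, cell_means = cell_means, crossover = crossover)
  })
  names(interactions) <- vapply(pairs, paste, character(1), collapse = ":")
  .new_sweep("factorial", res, main_effects = main_effects,
             effect_range = effect_range, interactions = interactions,
             config = cfg)
}
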