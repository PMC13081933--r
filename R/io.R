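#' Write a trial-trace table as tidy CSV
#'
#' Columns: `trial_id`, `level`, `iteration`, `delta_sum`, `delta_sq`,
#' `delta_max`, `work_cum`, `entropy_norm`, `lyapunov`.
#'
#' @param trace A trace data.frame from [run_trial()] (or several rbind-ed).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  cols <- c("trial_id", "level", "iteration", "delta_sum", "delta_sq",
            "delta_max", "work_cum", "entropy_norm", "lyapunov")
  stopifnot(all(cols %in% names(trace)))
  utils::write.csv(trace[cols], path, row.names = FALSE)
  invisible(path)
}

#' Write a siphon trajectory as CSV (with milestones JSON alongside)
#'
#' @param traj A `siphon_trajectory` from [run_siphon()].
#' @param path Trajectory CSV path.
#' @param milestones_path Optional milestones JSON path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, milestones_path = NULL) {
  stopifnot(inherits(traj, "siphon_trajectory"))
  utils::write.csv(traj$trajectory, path, row.names = FALSE)
  if (!is.null(milestones_path)) {
    jsonlite::write_json(traj$milestones, milestones_path,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Write an ensemble summary as JSON
#'
#' Serializes per-iteration means/SDs, AUC summaries, the Level-3 elevation
#' and the pairwise tests.
#'
#' @param ensemble A `tier_ensemble` from [run_ensemble()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "tier_ensemble"))
  out <- list(
    n_trials = ensemble$n_trials,
    base_seed = ensemble$base_seed,
    stimulus_regime = ensemble$stimulus$regime,
    per_iteration = ensemble$per_iteration,
    auc_summary = ensemble$auc_summary,
    elevation_pct = ensemble$elevation,
    tests = ensemble$tests
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null", pretty = TRUE)
  invisible(path)
}

#' Build a reproducibility manifest
#'
#' Snapshot of everything needed to reproduce a run bit-for-bit on the same
#' platform RNG: the configuration, the seed list, the package version and
#' any derived constants (e.g. the calibrated baseline failure-rate scalar).
#'
#' @param config Configuration object(s) (a list is serialized as-is).
#' @param seeds Integer seed vector used by the run.
#' @param derived Named list of derived constants.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, seeds = integer(0), derived = list()) {
  structure(
    list(
      package = "tiersim",
      version = as.character(utils::packageVersion("tiersim")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = unclass_deep(config),
      seeds = seeds,
      derived = derived
    ),
    class = "run_manifest"
  )
}

# strip S3 classes recursively so jsonlite serializes configs plainly
unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' Write a manifest as JSON
#'
#' @param manifest A [run_manifest()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a sweep result as CSV
#'
#' @param sweep A `tier_sweep`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "tier_sweep"))
  utils::write.csv(sweep$results, path, row.names = FALSE)
  invisible(path)
}
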