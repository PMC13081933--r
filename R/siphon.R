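#' Siphon model configuration
#'
#' Parameters of the coupled cortical/support population-failure model. A
#' distributed cortical population (1000 cells) carries a constant cognitive
#' demand (`w_required = 3000` work units per time) that must be met
#' regardless of cell death; a small support population (300 cells,
#' e.g. a neuromodulatory nucleus) provides baseline function
#' (`w_baseline = 500`) plus compensation proportional to cortical
#' dysfunction. Per-cell work intensity is capped at `intensity_cap` (the
#' physiological maximum), accumulates over time into a per-cell thermodynamic
#' entropy index `s`, and drives an exponential failure rate
#' `A * exp(s / FFE)`, where the fracture-fatigue-entropy threshold FFE is the
#' population's intrinsic resilience (`ffe_cortex = 6`, `ffe_support = 2` in
#' the reference run).
#'
#' `demand_pool` controls which cells carry the cognitive demand:
#' `"shared"` (default) spreads `w_required` over all functional cells of both
#' populations — the siphon itself, support cells shouldering cortical
#' demand — while the support compensation work is borne by support cells
#' alone; `"cortex_only"` keeps fully separate ledgers
#' (`w_required / n_cortex`).
#'
#' `a_scale` is the baseline failure-rate constant A shared by both
#' populations. Ordering properties (which population fails first) are
#' invariant to A; absolute milestone times are not. [reference_siphon_config()]
#' uses the value calibrated once so that the reference support t50 equals
#' 5.5 time units (see [calibrate_a_scale()]).
#'
#' @param n_cortex0,n_support0 Initial functional cell counts.
#' @param c_per_cell Per-cell capacity (kept at 1; populations are expressed
#'   in capacity units).
#' @param w_required Constant cognitive demand, work units per time.
#' @param w_baseline Baseline support work, work units per time.
#' @param comp_factor Compensation intensity (dimensionless).
#' @param ffe_cortex,ffe_support Fracture-fatigue-entropy thresholds.
#' @param a_scale Baseline failure-rate constant A.
#' @param dt Euler time step (<= 0.1 so milestones resolve to one decimal).
#' @param horizon Simulated time span.
#' @param intensity_cap Maximum work per cell per unit time.
#' @param demand_pool `"shared"` or `"cortex_only"` (see Details).
#' @return An object of class `siphon_config`.
#' @export
siphon_config <- function(n_cortex0 = 1000,
                          n_support0 = 300,
                          c_per_cell = 1.0,
                          w_required = 3000,
                          w_baseline = 500,
                          comp_factor = 2.0,
                          ffe_cortex = 6.0,
                          ffe_support = 2.0,
                          a_scale = 1.0,
                          dt = 0.1,
                          horizon = 20,
                          intensity_cap = 5.0,
                          demand_pool = c("shared", "cortex_only")) {
  demand_pool <- match.arg(demand_pool)
  vals <- c(n_cortex0, n_support0, c_per_cell, w_required, w_baseline,
            ffe_cortex, ffe_support, a_scale, dt, horizon, intensity_cap)
  if (any(vals <= 0)) stop("all siphon parameters must be positive",
                           call. = FALSE)
  if (comp_factor < 0) stop("comp_factor must be non-negative", call. = FALSE)
  if (dt > 0.1 + 1e-12) {
    stop("dt must be <= 0.1 so milestones resolve to one decimal",
         call. = FALSE)
  }
  structure(
    list(n_cortex0 = n_cortex0, n_support0 = n_support0,
         c_per_cell = c_per_cell, w_required = w_required,
         w_baseline = w_baseline, comp_factor = comp_factor,
         ffe_cortex = ffe_cortex, ffe_support = ffe_support,
         a_scale = a_scale, dt = dt, horizon = horizon,
         intensity_cap = intensity_cap, demand_pool = demand_pool),
    class = "siphon_config"
  )
}

#' @export
print.siphon_config <- function(x, ...) {
  cat(sprintf(
    "<siphon_config> %g cortical / %g support cells, FFE %g/%g, A = %g, dt = %g\n",
    x$n_cortex0, x$n_support0, x$ffe_cortex, x$ffe_support, x$a_scale, x$dt))
  invisible(x)
}

# Baseline failure-rate constant calibrated once (root-finding on the
# reference configuration) so that support t50 = 5.5 time units; frozen.
# See calibrate_a_scale().
.A_SCALE_REF <- 0.904289

#' Reference siphon configuration
#'
#' The reference parameterization (1000/300 cells, demand 3000, baseline 500,
#' compensation 2.0, FFE 6.0/2.0, cap 5.0, Euler dt = 0.1, horizon 20, shared
#' demand pool) with the frozen calibrated `a_scale` (~0.9043).
#'
#' @return A [siphon_config()].
#' @export
reference_siphon_config <- function() {
  siphon_config(a_scale = .A_SCALE_REF)
}

#' Support-system workload
#'
#' `W_support = W_baseline + comp_factor * (n_lost / n_cortex0) *
#' n_remaining`: baseline function plus compensation proportional to cortical
#' dysfunction. The compensation term peaks at intermediate cortical loss and
#' vanishes both with an intact cortex (nothing to compensate) and with a
#' fully lost cortex (nothing left to support).
#'
#' @param n_lost Failed cortical cells.
#' @param n_remaining Surviving cortical cells
#'   (`n_lost + n_remaining = n_cortex0`).
#' @param cfg A [siphon_config()].
#' @return Support work in work units per time.
#' @examples
#' support_work(0, 1000, siphon_config())    # 500
#' support_work(500, 500, siphon_config())   # 1000
#' @export
support_work <- function(n_lost, n_remaining, cfg) {
  cfg$w_baseline + cfg$comp_factor * (n_lost / cfg$n_cortex0) * n_remaining
}

#' Per-cell work intensity
#'
#' `min(total_work / n_functional, cap)`, with the denominator floored at a
#' tiny positive constant so an empty population saturates at the cap instead
#' of dividing by zero.
#'
#' @param total_work Work units per time carried by the population.
#' @param n_functional Functional cells.
#' @param cap Physiological maximum intensity.
#' @param floor Division floor (cells).
#' @return Intensity in work units per cell per time, `<= cap`.
#' @examples
#' per_cell_intensity(3000, 1000, 5)  # 3.0
#' @export
per_cell_intensity <- function(total_work, n_functional, cap, floor = 1e-9) {
  stopifnot(cap > 0)
  min(total_work / max(n_functional, floor), cap)
}

#' Entropy-driven failure rate
#'
#' `A * exp(s / FFE)`: the instantaneous failure rate grows exponentially
#' with the accumulated per-cell entropy index `s` and is tempered by the
#' population's fracture-fatigue-entropy threshold. Strictly increasing in
#' `s`, strictly decreasing in FFE; at `s = 0` it equals the baseline A.
#'
#' @param s Accumulated entropy index (>= 0).
#' @param ffe Fracture-fatigue-entropy threshold (> 0).
#' @param a_scale Baseline rate constant A.
#' @return Failure rate in cells per unit time.
#' @examples
#' failure_rate(0, 2, 1)  # 1
#' failure_rate(2, 2, 1)  # e
#' @export
failure_rate <- function(s, ffe, a_scale) {
  stopifnot(ffe > 0)
  a_scale * exp(s / ffe)
}

#' Thermodynamic state index
#'
#' Degradation coordinate `s / FFE`, clamped just below 1: zero in the
#' pristine state, approaching (but never reaching) one at failure, since a
#' zero entropy-generation rate is attained only at infinity.
#'
#' @param s Accumulated entropy index (>= 0).
#' @param ffe Fracture-fatigue-entropy threshold (> 0).
#' @return TSI in \[0, 1).
#' @export
tsi <- function(s, ffe) {
  stopifnot(ffe > 0, all(s >= 0))
  pmin(s / ffe, 1 - 1e-6)
}

#' Microstate count from entropy
#'
#' Inverts the Boltzmann relation `s = k * ln(w)`: the number of microstates
#' (disorder) reached at entropy `s` is `w = exp(s / k)`.
#'
#' @param s Entropy.
#' @param k Boltzmann-like constant (> 0).
#' @return Microstate count, `>= 1` for `s >= 0`.
#' @export
microstate_count <- function(s, k) {
  stopifnot(k > 0)
  exp(s / k)
}

#' One Euler step of the siphon model
#'
#' Explicit Euler composition: compute the two populations' workloads and
#' capped per-cell intensities, integrate the per-cell entropy indices
#' (`s <- s + intensity * dt`), evaluate the failure rates from the updated
#' entropy, and decrement the populations (rates are clipped at
#' `n / dt` so a step never removes more cells than exist).
#'
#' @param state List with `t`, `n_cortex`, `n_support`, `s_cortex`,
#'   `s_support`.
#' @param cfg A [siphon_config()].
#' @return Updated state, including the realized intensities and failure
#'   rates of the step.
#' @export
step_siphon <- function(state, cfg) {
  nc <- state$n_cortex
  ns <- state$n_support
  lost <- cfg$n_cortex0 - nc
  ws <- support_work(lost, nc, cfg)
  pool <- if (cfg$demand_pool == "shared") nc + ns else nc
  ic <- per_cell_intensity(cfg$w_required, pool, cfg$intensity_cap)
  is <- per_cell_intensity(ws, ns, cfg$intensity_cap)
  sc <- state$s_cortex + ic * cfg$dt
  ss <- state$s_support + is * cfg$dt
  rc <- min(failure_rate(sc, cfg$ffe_cortex, cfg$a_scale), nc / cfg$dt)
  rs <- min(failure_rate(ss, cfg$ffe_support, cfg$a_scale), ns / cfg$dt)
  list(t = state$t + cfg$dt,
       n_cortex = max(nc - rc * cfg$dt, 0),
       n_support = max(ns - rs * cfg$dt, 0),
       s_cortex = sc, s_support = ss,
       intensity_cortex = ic, intensity_support = is,
       rate_cortex = rc, rate_support = rs)
}

#' Run the siphon model
#'
#' Integrates the coupled population-failure model over the configured
#' horizon (deterministic; no randomness) and extracts milestones.
#'
#' @param cfg A [siphon_config()].
#' @return An object of class `siphon_trajectory`: a list with `trajectory`
#'   (data.frame with columns `t`, `n_cortex`, `n_support`,
#'   `intensity_cortex`, `intensity_support`, `s_cortex`, `s_support`,
#'   `rate_cortex`, `rate_support`, `tsi_cortex`, `tsi_support`),
#'   `milestones` (see [milestones()]) and `config`.
#' @examples
#' traj <- run_siphon(reference_siphon_config())
#' traj$milestones$t50_support
#' @export
run_siphon <- function(cfg) {
  stopifnot(inherits(cfg, "siphon_config"))
  steps <- round(cfg$horizon / cfg$dt)
  out <- matrix(NA_real_, steps + 1L, 9L)
  colnames(out) <- c("t", "n_cortex", "n_support", "intensity_cortex",
                     "intensity_support", "s_cortex", "s_support",
                     "rate_cortex", "rate_support")
  state <- list(t = 0, n_cortex = cfg$n_cortex0, n_support = cfg$n_support0,
                s_cortex = 0, s_support = 0)
  out[1L, ] <- c(0, cfg$n_cortex0, cfg$n_support0, 0, 0, 0, 0, 0, 0)
  for (k in seq_len(steps)) {
    state <- step_siphon(state, cfg)
    out[k + 1L, ] <- c(state$t, state$n_cortex, state$n_support,
                       state$intensity_cortex, state$intensity_support,
                       state$s_cortex, state$s_support,
                       state$rate_cortex, state$rate_support)
  }
  traj <- as.data.frame(out)
  traj$tsi_cortex <- tsi(traj$s_cortex, cfg$ffe_cortex)
  traj$tsi_support <- tsi(traj$s_support, cfg$ffe_support)
  res <- structure(list(trajectory = traj, config = cfg), class = "siphon_trajectory")
  res$milestones <- milestones(res)
  res
}

#' @export
print.siphon_trajectory <- function(x, ...) {
  m <- x$milestones
  cat("<siphon_trajectory> horizon", x$config$horizon, "time units\n")
  cat(sprintf("  support t50 = %s, cortical t50 = %s, lead = %s\n",
              format(m$t50_support), format(m$t50_cortex),
              format(m$lead_time)))
  invisible(x)
}

# first time a series crosses a threshold from above, linearly interpolated
.first_crossing <- function(tv, pop, threshold) {
  i <- which(pop <= threshold)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(tv[1L])
  p0 <- pop[i - 1L]
  p1 <- pop[i]
  tv[i - 1L] + (p0 - threshold) / (p0 - p1) * (tv[i] - tv[i - 1L])
}

#' Milestones of a siphon trajectory
#'
#' Extracts the landmark quantities: t50 and t90 (times of 50% and 90%
#' population loss, linearly interpolated between grid points; `NA` if the
#' threshold is never crossed within the horizon), the peak realized failure
#' rate and its time per population, the first time each population's
#' per-cell intensity reaches the cap, and the lead time
#' `t50_cortex - t50_support` (positive when the support population fails
#' first).
#'
#' @param traj A `siphon_trajectory` (or its `trajectory` data.frame plus a
#'   config).
#' @param cfg Configuration; defaults to the trajectory's own.
#' @return Named list of milestone values.
#' @export
milestones <- function(traj, cfg = NULL) {
  if (inherits(traj, "siphon_trajectory")) {
    cfg <- traj$config
    tr <- traj$trajectory
  } else {
    stopifnot(!is.null(cfg))
    tr <- traj
  }
  t50c <- .first_crossing(tr$t, tr$n_cortex, 0.5 * cfg$n_cortex0)
  t50s <- .first_crossing(tr$t, tr$n_support, 0.5 * cfg$n_support0)
  t90c <- .first_crossing(tr$t, tr$n_cortex, 0.1 * cfg$n_cortex0)
  t90s <- .first_crossing(tr$t, tr$n_support, 0.1 * cfg$n_support0)
  cap_c <- tr$t[which(tr$intensity_cortex >= cfg$intensity_cap)[1]]
  cap_s <- tr$t[which(tr$intensity_support >= cfg$intensity_cap)[1]]
  list(
    t50_cortex = t50c, t50_support = t50s,
    t90_cortex = t90c, t90_support = t90s,
    peak_rate_cortex = max(tr$rate_cortex),
    peak_rate_cortex_t = tr$t[which.max(tr$rate_cortex)],
    peak_rate_support = max(tr$rate_support),
    peak_rate_support_t = tr$t[which.max(tr$rate_support)],
    cap_time_cortex = cap_c, cap_time_support = cap_s,
    lead_time = t50c - t50s,
    failure_order = if (is.na(t50s) && is.na(t50c)) "tie"
      else if (is.na(t50c)) "support_first"
      else if (is.na(t50s)) "cortex_first"
      else if (isTRUE(all.equal(t50s, t50c))) "tie"
      else if (t50s < t50c) "support_first" else "cortex_first"
  )
}

#' Calibrate the baseline failure-rate constant
#'
#' One-time calibration of the single shared scalar A: root-finds the value
#' for which the reference-run support population crosses 50% loss at
#' `target_t50` time units. The result (~0.9043 for the defaults) is frozen
#' in [reference_siphon_config()] and recorded in run manifests. Ordering
#' properties of the model are invariant to A; only absolute milestone times
#' depend on it.
#'
#' @param cfg Base configuration (the reference parameters by default).
#' @param target_t50 Target support t50 in time units.
#' @param interval Search interval for A.
#' @return Calibrated `a_scale` (scalar).
#' @export
calibrate_a_scale <- function(cfg = siphon_config(), target_t50 = 5.5,
                              interval = c(1e-3, 50)) {
  f <- function(a) {
    cfg$a_scale <- a
    run_siphon(cfg)$milestones$t50_support - target_t50
  }
  stats::uniroot(f, interval, tol = 1e-8)$root
}
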