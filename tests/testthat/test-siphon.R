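test_that("support workload follows baseline-plus-compensation", {
  cfg <- siphon_config()
  expect_equal(support_work(0, 1000, cfg), 500)      # intact cortex
  expect_equal(support_work(1000, 0, cfg), 500)      # nothing left to support
  expect_equal(support_work(500, 500, cfg), 1000)    # peak at intermediate loss
  # compensation term is maximal at half loss for fixed total
  losses <- seq(0, 1000, by = 50)
  w <- support_work(losses, 1000 - losses, cfg)
  expect_equal(losses[which.max(w)], 500)
})

test_that("per-cell intensity divides, caps, and saturates on empty populations", {
  expect_equal(per_cell_intensity(3000, 1000, 5), 3)
  expect_equal(per_cell_intensity(10000, 1000, 5), 5)   # capped
  expect_equal(per_cell_intensity(500, 0, 5), 5)        # floor -> saturation
  set.seed(31)
  for (i in 1:25) {
    expect_lte(per_cell_intensity(runif(1, 0, 1e5), runif(1, 0, 1e4), 5), 5)
  }
})

test_that("failure rate is exponential in accumulated entropy", {
  expect_equal(failure_rate(0, 6, 1.7), 1.7)            # s = 0 -> A
  expect_equal(failure_rate(2, 2, 1), exp(1))           # s = FFE -> A*e
  # halving FFE at fixed s squares the ratio rate/A
  s <- 1.3; A <- 0.7
  r1 <- failure_rate(s, 4, A) / A
  r2 <- failure_rate(s, 2, A) / A
  expect_equal(r2, r1^2, tolerance = 1e-12)
  # strictly increasing in s over a grid
  grid <- seq(0, 10, by = 0.25)
  rates <- failure_rate(grid, 6, 1)
  expect_true(all(diff(rates) > 0))
})

test_that("thermodynamic state index stays in [0, 1)", {
  expect_equal(tsi(0, 6), 0)
  expect_equal(tsi(0.99 * 6, 6), 0.99)
  expect_lt(tsi(1e6, 6), 1)
  s <- seq(0, 20, by = 0.5)
  expect_true(all(tsi(s, 2) >= 0 & tsi(s, 2) < 1))
})

test_that("microstate count inverts the Boltzmann relation", {
  expect_equal(microstate_count(0, 1), 1)
  expect_equal(microstate_count(2, 2), exp(1))
  s <- seq(0, 5, by = 0.5)
  expect_true(all(diff(microstate_count(s, 1.4)) > 0))
})

test_that("reference run: support fails first at the calibrated milestones", {
  traj <- run_siphon(reference_siphon_config())
  m <- traj$milestones
  expect_equal(m$failure_order, "support_first")
  expect_equal(m$t50_support, 5.5, tolerance = 0.1 / 5.5)
  expect_gt(m$lead_time, 0)
  tr <- traj$trajectory
  # populations monotone non-increasing and non-negative
  expect_true(all(diff(tr$n_cortex) <= 1e-9) && all(tr$n_cortex >= 0))
  expect_true(all(diff(tr$n_support) <= 1e-9) && all(tr$n_support >= 0))
  # accumulated entropy indices monotone non-decreasing
  expect_true(all(diff(tr$s_cortex) >= 0) && all(diff(tr$s_support) >= 0))
  # intensities respect the cap
  expect_true(all(tr$intensity_cortex <= 5 & tr$intensity_support <= 5))
  expect_true(all(tr$tsi_cortex >= 0 & tr$tsi_cortex < 1))
})

test_that("the frozen reference a_scale reproduces the one-time calibration", {
  expect_equal(calibrate_a_scale(), reference_siphon_config()$a_scale,
               tolerance = 1e-4)
})

test_that("a symmetric configuration produces identical trajectories", {
  cfg <- siphon_config(n_cortex0 = 500, n_support0 = 500, w_required = 1000,
                       w_baseline = 1000, comp_factor = 1e-12,
                       ffe_cortex = 3, ffe_support = 3,
                       demand_pool = "cortex_only")
  tr <- run_siphon(cfg)$trajectory
  expect_equal(tr$n_cortex, tr$n_support, tolerance = 1e-9)
  expect_equal(tr$s_cortex, tr$s_support, tolerance = 1e-9)
})

test_that("with no compensation and equal per-capita load, FFE alone sets the order", {
  # equal populations and work; lower FFE must fail first in either assignment
  base <- list(n_cortex0 = 500, n_support0 = 500, w_required = 1000,
               w_baseline = 1000, comp_factor = 1e-12,
               demand_pool = "cortex_only")
  lowc <- do.call(siphon_config, c(base, ffe_cortex = 2, ffe_support = 4))
  lows <- do.call(siphon_config, c(base, ffe_cortex = 4, ffe_support = 2))
  expect_equal(run_siphon(lowc)$milestones$failure_order, "cortex_first")
  expect_equal(run_siphon(lows)$milestones$failure_order, "support_first")
})

test_that("doubling the baseline rate constant brings every milestone earlier", {
  cfg1 <- reference_siphon_config()
  cfg2 <- cfg1; cfg2$a_scale <- 2 * cfg1$a_scale
  m1 <- run_siphon(cfg1)$milestones
  m2 <- run_siphon(cfg2)$milestones
  for (f in c("t50_cortex", "t50_support", "t90_cortex", "t90_support")) {
    expect_lt(m2[[f]], m1[[f]])
  }
})

test_that("milestone interpolation recovers exact crossings of a linear decline", {
  # linear decline from 300 to 0 over [0, 10]: t50 at exactly 5
  tv <- seq(0, 10, by = 0.1)
  fake <- data.frame(t = tv, n_cortex = 1000, n_support = 300 * (1 - tv / 10),
                     intensity_cortex = 0, intensity_support = 0,
                     rate_cortex = 0, rate_support = 300 / 10)
  m <- milestones(fake, cfg = siphon_config())
  expect_equal(m$t50_support, 5)
  expect_equal(m$t90_support, 9)
  # a population that never crosses has no milestone
  expect_true(is.na(m$t50_cortex))
  expect_equal(m$failure_order, "support_first")
})

test_that("shared demand pool starts below, separate ledgers start at 3.0", {
  st0 <- list(t = 0, n_cortex = 1000, n_support = 300, s_cortex = 0,
              s_support = 0)
  shared <- step_siphon(st0, siphon_config(demand_pool = "shared"))
  solo <- step_siphon(st0, siphon_config(demand_pool = "cortex_only"))
  expect_equal(solo$intensity_cortex, 3.0)
  expect_equal(shared$intensity_cortex, 3000 / 1300)
  expect_equal(shared$intensity_support, 500 / 300)
})

test_that("config validation rejects non-positive parameters and coarse dt", {
  expect_error(siphon_config(ffe_cortex = 0), "positive")
  expect_error(siphon_config(dt = 0.5), "dt")
})
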