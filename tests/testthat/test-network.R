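test_that("architecture wiring matches the convergent columnar design", {
  st <- build_architecture(network_config(), seed = 1)
  w <- st$weights
  expect_length(w$w1, 4)           # Level 1: one external channel per node
  expect_length(w$w2, 4)           # Level 2: one-to-one relay from Level 1
  expect_equal(dim(w$w3), c(4, 4)) # Level 3: fan-in from all unimodal nodes
  all_w <- c(w$w1, w$w2, w$w3)
  expect_true(all(all_w >= 0.1 & all_w <= 0.9))

  # zero-width init interval pins every weight
  st0 <- build_architecture(network_config(weight_init_range = c(0.5, 0.5)),
                            seed = 2)
  expect_true(all(unlist(st0$weights) == 0.5))

  # seeded determinism
  a <- build_architecture(network_config(), seed = 99)
  b <- build_architecture(network_config(), seed = 99)
  expect_identical(a$weights, b$weights)
})

test_that("config invariants are enforced", {
  expect_error(network_config(eta = -0.1), "eta")
  expect_error(network_config(eta = 1.5), "eta")
  expect_error(network_config(weight_init_range = c(-0.1, 0.9)),
               "weight_init_range")
  expect_error(network_config(n_iterations = 0), "n_iterations")
  expect_error(network_config(tracked_node = 5), "tracked_node")
})

test_that("activation functions follow their standard definitions", {
  expect_equal(activate(1, 1, "tanh"), tanh(1), tolerance = 1e-12)
  expect_equal(round(activate(1, 1, "tanh"), 5), 0.76159)
  # zero pre-activation
  expect_equal(activate(c(0.3, 0.7), c(0, 0), "tanh"), 0)
  expect_equal(activate(c(0.3, 0.7), c(0, 0), "relu"), 0)
  expect_equal(activate(c(0.3, 0.7), c(0, 0), "linear"), 0)
  expect_equal(activate(c(0.3, 0.7), c(0, 0), "sigmoid"), 0.5)
  # open-interval ranges (checked where the bound is fp-representable)
  for (z in seq(-15, 15, by = 2.7)) {
    expect_true(abs(activate(1, z, "tanh")) < 1)
    s <- activate(1, z, "sigmoid")
    expect_true(s > 0 && s < 1)
    expect_gte(activate(1, z, "relu"), 0)
  }
  expect_error(activate(c(1, 2), 1, "tanh"), "length")
  expect_error(activate(1, 1, "softmax"), "unknown")
})

test_that("Hebbian rule moves weights toward inputs with the stated delta", {
  u <- hebbian_update(0.1, 0.6, 0.1)
  expect_equal(u$deltas, 0.05)
  expect_equal(u$weights, 0.15)
  # fixed point at w = x
  expect_equal(hebbian_update(0.5, 0.5, 0.3)$deltas, 0)
  # eta = 0 freezes everything
  u0 <- hebbian_update(c(0.2, 0.8), c(0.9, 0.1), 0)
  expect_equal(u0$weights, c(0.2, 0.8))
  expect_equal(u0$deltas, c(0, 0))
  # matrix weights with vector afferents (Level-3 layout)
  W <- matrix(0.5, 2, 2)
  um <- hebbian_update(W, c(0.1, 0.9), 0.1)
  expect_equal(um$weights, matrix(c(0.46, 0.46, 0.54, 0.54), 2, 2))
})

test_that("constant input drives the Level-1 weight gap down geometrically", {
  # closed form: |w(t) - x| = (1 - eta)^t |w(0) - x|
  cfg <- network_config(eta = 0.25)
  st <- build_architecture(cfg, seed = 4)
  x <- rep(0.55, 4)
  gap0 <- abs(st$weights$w1 - x)
  for (t in 1:12) {
    st <- step_network(st, x)$state
    expect_equal(abs(st$weights$w1 - x), gap0 * 0.75^t, tolerance = 1e-12)
  }
})

test_that("a zero learning rate computes activations but changes nothing", {
  cfg <- network_config(eta = 0)
  st <- build_architecture(cfg, seed = 8)
  res <- step_network(st, rep(0.5, 4))
  expect_true(all(abs(res$activations$y1) > 0))
  expect_identical(res$state$weights, st$weights)
  expect_equal(unlist(res$deltas), unlist(res$deltas) * 0)
})

test_that("work metrics aggregate magnitudes without cancellation", {
  expect_equal(work_metrics(list(c(0.1, 0.1)), "sum"), 0.2)
  expect_equal(work_metrics(list(c(0.1, 0.1)), "sum_sq"), 0.02)
  expect_equal(work_metrics(list(c(0.1, 0.1)), "max"), 0.1)
  # rate equals the per-iteration sum for unit steps
  d <- list(c(0.1, 0.2), c(0.05), c(0.3, 0.1, 0.1))
  expect_equal(work_metrics(d, "rate"), work_metrics(d, "sum"))
  # empty iteration contributes zero under every metric
  for (m in c("sum", "sum_sq", "max", "rate")) {
    expect_equal(work_metrics(list(numeric(0)), m), 0)
  }
  # opposing updates of equal magnitude add: entropy cannot cancel across sites
  expect_equal(work_metrics(list(c(0.2, -0.2)), "sum"), 0.4)
  expect_error(work_metrics(list(0.1), "median"), "arg")
})

test_that("Shannon entropy matches closed forms and validates input", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(1, 0, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.25, 0.75)),
               -(0.25 * log2(0.25) + 0.75 * log2(0.75)))
  expect_equal(round(shannon_entropy(c(0.25, 0.75)), 4), 0.8113)
  expect_error(shannon_entropy(c(-0.1, 1.1)), "non-negative")
  expect_error(shannon_entropy(c(0.3, 0.3)), "sum to 1")
})

test_that("level entropy is normalized, maximal iff equal magnitudes", {
  expect_equal(level_entropy(c(0.3, 0.3, 0.3, 0.3)), 1)
  expect_equal(level_entropy(c(-0.2, 0.2, 0.2, -0.2)), 1)  # magnitudes equal
  expect_equal(level_entropy(c(0, 0, 0.7, 0)), 0)
  expect_equal(level_entropy(c(0.2, 0.6)), shannon_entropy(c(0.25, 0.75)))
  expect_equal(level_entropy(c(0, 0, 0, 0)), 1)  # all-zero falls back to uniform
  set.seed(21)
  for (i in 1:50) {
    h <- level_entropy(runif(4, -1, 1))
    expect_true(h >= 0 && h <= 1)
  }
})

test_that("one-shot Lyapunov probe recovers log-gain of a linear map", {
  # linear activation, uniform weight g at Level 1: lambda_1 = log(g)
  for (g in c(0.3, 0.8)) {
    cfg <- network_config(activation = "linear",
                          weight_init_range = c(g, g))
    st <- build_architecture(cfg, seed = 1)
    lam <- lyapunov_probe(st, rep(0.5, 4), epsilon = 0.001)
    expect_equal(lam[1], log(g), tolerance = 1e-9)
    # Level 2 compounds the gain: lambda_2 = log(g^2)
    expect_equal(lam[2], 2 * log(g), tolerance = 1e-9)
  }
  # saturated tanh regime: derivative vanishes, exponent strongly negative
  stsat <- build_architecture(network_config(), seed = 1)
  stsat$weights$w1 <- rep(0.9, 4)
  lam_sat <- lyapunov_probe(stsat, rep(50, 4))
  expect_lt(lam_sat[1], -5)
})

test_that("trial traces are deterministic, monotone in work, and bounded", {
  cfg <- default_net()
  stim <- default_stim()
  a <- run_trial(cfg, stim, seed = 123)
  b <- run_trial(cfg, stim, seed = 123)
  expect_identical(a, b)
  expect_equal(nrow(a), 3 * 20)
  for (l in 1:3) {
    w <- a$work_cum[a$level == l]
    expect_true(all(diff(w) >= 0))            # cumulative work never decreases
    expect_true(all(a$delta_sum[a$level == l] >= 0))
  }
  expect_true(all(a$entropy_norm >= 0 & a$entropy_norm <= 1))
})

test_that("per-iteration entropy generation declines as learning stabilizes", {
  # constant-mean stimuli: the mean work increment late in learning is below
  # the early-transient increment, across a 200-trial ensemble
  es <- cached_ensemble("random", n_trials = 200, base_seed = 42)
  pi <- es$per_iteration
  for (l in 1:3) {
    m2 <- pi$delta_sum_mean[pi$level == l & pi$iteration == 2]
    m15 <- pi$delta_sum_mean[pi$level == l & pi$iteration == 15]
    expect_lt(m15, m2)
  }
})
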