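# shared fixtures: small ensembles are cached per test run so several test
# files can reuse the same trajectories

default_net <- function(...) network_config(...)
default_stim <- function(regime = "random") stimulus_config(regime)

.cache <- new.env(parent = emptyenv())

cached_ensemble <- function(regime = "random", n_trials = 200, base_seed = 42,
                            ...) {
  key <- paste(regime, n_trials, base_seed, ...)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- run_ensemble(network_config(...),
                                  stimulus_config(regime),
                                  n_trials = n_trials, base_seed = base_seed)
  }
  .cache[[key]]
}

# independently coded Welch / paired t for cross-checking compare_levels
brute_force_t <- function(x, y, paired) {
  if (paired) {
    d <- x - y
    n <- length(d)
    t <- mean(d) / (sd(d) / sqrt(n))
    df <- n - 1
  } else {
    vx <- var(x) / length(x)
    vy <- var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(vx + vy)
    df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  }
  list(t = t, p = 2 * pt(-abs(t), df))
}
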