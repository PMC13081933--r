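#' Network configuration
#'
#' Parameters of the three-level convergent columnar network. Level 1 holds
#' `nodes_per_level` primary nodes, each with a single external input channel;
#' Level 2 holds the same number of unimodal nodes wired one-to-one to Level 1
#' (redundant relay); Level 3 holds the heteromodal nodes, each receiving
#' input from *all* unimodal nodes (fan-in `nodes_per_level`). Every
#' connection carries one plastic weight, initialized uniformly on
#' `weight_init_range` (the default \[0.1, 0.9\] keeps tanh pre-activations
#' away from saturation).
#'
#' Learning uses the rule `dw = eta * (x - w)`, which tracks each weight
#' exponentially toward its afferent value; with a constant afferent `x` the
#' gap closes geometrically, `|w(t) - x| = (1 - eta)^t * |w(0) - x|`.
#'
#' Two Lyapunov estimators are available (see [run_trial()]):
#' `"twin"` (default) evolves a second, identically-seeded learner whose
#' external inputs are all shifted by `+lyapunov_epsilon` and reports the
#' log-ratio of tracked-level activation distance after vs before each
#' iteration's weight update; `"probe"` reports the one-shot input-perturbation
#' response `log(d / (epsilon * sqrt(n)))` of the frozen forward map.
#'
#' @param nodes_per_level Nodes per hierarchical level (default 4).
#' @param eta Learning rate in \[0, 1\] (0 is admitted as the degenerate
#'   no-learning diagnostic).
#' @param weight_init_range Length-2 interval within (0, 1).
#' @param activation One of `"tanh"`, `"sigmoid"`, `"relu"`, `"linear"`.
#' @param n_iterations Learning iterations per trial.
#' @param tracked_node 1-based index of the representative node tracked at
#'   each level.
#' @param lyapunov_epsilon Input perturbation magnitude.
#' @param lyapunov_mode `"twin"` or `"probe"`.
#' @return An object of class `network_config`.
#' @examples
#' cfg <- network_config()
#' st <- build_architecture(cfg, seed = 1)
#' lengths(st$weights)
#' @export
network_config <- function(nodes_per_level = 4L,
                           eta = 0.1,
                           weight_init_range = c(0.1, 0.9),
                           activation = c("tanh", "sigmoid", "relu", "linear"),
                           n_iterations = 20L,
                           tracked_node = 1L,
                           lyapunov_epsilon = 0.001,
                           lyapunov_mode = c("twin", "probe")) {
  activation <- match.arg(activation)
  lyapunov_mode <- match.arg(lyapunov_mode)
  nodes_per_level <- as.integer(nodes_per_level)
  n_iterations <- as.integer(n_iterations)
  tracked_node <- as.integer(tracked_node)
  # eta = 0 is admitted as a degenerate diagnostic (no learning, zero work)
  if (!(eta >= 0 && eta <= 1)) stop("eta must lie in [0, 1]", call. = FALSE)
  stopifnot(length(weight_init_range) == 2L,
            weight_init_range[1] <= weight_init_range[2])
  if (weight_init_range[1] < 0 || weight_init_range[2] > 1) {
    stop("weight_init_range must lie within [0, 1]", call. = FALSE)
  }
  if (n_iterations < 1L) stop("n_iterations must be >= 1", call. = FALSE)
  if (tracked_node < 1L || tracked_node > nodes_per_level) {
    stop("tracked_node out of range", call. = FALSE)
  }
  if (lyapunov_epsilon <= 0) stop("lyapunov_epsilon must be > 0", call. = FALSE)
  structure(
    list(n_levels = 3L, nodes_per_level = nodes_per_level, eta = eta,
         weight_init_range = weight_init_range, activation = activation,
         n_iterations = n_iterations, tracked_node = tracked_node,
         lyapunov_epsilon = lyapunov_epsilon, lyapunov_mode = lyapunov_mode),
    class = "network_config"
  )
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf(
    "<network_config> 3 x %d nodes, %s activation, eta = %g, %d iterations\n",
    x$nodes_per_level, x$activation, x$eta, x$n_iterations))
  invisible(x)
}

#' Build the network state
#'
#' Wires the convergent columnar architecture and draws every weight uniformly
#' from `config$weight_init_range`. Level-1 and Level-2 nodes carry one
#' incoming weight each; Level-3 nodes carry one weight per unimodal node.
#'
#' @param config A [network_config()].
#' @param seed Optional integer seed; when given, `set.seed(seed)` is called
#'   so identical seeds yield bit-identical weights.
#' @return An object of class `network_state`: a list with `weights`
#'   (list `w1`, `w2` numeric vectors; `w3` a nodes x afferents matrix) and
#'   the originating config.
#' @export
build_architecture <- function(config, seed = NULL) {
  stopifnot(inherits(config, "network_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$nodes_per_level
  lo <- config$weight_init_range[1]
  hi <- config$weight_init_range[2]
  structure(
    list(
      weights = list(
        w1 = stats::runif(n, lo, hi),
        w2 = stats::runif(n, lo, hi),
        w3 = matrix(stats::runif(n * n, lo, hi), nrow = n, ncol = n)
      ),
      config = config
    ),
    class = "network_state"
  )
}

#' Node activation
#'
#' Computes the activation of a single node, `f(sum(w * x))`, for the four
#' supported activation kinds. tanh is bounded in (-1, 1), sigmoid in (0, 1),
#' relu is `max(0, .)` and linear is the identity on the pre-activation.
#'
#' @param weights,inputs Numeric vectors of equal length.
#' @param kind Activation name.
#' @return Scalar activation.
#' @examples
#' activate(1, 1, "tanh")    # tanh(1) ~ 0.76159
#' @export
activate <- function(weights, inputs, kind = "tanh") {
  if (length(weights) != length(inputs)) {
    stop("weights and inputs must have the same length", call. = FALSE)
  }
  z <- sum(weights * inputs)
  switch(kind,
    tanh = tanh(z),
    sigmoid = 1 / (1 + exp(-z)),
    relu = max(0, z),
    linear = z,
    stop("unknown activation kind: ", kind, call. = FALSE)
  )
}

# vectorized forward pass for one level: rows of W are nodes
.activate_level <- function(W, x, kind) {
  z <- as.vector(W %*% x)
  switch(kind,
    tanh = tanh(z),
    sigmoid = 1 / (1 + exp(-z)),
    relu = pmax(0, z),
    linear = z
  )
}

#' Forward pass
#'
#' Propagates an external input vector through the three levels with the
#' current weights (no learning).
#'
#' @param state A `network_state`.
#' @param external_inputs Numeric vector, one entry per Level-1 node.
#' @return List of activation vectors `y1`, `y2`, `y3`.
#' @export
forward_pass <- function(state, external_inputs) {
  stopifnot(inherits(state, "network_state"))
  cfg <- state$config
  n <- cfg$nodes_per_level
  if (length(external_inputs) != n) {
    stop("external_inputs must have one entry per Level-1 node", call. = FALSE)
  }
  k <- cfg$activation
  w <- state$weights
  y1 <- .activate_level(diag(w$w1, n), external_inputs, k)
  y2 <- .activate_level(diag(w$w2, n), y1, k)
  y3 <- .activate_level(w$w3, y2, k)
  list(y1 = y1, y2 = y2, y3 = y3)
}

#' Hebbian weight update
#'
#' Applies `dw_i = eta * (x_i - w_i)` and returns both the new weights and the
#' absolute change magnitudes, which feed the work (entropy-generation)
#' accounting. `w = x` is a fixed point; `eta = 0` leaves weights untouched.
#'
#' @param weights Numeric vector (or matrix) of current weights.
#' @param inputs Afferent values, same shape as `weights` (for a matrix of
#'   node-row weights, a vector of afferents recycled across rows).
#' @param eta Learning rate in \[0, 1\].
#' @return List with `weights` (updated) and `deltas` (absolute magnitudes,
#'   same shape).
#' @examples
#' hebbian_update(0.1, 0.6, 0.1)   # dw = 0.05, new w = 0.15
#' @export
hebbian_update <- function(weights, inputs, eta) {
  if (!(eta >= 0 && eta <= 1)) stop("eta must lie in [0, 1]", call. = FALSE)
  if (is.matrix(weights)) {
    x <- if (is.matrix(inputs)) inputs else
      matrix(inputs, nrow(weights), ncol(weights), byrow = TRUE)
  } else {
    if (length(inputs) != length(weights)) {
      stop("weights and inputs must have the same length", call. = FALSE)
    }
    x <- inputs
  }
  d <- eta * (x - weights)
  list(weights = weights + d, deltas = abs(d))
}

#' One learning step of the whole network
#'
#' Computes the forward pass bottom-up with the current weights, then applies
#' the Hebbian update at every node using that node's afferent values in this
#' iteration: the external input for Level 1, the presynaptic activations for
#' Levels 2 and 3.
#'
#' @param state A `network_state`.
#' @param external_inputs Numeric vector, one entry per Level-1 node.
#' @return List with `state` (updated weights), `activations` (the forward
#'   pass used for the update) and `deltas` (per-level absolute weight-change
#'   magnitudes: vectors `d1`, `d2` and matrix `d3`).
#' @export
step_network <- function(state, external_inputs) {
  a <- forward_pass(state, external_inputs)
  eta <- state$config$eta
  w <- state$weights
  u1 <- hebbian_update(w$w1, external_inputs, eta)
  u2 <- hebbian_update(w$w2, a$y1, eta)
  u3 <- hebbian_update(w$w3, a$y2, eta)
  state$weights <- list(w1 = u1$weights, w2 = u2$weights, w3 = u3$weights)
  list(state = state, activations = a,
       deltas = list(d1 = u1$deltas, d2 = u2$deltas, d3 = u3$deltas))
}

#' One-shot Lyapunov probe
#'
#' Single forward-map sensitivity estimate: runs the frozen network once with
#' `external_inputs` and once with every input shifted by `+epsilon`, and
#' returns `log(d / (epsilon * sqrt(n)))` per level, where `d` is the
#' Euclidean distance between the two activation vectors of that level and
#' `n` the number of perturbed inputs. For a linear map with uniform gain `g`
#' this equals `log(g)` exactly. A zero distance is floored at machine-tiny,
#' yielding a large negative exponent.
#'
#' @param state A `network_state`.
#' @param external_inputs Input vector.
#' @param epsilon Perturbation magnitude (> 0).
#' @return Numeric vector of length 3 (one probe value per level).
#' @export
lyapunov_probe <- function(state, external_inputs,
                           epsilon = state$config$lyapunov_epsilon) {
  stopifnot(epsilon > 0)
  a <- forward_pass(state, external_inputs)
  b <- forward_pass(state, external_inputs + epsilon)
  n <- length(external_inputs)
  vapply(1:3, function(l) {
    d <- sqrt(sum((b[[l]] - a[[l]])^2))
    log(max(d, .Machine$double.xmin) / (epsilon * sqrt(n)))
  }, numeric(1))
}

# distance between two activation lists at each level
.act_dist <- function(a, b) {
  vapply(1:3, function(l) sqrt(sum((b[[l]] - a[[l]])^2)), numeric(1))
}

#' Run one learning trial
#'
#' Runs `config$n_iterations` learning iterations from a fresh seeded weight
#' draw and returns the tidy per-iteration trace of the tracked node at each
#' level. Stimuli are redrawn every iteration from the given regime.
#'
#' The work (thermodynamic entropy-generation) columns are per-synapse
#' intensities of the tracked node: `delta_sum` is the mean absolute weight
#' change over the node's afferents, `delta_sq` the mean squared change,
#' `delta_max` the largest single-synapse change, and `work_cum` the running
#' sum of `delta_sum`. Entropy accumulates at individual modification sites
#' (material points), so cross-level comparisons are made on the per-synapse
#' intensity scale rather than on raw node totals, which would scale with
#' fan-in. Node-level totals remain available by applying [work_metrics()] to
#' the raw delta lists of [step_network()].
#'
#' `entropy_norm` is the normalized Shannon entropy of the level's activation
#' magnitudes ([level_entropy()]); `lyapunov` is the per-iteration stability
#' estimate under `config$lyapunov_mode`.
#'
#' @param config A [network_config()].
#' @param stimulus A [stimulus_config()].
#' @param seed Integer seed: the trial is bit-reproducible given the seed.
#' @param trial_id Identifier copied into the trace.
#' @return A data.frame with columns `trial_id`, `level`, `iteration`,
#'   `delta_sum`, `delta_sq`, `delta_max`, `work_cum`, `entropy_norm`,
#'   `lyapunov`.
#' @examples
#' tr <- run_trial(network_config(), stimulus_config("random"), seed = 1)
#' head(tr)
#' @export
run_trial <- function(config, stimulus, seed, trial_id = seed) {
  stopifnot(inherits(config, "network_config"),
            inherits(stimulus, "stimulus_config"))
  if (stimulus$n_channels != config$nodes_per_level) {
    stop("stimulus channels must match nodes_per_level", call. = FALSE)
  }
  set.seed(seed)
  state <- build_architecture(config)
  twin <- if (config$lyapunov_mode == "twin") state else NULL
  eps <- config$lyapunov_epsilon
  nit <- config$n_iterations
  k <- config$tracked_node
  ds <- dq <- dm <- Hn <- lam <- matrix(NA_real_, 3, nit)
  for (t in seq_len(nit)) {
    x <- draw_stimulus(stimulus, t)
    if (config$lyapunov_mode == "twin") {
      a <- forward_pass(state, x)
      b <- forward_pass(twin, x + eps)
      d_pre <- .act_dist(a, b)
      st <- step_network(state, x)
      tw <- step_network(twin, x + eps)
      state <- st$state
      twin <- tw$state
      d_post <- .act_dist(forward_pass(state, x), forward_pass(twin, x + eps))
      lam[, t] <- log(pmax(d_post, .Machine$double.xmin) /
                        pmax(d_pre, .Machine$double.xmin))
      a <- st$activations
      deltas <- st$deltas
    } else {
      lam[, t] <- lyapunov_probe(state, x, eps)
      st <- step_network(state, x)
      state <- st$state
      a <- st$activations
      deltas <- st$deltas
    }
    trk <- list(deltas$d1[k], deltas$d2[k], deltas$d3[k, ])
    ds[, t] <- vapply(trk, mean, numeric(1))
    dq[, t] <- vapply(trk, function(d) mean(d^2), numeric(1))
    dm[, t] <- vapply(trk, max, numeric(1))
    Hn[, t] <- vapply(a, level_entropy, numeric(1))
  }
  data.frame(
    trial_id = trial_id,
    level = rep(1:3, each = nit),
    iteration = rep(seq_len(nit), times = 3),
    delta_sum = as.vector(t(ds)),
    delta_sq = as.vector(t(dq)),
    delta_max = as.vector(t(dm)),
    work_cum = as.vector(apply(ds, 1, cumsum)),
    entropy_norm = as.vector(t(Hn)),
    lyapunov = as.vector(t(lam))
  )
}
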