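#' Stimulus configuration
#'
#' Describes one of the three input regimes fed to the Level-1 nodes of the
#' hierarchical network: bounded random inputs (the baseline condition),
#' equicorrelated Gaussian inputs, or deterministic sinusoids with a distinct
#' frequency per channel.
#'
#' All regimes emit values in \[0, 1\]. The random regime draws
#' `U[base - half_range, base + half_range]` plus an additive uniform noise
#' term on `[-noise_halfwidth, +noise_halfwidth]`, i.e. `U[0.4, 0.6] +/- 0.05`
#' under the defaults, so every draw lies in \[0.35, 0.65\]. The Gaussian
#' regime has mean `base`, standard deviation `gaussian_sd` and common
#' pairwise correlation `rho`, and is clipped to \[0, 1\] (at sd = 0.05 the
#' clipped mass is negligible). The sinusoidal regime is seed-free:
#' `x_i(t) = base + 0.4 * sin(2*pi*freqs[i]*t + phases[i])`.
#'
#' @param regime One of `"random"`, `"correlated_gaussian"`, `"sinusoidal"`.
#' @param n_channels Number of input channels (one per Level-1 node).
#' @param base Central input level.
#' @param half_range Half-width of the uniform base draw (random regime).
#' @param noise_halfwidth Half-width of the additive uniform noise.
#' @param rho Common pairwise correlation of the Gaussian regime, in \[0, 1).
#' @param gaussian_sd Marginal standard deviation of the Gaussian regime.
#' @param freqs Cycles per iteration, one per channel (sinusoidal regime).
#'   Defaults to `(1:n_channels)/20` so channel i completes i cycles over a
#'   20-iteration trial.
#' @param phases Phase offsets in radians, one per channel.
#' @return An object of class `stimulus_config`.
#' @examples
#' cfg <- stimulus_config("random")
#' set.seed(1)
#' random_inputs(cfg)
#' @export
stimulus_config <- function(regime = c("random", "correlated_gaussian", "sinusoidal"),
                            n_channels = 4L,
                            base = 0.5,
                            half_range = 0.1,
                            noise_halfwidth = 0.05,
                            rho = 0.3,
                            gaussian_sd = 0.05,
                            freqs = NULL,
                            phases = NULL) {
  regime <- match.arg(regime)
  n_channels <- as.integer(n_channels)
  stopifnot(n_channels >= 1L, half_range >= 0, noise_halfwidth >= 0,
            gaussian_sd > 0)
  if (rho < 0 || rho >= 1) {
    stop("rho must lie in [0, 1)", call. = FALSE)
  }
  if (is.null(freqs)) freqs <- seq_len(n_channels) / 20
  if (is.null(phases)) phases <- rep(0, n_channels)
  stopifnot(length(freqs) == n_channels, length(phases) == n_channels)
  structure(
    list(regime = regime, n_channels = n_channels, base = base,
         half_range = half_range, noise_halfwidth = noise_halfwidth,
         rho = rho, gaussian_sd = gaussian_sd,
         freqs = freqs, phases = phases),
    class = "stimulus_config"
  )
}

#' @export
print.stimulus_config <- function(x, ...) {
  cat("<stimulus_config>", x$regime, "with", x$n_channels, "channels\n")
  invisible(x)
}

#' Bounded random inputs
#'
#' One draw of the baseline stimulus: each channel is
#' `U[base - half_range, base + half_range]` plus independent uniform noise on
#' `[-noise_halfwidth, +noise_halfwidth]`. Channels and iterations are
#' independent. Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param cfg A [stimulus_config()] with `regime = "random"`.
#' @return Numeric vector of length `cfg$n_channels`.
#' @export
random_inputs <- function(cfg) {
  stopifnot(inherits(cfg, "stimulus_config"), cfg$regime == "random")
  n <- cfg$n_channels
  stats::runif(n, cfg$base - cfg$half_range, cfg$base + cfg$half_range) +
    stats::runif(n, -cfg$noise_halfwidth, cfg$noise_halfwidth)
}

#' Equicorrelated Gaussian inputs
#'
#' One draw from a multivariate normal with mean `base`, marginal sd
#' `gaussian_sd` and common pairwise correlation `rho`, generated through the
#' Cholesky factor of the equicorrelation matrix and clipped to \[0, 1\].
#'
#' @param cfg A [stimulus_config()] with `regime = "correlated_gaussian"`.
#' @return Numeric vector of length `cfg$n_channels`.
#' @export
correlated_gaussian_inputs <- function(cfg) {
  stopifnot(inherits(cfg, "stimulus_config"),
            cfg$regime == "correlated_gaussian")
  n <- cfg$n_channels
  R <- matrix(cfg$rho, n, n)
  diag(R) <- 1
  # rho in [0, 1) keeps the equicorrelation matrix positive definite for any n
  L <- tryCatch(chol(R), error = function(e) {
    stop("correlation matrix is not positive definite", call. = FALSE)
  })
  z <- as.vector(crossprod(L, stats::rnorm(n)))
  pmin(pmax(cfg$base + cfg$gaussian_sd * z, 0), 1)
}

#' Sinusoidal inputs
#'
#' Deterministic stimulus `x_i(t) = base + 0.4 * sin(2*pi*freqs[i]*t +
#' phases[i])`, one distinct frequency per channel. No noise, no RNG use.
#'
#' @param cfg A [stimulus_config()] with `regime = "sinusoidal"`.
#' @param t Iteration index (scalar).
#' @return Numeric vector of length `cfg$n_channels`, in \[0.1, 0.9\] for the
#'   default base of 0.5.
#' @export
sinusoidal_inputs <- function(cfg, t) {
  stopifnot(inherits(cfg, "stimulus_config"), cfg$regime == "sinusoidal",
            length(t) == 1L)
  if (anyDuplicated(cfg$freqs)) {
    stop("sinusoidal regime requires distinct frequencies per channel",
         call. = FALSE)
  }
  cfg$base + 0.4 * sin(2 * pi * cfg$freqs * t + cfg$phases)
}

#' Draw one stimulus vector from any regime
#'
#' Dispatcher used by the trial driver: stochastic regimes consume the current
#' RNG stream, the sinusoidal regime depends only on the iteration index.
#'
#' @param cfg A [stimulus_config()].
#' @param t Iteration index (needed by the sinusoidal regime).
#' @return Numeric vector of length `cfg$n_channels`.
#' @export
draw_stimulus <- function(cfg, t) {
  switch(cfg$regime,
    random = random_inputs(cfg),
    correlated_gaussian = correlated_gaussian_inputs(cfg),
    sinusoidal = sinusoidal_inputs(cfg, t)
  )
}
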