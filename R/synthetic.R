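#' Membrane-time-constant distribution specification
#'
#' @param family `"gaussian"` (truncated by resampling) or `"lognormal"`
#'   (parameterised by its own mean and sd).
#' @param mean Distribution mean, ms (positive).
#' @param sd Distribution standard deviation, ms (non-negative).
#' @param lower Lower bound, ms; draws at or below it are resampled (positive).
#' @return An object of class `mtc_spec`.
#' @export
#' @examples
#' mtc_spec("gaussian", 10, 3)
mtc_spec <- function(family = c("gaussian", "lognormal"), mean = 10, sd = 3,
                     lower = 1) {
  family <- match.arg(family)
  stop_if_not_scalar(mean, "mean"); stop_if_not_scalar(sd, "sd")
  stop_if_not_scalar(lower, "lower")
  if (mean <= 0) stop("mean must be positive")
  if (sd < 0) stop("sd must be non-negative")
  if (lower <= 0) stop("lower bound must be positive")
  if (lower >= mean) stop("lower bound must sit below the mean")
  structure(list(family = family, mean = mean, sd = sd, lower = lower),
            class = "mtc_spec")
}

#' Sample membrane time constants
#'
#' Draws `n` positive membrane time constants from the configured
#' distribution. Truncation is enforced by resampling (not clipping), so no
#' point mass accumulates at the bound. With `sd = 0` all samples equal the
#' mean (homogeneous control).
#'
#' @param spec An [mtc_spec()].
#' @param n Number of samples (>= 1).
#' @param seed Optional integer seed (uses and restores the R RNG).
#' @return Numeric vector of `n` time constants, ms, all `> spec$lower`.
#' @export
#' @examples
#' summary(sample_mtc(mtc_spec("gaussian", 10, 3), 1000, seed = 1))
sample_mtc <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "mtc_spec"), n >= 1)
  with_seed(seed, {
    if (spec$sd == 0) return(rep(spec$mean, n))
    draw <- switch(spec$family,
      gaussian = function(k) rnorm(k, spec$mean, spec$sd),
      lognormal = function(k) {
        sdl2 <- log(1 + spec$sd^2 / spec$mean^2)
        rlnorm_mean <- log(spec$mean) - sdl2 / 2
        stats::rlnorm(k, rlnorm_mean, sqrt(sdl2))
      })
    out <- draw(n)
    bad <- which(out <= spec$lower)
    while (length(bad) > 0) {
      out[bad] <- draw(length(bad))
      bad <- bad[out[bad] <= spec$lower]
    }
    out
  })
}

#' Layer-specific membrane-timescale profiles
#'
#' Parametric stand-ins for the layer-resolved timescale distributions of
#' human cortical pyramidal cells: lognormal families whose per-layer mean
#' and sd are calibration defaults chosen to preserve the empirical ordering
#' (superficial layers faster than deep layers), not measured values. All
#' settings are overridable.
#'
#' @param config Optional named list of per-layer overrides, each a list with
#'   `mean`, `sd` and optionally `family`, `lower`, `rheobase_offset`.
#'   Layers default to III: 8 +/- 3, IV: 10 +/- 3, V: 15 +/- 5,
#'   VI: 20 +/- 6 ms.
#' @return A list of `layer_profile` objects (fields `layer`, `mtc`,
#'   `rheobase_offset`), ordered III, IV, V, VI (or as configured). A warning
#'   is raised if the configured means are not ordered superficial < deep.
#' @export
#' @examples
#' sapply(layer_profiles(), function(p) p$mtc$mean)
layer_profiles <- function(config = NULL) {
  defaults <- list(
    III = list(mean = 8,  sd = 3, rheobase_offset = 0),
    IV  = list(mean = 10, sd = 3, rheobase_offset = 0),
    V   = list(mean = 15, sd = 5, rheobase_offset = 0),
    VI  = list(mean = 20, sd = 6, rheobase_offset = 0))
  layers <- names(defaults)
  if (!is.null(config)) {
    unknown <- setdiff(names(config), layers)
    if (length(unknown) > 0)
      stop("unknown layer label(s): ", paste(unknown, collapse = ", "))
    for (l in names(config)) defaults[[l]] <- utils::modifyList(defaults[[l]], config[[l]])
    layers <- intersect(layers, names(config))  # configured layers only
  }
  means <- vapply(defaults[layers], function(d) d$mean, numeric(1))
  if (is.unsorted(means))
    warning("layer MTC means are not ordered superficial < deep")
  lapply(layers, function(l) {
    d <- defaults[[l]]
    structure(list(layer = l,
                   mtc = mtc_spec(d$family %||% "lognormal", d$mean, d$sd,
                                  d$lower %||% 1),
                   rheobase_offset = d$rheobase_offset %||% 0),
              class = "layer_profile")
  })
}

#' Sample initial synaptic weights
#'
#' Gaussian around the baseline `g_0` with sd `sigma_g`, clipped into
#' `[g_min, g_max]`.
#'
#' @param n_synapses Number of weights.
#' @param g_0 Baseline weight (positive).
#' @param sigma_g Weight sd (default `0.1 * g_0`).
#' @param g_min,g_max Clipping bounds (defaults `0.01 * g_0`, `2 * g_0`).
#' @param seed Optional integer seed.
#' @return Numeric vector of weights.
#' @export
initial_weights <- function(n_synapses, g_0, sigma_g = 0.1 * g_0,
                            g_min = 0.01 * g_0, g_max = 2 * g_0, seed = NULL) {
  stopifnot(g_0 > 0, sigma_g >= 0, n_synapses >= 0)
  with_seed(seed, pmin(pmax(rnorm(n_synapses, g_0, sigma_g), g_min), g_max))
}

#' Sample a white-noise input-current stream
#'
#' Per-step effective input currents under the Euler--Maruyama convention
#' used by the integrator: \eqn{\mu + (\sigma/\sqrt{dt})\,\xi_k} with
#' \eqn{\xi_k \sim N(0,1)} i.i.d. Multiplying by \eqn{dt/\tau_m} recovers the
#' membrane increment \eqn{(dt/\tau_m)\mu + (\sigma/\tau_m)\sqrt{dt}\,\xi_k}.
#'
#' @param spec A [noise_spec()].
#' @param dt Time step, ms.
#' @param n_steps Number of increments.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_steps`.
#' @export
noise_stream <- function(spec, dt, n_steps, seed = NULL) {
  stopifnot(inherits(spec, "noise_spec"), dt > 0, n_steps >= 0)
  with_seed(seed, spec$mu + (spec$sigma / sqrt(dt)) * rnorm(n_steps))
}

#' Calibrate a rheobase offset to a target sham firing rate
#'
#' Bisection on the constant current offset so that isolated neurons with
#' membrane time constants drawn from `mtc` fire at `target` Hz (within
#' `tol`) under the sham condition. Used to place every layer of the
#' multi-layer network in a comparable asynchronous working regime despite
#' widely differing timescales.
#'
#' @param mtc An [mtc_spec()] for the population to calibrate.
#' @param noise A [noise_spec()].
#' @param target Target mean rate, Hz (default 5).
#' @param tol Acceptable deviation, Hz (default 0.25 for the search; the
#'   protocol-level tolerance is wider).
#' @param n_neurons Sample size per evaluation (default 100).
#' @param duration Per-evaluation simulated time, s (default 5).
#' @param bounds Search interval for the offset, mV.
#' @param seed Integer seed.
#' @param dt Time step, ms.
#' @param params Template [neuron_params()] (tau_m is overridden per neuron).
#' @return The calibrated offset, mV.
#' @export
calibrate_rheobase <- function(mtc, noise = noise_spec(), target = 5,
                               tol = 0.25, n_neurons = 100, duration = 5,
                               bounds = c(-3, 3), seed = 1, dt = 0.1,
                               params = neuron_params()) {
  taus <- sample_mtc(mtc, n_neurons, seed = seed)
  seeds <- derive_seeds(seed, n_neurons)
  rate_at <- function(offset) {
    rates <- vapply(seq_len(n_neurons), function(i) {
      p <- neuron_params(tau_m = taus[i], v_rest = params$v_rest,
                         v_thr = params$v_thr, tau_ref = params$tau_ref,
                         rheobase_offset = offset)
      length(simulate_neuron(p, noise, duration = duration, dt = dt,
                             seed = seeds[i])$spikes) / duration
    }, numeric(1))
    mean(rates)
  }
  lo <- bounds[1]; hi <- bounds[2]
  r_lo <- rate_at(lo); r_hi <- rate_at(hi)
  if (r_lo > target || r_hi < target)
    stop("target rate not bracketed by the offset bounds")
  for (it in 1:20) {
    mid <- (lo + hi) / 2
    r <- rate_at(mid)
    if (abs(r - target) <= tol) return(mid)
    if (r < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
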