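#' Stimulation current at a given time
#'
#' Evaluates the sinusoidal stimulation waveform
#' \eqn{I_s(t) = A_s \sin(2\pi \omega_s t/1000 + \theta)} (with `t` in ms and
#' \eqn{\omega_s} in Hz) inside the stimulation window, and 0 outside it.
#'
#' @param t Time, ms (vectorised).
#' @param stim A [stimulus_spec()] (window `t_on`/`t_off` in seconds).
#' @return Current, mV, same length as `t`.
#' @export
#' @examples
#' tacs_current(10, stimulus_spec(amplitude = 0.5, frequency = 25))
tacs_current <- function(t, stim) {
  stopifnot(inherits(stim, "stimulus_spec"))
  on <- t >= stim$t_on * 1000 & t < stim$t_off * 1000
  ifelse(on,
         stim$amplitude * sin(2 * pi * stim$frequency * t / 1000 + stim$phase),
         0)
}

#' Closed-form passive membrane decay
#'
#' Zero-input solution of the LIF membrane equation:
#' \eqn{v(t) = V_{rest} + (v_0 - V_{rest}) e^{-t/\tau_m}}. Serves as the
#' analytic oracle for the numerical integrator.
#'
#' @param v0 Initial potential, mV.
#' @param t Time since start, ms (non-negative; vectorised).
#' @param params A [neuron_params()].
#' @return Membrane potential, mV.
#' @export
analytic_decay <- function(v0, t, params) {
  stopifnot(inherits(params, "neuron_params"), all(t >= 0))
  params$v_rest + (v0 - params$v_rest) * exp(-t / params$tau_m)
}

#' One Euler--Maruyama step of the LIF membrane equation
#'
#' Advances a single neuron state by one time step. If the neuron is
#' refractory, the potential stays clamped at `v_rest` and the refractory
#' clock is decremented; otherwise
#' \deqn{v \leftarrow v + \frac{dt}{\tau_m}(V_{rest} - v + \mu + I_{syn} + I_s)
#'       + \frac{\sigma}{\tau_m}\sqrt{dt}\,\xi}
#' and a spike is emitted when the new potential reaches `v_thr` (the
#' potential then resets to `v_rest` and the refractory clock is armed).
#'
#' This R-level stepper defines the integration contract; the compiled
#' network engine implements the identical scheme.
#'
#' @param state List with `v` (mV), `refractory_remaining` (ms) and
#'   `last_spike_time` (ms or `NULL`).
#' @param synaptic_drive Synaptic input current, mV.
#' @param params A [neuron_params()].
#' @param noise A [noise_spec()].
#' @param stim A [stimulus_spec()].
#' @param t Current time, ms.
#' @param dt Time step, ms (default 0.1).
#' @param xi Standard-normal increment; drawn with [rnorm()] if missing.
#' @return List with the advanced `state` and logical `spiked`.
#' @export
membrane_step <- function(state, synaptic_drive, params, noise, stim,
                          t, dt = 0.1, xi = NULL) {
  stopifnot(dt > 0)
  if (!is.finite(state$v)) stop("non-finite membrane potential in state")
  if (state$refractory_remaining > 0) {
    state$refractory_remaining <- max(0, state$refractory_remaining - dt)
    state$v <- params$v_rest
    return(list(state = state, spiked = FALSE))
  }
  if (is.null(xi)) xi <- if (noise$sigma > 0) rnorm(1) else 0
  drift <- (params$v_rest - state$v + noise$mu + params$rheobase_offset +
              synaptic_drive + tacs_current(t, stim)) * dt / params$tau_m
  v_new <- state$v + drift + (noise$sigma / params$tau_m) * sqrt(dt) * xi
  if (!is.finite(v_new)) stop("membrane update produced a non-finite value")
  spiked <- v_new >= params$v_thr
  if (spiked) {
    state$v <- params$v_rest
    state$refractory_remaining <- params$tau_ref
    state$last_spike_time <- t + dt
  } else {
    state$v <- v_new
  }
  list(state = state, spiked = spiked)
}

#' Analytic inter-spike interval of the deterministic LIF neuron
#'
#' For constant suprathreshold input \eqn{\Delta I > v_{thr} - V_{rest}} and
#' no noise, the LIF period is
#' \eqn{T = \tau_{ref} + \tau_m \ln\left(\frac{\Delta I}{\Delta I - (v_{thr} - V_{rest})}\right)}.
#'
#' @param delta_I Constant input current above rest, mV.
#' @param params A [neuron_params()].
#' @return Inter-spike interval, ms (`Inf` if subthreshold).
#' @export
lif_isi <- function(delta_I, params) {
  stopifnot(inherits(params, "neuron_params"))
  gap <- params$v_thr - params$v_rest
  ifelse(delta_I > gap,
         params$tau_ref + params$tau_m * log(delta_I / (delta_I - gap)),
         Inf)
}

#' Analytic power spectral density of the passive membrane
#'
#' For a passive (non-spiking) membrane driven by zero-mean white noise and a
#' sinusoid, the membrane-potential power density is a Lorentzian low-pass
#' shape plus spectral lines at the stimulation frequency:
#' \deqn{S(\omega) \propto \frac{1}{1 + 4\pi^2\tau_m^2\omega^2}
#'   \left(2\sigma^2 + \frac{A_s^2}{4}\,\delta(\omega \pm \omega_s)\right)}
#' The continuous part and the discrete line powers are returned separately;
#' the continuous half-power point sits at \eqn{\omega = 1/(2\pi\tau_m)}.
#'
#' @param omega Frequencies at which to evaluate the continuous density, Hz.
#' @param params A [neuron_params()].
#' @param noise A [noise_spec()] (the derivation assumes `mu = 0`).
#' @param stim A [stimulus_spec()] (lines omitted when `amplitude = 0`).
#' @return List with `omega`, `density` (continuous part, relative power) and
#'   `lines` (data frame `omega`, `power` for the discrete components).
#' @export
passive_psd <- function(omega, params, noise, stim = stimulus_spec()) {
  stopifnot(inherits(params, "neuron_params"), all(omega >= 0))
  tau_s <- params$tau_m / 1000     # formula uses seconds against Hz
  lorentz <- function(w) 1 / (1 + 4 * pi^2 * tau_s^2 * w^2)
  density <- 2 * noise$sigma^2 * lorentz(omega)
  lines <- if (stim$amplitude > 0 && stim$frequency > 0) {
    data.frame(omega = c(-stim$frequency, stim$frequency),
               power = (stim$amplitude^2 / 4) * lorentz(stim$frequency))
  } else {
    data.frame(omega = numeric(0), power = numeric(0))
  }
  list(omega = omega, density = density, lines = lines)
}

#' Simulate a single isolated LIF neuron
#'
#' Convenience wrapper running the compiled engine on a one-neuron network
#' with no synapses.
#'
#' @param params A [neuron_params()].
#' @param noise A [noise_spec()].
#' @param stim A [stimulus_spec()].
#' @param duration Simulated time, s.
#' @param dt Time step, ms.
#' @param seed Integer seed for the noise stream.
#' @param v0 Initial potential, mV (default `v_rest`).
#' @param record_v Record the membrane trace? (every `v_stride` steps).
#' @param v_stride Recording stride in steps.
#' @param passive Disable spiking (passive membrane).
#' @return List with `spikes` (spike times, ms), `v`, `v_times` (if recorded),
#'   `duration_ms` and `dt`.
#' @export
#' @examples
#' s <- simulate_neuron(neuron_params(), noise_spec(), duration = 1, seed = 1)
#' length(s$spikes)
simulate_neuron <- function(params, noise = noise_spec(), stim = stimulus_spec(),
                            duration = 1, dt = 0.1, seed = 1,
                            v0 = params$v_rest, record_v = FALSE,
                            v_stride = 1L, passive = FALSE) {
  stopifnot(inherits(params, "neuron_params"), duration > 0, dt > 0)
  net <- list(
    tau_m = params$tau_m, v_rest = params$v_rest, rheo = params$rheobase_offset,
    v_thr = params$v_thr, tau_ref = params$tau_ref, conductance = FALSE,
    syn_pre = integer(0), syn_post = integer(0), syn_g = numeric(0),
    syn_delay_steps = integer(0), syn_kclass = integer(0),
    syn_plastic = integer(0), syn_g0ref = numeric(0),
    ker_tau_r = 0.5, ker_tau_d = 3, ker_E_syn = 0)
  rec <- list(spikes = TRUE, passive = passive,
              snapshot_steps = integer(0), snapshot_idx = integer(0),
              v_idx = if (record_v) 0L else integer(0),
              v_stride = as.integer(v_stride),
              drive_group = -1L, drive_stride = 1L, v0 = v0)
  out <- cpp_simulate(net,
                      stim = list(amplitude = stim$amplitude,
                                  frequency = stim$frequency,
                                  phase = stim$phase,
                                  t_on = stim$t_on * 1000,
                                  t_off = stim$t_off * 1000),
                      noise = list(mu = noise$mu, sigma = noise$sigma),
                      stdp = list(enabled = FALSE, A_plus = 1, A_minus = 1,
                                  gamma_plus = 1, gamma_minus = 1,
                                  g_max_factor = 2, g_min_factor = 0.01),
                      record = rec, dt = dt, t_total = duration * 1000,
                      seed = as.double(seed))
  nsteps <- round(duration * 1000 / dt)
  res <- list(spikes = out$spike_time, duration_ms = duration * 1000, dt = dt)
  if (record_v) {
    used <- floor((nsteps - 1) / v_stride) + 1
    res$v <- out$v[seq_len(used), 1]
    res$v_times <- out$v_times[seq_len(used)]
  }
  res
}

#' Frequency--input (F--I) curve of a LIF neuron
#'
#' Firing rate as a function of the constant input-current offset
#' \eqn{\Delta I}, estimated from simulated spike counts and averaged over
#' trials, optionally under sinusoidal stimulation.
#'
#' @param delta_I_grid Input-current offsets, mV (replaces the mean of
#'   `noise`; must be non-empty).
#' @param params A [neuron_params()].
#' @param noise A [noise_spec()] supplying the noise intensity `sigma`.
#' @param stim A [stimulus_spec()].
#' @param duration Per-trial simulated time, s (default 10).
#' @param n_trials Trials averaged per grid point (default 10).
#' @param seed Master seed; per-trial seeds are derived with [derive_seeds()].
#' @param dt Time step, ms.
#' @return Data frame with `delta_I`, `rate` (Hz) and `rate_sd` across trials.
#' @export
fi_curve <- function(delta_I_grid, params, noise = noise_spec(),
                     stim = stimulus_spec(), duration = 10, n_trials = 10,
                     seed = 1, dt = 0.1) {
  if (length(delta_I_grid) == 0) stop("delta_I_grid must be non-empty")
  stopifnot(duration >= 1)
  seeds <- derive_seeds(seed, n_trials * length(delta_I_grid))
  k <- 0
  rows <- lapply(delta_I_grid, function(dI) {
    rates <- vapply(seq_len(n_trials), function(tr) {
      k <<- k + 1
      s <- simulate_neuron(params, noise_spec(mu = dI, sigma = noise$sigma),
                           stim, duration = duration, dt = dt,
                           seed = seeds[k])
      length(s$spikes) / duration
    }, numeric(1))
    data.frame(delta_I = dI, rate = mean(rates), rate_sd = sd(rates))
  })
  do.call(rbind, rows)
}
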