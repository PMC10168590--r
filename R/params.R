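#' Single-neuron biophysical parameters
#'
#' Parameters of the leaky integrate-and-fire (LIF) membrane: time constant
#' \eqn{\tau_m}, resting/reset potential, spike threshold, absolute refractory
#' period, and an optional rheobase offset current used to calibrate
#' layer-specific excitability.
#'
#' @param tau_m Membrane time constant, ms. Must be positive.
#' @param v_rest Resting (and reset) potential, mV.
#' @param v_thr Spike threshold, mV. Must exceed `v_rest`.
#' @param tau_ref Absolute refractory period, ms (non-negative). While
#'   refractory the membrane is clamped at `v_rest` and all inputs are
#'   ignored.
#' @param rheobase_offset Constant current offset, mV, added to the mean input
#'   (default 0). Used for per-layer excitability calibration.
#' @return An object of class `neuron_params`.
#' @export
#' @examples
#' neuron_params(tau_m = 10)
neuron_params <- function(tau_m = 10, v_rest = -60, v_thr = -54,
                          tau_ref = 2, rheobase_offset = 0) {
  for (nm in c("tau_m", "v_rest", "v_thr", "tau_ref", "rheobase_offset"))
    stop_if_not_scalar(get(nm), nm)
  if (tau_m <= 0) stop("tau_m must be positive")
  if (v_thr <= v_rest) stop("v_thr must exceed v_rest")
  if (tau_ref < 0) stop("tau_ref must be non-negative")
  structure(list(tau_m = tau_m, v_rest = v_rest, v_thr = v_thr,
                 tau_ref = tau_ref, rheobase_offset = rheobase_offset),
            class = "neuron_params")
}

#' White-noise input current specification
#'
#' The background input \eqn{I_\zeta} is Gaussian white noise with mean `mu`
#' and intensity `sigma`, entering the membrane equation like a current. Under
#' the Euler--Maruyama discretisation the per-step increment is
#' \eqn{(dt/\tau_m)(V_{rest} - v + \mu + \dots) + (\sigma/\tau_m)\sqrt{dt}\,\xi}
#' with \eqn{\xi \sim N(0,1)}.
#'
#' @param mu Mean input current, mV (default 5.5).
#' @param sigma Noise intensity, mV (default 1; non-negative).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(mu = 5.5, sigma = 1) {
  stop_if_not_scalar(mu, "mu"); stop_if_not_scalar(sigma, "sigma")
  if (sigma < 0) stop("sigma must be non-negative")
  structure(list(mu = mu, sigma = sigma), class = "noise_spec")
}

#' Sinusoidal stimulation waveform
#'
#' tACS-like stimulation is modelled as a sinusoidal current
#' \eqn{I_s(t) = A_s \sin(2\pi \omega_s t + \theta)} added identically to
#' every neuron's membrane equation while `t_on <= t < t_off`, and zero
#' otherwise.
#'
#' @param amplitude Stimulation amplitude \eqn{A_s}, mV (non-negative).
#' @param frequency Stimulation frequency \eqn{\omega_s}, Hz (non-negative).
#' @param phase Stimulation phase \eqn{\theta}, radians (default 0, identical
#'   for all neurons).
#' @param t_on,t_off Stimulation window, seconds (`t_on <= t_off`).
#' @return An object of class `stimulus_spec`.
#' @export
#' @examples
#' stimulus_spec(amplitude = 1, frequency = 25, t_on = 4, t_off = 40)
stimulus_spec <- function(amplitude = 0, frequency = 0, phase = 0,
                          t_on = 0, t_off = Inf) {
  stop_if_not_scalar(amplitude, "amplitude")
  stop_if_not_scalar(frequency, "frequency")
  stop_if_not_scalar(phase, "phase")
  if (!is.numeric(t_on) || !is.numeric(t_off)) stop("t_on/t_off must be numeric")
  if (amplitude < 0) stop("amplitude must be non-negative")
  if (frequency < 0) stop("frequency must be non-negative")
  if (t_on > t_off) stop("t_on must not exceed t_off")
  structure(list(amplitude = amplitude, frequency = frequency, phase = phase,
                 t_on = t_on, t_off = t_off), class = "stimulus_spec")
}

#' Synaptic kernel and reversal-potential parameters
#'
#' Double-exponential synaptic response with rise time `tau_r`, decay time
#' `tau_d`, reversal potential `E_syn` (conductance mode) and axonal delay
#' `t_d`.
#'
#' @param tau_r Rise time constant, ms; `0 < tau_r < tau_d`.
#' @param tau_d Decay time constant, ms.
#' @param E_syn Reversal potential, mV (0 for AMPA, -85 for GABA_a).
#' @param t_d Axonal delay, ms (non-negative).
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(tau_r = 0.5, tau_d = 3, E_syn = 0, t_d = 0.5) {
  for (nm in c("tau_r", "tau_d", "E_syn", "t_d")) stop_if_not_scalar(get(nm), nm)
  if (!(tau_r > 0 && tau_r < tau_d)) stop("requires 0 < tau_r < tau_d")
  if (t_d < 0) stop("t_d must be non-negative")
  structure(list(tau_r = tau_r, tau_d = tau_d, E_syn = E_syn, t_d = t_d),
            class = "synapse_params")
}

#' Soft-bound symmetric Hebbian STDP parameters
#'
#' Potentiation for positive spike-time differences
#' \eqn{\Delta T = t_{post} - t_{pre}} and depression for negative ones, with
#' weight-dependent (soft-bound) learning rates:
#' \deqn{\Delta g = A_+ (1 - g/g_{max}) e^{-\Delta T/\gamma_+}, \quad \Delta T > 0}
#' \deqn{\Delta g = -A_- (g/g_0) e^{\Delta T/\gamma_-}, \quad \Delta T < 0}
#' Weights are clipped to `[g_min, g_max]` after every update.
#'
#' @param A_plus Potentiation rate (default 0.02).
#' @param A_minus Depression rate (default `A_plus / 2`).
#' @param gamma_plus,gamma_minus Exponential decay constants, ms (default 10).
#' @param g_0 Baseline weight (sets the depression soft bound).
#' @param g_min,g_max Hard weight bounds (defaults `0.01 * g_0` and `2 * g_0`).
#' @return An object of class `stdp_params`.
#' @export
#' @examples
#' stdp_params(g_0 = 0.1)
stdp_params <- function(A_plus = 0.02, A_minus = A_plus / 2,
                        gamma_plus = 10, gamma_minus = 10,
                        g_0 = 0.1, g_min = 0.01 * g_0, g_max = 2 * g_0) {
  for (nm in c("A_plus", "A_minus", "gamma_plus", "gamma_minus",
               "g_0", "g_min", "g_max"))
    stop_if_not_scalar(get(nm), nm)
  if (A_plus <= 0 || A_minus <= 0) stop("A_plus and A_minus must be positive")
  if (gamma_plus <= 0 || gamma_minus <= 0) stop("gamma_plus/gamma_minus must be positive")
  if (!(g_min < g_0 && g_0 < g_max)) stop("requires g_min < g_0 < g_max")
  structure(list(A_plus = A_plus, A_minus = A_minus,
                 gamma_plus = gamma_plus, gamma_minus = gamma_minus,
                 g_0 = g_0, g_min = g_min, g_max = g_max),
            class = "stdp_params")
}

#' Pre / stimulation / post epoch schedule
#'
#' The standard protocol simulates `t_total` seconds with stimulation applied
#' from `t_pre_end` to `t_stim_end` (defaults: 4 s of baseline, stimulation
#' until 40 s, then recovery until 60 s).
#'
#' @param t_pre_end End of the pre-stimulation epoch, s.
#' @param t_stim_end End of the stimulation epoch, s.
#' @param t_total Total simulated time, s.
#' @return An object of class `epoch_schedule`.
#' @export
epoch_schedule <- function(t_pre_end = 4, t_stim_end = 40, t_total = 60) {
  stop_if_not_scalar(t_pre_end, "t_pre_end")
  stop_if_not_scalar(t_stim_end, "t_stim_end")
  stop_if_not_scalar(t_total, "t_total")
  if (!(0 < t_pre_end && t_pre_end < t_stim_end && t_stim_end <= t_total))
    stop("requires 0 < t_pre_end < t_stim_end <= t_total")
  structure(list(t_pre_end = t_pre_end, t_stim_end = t_stim_end,
                 t_total = t_total), class = "epoch_schedule")
}
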