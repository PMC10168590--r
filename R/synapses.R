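#' Peak-normalised double-exponential synaptic kernel
#'
#' Causal synaptic response \eqn{S(s) \propto e^{-s/\tau_d} - e^{-s/\tau_r}}
#' for time `s` since spike arrival, scaled so that its maximum equals 1
#' (making the synaptic weight the peak conductance / peak current).
#'
#' @param s Time since spike arrival, ms (vectorised; negative values give 0).
#' @param params A [synapse_params()].
#' @return Dimensionless activation in `[0, 1]`.
#' @export
#' @examples
#' synaptic_kernel(kernel_peak_time(synapse_params()), synapse_params())
synaptic_kernel <- function(s, params) {
  stopifnot(inherits(params, "synapse_params"))
  peak <- kernel_peak_time(params)
  norm <- exp(-peak / params$tau_d) - exp(-peak / params$tau_r)
  out <- (exp(-s / params$tau_d) - exp(-s / params$tau_r)) / norm
  out[s < 0] <- 0
  out
}

#' Time of the synaptic kernel's peak
#'
#' @param params A [synapse_params()].
#' @return \eqn{s^\ast = \frac{\tau_r \tau_d}{\tau_d - \tau_r}
#'   \ln(\tau_d/\tau_r)}, ms.
#' @export
kernel_peak_time <- function(params) {
  stopifnot(inherits(params, "synapse_params"))
  params$tau_r * params$tau_d / (params$tau_d - params$tau_r) *
    log(params$tau_d / params$tau_r)
}

#' Total synaptic drive onto a neuron (reference implementation)
#'
#' Direct summation of delayed, kernel-filtered contributions from every
#' presynaptic spike: in conductance mode
#' \eqn{I_{syn,i}(t) = \sum_j g_{ij} S(t - t^{sp}_j - t_d)(E_{syn} - v_i)},
#' so AMPA synapses (\eqn{E_{syn}=0}) depolarise and GABA_a synapses
#' (\eqn{E_{syn}=-85} mV) hyperpolarise a neuron at typical potentials; in
#' current mode the reversal-potential factor is omitted and the weight is a
#' current in mV. This direct sum is the oracle against which the compiled
#' engine's exponential-accumulator implementation is verified.
#'
#' @param i Postsynaptic neuron id.
#' @param t Evaluation time, ms.
#' @param spikes Data frame with columns `neuron`, `time` (ms).
#' @param table Data frame of synapses with columns `pre`, `post`, `g`,
#'   `delay`, `tau_r`, `tau_d`, `E_syn`.
#' @param v_i Membrane potential of neuron `i`, mV (conductance mode).
#' @param mode `"conductance"` or `"current"`.
#' @return Synaptic current, mV.
#' @export
total_synaptic_drive <- function(i, t, spikes, table, v_i = NULL,
                                 mode = c("conductance", "current")) {
  mode <- match.arg(mode)
  if (!i %in% c(table$pre, table$post) && nrow(table) > 0)
    stop(sprintf("unknown neuron id %s", i))
  if (mode == "conductance" && is.null(v_i))
    stop("conductance mode requires v_i")
  incoming <- table[table$post == i, , drop = FALSE]
  drive <- 0
  for (r in seq_len(nrow(incoming))) {
    syn <- incoming[r, ]
    pre_sp <- spikes$time[spikes$neuron == syn$pre]
    if (length(pre_sp) == 0) next
    sp <- synapse_params(tau_r = syn$tau_r, tau_d = syn$tau_d,
                         E_syn = syn$E_syn, t_d = syn$delay)
    kern <- sum(synaptic_kernel(t - pre_sp - syn$delay, sp))
    drive <- drive + if (mode == "conductance")
      syn$g * kern * (syn$E_syn - v_i) else syn$g * kern
  }
  drive
}
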