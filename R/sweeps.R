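# Frequency x timescale sweeps: the pair-motif heatmap and the inter-laminar
# weight-change matrix.

#' Pair-motif frequency x timescale sweep
#'
#' For each (stimulation frequency, postsynaptic timescale) cell, simulates
#' the two-neuron motif through the stimulation epoch and reports the change
#' of the tracked `1 -> 2` weight (final minus initial) per trial, together
#' with the integral predictor of mean weight change computed from the spike-
#' timing-difference distribution measured during stimulation (soft-bound
#' rates evaluated at the baseline weight, where they balance for a flat
#' distribution).
#'
#' @param tau_pre Presynaptic membrane time constant, ms (default 10).
#' @param tau_post_grid Postsynaptic time constants, ms.
#' @param omega_grid Stimulation frequencies, Hz.
#' @param n_trials Independent trials per cell (default 10).
#' @param amplitude Stimulation amplitude, mV (default 1; 0 gives sham).
#' @param noise A [noise_spec()].
#' @param schedule An [epoch_schedule()]; the simulation runs to
#'   `t_stim_end` with stimulation from `t_pre_end`.
#' @param seed Master seed; trial seeds derived with [derive_seeds()].
#' @param dt Time step, ms.
#' @param delta_t_window,delta_t_binwidth Pairing window and bin width, ms,
#'   for the measured \eqn{f(\Delta T)}.
#' @return Data frame with one row per (omega, tau_post, trial): `dg`
#'   (simulated weight change of `g_{1->2}`), `dg_pred` (integral
#'   prediction), `n_pairs` (pairings measured), `seed`.
#' @export
#' @examples
#' \donttest{
#' sw <- sweep_pair(10, c(6, 14), 25, n_trials = 2,
#'                  schedule = epoch_schedule(1, 5, 5), seed = 1)
#' aggregate(dg ~ tau_post, sw, mean)
#' }
sweep_pair <- function(tau_pre = 10, tau_post_grid = c(6, 10, 14),
                       omega_grid = c(5, 15, 25, 35), n_trials = 10,
                       amplitude = 1, noise = noise_spec(),
                       schedule = epoch_schedule(), seed = 1, dt = 0.1,
                       delta_t_window = 100, delta_t_binwidth = 1) {
  if (length(tau_post_grid) == 0 || length(omega_grid) == 0)
    stop("grids must be non-empty")
  seeds <- derive_seeds(seed, n_trials * length(tau_post_grid) *
                          length(omega_grid))
  stim_ms <- c(schedule$t_pre_end, schedule$t_stim_end) * 1000
  rows <- list(); k <- 0
  for (om in omega_grid) for (tp in tau_post_grid) {
    for (tr in seq_len(n_trials)) {
      k <- k + 1
      net <- build_pair_motif(tau_1 = tau_pre, tau_2 = tp, noise = noise)
      sim <- simulate_network(net, t_total = schedule$t_stim_end,
                              stim = stimulus_spec(amplitude, om,
                                                   t_on = schedule$t_pre_end,
                                                   t_off = schedule$t_stim_end),
                              seed = seeds[k], dt = dt)
      sp <- sim$spikes[sim$spikes$time > stim_ms[1] &
                         sim$spikes$time <= stim_ms[2], ]
      h <- delta_t_histogram(sp$time[sp$neuron == 1], sp$time[sp$neuron == 2],
                             window = delta_t_window,
                             binwidth = delta_t_binwidth)
      rows[[k]] <- data.frame(
        omega = om, tau_post = tp, trial = tr,
        dg = sim$g_final[1] - sim$g_initial[1],
        dg_pred = predicted_mean_change(h, net$stdp, g = net$stdp$g_0),
        n_pairs = h$n_pairs, seed = seeds[k])
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "tau_pre") <- tau_pre
  attr(out, "amplitude") <- amplitude
  out
}

#' Inter-laminar frequency sweep
#'
#' For each stimulation frequency and trial, builds an independent four-layer
#' laminar network, simulates through the stimulation epoch, and reports the
#' net weight change (sum of final minus initial weights) per ordered layer
#' pair over excitatory synapses whose membrane-time-constant gap is at least
#' `min_gap` ms.
#'
#' @param omega_grid Stimulation frequencies, Hz (0 gives sham).
#' @param n_per_layer Neurons per layer.
#' @param profiles Layer profiles from [layer_profiles()].
#' @param adjacency A [laminar_adjacency()] matrix.
#' @param n_trials Independent trials (new wiring and noise) per frequency.
#' @param amplitude Stimulation amplitude, mV.
#' @param schedule An [epoch_schedule()]; runs to `t_stim_end`.
#' @param min_gap Timescale-gap selector, ms (default 5).
#' @param rheobase_offsets Optional named per-layer offsets, mV; when `NULL`
#'   they are calibrated once and reused across trials.
#' @param seed Master seed.
#' @param dt Time step, ms.
#' @param ... Passed to [build_multilayer()].
#' @return Data frame with `omega`, `trial`, `layer_pre`, `layer_post`,
#'   `change`, `n`.
#' @export
sweep_interlaminar <- function(omega_grid, n_per_layer = 600,
                               profiles = layer_profiles(),
                               adjacency = laminar_adjacency(),
                               n_trials = 5, amplitude = 1,
                               schedule = epoch_schedule(), min_gap = 5,
                               rheobase_offsets = NULL, seed = 1, dt = 0.1,
                               ...) {
  if (length(omega_grid) == 0) stop("omega_grid must be non-empty")
  if (is.null(rheobase_offsets)) {
    cal_seeds <- derive_seeds(seed + 1, length(profiles))
    rheobase_offsets <- stats::setNames(
      vapply(seq_along(profiles), function(i)
        calibrate_rheobase(profiles[[i]]$mtc, seed = cal_seeds[i]),
        numeric(1)),
      vapply(profiles, function(p) p$layer, character(1)))
  }
  seeds <- derive_seeds(seed, 2 * n_trials)
  rows <- list()
  for (tr in seq_len(n_trials)) {
    net <- build_multilayer(n_per_layer = n_per_layer, profiles = profiles,
                            adjacency = adjacency,
                            rheobase_offsets = rheobase_offsets,
                            seed = seeds[tr], ...)
    for (om in omega_grid) {
      sim <- simulate_network(net, t_total = schedule$t_stim_end,
                              stim = stimulus_spec(amplitude, max(om, 0),
                                                   t_on = schedule$t_pre_end,
                                                   t_off = if (om > 0)
                                                     schedule$t_stim_end else
                                                     schedule$t_pre_end),
                              seed = seeds[n_trials + tr], dt = dt)
      ch <- net_weight_change(net, sim$g_initial, sim$g_final,
                              min_gap = min_gap, type_pair = "EE",
                              by_layer = TRUE)
      ch$omega <- om; ch$trial <- tr
      rows[[length(rows) + 1]] <- ch
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "rheobase_offsets") <- rheobase_offsets
  out[, c("omega", "trial", "layer_pre", "layer_post", "change", "n")]
}
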