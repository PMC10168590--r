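# Engine wrapper and the epoched stimulation protocol.

#' Simulate a network
#'
#' Runs the compiled event-driven LIF engine on a `tacs_network`:
#' Euler--Maruyama membrane integration (default `dt = 0.1` ms), delayed
#' kernel-filtered synaptic drive, sinusoidal stimulation applied identically
#' to all neurons, and (optionally) online soft-bound STDP applied
#' event-wise at spike times with sequential clipping.
#'
#' @param network A `tacs_network`.
#' @param t_total Simulated time, s.
#' @param stim A [stimulus_spec()] (window in seconds).
#' @param seed Integer seed for the noise stream.
#' @param dt Time step, ms.
#' @param stdp_active Apply plasticity? (default `TRUE`).
#' @param snapshot_times Times (s) at which to snapshot weights; `0` records
#'   the initial weights.
#' @param snapshot_synapses Integer indices (rows of `network$synapses`) to
#'   snapshot; default all.
#' @param record_v Integer neuron ids whose membrane potential to record.
#' @param v_stride Stride (steps) for membrane recording.
#' @param drive_groups Optional factor/character per neuron; mean synaptic
#'   drive per group is recorded every `drive_stride` steps.
#' @param drive_stride Stride (steps) for drive recording.
#' @param passive Disable spiking (passive membranes; for spectral checks).
#' @return A `tacs_sim` object: `spikes` (data frame `neuron`, `time` in ms),
#'   `g_final`, `snapshots` (matrix synapses x times) with `snapshot_times`
#'   (s) and `snapshot_synapses`, optional `v`/`v_times`, `drive`
#'   (matrix times x groups) with `drive_times`, plus run metadata.
#' @export
#' @examples
#' net <- build_pair_motif(10, 14)
#' sim <- simulate_network(net, t_total = 1,
#'                         stim = stimulus_spec(1, 25, t_on = 0, t_off = 1),
#'                         seed = 1)
#' head(sim$spikes)
simulate_network <- function(network, t_total, stim = stimulus_spec(),
                             seed = 1, dt = 0.1, stdp_active = TRUE,
                             snapshot_times = numeric(0),
                             snapshot_synapses = NULL,
                             record_v = integer(0), v_stride = 1L,
                             drive_groups = NULL, drive_stride = 10L,
                             passive = FALSE) {
  stopifnot(inherits(network, "tacs_network"), t_total > 0, dt > 0)
  neurons <- network$neurons; synapses <- network$synapses
  kern <- network$kernels[order(network$kernels$kclass), ]
  kmap <- match(synapses$kclass, kern$kclass) - 1L
  stdp <- network$stdp
  t_total_ms <- t_total * 1000

  if (is.null(snapshot_synapses)) snapshot_synapses <- seq_len(nrow(synapses))
  snap_steps <- as.integer(round(snapshot_times * 1000 / dt) - 1)  # -1 => initial

  grp_idx <- rep(-1L, nrow(neurons)); grp_levels <- character(0)
  if (!is.null(drive_groups)) {
    f <- as.factor(drive_groups)
    grp_levels <- levels(f)
    grp_idx <- as.integer(f) - 1L
    grp_idx[is.na(grp_idx)] <- -1L
  }

  net_arg <- list(
    tau_m = neurons$tau_m, v_rest = neurons$v_rest,
    rheo = neurons$rheobase_offset,
    v_thr = network$v_thr, tau_ref = network$tau_ref,
    conductance = network$conductance,
    syn_pre = as.integer(synapses$pre - 1L),
    syn_post = as.integer(synapses$post - 1L),
    syn_g = synapses$g,
    syn_delay_steps = pmax(1L, as.integer(round(synapses$delay / dt))),
    syn_kclass = kmap, syn_plastic = as.integer(synapses$plastic),
    syn_g0ref = synapses$g0_ref,
    ker_tau_r = kern$tau_r, ker_tau_d = kern$tau_d, ker_E_syn = kern$E_syn)
  rec <- list(spikes = TRUE, passive = passive,
              snapshot_steps = snap_steps,
              snapshot_idx = as.integer(snapshot_synapses - 1L),
              v_idx = as.integer(record_v - 1L),
              v_stride = as.integer(v_stride),
              drive_group = grp_idx, drive_stride = as.integer(drive_stride),
              v0 = neurons$v_rest)
  out <- cpp_simulate(net_arg,
                      stim = list(amplitude = stim$amplitude,
                                  frequency = stim$frequency,
                                  phase = stim$phase,
                                  t_on = stim$t_on * 1000,
                                  t_off = stim$t_off * 1000),
                      noise = list(mu = network$noise$mu,
                                   sigma = network$noise$sigma),
                      stdp = list(enabled = stdp_active,
                                  A_plus = stdp$A_plus, A_minus = stdp$A_minus,
                                  gamma_plus = stdp$gamma_plus,
                                  gamma_minus = stdp$gamma_minus,
                                  g_max_factor = stdp$g_max / stdp$g_0,
                                  g_min_factor = stdp$g_min / stdp$g_0),
                      record = rec, dt = dt, t_total = t_total_ms,
                      seed = as.double(seed))
  nsteps <- round(t_total_ms / dt)
  sim <- list(
    spikes = data.frame(neuron = out$spike_neuron, time = out$spike_time),
    g_final = out$g_final,
    g_initial = synapses$g,
    snapshots = out$snapshots,
    snapshot_times = snapshot_times,
    snapshot_synapses = snapshot_synapses,
    duration_ms = t_total_ms, dt = dt, seed = seed,
    stim = stim, n_neurons = nrow(neurons))
  if (length(record_v) > 0) {
    used <- floor((nsteps - 1) / v_stride) + 1
    sim$v <- out$v[seq_len(used), , drop = FALSE]
    sim$v_times <- out$v_times[seq_len(used)]
  }
  if (length(grp_levels) > 0) {
    used <- floor((nsteps - 1) / drive_stride) + 1
    sim$drive <- out$drive[seq_len(used), , drop = FALSE]
    colnames(sim$drive) <- grp_levels
    sim$drive_times <- out$drive_times[seq_len(used)]
  }
  class(sim) <- "tacs_sim"
  sim
}

#' @export
print.tacs_sim <- function(x, ...) {
  cat(sprintf("<tacs_sim> %d neurons, %.1f s, %d spikes (%.2f Hz mean)\n",
              x$n_neurons, x$duration_ms / 1000, nrow(x$spikes),
              nrow(x$spikes) / x$n_neurons / (x$duration_ms / 1000)))
  invisible(x)
}

#' Run the epoched stimulation protocol
#'
#' Simulates a network through the pre / stimulation / post schedule with
#' plasticity active throughout. Stimulation is applied from `t_pre_end` to
#' `t_stim_end`; weight snapshots are taken at a fixed cadence and the mean
#' synaptic drive is recorded per timescale-and-type group.
#'
#' @param network A `tacs_network`.
#' @param schedule An [epoch_schedule()].
#' @param amplitude,frequency,phase Stimulation parameters (mV, Hz, rad).
#' @param seed Integer seed.
#' @param snapshot_every Weight-snapshot cadence, s (default 0.5; `NA`
#'   disables snapshots beyond initial and final).
#' @param snapshot_synapses Synapse rows to snapshot (default: plastic
#'   synapses whose pre neuron sits in the mid timescale group and whose post
#'   neuron is in the fast or slow group, the trajectories the analysis
#'   tracks; use `"all"` for every synapse).
#' @param drive_groups Per-neuron grouping for drive traces (default:
#'   cell type crossed with timescale group).
#' @param stim_window Optional numeric `c(t_on, t_off)` (s) overriding the
#'   schedule's stimulation window.
#' @param dt Time step, ms.
#' @param ... Passed to [simulate_network()].
#' @return A `tacs_sim` with an `epochs` element giving the epoch windows in
#'   ms and a `schedule` element.
#' @export
run_protocol <- function(network, schedule = epoch_schedule(),
                         amplitude = 1, frequency = 25, phase = 0, seed = 1,
                         snapshot_every = 0.5, snapshot_synapses = NULL,
                         drive_groups = NULL, stim_window = NULL,
                         dt = 0.1, ...) {
  stopifnot(inherits(network, "tacs_network"), inherits(schedule, "epoch_schedule"))
  if (is.null(stim_window))
    stim_window <- c(schedule$t_pre_end, schedule$t_stim_end)
  stim <- stimulus_spec(amplitude = amplitude, frequency = frequency,
                        phase = phase, t_on = stim_window[1],
                        t_off = stim_window[2])
  snap_times <- if (is.na(snapshot_every)) c(0, schedule$t_total) else
    seq(0, schedule$t_total, by = snapshot_every)
  if (is.null(snapshot_synapses)) {
    grp <- mtc_groups(network$neurons$tau_m)
    pre_mid <- grp[network$synapses$pre] == "mid"
    post_out <- grp[network$synapses$post] %in% c("fast", "slow")
    snapshot_synapses <- which(network$synapses$plastic & pre_mid & post_out)
    if (length(snapshot_synapses) == 0)
      snapshot_synapses <- which(network$synapses$plastic)
  } else if (identical(snapshot_synapses, "all")) {
    snapshot_synapses <- seq_len(nrow(network$synapses))
  }
  if (is.null(drive_groups)) {
    grp <- mtc_groups(network$neurons$tau_m)
    drive_groups <- ifelse(grp == "unassigned", NA_character_,
                           paste0(network$neurons$cell_type, "_", grp))
  }
  sim <- simulate_network(network, t_total = schedule$t_total, stim = stim,
                          seed = seed, dt = dt,
                          snapshot_times = snap_times,
                          snapshot_synapses = snapshot_synapses,
                          drive_groups = drive_groups, ...)
  sim$schedule <- schedule
  sim$epochs <- list(pre = c(0, schedule$t_pre_end) * 1000,
                     stim = c(schedule$t_pre_end, schedule$t_stim_end) * 1000,
                     post = c(schedule$t_stim_end, schedule$t_total) * 1000)
  sim
}
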