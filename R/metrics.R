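# Analysis metrics: firing rates, timescale grouping, stimulation-phase
# statistics, spike-timing-difference distributions, weight trajectories and
# net weight-change summaries.

#' Per-neuron firing rates in a time window
#'
#' @param spikes Data frame with columns `neuron`, `time` (ms), or a
#'   `tacs_sim`.
#' @param window Numeric `c(t0, t1)`, ms, with `t1 > t0`. Spikes with
#'   `t0 < time <= t1` are counted.
#' @param n_neurons Number of neurons (inferred from a `tacs_sim`).
#' @return Numeric vector of rates, Hz, one per neuron id `1..n_neurons`.
#' @export
firing_rates <- function(spikes, window, n_neurons = NULL) {
  if (inherits(spikes, "tacs_sim")) {
    n_neurons <- n_neurons %||% spikes$n_neurons
    spikes <- spikes$spikes
  }
  if (is.null(n_neurons)) n_neurons <- max(spikes$neuron, 0L)
  stopifnot(length(window) == 2)
  if (window[2] <= window[1]) stop("degenerate window: t1 must exceed t0")
  sel <- spikes$time > window[1] & spikes$time <= window[2]
  counts <- tabulate(spikes$neuron[sel], nbins = n_neurons)
  counts / ((window[2] - window[1]) / 1000)
}

#' Classify neurons into timescale groups
#'
#' Fast (\eqn{\tau_m \le 8} ms), mid (\eqn{\tau_m \in [9.5, 10.5]} ms) and
#' slow (\eqn{\tau_m \ge 12} ms) groups; neurons between the thresholds are
#' `unassigned` and excluded from group summaries.
#'
#' @param tau_m Membrane time constants, ms.
#' @param fast_max,mid_range,slow_min Group thresholds, ms.
#' @return Factor with levels `fast`, `mid`, `slow`, `unassigned`.
#' @export
#' @examples
#' table(mtc_groups(c(6, 10, 15, 11)))
mtc_groups <- function(tau_m, fast_max = 8, mid_range = c(9.5, 10.5),
                       slow_min = 12) {
  out <- rep("unassigned", length(tau_m))
  out[tau_m <= fast_max] <- "fast"
  out[tau_m >= mid_range[1] & tau_m <= mid_range[2]] <- "mid"
  out[tau_m >= slow_min] <- "slow"
  factor(out, levels = c("fast", "mid", "slow", "unassigned"))
}

#' Stimulation-phase histogram and vector strength
#'
#' Maps each spike to the stimulation phase
#' \eqn{\phi = (2\pi\omega_s t/1000 + \theta) \bmod 2\pi} and summarises
#' entrainment by the phase histogram and the vector strength (resultant
#' length; 0 for uniform phases, 1 for perfect locking).
#'
#' @param spikes Data frame with `time` (ms), a numeric vector of spike
#'   times, or a `tacs_sim`.
#' @param stim A [stimulus_spec()] with positive frequency.
#' @param bins Number of phase bins (default 36).
#' @return Object of class `phase_histogram`: `breaks` (radians), `counts`,
#'   `vector_strength`, `mean_phase`, `n`.
#' @export
phase_histogram <- function(spikes, stim, bins = 36) {
  if (inherits(spikes, "tacs_sim")) spikes <- spikes$spikes
  times <- if (is.data.frame(spikes)) spikes$time else spikes
  if (stim$frequency <= 0) stop("stimulation frequency must be positive")
  phase <- (2 * pi * stim$frequency * times / 1000 + stim$phase) %% (2 * pi)
  breaks <- seq(0, 2 * pi, length.out = bins + 1)
  counts <- tabulate(findInterval(phase, breaks, rightmost.closed = TRUE),
                     nbins = bins)
  n <- length(phase)
  vs <- if (n > 0) Mod(sum(exp(1i * phase))) / n else NA_real_
  mp <- if (n > 0) Arg(sum(exp(1i * phase))) %% (2 * pi) else NA_real_
  structure(list(breaks = breaks, counts = counts, vector_strength = vs,
                 mean_phase = mp, n = n), class = "phase_histogram")
}

#' @export
print.phase_histogram <- function(x, ...) {
  cat(sprintf("<phase_histogram> %d spikes, vector strength %.3f, mean phase %.2f rad\n",
              x$n, x$vector_strength, x$mean_phase))
  invisible(x)
}

#' Phase response and rate across timescales and stimulation frequencies
#'
#' For each (\eqn{\tau_m}, \eqn{\omega_s}) cell, simulates isolated neurons
#' under continuous stimulation and reports the circular-mean firing phase,
#' vector strength and mean firing rate, averaged over trials. Undefined
#' circular means (no spikes, or vector strength below `vs_floor`) are
#' flagged `NA`.
#'
#' @param tau_grid Membrane time constants, ms.
#' @param omega_grid Stimulation frequencies, Hz.
#' @param noise A [noise_spec()].
#' @param amplitude Stimulation amplitude, mV (default 1).
#' @param duration Per-trial time, s (default 10).
#' @param n_trials Trials per cell (default 10).
#' @param seed Master seed.
#' @param vs_floor Vector-strength floor below which the mean phase is
#'   reported `NA` (default 0.05).
#' @param params Template [neuron_params()].
#' @param dt Time step, ms.
#' @return Data frame with `tau_m`, `omega`, `rate`, `vector_strength`,
#'   `mean_phase`.
#' @export
phase_response_map <- function(tau_grid, omega_grid, noise = noise_spec(),
                               amplitude = 1, duration = 10, n_trials = 10,
                               seed = 1, vs_floor = 0.05,
                               params = neuron_params(), dt = 0.1) {
  if (length(tau_grid) == 0 || length(omega_grid) == 0)
    stop("grids must be non-empty")
  seeds <- derive_seeds(seed, n_trials)
  rows <- list()
  for (tau in tau_grid) for (om in omega_grid) {
    p <- neuron_params(tau_m = tau, v_rest = params$v_rest,
                       v_thr = params$v_thr, tau_ref = params$tau_ref,
                       rheobase_offset = params$rheobase_offset)
    stim <- stimulus_spec(amplitude = amplitude, frequency = om,
                          t_on = 0, t_off = duration)
    phases <- complex(0); n_sp <- 0
    for (tr in seq_len(n_trials)) {
      sp <- simulate_neuron(p, noise, stim, duration = duration, dt = dt,
                            seed = seeds[tr])$spikes
      n_sp <- n_sp + length(sp)
      if (length(sp) > 0 && om > 0)
        phases <- c(phases, exp(1i * ((2 * pi * om * sp / 1000) %% (2 * pi))))
    }
    vs <- if (length(phases) > 0) Mod(mean(phases)) else NA_real_
    mp <- if (length(phases) > 0 && isTRUE(vs >= vs_floor))
      Arg(mean(phases)) %% (2 * pi) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      tau_m = tau, omega = om, rate = n_sp / (n_trials * duration),
      vector_strength = vs, mean_phase = mp)
  }
  do.call(rbind, rows)
}

#' Spike-timing-difference distribution
#'
#' Normalised histogram of \eqn{\Delta T = t_{post} - t_{pre}} over all cross
#' pairs of pre- and postsynaptic spikes with \eqn{|\Delta T|} within the
#' pairing window. The window (default +/- 100 ms, ten plasticity decay
#' constants) truncates the STDP integral with negligible error.
#'
#' @param pre_times,post_times Spike times, ms.
#' @param window Half-width of the pairing window, ms (positive).
#' @param binwidth Histogram bin width, ms (default 1).
#' @return Object of class `delta_t_histogram`: `edges` (ms), `counts`,
#'   `density` (normalised to unit mass), `window`, `n_pairs`.
#' @export
delta_t_histogram <- function(pre_times, post_times, window = 100,
                              binwidth = 1) {
  stopifnot(window > 0, binwidth > 0)
  pre <- sort(pre_times); post <- sort(post_times)
  edges <- seq(-window, window, by = binwidth)
  if (edges[length(edges)] < window) edges <- c(edges, window)
  deltas <- if (length(pre) == 0 || length(post) == 0) numeric(0) else {
    lo <- findInterval(pre - window, post) + 1
    hi <- findInterval(pre + window, post)
    keep <- which(hi >= lo)
    unlist(lapply(keep, function(k) post[lo[k]:hi[k]] - pre[k]),
           use.names = FALSE)
  }
  deltas <- deltas[abs(deltas) <= window]
  counts <- tabulate(findInterval(deltas, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  total <- sum(counts)
  density <- if (total > 0) counts / (total * diff(edges)) else
    rep(0, length(counts))
  structure(list(edges = edges, counts = counts, density = density,
                 window = window, n_pairs = total),
            class = "delta_t_histogram")
}

#' @export
print.delta_t_histogram <- function(x, ...) {
  cat(sprintf("<delta_t_histogram> %d pairs in +/- %g ms, %d bins\n",
              x$n_pairs, x$window, length(x$counts)))
  invisible(x)
}

#' Timescale-grouped synaptic weight trajectories
#'
#' Summarises weight snapshots per (pre group, post group, pre type, post
#' type) combination over snapshot times: mean, sd and count of the tracked
#' weights at each time.
#'
#' @param sim A `tacs_sim` carrying weight snapshots, or a snapshot matrix
#'   (synapses x times).
#' @param network The `tacs_network` that produced it.
#' @param groups Optional factor per neuron from [mtc_groups()] (computed
#'   from the network when `NULL`).
#' @param times Snapshot times, s (taken from the `tacs_sim` when omitted).
#' @param synapse_idx Rows of `network$synapses` matching the snapshot matrix
#'   rows (taken from the `tacs_sim` when omitted).
#' @return Data frame with `time`, `pre_group`, `post_group`, `pre_type`,
#'   `post_type`, `mean`, `sd`, `n`.
#' @export
weight_trajectory <- function(sim, network, groups = NULL, times = NULL,
                              synapse_idx = NULL) {
  if (inherits(sim, "tacs_sim")) {
    snapshots <- sim$snapshots
    times <- times %||% sim$snapshot_times
    synapse_idx <- synapse_idx %||% sim$snapshot_synapses
  } else snapshots <- sim
  if (length(times) < 2) stop("need at least two snapshots")
  if (is.null(groups)) groups <- mtc_groups(network$neurons$tau_m)
  syn <- network$synapses[synapse_idx, , drop = FALSE]
  key <- interaction(groups[syn$pre], groups[syn$post],
                     network$neurons$cell_type[syn$pre],
                     network$neurons$cell_type[syn$post],
                     sep = ":", drop = TRUE)
  rows <- list()
  for (j in seq_along(times)) {
    m <- tapply(snapshots[, j], key, mean)
    s <- tapply(snapshots[, j], key, sd)
    n <- tapply(snapshots[, j], key, length)
    parts <- do.call(rbind, strsplit(names(m), ":", fixed = TRUE))
    rows[[j]] <- data.frame(time = times[j],
                            pre_group = parts[, 1], post_group = parts[, 2],
                            pre_type = parts[, 3], post_type = parts[, 4],
                            mean = as.numeric(m), sd = as.numeric(s),
                            n = as.integer(n))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Net synaptic weight change over a synapse selection
#'
#' \eqn{\sum g_{final} - \sum g_{initial}} over selected synapses, optionally
#' resolved per ordered layer pair. The default selector keeps excitatory
#' synapses whose pre/post membrane-time-constant gap is at least `min_gap`
#' ms.
#'
#' @param network The `tacs_network`.
#' @param g_initial,g_final Weight vectors aligned with `network$synapses`
#'   (equal length; mismatched edge sets fail).
#' @param min_gap Minimum `|tau_post - tau_pre|`, ms (default 5; `0` keeps
#'   all).
#' @param type_pair Restrict to a pre/post cell-type pair such as `"EE"`
#'   (default) or `NULL` for all.
#' @param by_layer Return a data frame per ordered layer pair instead of a
#'   scalar.
#' @return Scalar, or data frame `layer_pre`, `layer_post`, `change`, `n`.
#' @export
net_weight_change <- function(network, g_initial, g_final, min_gap = 5,
                              type_pair = "EE", by_layer = FALSE) {
  syn <- network$synapses
  if (length(g_initial) != nrow(syn) || length(g_final) != nrow(syn))
    stop("weight vectors do not match the network's edge set")
  tau <- network$neurons$tau_m
  keep <- abs(tau[syn$post] - tau[syn$pre]) >= min_gap
  if (!is.null(type_pair)) {
    ct <- network$neurons$cell_type
    keep <- keep & paste0(ct[syn$pre], ct[syn$post]) == type_pair
  }
  dg <- g_final - g_initial
  if (!by_layer) return(sum(dg[keep]))
  lay <- network$neurons$layer
  key <- paste(lay[syn$pre], lay[syn$post], sep = "->")
  agg <- tapply(dg[keep], key[keep], sum)
  cnt <- tapply(dg[keep], key[keep], length)
  parts <- do.call(rbind, strsplit(names(agg), "->", fixed = TRUE))
  data.frame(layer_pre = parts[, 1], layer_post = parts[, 2],
             change = as.numeric(agg), n = as.integer(cnt),
             row.names = NULL)
}
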