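# Network construction: two-neuron pair motif, a balanced E/I cortical layer,
# and the four-layer laminar network. A network is an S3 list holding a
# neuron table, a synapse table, the receptor-kernel table, global LIF
# parameters and provenance metadata.

new_tacs_network <- function(neurons, synapses, kernels, conductance,
                             v_thr, tau_ref, stdp, noise, meta = list()) {
  if (nrow(synapses) > 0 && any(synapses$pre == synapses$post))
    stop("self-connections are not allowed")
  structure(list(neurons = neurons, synapses = synapses, kernels = kernels,
                 conductance = conductance, v_thr = v_thr, tau_ref = tau_ref,
                 stdp = stdp, noise = noise, meta = meta),
            class = "tacs_network")
}

#' @export
print.tacs_network <- function(x, ...) {
  nE <- sum(x$neurons$cell_type == "E"); nI <- sum(x$neurons$cell_type == "I")
  cat(sprintf("<tacs_network> %d neurons (%d E, %d I), %d synapses (%d plastic)\n",
              nrow(x$neurons), nE, nI, nrow(x$synapses),
              sum(x$synapses$plastic)))
  cat(sprintf("  mode: %s | tau_m: %.2f-%.2f ms | layers: %s\n",
              if (x$conductance) "conductance" else "current-based",
              min(x$neurons$tau_m), max(x$neurons$tau_m),
              paste(unique(x$neurons$layer), collapse = ", ")))
  invisible(x)
}

# sample directed Bernoulli(p) edges from pre_ids to post_ids, no self-loops
sample_edges <- function(pre_ids, post_ids, p) {
  if (p <= 0 || length(pre_ids) == 0 || length(post_ids) == 0)
    return(list(pre = integer(0), post = integer(0)))
  pre_out <- vector("list", length(pre_ids))
  for (k in seq_along(pre_ids)) {
    pool <- post_ids[post_ids != pre_ids[k]]
    deg <- rbinom(1, length(pool), p)
    pre_out[[k]] <- if (deg > 0) sample(pool, deg) else integer(0)
  }
  list(pre = rep(pre_ids, lengths(pre_out)), post = unlist(pre_out))
}

#' Build the two-neuron pair motif
#'
#' Two mutually synapsing excitatory LIF neurons with current-based,
#' kernel-filtered plastic synapses: the minimal testbed for timescale
#' mismatch. Weights are currents (mV kicks) with baseline `g_0 = 0.1` mV and
#' a fixed 0.5 ms axonal delay.
#'
#' @param tau_1,tau_2 Membrane time constants of neuron 1 (presynaptic for
#'   the tracked synapse) and neuron 2, ms.
#' @param g_0 Baseline synaptic weight, mV.
#' @param delay Axonal delay, ms.
#' @param tau_r,tau_d Synaptic kernel time constants, ms.
#' @param v_thr,v_rest,tau_ref LIF parameters (Table defaults).
#' @param stdp An [stdp_params()]; defaults to the study parameters with
#'   `g_0` as baseline.
#' @param noise A [noise_spec()].
#' @return A `tacs_network` with two neurons and two plastic synapses
#'   (`1 -> 2` first).
#' @export
#' @examples
#' build_pair_motif(10, 14)
build_pair_motif <- function(tau_1 = 10, tau_2 = 14, g_0 = 0.1, delay = 0.5,
                             tau_r = 0.5, tau_d = 3,
                             v_thr = -54, v_rest = -60, tau_ref = 2,
                             stdp = stdp_params(g_0 = g_0),
                             noise = noise_spec()) {
  stopifnot(tau_1 > 0, tau_2 > 0)
  neurons <- data.frame(id = 1:2, tau_m = c(tau_1, tau_2),
                        v_rest = v_rest, rheobase_offset = 0,
                        cell_type = "E", layer = NA_character_,
                        stringsAsFactors = FALSE)
  synapses <- data.frame(pre = c(1L, 2L), post = c(2L, 1L), g = g_0,
                         delay = delay, kclass = 1L, plastic = TRUE,
                         g0_ref = g_0)
  kernels <- data.frame(kclass = 1L, tau_r = tau_r, tau_d = tau_d, E_syn = 0)
  new_tacs_network(neurons, synapses, kernels, conductance = FALSE,
                   v_thr = v_thr, tau_ref = tau_ref, stdp = stdp,
                   noise = noise,
                   meta = list(kind = "pair", g_0 = g_0))
}

#' Build a balanced excitatory/inhibitory cortical layer
#'
#' A sparse, randomly wired network of LIF neurons at a 4:1 E:I ratio with
#' uniform connection probability across all ordered type pairs, conductance
#' synapses (AMPA for excitatory, GABA_a for inhibitory presynaptic cells),
#' heterogeneous membrane time constants, per-neuron resting-potential
#' jitter, and soft-bound STDP on E->E, E->I and I->E synapses (I->I static).
#' The study scale is `N = 10000`; the default `N = 2000` preserves all
#' ratios and probabilities at desk scale.
#'
#' @param N Total number of neurons (divisible into 4:1).
#' @param p_connect Connection probability for every ordered type pair.
#' @param mtc An [mtc_spec()] for the membrane time constants.
#' @param g_0_EE,g_0_EI,g_0_IE,g_0_II Baseline weights (a.u.) by type pair
#'   (pre -> post); weight sd is `0.1 * g_0`, clipped to `[0.01, 2] * g_0`.
#' @param delay_range Axonal delay range, ms (sampled uniformly).
#' @param v_thr,v_rest,tau_ref,v_rest_jitter LIF parameters; each neuron's
#'   rest/reset potential is `v_rest` plus a uniform offset in
#'   `+/- v_rest_jitter`.
#' @param stdp An [stdp_params()]; its `g_0`, `g_min`, `g_max` are applied
#'   per synapse relative to that synapse's type-pair baseline.
#' @param noise A [noise_spec()].
#' @param layer Layer label stamped on the neurons (default `NA`).
#' @param rheobase_offset Constant current offset for all neurons, mV.
#' @param seed Integer seed (wiring, weights, time constants).
#' @return A `tacs_network`.
#' @export
#' @examples
#' net <- build_cortical_layer(N = 100, seed = 1)
#' table(net$neurons$cell_type)
build_cortical_layer <- function(N = 2000, p_connect = 0.1,
                                 mtc = mtc_spec("gaussian", 10, 3),
                                 g_0_EE = 5e-5, g_0_EI = 5e-5,
                                 g_0_IE = 25e-5, g_0_II = 25e-5,
                                 delay_range = c(0.5, 1),
                                 v_thr = -54, v_rest = -60, tau_ref = 2,
                                 v_rest_jitter = 0.2,
                                 stdp = stdp_params(g_0 = g_0_EE),
                                 noise = noise_spec(),
                                 layer = NA_character_,
                                 rheobase_offset = 0, seed = 1) {
  if (N %% 5 != 0) stop("N must divide into a 4:1 E:I ratio")
  n_E <- as.integer(N * 4 / 5); n_I <- N - n_E
  with_seed(seed, {
    types <- c(rep("E", n_E), rep("I", n_I))
    neurons <- data.frame(
      id = seq_len(N), tau_m = sample_mtc(mtc, N),
      v_rest = v_rest + runif(N, -v_rest_jitter, v_rest_jitter),
      rheobase_offset = unname(rheobase_offset), cell_type = types,
      layer = layer, stringsAsFactors = FALSE)
    e_ids <- which(types == "E"); i_ids <- which(types == "I")
    blocks <- list(
      EE = list(pre = e_ids, post = e_ids, g0 = g_0_EE, plastic = TRUE),
      EI = list(pre = e_ids, post = i_ids, g0 = g_0_EI, plastic = TRUE),
      IE = list(pre = i_ids, post = e_ids, g0 = g_0_IE, plastic = TRUE),
      II = list(pre = i_ids, post = i_ids, g0 = g_0_II, plastic = FALSE))
    syn <- lapply(blocks, function(b) {
      ed <- sample_edges(b$pre, b$post, p_connect)
      m <- length(ed$pre)
      data.frame(pre = ed$pre, post = ed$post,
                 g = initial_weights(m, b$g0,
                                     g_min = (stdp$g_min / stdp$g_0) * b$g0,
                                     g_max = (stdp$g_max / stdp$g_0) * b$g0),
                 delay = runif(m, delay_range[1], delay_range[2]),
                 kclass = if (identical(b$pre, e_ids)) 1L else 2L,
                 plastic = b$plastic, g0_ref = b$g0)
    })
    synapses <- do.call(rbind, c(syn, list(make.row.names = FALSE)))
    kernels <- data.frame(kclass = c(1L, 2L), tau_r = c(0.5, 0.5),
                          tau_d = c(3, 5), E_syn = c(0, -85))
    new_tacs_network(neurons, synapses, kernels, conductance = TRUE,
                     v_thr = v_thr, tau_ref = tau_ref, stdp = stdp,
                     noise = noise,
                     meta = list(kind = "layer", N_E = n_E, N_I = n_I,
                                 p_connect = p_connect, seed = seed))
  })
}

#' Default inter-laminar adjacency
#'
#' Directed boolean matrix over layers III, IV, V, VI saying which ordered
#' layer pairs carry inter-laminar excitatory projections (wired at
#' probability 0.05 where allowed). The default enables every ordered pair;
#' the diagonal is ignored (intra-laminar wiring is handled separately).
#'
#' @param allow Optional logical 4x4 matrix (dimnames III, IV, V, VI) to
#'   override the default.
#' @return Logical matrix with layer dimnames.
#' @export
laminar_adjacency <- function(allow = NULL) {
  layers <- c("III", "IV", "V", "VI")
  if (is.null(allow)) {
    allow <- matrix(TRUE, 4, 4, dimnames = list(layers, layers))
    diag(allow) <- FALSE
  }
  stopifnot(is.logical(allow), all(dim(allow) == c(4, 4)))
  dimnames(allow) <- list(layers, layers)
  allow
}

#' Build the four-layer laminar network
#'
#' Four balanced E/I populations (layers III, IV, V, VI), each wired
#' intra-laminarly as [build_cortical_layer()] with its own layer-specific
#' membrane-timescale distribution, connected by inter-laminar excitatory
#' projections at probability `p_inter` where the adjacency allows.
#' Inter-laminar inhibitory connections are omitted. Per-layer rheobase
#' offsets place all layers in a comparable sham firing regime; pass
#' `calibrate = TRUE` to run [calibrate_rheobase()] per layer, or supply
#' offsets directly via `rheobase_offsets`.
#'
#' @param n_per_layer Neurons per layer (divisible into 4:1). The study scale
#'   is 3000 per layer (2400 E + 600 I); the default 600 preserves ratios at
#'   desk scale.
#' @param profiles A list of layer profiles from [layer_profiles()].
#' @param adjacency A [laminar_adjacency()] matrix.
#' @param p_intra,p_inter Intra-/inter-laminar connection probabilities.
#' @param calibrate Calibrate per-layer rheobase offsets to ~5 Hz sham firing
#'   (default `TRUE` when `rheobase_offsets` is `NULL`).
#' @param rheobase_offsets Optional named numeric vector of per-layer offsets
#'   (mV); skips calibration.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [build_cortical_layer()].
#' @return A `tacs_network` spanning all four layers.
#' @export
build_multilayer <- function(n_per_layer = 600, profiles = layer_profiles(),
                             adjacency = laminar_adjacency(),
                             p_intra = 0.1, p_inter = 0.05,
                             calibrate = is.null(rheobase_offsets),
                             rheobase_offsets = NULL, seed = 1, ...) {
  stopifnot(length(profiles) == 4)
  labels <- vapply(profiles, function(p) p$layer, character(1))
  seeds <- derive_seeds(seed, 8)
  offsets <- if (!is.null(rheobase_offsets)) {
    rheobase_offsets[labels]
  } else if (calibrate) {
    vapply(seq_along(profiles), function(i)
      calibrate_rheobase(profiles[[i]]$mtc, seed = seeds[4 + i]),
      numeric(1))
  } else {
    vapply(profiles, function(p) p$rheobase_offset, numeric(1))
  }
  nets <- lapply(seq_along(profiles), function(i)
    build_cortical_layer(N = n_per_layer, p_connect = p_intra,
                         mtc = profiles[[i]]$mtc, layer = labels[i],
                         rheobase_offset = offsets[i],
                         seed = seeds[i], ...))
  # concatenate layers with shifted ids
  offset_id <- cumsum(c(0, rep(n_per_layer, 3)))
  neurons <- do.call(rbind, lapply(seq_along(nets), function(i) {
    df <- nets[[i]]$neurons; df$id <- df$id + offset_id[i]; df
  }))
  synapses <- do.call(rbind, lapply(seq_along(nets), function(i) {
    df <- nets[[i]]$synapses
    df$pre <- df$pre + offset_id[i]; df$post <- df$post + offset_id[i]; df
  }))
  template <- nets[[1]]
  g0_ee <- template$synapses$g0_ref[template$synapses$kclass == 1L][1]
  # inter-laminar E->E wiring
  inter <- with_seed(seeds[4], {
    rows <- list()
    for (a in seq_along(labels)) for (b in seq_along(labels)) {
      if (a == b || !adjacency[labels[a], labels[b]]) next
      pre_ids <- neurons$id[neurons$layer == labels[a] & neurons$cell_type == "E"]
      post_ids <- neurons$id[neurons$layer == labels[b] & neurons$cell_type == "E"]
      ed <- sample_edges(pre_ids, post_ids, p_inter)
      m <- length(ed$pre)
      if (m == 0) next
      rows[[paste(a, b)]] <- data.frame(
        pre = ed$pre, post = ed$post,
        g = initial_weights(m, g0_ee),
        delay = runif(m, 0.5, 1), kclass = 1L, plastic = TRUE,
        g0_ref = g0_ee)
    }
    rows
  })
  synapses <- do.call(rbind, c(list(synapses), inter,
                               list(make.row.names = FALSE)))
  new_tacs_network(neurons, synapses, template$kernels, conductance = TRUE,
                   v_thr = template$v_thr, tau_ref = template$tau_ref,
                   stdp = template$stdp, noise = template$noise,
                   meta = list(kind = "multilayer", n_per_layer = n_per_layer,
                               labels = labels, p_intra = p_intra,
                               p_inter = p_inter, seed = seed,
                               rheobase_offsets = stats::setNames(offsets, labels)))
}
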