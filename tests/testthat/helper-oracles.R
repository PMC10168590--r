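# Independent oracles and fixtures used across test files.

# Homogeneous Poisson spike train on (0, duration_ms)
poisson_train <- function(rate_hz, duration_ms, seed) {
  set.seed(seed)
  n <- rpois(1, rate_hz * duration_ms / 1000)
  sort(runif(n, 0, duration_ms))
}

# Brute-force all-pairs soft-bound STDP: processes spike events in time
# order; at each event it sums the exponential window explicitly over all
# earlier opposite-side spikes (no running traces, no clipping). Independent
# of the trace implementation it checks.
brute_force_stdp <- function(pre_times, post_times, g0, params) {
  ev <- rbind(data.frame(t = pre_times, is_pre = TRUE),
              data.frame(t = post_times, is_pre = FALSE))
  ev <- ev[order(ev$t), ]
  g <- g0
  for (k in seq_len(nrow(ev))) {
    tt <- ev$t[k]
    if (ev$is_pre[k]) {
      earlier <- post_times[post_times < tt]
      g <- g - params$A_minus * (g / params$g_0) *
        sum(exp(-(tt - earlier) / params$gamma_minus))
    } else {
      earlier <- pre_times[pre_times < tt]
      g <- g + params$A_plus * (1 - g / params$g_max) *
        sum(exp(-(tt - earlier) / params$gamma_plus))
    }
  }
  g
}

# Relative group-mean weight shift (vs the initial snapshot) for synapses
# from mid-timescale presynaptic cells onto fast/slow postsynaptic cells,
# averaged over the snapshot times inside `window_s`.
group_shift <- function(sim, net, window_s) {
  grp <- mtc_groups(net$neurons$tau_m)
  syn <- net$synapses[sim$snapshot_synapses, ]
  sel_t <- which(sim$snapshot_times >= window_s[1] &
                   sim$snapshot_times <= window_s[2])
  out <- c(mid_fast = NA_real_, mid_slow = NA_real_)
  for (tgt in c("fast", "slow")) {
    rows <- which(grp[syn$pre] == "mid" & grp[syn$post] == tgt)
    if (length(rows) == 0) next
    base <- mean(sim$snapshots[rows, 1])
    late <- mean(sim$snapshots[rows, sel_t, drop = FALSE])
    out[paste0("mid_", tgt)] <- (late - base) / base
  }
  out
}

# percentile bootstrap CI for a mean over trials
boot_ci <- function(x, n_boot = 2000, probs = c(0.025, 0.975), seed = 1) {
  set.seed(seed)
  means <- replicate(n_boot, mean(sample(x, replace = TRUE)))
  quantile(means, probs)
}

ci_excludes_zero <- function(x, ...) {
  ci <- boot_ci(x, ...)
  ci[1] > 0 || ci[2] < 0
}
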