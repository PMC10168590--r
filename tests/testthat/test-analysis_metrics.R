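test_that("firing rates are plain spike counts over the window", {
  empty <- data.frame(neuron = integer(0), time = numeric(0))
  expect_equal(firing_rates(empty, c(0, 1000), n_neurons = 3), c(0, 0, 0))
  sp <- data.frame(neuron = rep(1L, 10), time = seq(100, 1900, length.out = 10))
  expect_equal(firing_rates(sp, c(0, 2000), n_neurons = 2), c(5, 0))
  expect_error(firing_rates(sp, c(5, 5), n_neurons = 1), "degenerate")
})

test_that("timescale grouping uses the study thresholds and leaves gaps unassigned", {
  g <- mtc_groups(c(6, 8, 9, 9.5, 10.5, 11, 12, 20))
  expect_equal(as.character(g),
               c("fast", "fast", "unassigned", "mid", "mid", "unassigned",
                 "slow", "slow"))
})

test_that("phase histogram captures locking and is invariant to a global phase shift", {
  st <- stimulus_spec(1, 25, t_on = 0, t_off = Inf)
  # single spike at the peak phase: all mass in one bin, vector strength 1
  one <- phase_histogram(data.frame(neuron = 1, time = 10), st)
  expect_equal(one$vector_strength, 1)
  expect_equal(sum(one$counts > 0), 1)
  expect_equal(sum(one$counts), 1)
  # asynchronous spikes: approximately uniform, vector strength near 0
  set.seed(1)
  asyn <- data.frame(neuron = 1, time = runif(4000, 0, 10000))
  h <- phase_histogram(asyn, st)
  expect_lt(h$vector_strength, 0.05)
  expect_equal(sum(h$counts), 4000)
  # vector strength unchanged by the stimulus phase offset theta
  st2 <- stimulus_spec(1, 25, phase = 1.3, t_on = 0, t_off = Inf)
  expect_equal(phase_histogram(asyn, st2)$vector_strength,
               h$vector_strength, tolerance = 1e-12)
  expect_error(phase_histogram(asyn, stimulus_spec(1, 0)), "positive")
})

test_that("the single-cell phase response map lags with timescale and drops with frequency", {
  pm <- phase_response_map(c(6, 10, 14), c(10, 35), duration = 4,
                           n_trials = 3, seed = 2)
  at25 <- pm[pm$omega == 35, ]
  expect_true(all(diff(at25$mean_phase[order(at25$tau_m)]) > 0))
  # for a slow cell the rate does not increase with stimulation frequency
  slow <- pm[pm$tau_m == 14, ]
  expect_lte(slow$rate[slow$omega == 35], slow$rate[slow$omega == 10])
})

test_that("spike-timing-difference histograms behave like densities", {
  # a rigid +3 ms shift puts all mass in one bin
  pre <- seq(100, 900, by = 50)
  h <- delta_t_histogram(pre, pre + 3, window = 10, binwidth = 1)
  mids <- (head(h$edges, -1) + tail(h$edges, -1)) / 2
  expect_equal(sum(h$counts > 0), 1)
  expect_lt(abs(mids[which(h$counts > 0)] - 3), 1)  # mass lands at +3 ms
  expect_equal(sum(h$density * diff(h$edges)), 1)
  # mirror symmetry under swapping pre and post
  a <- poisson_train(50, 60000, 1); b <- poisson_train(50, 60000, 2)
  hab <- delta_t_histogram(a, b, 50, 1)
  hba <- delta_t_histogram(b, a, 50, 1)
  expect_equal(hab$counts, rev(hba$counts))
  expect_equal(hab$n_pairs, hba$n_pairs)
  # independent Poisson trains: flat within Poisson sampling error per bin
  per_bin <- hab$n_pairs / length(hab$counts)
  expect_lt(sd(hab$density) / mean(hab$density), 2 / sqrt(per_bin))
  expect_lt(max(abs(hab$density - mean(hab$density))) / mean(hab$density),
            5 / sqrt(per_bin))
})

test_that("weight trajectories summarise grouped snapshots", {
  net <- build_cortical_layer(N = 200, seed = 3)
  idx <- which(net$synapses$plastic)[1:50]
  snaps <- cbind(net$synapses$g[idx], net$synapses$g[idx])  # duplicated
  wt <- weight_trajectory(snaps, net, times = c(0, 1), synapse_idx = idx)
  expect_true(all(c("time", "pre_group", "post_group", "mean", "sd") %in%
                    names(wt)))
  for (k in unique(paste(wt$pre_group, wt$post_group, wt$pre_type, wt$post_type))) {
    rows <- wt[paste(wt$pre_group, wt$post_group, wt$pre_type, wt$post_type) == k, ]
    expect_equal(rows$mean[rows$time == 0], rows$mean[rows$time == 1])
  }
})

test_that("net weight change sums exactly over the selection", {
  neurons <- data.frame(id = 1:4, tau_m = c(6, 10, 16, 10), v_rest = -60,
                        rheobase_offset = 0, cell_type = "E",
                        layer = c("III", "III", "V", "V"))
  synapses <- data.frame(pre = c(1L, 2L, 4L), post = c(3L, 3L, 1L),
                         g = c(1, 2, 3), delay = 0.5, kclass = 1L,
                         plastic = TRUE, g0_ref = 1)
  kernels <- data.frame(kclass = 1L, tau_r = 0.5, tau_d = 3, E_syn = 0)
  net <- tacsnet:::new_tacs_network(neurons, synapses, kernels, TRUE, -54, 2,
                                    stdp_params(g_0 = 1), noise_spec())
  g0 <- c(1, 2, 3); g1 <- c(1.5, 1.8, 3.2)
  # identical tables give zero
  expect_equal(net_weight_change(net, g0, g0, min_gap = 0), 0)
  # hand-computed: all three synapses have |tau gap| >= 4
  expect_equal(net_weight_change(net, g0, g1, min_gap = 4),
               0.5 - 0.2 + 0.2)
  # gap >= 5 drops synapse 2->3 (gap 6? no: 16-10=6 stays) and 4->1 (gap 4)
  expect_equal(net_weight_change(net, g0, g1, min_gap = 5), 0.5 - 0.2)
  by_l <- net_weight_change(net, g0, g1, min_gap = 0, by_layer = TRUE)
  expect_equal(by_l$change[by_l$layer_pre == "III" & by_l$layer_post == "V"],
               0.5 - 0.2)
  expect_error(net_weight_change(net, g0[1:2], g1), "edge set")
})
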