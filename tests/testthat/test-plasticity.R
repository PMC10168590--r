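test_that("pairwise STDP rule matches direct evaluation and its limits", {
  p <- stdp_params(g_0 = 1)   # normalised units: A+ = 0.02, gmax = 2
  # g -> 0 limit at DeltaT = +10 ms: A+ e^-1
  expect_equal(stdp_delta(0, 10, p), 0.02 * exp(-1))
  expect_equal(stdp_delta(0, 10, p), 7.357589e-3, tolerance = 1e-6)
  # soft bounds: no potentiation at g_max, depression scales with g/g_0
  expect_equal(stdp_delta(p$g_max, 10, p), 0)
  expect_equal(stdp_delta(1, -10, p), -0.01 * exp(-1))
  expect_equal(stdp_delta(1, 0, p), 0)
  # exponential decay to zero at large |DeltaT|
  expect_lt(abs(stdp_delta(1, 200, p)), 1e-8)
  expect_lt(abs(stdp_delta(1, -200, p)), 1e-8)
})

test_that("weight clipping maps onto [g_min, g_max]", {
  p <- stdp_params(g_0 = 5e-5)
  expect_equal(clip_weight(3 * p$g_0, p), 2 * p$g_0)
  expect_equal(clip_weight(0, p), 0.01 * p$g_0)
  expect_equal(clip_weight(p$g_0, p), p$g_0)
})

test_that("a single pre/post pair reproduces stdp_delta through the traces", {
  p <- stdp_params(g_0 = 1)
  out <- stdp_weight_path(0, 10, g0 = 1, params = p)
  expect_equal(out$g - 1, stdp_delta(1, 10, p))
  # isolated pre spike leaves the weight untouched
  expect_equal(stdp_weight_path(5, numeric(0), g0 = 1, params = p)$g, 1)
})

test_that("online trace updates equal brute-force all-pairs summation", {
  p <- stdp_params(g_0 = 1)
  for (seed in 1:4) {
    pre <- poisson_train(8, 4000, seed)
    post <- poisson_train(8, 4000, seed + 100)
    online <- stdp_weight_path(pre, post, g0 = 1, params = p, clip = FALSE)
    brute <- brute_force_stdp(pre, post, g0 = 1, params = p)
    expect_equal(online$g, brute, tolerance = 1e-9)
  }
})

test_that("the compiled engine's weight path matches the R trace implementation", {
  net <- build_pair_motif(10, 14)
  sim <- simulate_network(net, t_total = 5,
                          stim = stimulus_spec(1, 25, t_on = 0, t_off = 5),
                          seed = 7)
  pre <- sim$spikes$time[sim$spikes$neuron == 1]
  post <- sim$spikes$time[sim$spikes$neuron == 2]
  expect_gt(length(pre), 20); expect_gt(length(post), 20)
  # the engine evolves weights in baseline-normalised units
  p_norm <- stdp_params(g_0 = 1)
  for (s in 1:2) {
    a <- if (s == 1) pre else post
    b <- if (s == 1) post else pre
    replay <- stdp_weight_path(a, b, g0 = net$synapses$g[s] / 0.1,
                               params = p_norm)
    expect_equal(sim$g_final[s], replay$g * 0.1, tolerance = 1e-9)
  }
})

test_that("weights never leave their bounds during simulation", {
  net <- build_cortical_layer(N = 200, seed = 2)
  sim <- simulate_network(net, t_total = 3,
                          stim = stimulus_spec(1, 25, t_on = 0, t_off = 3),
                          seed = 3, snapshot_times = seq(0, 3, 0.5))
  syn <- net$synapses
  lo <- 0.01 * syn$g0_ref; hi <- 2 * syn$g0_ref
  expect_true(all(sim$g_final >= lo - 1e-15 & sim$g_final <= hi + 1e-15))
  expect_true(all(sim$snapshots >= lo - 1e-15 & sim$snapshots <= hi + 1e-15))
})

test_that("baseline weights sit at the soft-bound fixed point under sham firing", {
  p <- stdp_params(g_0 = 5e-5)
  gstar <- stdp_fixed_point(p)
  # with A+ = 2A-, gamma+ = gamma-, gmax = 2 g0 the balance sits exactly at g0
  expect_equal(gstar, p$g_0)
  # empirically: sham asynchronous network, mean plastic weight stays near g*
  net <- build_cortical_layer(N = 400, seed = 8)
  sim <- simulate_network(net, t_total = 20, stim = stimulus_spec(0, 0),
                          seed = 9, snapshot_times = c(0, 10, 20),
                          snapshot_synapses = which(net$synapses$plastic &
                                                      net$synapses$g0_ref == 5e-5))
  means <- colMeans(sim$snapshots)
  expect_true(all(abs(means / gstar - 1) < 0.05))
})

test_that("the integral predictor handles symmetric, point-mass and balanced cases", {
  sym <- stdp_params(A_plus = 0.02, A_minus = 0.02, g_0 = 1)
  edges <- seq(-50, 50, 1)
  f_flat <- structure(list(edges = edges,
                           counts = rep(1L, 100),
                           density = rep(1 / 100, 100),
                           window = 50, n_pairs = 100),
                      class = "delta_t_histogram")
  # symmetric f with A+ = A-: odd integrand, exactly zero
  expect_equal(predicted_mean_change(f_flat, sym), 0, tolerance = 1e-12)
  # point mass at +5 ms
  pm <- delta_t_histogram(0, 5, window = 50, binwidth = 10)
  p <- stdp_params(g_0 = 1)
  expect_equal(predicted_mean_change(pm, p), p$A_plus * exp(-5 / 10),
               tolerance = 0.05)   # bin-midpoint quadrature
  # asymmetric rates: flat f gives a positive bare value, but evaluating the
  # soft-bound factors at baseline cancels it exactly
  expect_gt(predicted_mean_change(f_flat, p), 0)
  expect_equal(predicted_mean_change(f_flat, p, g = p$g_0), 0,
               tolerance = 1e-12)
})
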