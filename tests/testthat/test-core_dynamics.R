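test_that("stimulation waveform respects amplitude, phase and window", {
  st <- stimulus_spec(amplitude = 0.5, frequency = 25, phase = 0,
                      t_on = 0, t_off = 1)
  expect_equal(tacs_current(0, st), 0)
  # quarter period of 25 Hz = 10 ms: peak of the unit sine
  expect_equal(tacs_current(10, st), 0.5)
  # outside the stimulation window
  st2 <- stimulus_spec(0.5, 25, t_on = 1, t_off = 2)
  expect_equal(tacs_current(10, st2), 0)
  expect_equal(tacs_current(2000, st2), 0)   # t_off is exclusive
  # vectorised, phase offset shifts the zero crossing
  st3 <- stimulus_spec(1, 10, phase = pi / 2, t_on = 0, t_off = 10)
  expect_equal(tacs_current(0, st3), 1)
})

test_that("analytic decay has the defining time-constant property", {
  p <- neuron_params(tau_m = 12)
  expect_equal(analytic_decay(p$v_rest, c(0, 5, 50), p), rep(p$v_rest, 3))
  dev0 <- -50 - p$v_rest
  expect_equal(analytic_decay(-50, p$tau_m, p) - p$v_rest, dev0 / exp(1))
})

test_that("membrane stepping holds the resting fixed point and stays subthreshold", {
  p <- neuron_params(tau_m = 10)
  st <- list(v = p$v_rest, refractory_remaining = 0, last_spike_time = NULL)
  quiet <- noise_spec(mu = 0, sigma = 0)
  out <- membrane_step(st, 0, p, quiet, stimulus_spec(), t = 0, dt = 0.1)
  expect_equal(out$state$v, p$v_rest)
  expect_false(out$spiked)
  # constant drive 5.9 mV < threshold gap 6 mV: converges below threshold
  s <- simulate_neuron(neuron_params(tau_m = 10, tau_ref = 0),
                       noise_spec(mu = 5.9, sigma = 0),
                       duration = 1, seed = 1, record_v = TRUE)
  expect_length(s$spikes, 0)
  expect_lt(max(s$v), -54)
  expect_equal(tail(s$v, 1), -60 + 5.9, tolerance = 1e-3)
})

test_that("non-finite membrane state is rejected with a diagnostic", {
  p <- neuron_params()
  st <- list(v = NaN, refractory_remaining = 0, last_spike_time = NULL)
  expect_error(membrane_step(st, 0, p, noise_spec(0, 0), stimulus_spec(),
                             0, 0.1),
               "non-finite")
})

test_that("deterministic integration converges to the closed form at first order", {
  p <- neuron_params(tau_m = 10, tau_ref = 0)
  err_at <- function(dt) {
    s <- simulate_neuron(p, noise_spec(0, 0), duration = 0.05, dt = dt,
                         seed = 1, v0 = -50, record_v = TRUE, passive = TRUE)
    max(abs(s$v - analytic_decay(-50, s$v_times, p)))
  }
  e1 <- err_at(0.1); e2 <- err_at(0.05); e4 <- err_at(0.025)
  expect_lt(e2, e1); expect_lt(e4, e2)
  # first-order scheme: halving dt roughly halves the error
  expect_gt(e1 / e2, 1.7); expect_lt(e1 / e2, 2.4)
  expect_gt(e2 / e4, 1.7); expect_lt(e2 / e4, 2.4)
})

test_that("deterministic suprathreshold firing matches the analytic LIF period", {
  p <- neuron_params(tau_m = 10, tau_ref = 2)
  for (dI in c(6.5, 8, 12)) {
    s <- simulate_neuron(p, noise_spec(mu = dI, sigma = 0), duration = 5,
                         seed = 1)
    isi <- diff(s$spikes)
    expect_lt(max(abs(isi - lif_isi(dI, p))), 0.1 + 1e-9)  # within one dt
  }
  expect_equal(lif_isi(5.9, p), Inf)  # subthreshold
})

test_that("refractory period is respected by every inter-spike interval", {
  p <- neuron_params(tau_m = 4, tau_ref = 3)
  s <- simulate_neuron(p, noise_spec(mu = 8, sigma = 2), duration = 5,
                       seed = 3)
  expect_gt(length(s$spikes), 50)
  expect_true(all(diff(s$spikes) >= p$tau_ref))
})

test_that("identical seeds give bit-identical spike records", {
  net <- build_cortical_layer(N = 100, seed = 5)
  a <- simulate_network(net, 2, stimulus_spec(1, 10, t_on = 0, t_off = 2),
                        seed = 9)
  b <- simulate_network(net, 2, stimulus_spec(1, 10, t_on = 0, t_off = 2),
                        seed = 9)
  expect_identical(a$spikes, b$spikes)
  expect_identical(a$g_final, b$g_final)
  c <- simulate_network(net, 2, stimulus_spec(1, 10, t_on = 0, t_off = 2),
                        seed = 10)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("passive PSD is a low-pass Lorentzian with lines at the stimulation frequency", {
  p <- neuron_params(tau_m = 10)
  nz <- noise_spec(mu = 0, sigma = 1)
  st <- stimulus_spec(0.5, 25, t_on = 0, t_off = Inf)
  psd <- passive_psd(c(0, 1000 / (2 * pi * p$tau_m), 1e6), p, nz, st)
  # half-power at omega = 1/(2 pi tau_m)
  expect_equal(psd$density[2] / psd$density[1], 0.5, tolerance = 1e-12)
  expect_lt(psd$density[3], 1e-6 * psd$density[1])     # low-pass limit
  expect_equal(sort(psd$lines$omega), c(-25, 25))
  expect_equal(psd$lines$power[1],
               (0.5^2 / 4) / (1 + 4 * pi^2 * (0.01)^2 * 25^2))
  expect_equal(nrow(passive_psd(1, p, nz, stimulus_spec())$lines), 0)
})

test_that("F-I curve is zero below rheobase and analytic above it (sigma = 0)", {
  p <- neuron_params(tau_m = 10, tau_ref = 2)
  quiet <- noise_spec(mu = 0, sigma = 0)
  fi <- fi_curve(c(4, 5.9, 6.5, 8, 12), p, quiet, duration = 2, n_trials = 1,
                 seed = 1)
  expect_equal(fi$rate[1:2], c(0, 0))
  expect_equal(fi$rate[3:5], 1000 / lif_isi(c(6.5, 8, 12), p),
               tolerance = 0.02)
  expect_true(all(diff(fi$rate) >= 0))   # monotone in the drive
  expect_error(fi_curve(numeric(0), p, quiet), "non-empty")
})

test_that("faster membranes stay phase-locked to higher stimulation frequencies", {
  # subthreshold drift (mu = 5.9 < 6) made suprathreshold only by the
  # stimulation peaks: a fast cell follows one-spike-per-cycle far beyond a
  # slow cell
  quiet <- noise_spec(mu = 5.9, sigma = 0)
  st35 <- stimulus_spec(0.5, 35, t_on = 0, t_off = 10)
  fast <- simulate_neuron(neuron_params(tau_m = 6, tau_ref = 0), quiet, st35,
                          duration = 10, seed = 1)
  slow <- simulate_neuron(neuron_params(tau_m = 14, tau_ref = 0), quiet, st35,
                          duration = 10, seed = 1)
  expect_equal(length(fast$spikes) / 10, 35, tolerance = 0.01)
  expect_gt(phase_histogram(fast$spikes, st35)$vector_strength, 0.99)
  expect_lt(length(slow$spikes) / 10, 0.5 * 35)
  # the slow cell still locks 1:1 at a lower frequency
  st15 <- stimulus_spec(0.5, 15, t_on = 0, t_off = 10)
  slow15 <- simulate_neuron(neuron_params(tau_m = 14, tau_ref = 0), quiet,
                            st15, duration = 10, seed = 1)
  expect_equal(length(slow15$spikes) / 10, 15, tolerance = 0.01)
})
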