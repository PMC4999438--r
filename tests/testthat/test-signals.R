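# Spectral analysis, band power, stimulus-locked averaging and spike
# histograms, checked against closed forms and brute-force oracles.

test_that("the periodogram is Parseval-consistent and finds pure tones", {
  t_s <- (0:8999) / 1000
  x <- sin(2 * pi * 40 * t_s)
  ps <- power_spectrum(x, fs_hz = 1000)
  expect_equal(ps$freq_hz[which.max(ps$power)], 40, tolerance = 1e-9)
  set.seed(1)
  y <- rnorm(4000)
  psy <- power_spectrum(y, fs_hz = 1000, detrend = TRUE)
  expect_equal(sum(psy$power), mean((y - mean(y))^2), tolerance = 1e-6)
  expect_error(power_spectrum(x[1:500], fs_hz = 1000), "at least 1 s")
})

test_that("white noise shows no dominant narrowband peak", {
  n_bad <- 0
  for (s in 1:100) {
    set.seed(s)
    ps <- power_spectrum(rnorm(2000), fs_hz = 1000)
    if (max(ps$power) > 5 * median(ps$power) * 3) n_bad <- n_bad + 1
  }
  expect_lte(n_bad, 5)
})

test_that("band power separates components and respects resolution", {
  t_s <- (0:9999) / 1000
  x <- sin(2 * pi * 40 * t_s)
  ps <- power_spectrum(x, fs_hz = 1000)
  expect_gt(band_power(ps, 40) / sum(ps$power), 0.99)
  expect_lt(band_power(ps, 30), 0.01 * band_power(ps, 40))
  two <- sin(2 * pi * 20 * t_s) + sin(2 * pi * 40 * t_s)
  ps2 <- power_spectrum(two, fs_hz = 1000)
  expect_equal(band_power(ps2, 20), band_power(ps2, 40), tolerance = 0.01)
  expect_error(band_power(ps, 40, halfwidth = 1e-5), "resolution")
})

test_that("two-cycle averages equal brute-force segment means", {
  train <- generate_click_train(stimulus_spec("periodic", 40, 4000))
  # alternating tall/short cycle peaks: a 20 Hz component on top of 40 Hz
  t_s <- (0:3999) / 1000
  x <- sin(2 * pi * 40 * t_s) + 0.6 * sin(2 * pi * 20 * t_s)
  sla <- stimulus_locked_average(x, train, n_cycles = 2, fs_hz = 1000)
  starts <- train$times[seq(1, length(train$times), 2)]
  oracle <- oracle_segment_mean(x, starts, 50)
  expect_equal(sla$avg, oracle, tolerance = 1e-12)
  # the two-peak asymmetry is preserved
  expect_gt(max(sla$avg[1:25]) - max(sla$avg[26:50]), 0.1)
  # exactly periodic trace: the average equals any single 50 ms stretch
  xp <- rep(sin(2 * pi * (0:49) / 50), 80)
  slp <- stimulus_locked_average(xp, generate_click_train(
    stimulus_spec("periodic", 40, 4000)), fs_hz = 1000)
  expect_equal(slp$avg, xp[1:50], tolerance = 1e-12)
})

test_that("averaging noise shrinks like one over root n segments", {
  set.seed(2)
  amp <- vapply(c(2000, 8000, 32000), function(dur) {
    tr <- generate_click_train(stimulus_spec("periodic", 40, dur))
    x <- rnorm(dur)
    sd(stimulus_locked_average(x, tr, fs_hz = 1000)$avg)
  }, numeric(1))
  expect_equal(amp[1] / amp[2], 2, tolerance = 0.35)
  expect_equal(amp[2] / amp[3], 2, tolerance = 0.35)
})

test_that("locking is refused for irregular trains and short traces", {
  pois <- generate_click_train(stimulus_spec("poisson", 40, 4000, seed = 1))
  expect_error(stimulus_locked_average(rnorm(4000), pois), "poisson")
  short <- generate_click_train(stimulus_spec("periodic", 40, 300))
  expect_error(stimulus_locked_average(rnorm(300), short), "10 segments")
})

test_that("spike histograms count phases exactly", {
  train <- generate_click_train(stimulus_spec("periodic", 40, 2000))
  h0 <- spike_histogram(numeric(0), train)
  expect_true(all(h0$counts == 0))
  # spikes exactly at click times concentrate in the two click-phase bins
  h1 <- spike_histogram(train$times + 1e-6, train)
  nz <- which(h1$counts > 0)
  expect_true(all(h1$bin_centers_ms[nz] %in% c(0.5, 25.5)))
  # the histogram total equals the windowed spike count
  set.seed(4)
  sp <- runif(300, 0, 2000)
  h2 <- spike_histogram(sp, train)
  starts <- train$times[seq(1, length(train$times), 2)]
  starts <- starts[starts + 50 <= 2000]
  expected <- sum(vapply(starts, function(s0)
    sum(sp >= s0 & sp < s0 + 50), numeric(1)))
  expect_equal(sum(h2$counts), expected)
})

test_that("suppressing alternate cycles moves band power 40 -> 20 Hz", {
  plain <- generate_cycle_skipping_eeg(40, 8000, skip_every = Inf)
  skipped <- generate_cycle_skipping_eeg(40, 8000, skip_every = 2)
  pp <- power_spectrum(plain)
  pk <- power_spectrum(skipped)
  expect_gt(band_power(pk, 20), band_power(pp, 20))
  expect_lt(band_power(pk, 40), band_power(pp, 40))
})

test_that("the simulated EEG is the attenuated synaptic current sum", {
  # a single weak thalamic event onto one quiescent cell: the trace follows
  # the dual-exponential conductance times the (approximately constant)
  # driving force at the receiving compartment
  cfg <- network_config(e_grid = c(1, 1), i_grid = c(1, 1),
                        background_rate_hz = 0, seed = 1)
  net <- build_network(cfg)
  tr <- event_train <- generate_click_train(stimulus_spec("periodic", 0.5, 1900))
  res <- run_simulation(net, tr, simulation_config(duration_ms = 1900,
                                                   transient_ms = 0,
                                                   eeg_dt_ms = 1))
  eeg <- compute_eeg(res)
  st <- net$synapse_table
  g_eff <- st$g_ns[st$pathway == "ThE"] *
    net$config$pyramidal$compartments$syn_attenuation[2]
  # driving force at rest; compare shape in the low-depolarization tail
  tt <- (0:1899) + 0.5
  pred <- dual_exp_conductance(pmax(tt, 0), 1, 3, g_eff) * 67
  # scale-free shape comparison on the decay tail (10-20 ms post event)
  win <- 11:20
  expect_gt(cor(eeg[win], pred[win]), 0.98)
  # linearity: doubling the weight doubles the trace
  st2 <- st
  st2$g_ns[st2$pathway == "ThE"] <- st2$g_ns[st2$pathway == "ThE"] * 2
  net2 <- build_network(network_config(e_grid = c(1, 1), i_grid = c(1, 1),
                                       background_rate_hz = 0, seed = 1,
                                       synapse_table = st2))
  res2 <- run_simulation(net2, tr, simulation_config(duration_ms = 1900,
                                                     transient_ms = 0))
  expect_equal(compute_eeg(res2)[win] / eeg[win], rep(2, length(win)),
               tolerance = 0.05)
  # no events anywhere -> identically zero EEG
  res0 <- run_simulation(build_network(cfg),
                         generate_click_train(stimulus_spec("periodic", 0, 1900)),
                         simulation_config(duration_ms = 1900, transient_ms = 0))
  expect_true(all(compute_eeg(res0) == 0))
})
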