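test_that("orientation tuning hits its anchors and is symmetric", {
  expect_equal(orientation_on_rate(45, 45), 14)
  expect_equal(orientation_on_rate(45, 135), 0.5) # orthogonal orientation
  th <- seq(0, 180, by = 22.5)
  expect_equal(
    orientation_on_rate(0, th),
    orientation_on_rate(0, -th)
  )
  # monotone decrease from preferred to orthogonal on the wheel
  wheel <- orientation_on_rate(0, seq(0, 90, by = 22.5))
  expect_true(all(diff(wheel) < 0))
})

test_that("state switching respects rates and the active-duration cap", {
  seq1 <- sample_state_sequence(1, 20, 500000, seed = 2)
  per <- seq1$periods
  act <- per$duration_ms[per$state == "elevated"]
  bg <- per$duration_ms[per$state == "background"]
  bg <- bg[is.finite(bg)]
  expect_true(all(act <= 150))
  # mean background duration ~ 1/omega_on = 1000 ms within 3 SE
  expect_lt(
    abs(mean(bg) - 1000),
    3 * stats::sd(bg) / sqrt(length(bg))
  )
  # omega_on = 0 never leaves the background state
  all_bg <- sample_state_sequence(0, 20, 10000, seed = 3)
  expect_true(all(all_bg$state == 0L))
  # reproducible given the seed
  expect_identical(
    sample_state_sequence(2, 20, 5000, seed = 7)$state,
    sample_state_sequence(2, 20, 5000, seed = 7)$state
  )
})

test_that("capped duration sampler never exceeds the cap", {
  d <- sample_active_durations(10000, omega_off = 20, max_ms = 150, seed = 4)
  expect_true(all(d <= 150))
  expect_gt(mean(d == 150), 0.01) # the cap actually binds sometimes
})

test_that("OU rates revert to state equilibria with the configured spread", {
  # zero SD: the trace equals the state-dependent equilibrium exactly
  st <- c(rep(0L, 50), rep(1L, 50))
  r0 <- sample_ou_rates(st,
    ou = ou_params(sd_background = 0, sd_elevated = 0),
    seed = 5
  )
  expect_identical(r0, ifelse(st == 1, 20, 5))
  # long background-only run: sample SD close to 2.5 Hz
  rb <- sample_ou_rates(rep(0L, 400000), seed = 6)
  expect_equal(stats::sd(rb), 2.5, tolerance = 0.1)
  expect_equal(mean(rb), 5, tolerance = 0.1)
  # autocorrelation decays on the configured 500 ms timescale
  ts <- autocorrelation_timescale(rb - mean(rb), dt = 1, max_lag_ms = 2000)
  expect_equal(ts, 500, tolerance = 0.2)
})

test_that("inhibition tracks mean excitation between its anchors", {
  expect_equal(inhibitory_rate(5), 20)
  expect_equal(inhibitory_rate(20), 30)
  expect_equal(inhibitory_rate(12.5), 25) # midpoint of the affine map
})

test_that("Poisson sampling matches the rate integral and the seed contract", {
  g <- time_grid(1, 200000)
  expect_length(sample_poisson_spikes(rep(0, g$n_bins), g, seed = 1), 0)
  n <- length(sample_poisson_spikes(rep(5, g$n_bins), g, seed = 2))
  expect_lt(abs(n - 1000), 3 * sqrt(1000))
  s1 <- sample_poisson_spikes(rep(5, g$n_bins), g, seed = 3)
  s2 <- sample_poisson_spikes(rep(5, g$n_bins), g, seed = 4)
  expect_false(identical(s1, s2))
  expect_identical(s1, sample_poisson_spikes(rep(5, g$n_bins), g, seed = 3))
})

test_that("a default session is 16 orientation blocks of 3 s", {
  cfg <- ensemble_config(n_ensembles = 3, n_exc = 12, n_inh = 3)
  inp <- generate_inputs(cfg, seed = 9)
  expect_equal(nrow(inp$schedule), 16L)
  expect_equal(unique(diff(inp$schedule$t_start_ms)), 3000)
  expect_equal(grid_duration(inp$grid), 48000)
  expect_equal(
    sort(unique(inp$spikes$label)),
    c("excitatory", "inhibitory")
  )
  # preferred orientations sit on the 22.5 degree wheel
  expect_true(all(inp$ensembles$preferred_deg %% 22.5 == 0))
  # determinism: identical seed, identical dataset
  inp2 <- generate_inputs(cfg, seed = 9)
  expect_identical(inp$spikes, inp2$spikes)
  expect_identical(inp$rates, inp2$rates)
})

test_that("state-conditional spike rates match the configured rates", {
  cfg <- ensemble_config(
    n_ensembles = 1, n_exc = 50, n_inh = 0,
    ou = ou_params(sd_background = 0, sd_elevated = 0)
  )
  inp <- generate_inputs(cfg,
    duration_s = 100, orientations_deg = 0,
    block_s = 100, seed = 12
  )
  st <- inp$states$state
  counts <- bin_events(inp$spikes$time_ms, inp$grid)
  for (s in 0:1) {
    n_bins <- sum(st == s)
    n_spk <- sum(counts[st == s])
    rate <- n_spk / (n_bins / 1000) / 50
    want <- if (s == 0) 5 else 20
    se <- sqrt(n_spk) / (n_bins / 1000) / 50
    expect_lt(abs(rate - want), 3 * se + 0.02 * want)
  }
})

test_that("correlations are shared within but not across ensembles", {
  cfg <- ensemble_config(n_ensembles = 4, n_exc = 40, n_inh = 0)
  inp <- generate_inputs(cfg,
    duration_s = 120, orientations_deg = 0,
    block_s = 120, seed = 14
  )
  # spike counts in 100 ms windows per synapse
  win <- 100
  n_win <- grid_duration(inp$grid) / win
  ids <- inp$synapses$synapse_id[inp$synapses$label == "excitatory"]
  m <- vapply(ids, function(i) {
    tt <- inp$spikes$time_ms[inp$spikes$synapse_id == i]
    tabulate(floor(tt / win) + 1, nbins = n_win)
  }, numeric(n_win))
  ens <- inp$synapses$ensemble_id[match(ids, inp$synapses$synapse_id)]
  cc <- stats::cor(m)
  same <- outer(ens, ens, "==") & !diag(TRUE, length(ids))
  diff_ens <- outer(ens, ens, "!=")
  expect_gt(mean(cc[same]), 0.1)
  expect_lt(abs(mean(cc[diff_ens])), 0.05)
})
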