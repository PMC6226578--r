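test_that("raised-cosine basis has unit peaks on log-spaced supports", {
  g <- time_grid(1, 2000)
  b <- raised_cosine_basis(g)
  expect_equal(b$n_basis, 10L)
  expect_equal(ncol(b$psi), 10L)
  # peak value 1 exactly at the centre tau_i = exp(phi_i / a) - c
  for (i in seq_len(10)) {
    tau_i <- exp(b$phi[i] / b$a) - b$c
    z <- b$a * log(tau_i + b$c)
    expect_equal(0.5 * (cos(z - b$phi[i]) + 1), 1)
  }
  # zero outside the inverted support condition
  for (i in c(1, 5, 10)) {
    supp <- hlnd:::basis_support(b, i)
    outside <- b$lag_ms < supp[1] - 1 | b$lag_ms > supp[2] + 1
    expect_true(all(b$psi[outside, i] == 0))
    inside <- b$lag_ms > supp[1] + 1 & b$lag_ms < supp[2] - 1
    expect_true(all(b$psi[inside, i] > 0))
  }
  expect_error(raised_cosine_basis(g, phi_range = c(5, 5)), "increasing")
})

test_that("adaptation adds basis waveforms per output spike", {
  syn <- make_synapses(4, 0)
  arch <- make_teacher_single(syn, v0 = -65)
  g <- time_grid(1, 3000)
  spk <- make_poisson_spikes(syn, 8, 3000, seed = 3)
  b <- raised_cosine_basis(g, n_basis = 3, phi_range = c(3, 10))
  v_plain <- hln_forward(spk, arch, g)$v_mv
  # gamma = 0 reduces exactly to the forward response
  v0g <- subthreshold_with_adaptation(spk, arch, c(500), b, rep(0, 3), g)$v_mv
  expect_identical(v0g, v_plain)
  # one spike, one active basis: the trace gains that basis waveform
  v1 <- subthreshold_with_adaptation(spk, arch, c(500), b, c(1, 0, 0), g)$v_mv
  added <- v1 - v_plain
  spike_bin <- 501
  expect_equal(
    added[spike_bin:(spike_bin + nrow(b$psi) - 1)],
    b$psi[, 1],
    tolerance = 1e-9
  )
  # two spikes superpose linearly
  v2 <- subthreshold_with_adaptation(
    spk, arch, c(500, 900), b, c(1, 0, 0), g
  )$v_mv
  vb <- subthreshold_with_adaptation(spk, arch, c(900), b, c(1, 0, 0), g)$v_mv
  expect_equal(v2 - v_plain, (v1 - v_plain) + (vb - v_plain), tolerance = 1e-9)
  expect_error(
    subthreshold_with_adaptation(spk, arch, 500, b, c(1, 0), g),
    "one weight per basis"
  )
})

test_that("the rate nonlinearity is exponential in the subthreshold signal", {
  v <- rep(0, 100)
  expect_equal(firing_rate(v, lambda0 = 3, beta = 2), rep(3, 100))
  expect_equal(firing_rate(stats::rnorm(50), 4, beta = 0), rep(4, 50))
  beta <- 0.7
  expect_equal(firing_rate(log(2) / beta, 5, beta), 10)
  expect_error(firing_rate(v, lambda0 = 0, beta = 1), "positive")
})

test_that("the thinning sampler delivers the integral of the rate", {
  g <- time_grid(1, 100000) # 100 s
  rate <- rep(20, g$n_bins)
  counts <- vapply(
    1:10,
    function(s) length(sample_spikes_thinning(rate, g, seed = s)),
    numeric(1)
  )
  expected <- 20 * 100
  se <- sqrt(expected / 10)
  expect_lt(abs(mean(counts) - expected), 3 * se + 0.01 * expected)
})

test_that("spiking MLE reduces to the homogeneous Poisson rate", {
  g <- time_grid(1, 200000)
  v <- rep(0, g$n_bins)
  spikes <- sample_spikes_thinning(rep(5, g$n_bins), g, seed = 8)
  fitp <- fit_spiking(v, spikes, g)
  expect_equal(fitp$lambda0, length(spikes) / 200, tolerance = 1e-4)
  expect_gte(fitp$loglik, fitp$loglik_homogeneous - 1e-6)
  expect_warning(out <- fit_spiking(v, numeric(0), g), "No output spikes")
  expect_equal(out$lambda0, 1e-4)
})

test_that("the spiking likelihood optimum is start-independent (concavity)", {
  g <- time_grid(1, 100000)
  withr::with_seed(12, {
    v <- as.numeric(stats::filter(
      stats::rnorm(g$n_bins), rep(1 / 30, 30),
      circular = TRUE
    )) * sqrt(30)
  })
  lam <- firing_rate(v, 3, 0.8)
  spikes <- sample_spikes_thinning(lam, g, seed = 13)
  f1 <- fit_spiking(v, spikes, g)
  # same optimum from a deliberately distant start: refit on shifted data
  f2 <- fit_spiking(v + 5, spikes, g) # v shifted: lambda0 absorbs exp(5 beta)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-3)
  expect_equal(f2$lambda0 * exp(5 * f2$beta), f1$lambda0, tolerance = 1e-3)
  # and parameters are recovered reasonably even at this short duration
  expect_equal(f1$lambda0, 3, tolerance = 0.15)
  expect_equal(f1$beta, 0.8, tolerance = 0.15)
})

test_that("the closed-loop hGLM simulation feeds spikes back through adaptation", {
  syn <- make_synapses(6, 0)
  arch <- make_teacher_single(syn, v0 = 0)
  g <- time_grid(1, 20000)
  spk <- make_poisson_spikes(syn, 10, 20000, seed = 17)
  b <- raised_cosine_basis(g)
  sim_free <- simulate_hglm(spk, arch, g, lambda0 = 20, beta = 0.3, seed = 19)
  sim_adapt <- simulate_hglm(spk, arch, g,
    lambda0 = 20, beta = 0.3,
    basis = b, gamma = c(-5, rep(0, 9)), seed = 19
  )
  # strong negative adaptation suppresses spiking
  expect_lt(length(sim_adapt$spike_times), length(sim_free$spike_times))
  expect_gt(length(sim_adapt$spike_times), 0)
})
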