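test_that("the subunit nonlinearity is a threshold-shifted logistic", {
  expect_equal(sigmoid(3, theta = 3), 0.5)
  expect_equal(sigmoid(1e4, 0), 1)
  expect_equal(sigmoid(-1e4, 0), 0)
  y <- seq(-5, 5, by = 0.1)
  expect_true(all(diff(sigmoid(y, 1.2)) > 0))
})

test_that("forward with no spikes and zero kernels is the constant offset", {
  arch <- make_teacher_single(make_synapses(4, 2), v0 = -71)
  arch$kernels$w_fast <- 0
  g <- time_grid(1, 300)
  spk <- tibble::tibble(synapse_id = integer(0), time_ms = numeric(0))
  expect_equal(hln_forward(spk, arch, g)$v_mv, rep(-71, 300))
})

test_that("single spike through a linear root equals offset plus kernel", {
  syn <- make_synapses(1, 0)
  arch <- make_teacher_single(syn, v0 = -70, delay_ms = 2)
  g <- time_grid(1, 400)
  spk <- tibble::tibble(synapse_id = 1L, time_ms = 100)
  v <- hln_forward(spk, arch, g)$v_mv
  p <- kernel_params(
    w_fast = arch$kernels$w_fast[1], tau_fast = arch$kernels$tau_fast[1],
    delay = 2
  )
  expect_equal(v, -70 + oracle_convolve(100, p, g), tolerance = 1e-9)
})

test_that("zero input into a sigmoidal channel gives a constant one half", {
  syn <- make_synapses(2, 0)
  arch <- hln_architecture(
    tibble::tibble(
      subunit_id = 1L, parent_id = NA, nonlinear = TRUE, theta = 0
    ),
    syn,
    v0 = 0
  )
  arch$kernels$w_fast <- 0
  g <- time_grid(1, 100)
  spk <- tibble::tibble(synapse_id = 1L, time_ms = 50)
  # v = coupling * sigmoid(0) + v0 = 0.5
  expect_equal(hln_forward(spk, arch, g)$v_mv, rep(0.5, 100))
})

test_that("two identical multiplexed channels double the single-channel output", {
  syn <- make_synapses(6, 0)
  single <- hln_architecture(
    tibble::tibble(
      subunit_id = 1L, parent_id = NA, nonlinear = TRUE, theta = 0.7
    ),
    syn,
    v0 = -65
  )
  single$kernels$w_fast <- 0.4
  duplex <- hln_architecture(
    tibble::tibble(
      subunit_id = 1L, parent_id = NA, nonlinear = TRUE,
      n_channels = 2L, theta = 0.7, theta2 = 0.7
    ),
    syn,
    v0 = -65
  )
  duplex$kernels$w_fast <- 0.4
  g <- time_grid(1, 2000)
  spk <- make_poisson_spikes(syn, 10, 2000, seed = 5)
  v1 <- hln_forward(spk, single, g)$v_mv
  v2 <- hln_forward(spk, duplex, g)$v_mv
  expect_equal(v2 - (-65), 2 * (v1 - (-65)), tolerance = 1e-12)
})

test_that("a child in its zeroed/linear regime reproduces the smaller model", {
  # nested-model consistency: adding a subunit with zero kernel amplitudes
  # and a linear channel leaves the forward response unchanged up to the
  # constant absorbed by v0
  syn <- make_synapses(8, 2)
  small <- make_teacher_single(syn, v0 = -70)
  syn2 <- small$synapses
  big <- hln_architecture(
    tibble::tibble(
      subunit_id = c(1L, 2L), parent_id = c(NA, 1L),
      nonlinear = FALSE, delay_ms = c(1, 0)
    ),
    dplyr::bind_rows(
      syn2,
      tibble::tibble(
        synapse_id = 99L, subunit_id = 2L, group_id = 5L,
        label = "excitatory", position_class = NA_character_
      )
    ),
    v0 = -70
  )
  big$kernels$w_fast[big$kernels$subunit_id == 1L] <- small$kernels$w_fast
  big$kernels$tau_fast[big$kernels$subunit_id == 1L] <- small$kernels$tau_fast
  big$kernels$w_fast[big$kernels$subunit_id == 2L] <- 0
  big$subunits$delay_ms <- c(1, 0)
  g <- time_grid(1, 3000)
  spk <- make_poisson_spikes(syn, 8, 3000, seed = 7)
  expect_equal(
    hln_forward(spk, big, g)$v_mv,
    hln_forward(spk, small, g)$v_mv,
    tolerance = 1e-12
  )
})

test_that("forward is invariant to subunit storage order", {
  arch <- make_teacher_two()
  g <- time_grid(1, 2000)
  spk <- make_poisson_spikes(arch$synapses, 10, 2000, seed = 9)
  v1 <- hln_forward(spk, arch, g)$v_mv
  arch2 <- arch
  arch2$subunits <- arch2$subunits[c(2, 1), ]
  arch2$kernels <- arch2$kernels[rev(seq_len(nrow(arch2$kernels))), ]
  expect_identical(hln_forward(spk, arch2, g)$v_mv, v1)
})

test_that("bypassing all nonlinearities equals per-synapse superposition", {
  arch <- make_teacher_two()
  arch$channels$nonlinear <- rep(FALSE, nrow(arch$channels))
  g <- time_grid(1, 4000)
  spk <- make_poisson_spikes(arch$synapses, 10, 4000, seed = 13)
  v <- hln_forward(spk, arch, g)$v_mv
  # superposition oracle: each synapse's kernel, scaled by the couplings on
  # its path to the root, plus v0
  oracle <- rep(arch$v0, g$n_bins)
  for (i in seq_len(nrow(arch$synapses))) {
    srow <- arch$synapses[i, ]
    kr <- arch$kernels[arch$kernels$subunit_id == srow$subunit_id &
      arch$kernels$group_id == srow$group_id, ]
    cpath <- arch$subunits$coupling[arch$subunits$subunit_id == srow$subunit_id]
    p <- arch$subunits$parent_id[arch$subunits$subunit_id == srow$subunit_id]
    while (!is.na(p)) {
      cpath <- cpath * arch$subunits$coupling[arch$subunits$subunit_id == p]
      p <- arch$subunits$parent_id[arch$subunits$subunit_id == p]
    }
    tt <- spk$time_ms[spk$synapse_id == srow$synapse_id]
    delay <- arch$subunits$delay_ms[arch$subunits$subunit_id == srow$subunit_id]
    oracle <- oracle + cpath * oracle_convolve(
      tt, kernel_params(kr$w_fast, kr$tau_fast, delay = delay), g
    )
  }
  expect_equal(v, oracle, tolerance = 1e-9)
})

test_that("spikes from unassigned synapses are reported by id", {
  arch <- make_teacher_single(make_synapses(3, 0))
  g <- time_grid(1, 100)
  spk <- tibble::tibble(synapse_id = c(1L, 77L), time_ms = c(10, 20))
  expect_error(hln_forward(spk, arch, g), "77")
})

test_that("synapse amplitudes compose kernel weight, couplings and slopes", {
  # all-linear: amplitude is w times the product of couplings on the path
  arch <- make_teacher_two()
  arch$channels$nonlinear <- rep(FALSE, nrow(arch$channels))
  syn_child <- arch$synapses$synapse_id[arch$synapses$subunit_id == 2L][1]
  w <- arch$kernels$w_fast[arch$kernels$subunit_id == 2L]
  expect_equal(synapse_amplitude(arch, syn_child), w * 5 * 1)
  # zero weight gives zero amplitude
  arch0 <- arch
  arch0$kernels$w_fast[arch0$kernels$subunit_id == 2L] <- 0
  expect_equal(synapse_amplitude(arch0, syn_child), 0)
  # single nonlinear subunit at its threshold operating point: the logistic
  # slope there, obtained by numeric differentiation, is 1/4
  syn <- make_synapses(1, 0)
  nl <- hln_architecture(
    tibble::tibble(subunit_id = 1L, parent_id = NA, nonlinear = TRUE, theta = 1.3),
    syn,
    v0 = 0
  )
  nl$kernels$w_fast <- 0.6
  nl$subunits$coupling <- 2
  h <- 1e-6
  slope_fd <- (sigmoid(1.3 + h, 1.3) - sigmoid(1.3 - h, 1.3)) / (2 * h)
  expect_equal(
    synapse_amplitude(nl, 1, y_means = list("1.1" = 1.3)),
    0.6 * 2 * slope_fd,
    tolerance = 1e-9
  )
  expect_error(synapse_amplitude(nl, 42), "not found")
})
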