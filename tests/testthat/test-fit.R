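test_that("the loss is the mean squared deviation in mV^2", {
  arch <- make_teacher_single(make_synapses(4, 2))
  g <- time_grid(1, 1000)
  spk <- make_poisson_spikes(arch$synapses, 10, 1000, seed = 2)
  v <- hln_forward(spk, arch, g)
  # the generating parameters reproduce their own output exactly
  expect_equal(hln_loss(arch, spk, v, g), 0, tolerance = 1e-20)
  # a constant 1 mV offset costs exactly 1 mV^2
  expect_equal(hln_loss(arch, spk, v$v_mv + 1, g), 1, tolerance = 1e-12)
  expect_error(hln_loss(arch, spk, v$v_mv[-1], g), "different lengths")
})

test_that("analytic gradients match central finite differences", {
  # one architecture exercising every parameter class: double and coupled
  # kernels, thresholds, couplings, offset; taus chosen so the finite
  # difference never straddles a support-truncation bin boundary
  withr::with_seed(42, {
    g <- time_grid(1, 3000)
    syn <- make_synapses(16, 4)
    syn$subunit_id <- rep(c(1L, 2L), 10)
    arch <- hln_architecture(
      tibble::tibble(
        subunit_id = c(1L, 2L), parent_id = c(NA, 1L),
        nonlinear = TRUE, delay_ms = 1
      ),
      syn,
      v0 = -69
    )
    arch$kernels$w_fast <- c(0.3, -0.2, 0.25, -0.15)
    arch$kernels$tau_fast <- c(9.73, 13.31, 7.12, 21.73)
    arch$kernels$w_slow[1] <- 0.1
    arch$kernels$coupled[1] <- TRUE
    arch$kernels$tau_slow[1] <- coupled_tau_slow(9.73)
    arch$kernels$w_slow[3] <- 0.05
    arch$kernels$tau_slow[3] <- 33.77
    arch$subunits$coupling <- c(1.5, 0.8)
    arch$channels$theta <- c(0.2, 0.4)
    spk <- tibble::tibble(
      synapse_id = sample(1:20, 300, TRUE),
      time_ms = sort(stats::runif(300, 0, 2999))
    )
    target <- stats::rnorm(g$n_bins, -69, 1)
    map <- hlnd:::hln_par_map(arch, tie = "none")
    prior <- hlnd:::prior_from_map(map, map$init, sd = 0.5, weight = 0.01)
    for (pr in list(NULL, prior)) {
      res <- hln_loss(arch, spk, target, g, prior = pr, gradient = TRUE)
      p0 <- map$init
      fd <- vapply(names(p0), function(nm) {
        h <- 1e-6 * max(1, abs(p0[[nm]]))
        pp <- p0
        pp[[nm]] <- pp[[nm]] + h
        pm <- p0
        pm[[nm]] <- pm[[nm]] - h
        (hln_loss(hlnd:::hln_unpack(arch, map, pp), spk, target, g, prior = pr) -
          hln_loss(hlnd:::hln_unpack(arch, map, pm), spk, target, g, prior = pr)) /
          (2 * h)
      }, numeric(1))
      rel <- abs(fd - res$gradient) / pmax(abs(fd), 1e-8)
      expect_lt(max(rel), 1e-5)
    }
  })
})

test_that("coupled stage recovers shared kernels from self-generated data", {
  syn <- make_synapses(20, 5)
  teacher <- make_teacher_single(syn, v0 = -70, delay_ms = 1)
  # force shared kernels (one group per label already)
  g <- time_grid(1, 10000)
  spk <- make_poisson_spikes(syn, 10, 10000, seed = 21)
  target <- hln_forward(spk, teacher, g)
  res <- fit_stage_coupled(spk, target, g, quick_fit_config())
  expect_equal(res$delay_ms, 1)
  expect_equal(
    res$arch$kernels$w_fast, teacher$kernels$w_fast,
    tolerance = 0.02
  )
  expect_equal(
    res$arch$kernels$tau_fast, teacher$kernels$tau_fast,
    tolerance = 0.02
  )
  expect_equal(res$arch$v0, -70, tolerance = 1e-3)
  expect_lt(res$train_mse, 1e-6)
})

test_that("an all-zero target drives amplitudes and offset to zero", {
  syn <- make_synapses(6, 2)
  g <- time_grid(1, 5000)
  spk <- make_poisson_spikes(syn, 10, 5000, seed = 22)
  res <- fit_stage_coupled(spk, rep(0, g$n_bins), g, quick_fit_config())
  expect_lt(max(abs(res$arch$kernels$w_fast)), 1e-4)
  expect_lt(abs(res$arch$v0), 1e-4)
})

test_that("pretuning centres subunit input on the sigmoid at SD 1/rho while
           preserving somatic amplitudes of the linear reference", {
  teacher <- make_teacher_two()
  g <- time_grid(1, 8000)
  spk <- make_poisson_spikes(teacher$synapses, 10, 8000, seed = 31)
  target <- hln_forward(spk, teacher, g)
  coupled <- fit_stage_coupled(spk, target, g, quick_fit_config())
  arch1 <- hlnd:::transfer_coupled(teacher, coupled)
  lin <- arch1
  lin$channels$nonlinear <- rep(FALSE, nrow(lin$channels))
  ids <- teacher$synapses$synapse_id[c(1, 10, 20)]
  a_ref <- vapply(ids, function(s) synapse_amplitude(lin, s), numeric(1))
  for (rho in c(1, 4, 8)) {
    pt <- pretune_nonlinearities(arch1, spk, g, rho)
    compiled <- hlnd:::compile_hln_inputs(spk, pt, g)
    ev <- hlnd:::hln_eval(pt, compiled, cache = TRUE)
    y2 <- ev$y[["2.1"]]
    th <- pt$channels$theta[pt$channels$subunit_id == 2L]
    expect_equal(stats::sd(y2), 1 / rho, tolerance = 1e-10)
    expect_equal(mean(y2), th, tolerance = 1e-10)
    a_pt <- vapply(
      ids, function(s) synapse_amplitude(pt, s, spk, g), numeric(1)
    )
    expect_equal(a_pt, a_ref, tolerance = 1e-9)
  }
  # rho -> infinity: the pretuned model converges to linear integration
  d8 <- max(abs(
    hln_forward(spk, pretune_nonlinearities(arch1, spk, g, 8), g)$v_mv -
      hln_forward(spk, lin, g)$v_mv
  ))
  d64 <- max(abs(
    hln_forward(spk, pretune_nonlinearities(arch1, spk, g, 64), g)$v_mv -
      hln_forward(spk, lin, g)$v_mv
  ))
  expect_lt(d64, d8 / 10)
  expect_lt(d64, 1e-3)
})

test_that("pretuning a silent subunit is a degenerate-input error", {
  teacher <- make_teacher_two()
  g <- time_grid(1, 1000)
  # no spikes at all for subunit 2's synapses
  spk <- make_poisson_spikes(
    teacher$synapses[teacher$synapses$subunit_id == 1L, ], 10, 1000,
    seed = 5
  )
  expect_error(
    pretune_nonlinearities(teacher, spk, g, 2),
    "degenerate"
  )
})

test_that("the staged fit descends across stages and is deterministic", {
  teacher <- make_teacher_two()
  g <- time_grid(1, 12000)
  spk <- make_poisson_spikes(teacher$synapses, 10, 12000, seed = 41)
  target <- hln_forward(spk, teacher, g)
  cfg <- quick_fit_config()
  fit1 <- fit_hln(spk, target, teacher, g, config = cfg)
  expect_true(all(diff(fit1$stage_mse) <= 1e-12))
  expect_lt(fit1$train_mse, fit1$stage_mse[["coupled"]])
  # deterministic: the same data and configuration give the same result
  fit2 <- fit_hln(spk, target, teacher, g, config = cfg)
  expect_identical(fit1$train_mse, fit2$train_mse)
  expect_identical(fit1$arch$kernels$w_fast, fit2$arch$kernels$w_fast)
  # tidy/glance expose the fitted parameters
  td <- generics::tidy(fit1)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_true("v0" %in% td$term)
  gl <- generics::glance(fit1)
  expect_equal(nrow(gl), 1L)
  expect_lt(gl$train_mse, 1e-3)
})

test_that("positivity of taus and couplings survives optimization", {
  teacher <- make_teacher_two()
  g <- time_grid(1, 8000)
  spk <- make_poisson_spikes(teacher$synapses, 10, 8000, seed = 43)
  target <- hln_forward(spk, teacher, g)
  fit <- fit_hln(spk, target, teacher, g, config = quick_fit_config())
  expect_true(all(fit$arch$kernels$tau_fast > 0))
  expect_true(all(fit$arch$subunits$coupling > 0))
  expect_true(all(fit$arch$subunits$delay_ms >= 0))
})
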