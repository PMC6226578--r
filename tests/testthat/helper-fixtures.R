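# Shared fixtures: small synapse tables, homogeneous-Poisson spike trains
# (independent of the input-generator module, so low-level tests do not
# depend on it), and teacher architectures with known parameters.

make_synapses <- function(n_exc = 8, n_inh = 2, n_groups_exc = 1) {
  tibble::tibble(
    synapse_id = seq_len(n_exc + n_inh),
    label = rep(c("excitatory", "inhibitory"), c(n_exc, n_inh)),
    group_id = c(
      rep(seq_len(n_groups_exc), length.out = n_exc),
      rep(n_groups_exc + 1L, n_inh)
    ),
    subunit_id = 1L
  )
}

# independent homogeneous Poisson trains per synapse
make_poisson_spikes <- function(synapses, rate_hz, duration_ms, seed = 1) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(synapses)), function(i) {
      n <- stats::rpois(1, rate_hz * duration_ms / 1000)
      tibble::tibble(
        synapse_id = synapses$synapse_id[i],
        time_ms = sort(stats::runif(n, 0, duration_ms - 1e-6)),
        label = synapses$label[i]
      )
    })
  })
}

# single-subunit linear teacher with distinct per-group kernels
make_teacher_single <- function(synapses, v0 = -70, delay_ms = 1) {
  arch <- hln_architecture(
    tibble::tibble(
      subunit_id = 1L, parent_id = NA_integer_,
      nonlinear = FALSE, delay_ms = delay_ms
    ),
    synapses,
    v0 = v0
  )
  k <- nrow(arch$kernels)
  lab <- dplyr::distinct(arch$synapses, group_id, label)
  sign <- ifelse(
    lab$label[match(arch$kernels$group_id, lab$group_id)] == "excitatory",
    1, -1
  )
  arch$kernels$w_fast <- sign * seq(0.25, 0.55, length.out = k)
  arch$kernels$tau_fast <- seq(6.3, 14.9, length.out = k)
  arch
}

# two-subunit teacher: inhibition + half the excitation on the linear root,
# the rest on a sigmoidal child
make_teacher_two <- function(n_exc = 16, n_inh = 4, v0 = -70) {
  syn <- make_synapses(n_exc, n_inh)
  syn$subunit_id <- ifelse(
    syn$label == "inhibitory", 1L,
    ifelse(syn$synapse_id <= n_exc / 2, 1L, 2L)
  )
  arch <- hln_architecture(
    tibble::tibble(
      subunit_id = c(1L, 2L), parent_id = c(NA, 1L),
      nonlinear = c(FALSE, TRUE), delay_ms = 1
    ),
    syn,
    v0 = v0
  )
  arch$kernels$w_fast <- c(0.4, -0.35, 0.3)[seq_len(nrow(arch$kernels))]
  arch$kernels$tau_fast <- c(8.3, 12.2, 10.1)[seq_len(nrow(arch$kernels))]
  arch$subunits$coupling <- c(1, 5)
  arch$channels$theta[arch$channels$subunit_id == 2L] <- 1.5
  arch
}

# a fast fitting configuration for unit tests (the acceptance tests use the
# defaults)
quick_fit_config <- function(...) {
  fit_config(rho_grid = c(1, 3), delay_grid_ms = c(0, 1), maxit = 120, ...)
}

# brute-force per-spike convolution oracle: sums the sampled kernel over
# binned spike times; the reference for the FFT convolution engine
oracle_convolve <- function(times, params, grid, horizon_tau = 10) {
  out <- numeric(grid$n_bins)
  if (length(times) == 0) {
    return(out)
  }
  k <- build_kernel(params, grid, horizon_tau = horizon_tau)
  bins <- floor((times - grid$t0) / grid$dt) + 1
  for (b in bins) {
    idx <- b + seq_along(k) - 1
    keep <- idx <= grid$n_bins
    out[idx[keep]] <- out[idx[keep]] + k[keep]
  }
  out
}
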