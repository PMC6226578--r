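#' Raised-cosine adaptation basis
#'
#' Post-spike adaptation is modelled as a weighted sum of raised-cosine
#' "bump" basis functions of the time since an output spike:
#' `psi_i(tau) = 0.5 * (cos(a * log(tau + c) - phi_i) + 1)` wherever
#' `a * log(tau + c)` lies within `phi_i +/- pi`, and 0 elsewhere. The
#' centres `phi_i` are uniformly spaced, so the bumps tile log-time: narrow
#' early bumps capture fast after-spike dynamics and wide late bumps slow
#' adaptation. Lag `tau` is in ms; with the defaults (`a = 3.75`,
#' `c = 0.01`, centres from 3 to 22) the supports span roughly 1 ms to
#' 800 ms.
#'
#' @param grid A [time_grid()]; bases are sampled at lags `0, dt, 2 dt, ...`.
#' @param n_basis Number of basis functions (default 10).
#' @param a Log-time stretch factor.
#' @param c Log-time offset (ms).
#' @param phi_range Range of the uniformly spaced centres.
#' @return An object of class `adaptation_basis`: a list with the sampled
#'   basis matrix `psi` (lags x basis), the lag vector `lag_ms`, and the
#'   parameters.
#' @export
raised_cosine_basis <- function(grid, n_basis = 10, a = 3.75, c = 0.01,
                                phi_range = c(3, 22)) {
  stopifnot(inherits(grid, "time_grid"))
  if (n_basis < 1) stop("`n_basis` must be >= 1.", call. = FALSE)
  if (length(phi_range) != 2 || phi_range[1] >= phi_range[2]) {
    stop("`phi_range` must be an increasing pair.", call. = FALSE)
  }
  phi <- if (n_basis == 1) {
    mean(phi_range)
  } else {
    seq(phi_range[1], phi_range[2], length.out = n_basis)
  }
  # longest support determines how many lag bins we need
  tau_max <- exp((max(phi) + pi) / a) - c
  n_lag <- min(grid$n_bins, as.integer(ceiling(tau_max / grid$dt)) + 1L)
  lag <- (seq_len(n_lag) - 1) * grid$dt
  z <- a * log(lag + c)
  psi <- sapply(phi, function(p) {
    v <- 0.5 * (cos(z - p) + 1)
    v[z < p - pi | z > p + pi] <- 0
    v
  })
  psi <- matrix(psi, nrow = n_lag)
  structure(
    list(
      psi = psi, lag_ms = lag, phi = phi, a = a, c = c,
      n_basis = as.integer(n_basis), dt = grid$dt
    ),
    class = "adaptation_basis"
  )
}

#' @export
print.adaptation_basis <- function(x, ...) {
  cat(sprintf(
    "<adaptation_basis> %d raised-cosine bumps, supports within %g-%g ms\n",
    x$n_basis, min(x$lag_ms), max(x$lag_ms)
  ))
  invisible(x)
}

# support interval of bump i in lag (ms): invert a*log(tau+c) = phi +/- pi
basis_support <- function(basis, i) {
  c(
    exp((basis$phi[i] - pi) / basis$a) - basis$c,
    exp((basis$phi[i] + pi) / basis$a) - basis$c
  )
}

#' Subthreshold response with spike-triggered adaptation
#'
#' Evaluates the hLN response with an additive adaptation term inside the
#' root subunit's input: each output spike contributes every basis waveform,
#' weighted by the coefficients `gamma`. With `gamma = 0` this reduces to
#' [hln_forward()].
#'
#' @param spikes Presynaptic spike data frame.
#' @param arch An `hln_arch`.
#' @param out_spikes Output (somatic) spike times in ms, within the grid.
#' @param basis An [raised_cosine_basis()] built on the same grid step.
#' @param gamma Numeric vector of length `basis$n_basis` (mV weights).
#' @param grid A [time_grid()].
#' @return A voltage tibble (`time_ms`, `v_mv`).
#' @export
subthreshold_with_adaptation <- function(spikes, arch, out_spikes, basis,
                                         gamma, grid) {
  stopifnot(inherits(basis, "adaptation_basis"))
  if (!isTRUE(all.equal(basis$dt, grid$dt))) {
    stop("Adaptation basis and grid have different time steps.",
      call. = FALSE
    )
  }
  if (length(gamma) != basis$n_basis) {
    stop("`gamma` must have one weight per basis function.", call. = FALSE)
  }
  extra <- adaptation_signal(out_spikes, basis, gamma, grid)
  hln_forward(spikes, arch, grid, extra_root_input = extra)
}

adaptation_signal <- function(out_spikes, basis, gamma, grid) {
  counts <- as.numeric(bin_events(out_spikes, grid))
  extra <- numeric(grid$n_bins)
  for (i in seq_len(basis$n_basis)) {
    if (gamma[i] != 0) {
      extra <- extra + gamma[i] * causal_conv(counts, basis$psi[, i])
    }
  }
  extra
}

#' Conditional firing rate of the spiking model
#'
#' The instantaneous Poisson rate is an exponential function of the
#' subthreshold response: `lambda(t) = lambda0 * exp(beta * v(t))`.
#'
#' @param vtilde Subthreshold response (numeric vector or tibble with
#'   `v_mv`), in mV.
#' @param lambda0 Baseline rate (Hz, > 0).
#' @param beta Threshold sharpness (1/mV).
#' @return Rate trace in Hz, same length as the input.
#' @export
firing_rate <- function(vtilde, lambda0, beta) {
  if (lambda0 <= 0) stop("`lambda0` must be positive.", call. = FALSE)
  v <- as_signal(vtilde)
  lambda0 * exp(beta * v)
}

#' Sample output spikes from a rate trace
#'
#' Discrete-time thinning: at most one spike per bin, emitted with
#' probability `1 - exp(-lambda * dt)`. Spikes are stamped at bin centres.
#'
#' @param rate_hz Rate trace (Hz), one value per grid bin.
#' @param grid A [time_grid()].
#' @param seed Optional integer seed (restores the RNG state afterwards).
#' @return Numeric vector of spike times (ms).
#' @export
sample_spikes_thinning <- function(rate_hz, grid, seed = NULL) {
  stopifnot(length(rate_hz) == grid$n_bins, all(rate_hz >= 0))
  draw <- function() {
    p <- 1 - exp(-rate_hz * grid$dt / 1000)
    hit <- stats::runif(grid$n_bins) < p
    grid_times(grid)[hit] + grid$dt / 2
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Fit the spiking nonlinearity by maximum likelihood
#'
#' Maximizes the inhomogeneous-Poisson log-likelihood
#' `sum(log lambda(t_spike)) - integral(lambda)` over the baseline rate
#' `lambda0` and sharpness `beta`, given a subthreshold response. The
#' likelihood is concave in `(log lambda0, beta)`, so BFGS from any start
#' reaches the optimum. With no observed spikes, `lambda0` is returned at a
#' small lower bound with a warning.
#'
#' @param vtilde Subthreshold response (vector or tibble with `v_mv`).
#' @param spike_times Observed output spike times (ms) within the grid.
#' @param grid A [time_grid()].
#' @param lambda0_floor Lower bound used when no spikes are observed (Hz).
#' @return A list with `lambda0` (Hz), `beta` (1/mV), `loglik`, and
#'   `loglik_homogeneous` (the nested constant-rate model).
#' @export
fit_spiking <- function(vtilde, spike_times, grid, lambda0_floor = 1e-4) {
  v <- as_signal(vtilde, grid)
  dt_s <- grid$dt / 1000
  y <- as.numeric(bin_events(spike_times, grid))
  n_spk <- sum(y)
  t_tot <- grid$n_bins * dt_s
  if (n_spk == 0) {
    warning("No output spikes; returning `lambda0` at its lower bound.")
    return(list(
      lambda0 = lambda0_floor, beta = 0,
      loglik = -lambda0_floor * t_tot, loglik_homogeneous = -lambda0_floor * t_tot
    ))
  }
  # log-likelihood in (log lambda0, beta); concave
  nll <- function(par) {
    eta <- par[1] + par[2] * v
    -(sum(y * (eta + log(dt_s))) - sum(exp(eta)) * dt_s)
  }
  gr <- function(par) {
    lam_dt <- exp(par[1] + par[2] * v) * dt_s
    -c(sum(y) - sum(lam_dt), sum(y * v) - sum(lam_dt * v))
  }
  start <- c(log(n_spk / t_tot), 0)
  opt <- stats::optim(start, nll,
    gr = gr, method = "BFGS",
    control = list(maxit = 500, reltol = 1e-12)
  )
  ll_hom <- -nll(start)
  list(
    lambda0 = exp(opt$par[1]), beta = opt$par[2],
    loglik = -opt$value, loglik_homogeneous = ll_hom,
    converged = opt$convergence == 0
  )
}

#' Simulate the spiking (hGLM) model
#'
#' Runs the subthreshold model, applies the exponential rate nonlinearity
#' and samples output spikes by thinning. When adaptation weights are
#' given, spiking is simulated sequentially so each emitted spike feeds
#' back onto the subsequent membrane potential through the adaptation
#' kernels.
#'
#' @param spikes Presynaptic spike data frame.
#' @param arch An `hln_arch`.
#' @param grid A [time_grid()].
#' @param lambda0,beta Spiking parameters (see [firing_rate()]).
#' @param basis Optional [raised_cosine_basis()] for adaptation.
#' @param gamma Optional adaptation weights (mV).
#' @param seed Optional integer seed.
#' @return A list with `spike_times` (ms), `v` (voltage tibble) and
#'   `rate_hz`.
#' @export
simulate_hglm <- function(spikes, arch, grid, lambda0, beta,
                          basis = NULL, gamma = NULL, seed = NULL) {
  run <- function() {
    if (is.null(basis) || is.null(gamma) || all(gamma == 0)) {
      v <- hln_forward(spikes, arch, grid)
      lam <- firing_rate(v, lambda0, beta)
      st <- sample_spikes_thinning(lam, grid)
      return(list(spike_times = st, v = v, rate_hz = lam))
    }
    # sequential simulation with spike feedback
    compiled <- compile_hln_inputs(spikes, arch, grid)
    v_base <- hln_eval(arch, compiled)$v
    n <- grid$n_bins
    adapt <- numeric(n)
    kern <- as.numeric(basis$psi %*% gamma)
    v <- v_base
    times <- grid_times(grid)
    spk <- numeric(0)
    dt_s <- grid$dt / 1000
    u <- stats::runif(n)
    for (t in seq_len(n)) {
      v[t] <- v_base[t] + adapt[t]
      lam <- lambda0 * exp(beta * v[t])
      if (u[t] < 1 - exp(-lam * dt_s)) {
        spk <- c(spk, times[t] + grid$dt / 2)
        idx <- t + seq_along(kern)
        idx <- idx[idx <= n]
        adapt[idx] <- adapt[idx] + kern[seq_along(idx)]
      }
    }
    lam_all <- lambda0 * exp(beta * v)
    list(spike_times = spk, v = voltage_trace(v, grid), rate_hz = lam_all)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
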