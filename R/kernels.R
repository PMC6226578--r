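#' Alpha-function synaptic kernel
#'
#' The elementary temporal filter converting a presynaptic spike into a
#' postsynaptic potential waveform: `H(t) * (t/tau) * exp(-t/tau)`, where `H`
#' is the Heaviside step. The kernel peaks at `t = tau` with value `exp(-1)`
#' and has unit amplitude parameterisation (amplitudes are carried separately
#' by [kernel_params()]).
#'
#' @param t Time offsets in ms (vectorised).
#' @param tau Time constant in ms (> 0).
#' @return Kernel values, zero for `t <= 0`.
#' @examples
#' alpha_kernel(5, tau = 5) # peak, exp(-1)
#' @export
alpha_kernel <- function(t, tau) {
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("`tau` must be a single positive number (ms).", call. = FALSE)
  }
  out <- (t / tau) * exp(-t / tau)
  out[t <= 0] <- 0
  out
}

# d kappa / d tau, same support as the kernel. Used by analytic gradients.
alpha_kernel_dtau <- function(t, tau) {
  out <- (t / tau^2) * exp(-t / tau) * (t / tau - 1)
  out[t <= 0] <- 0
  out
}

# Slow time constant coupled to the fast one; keeps the double-kernel model
# at a single shape parameter per group.
#' Coupled slow time constant
#'
#' In the double-kernel excitatory model the slow component's time constant
#' can be tied to the fast one through `tau_slow = 10.4 + 2.8 * tau_fast`
#' (ms), trading flexibility for fewer parameters.
#'
#' @param tau_fast Fast time constant (ms).
#' @return Slow time constant (ms).
#' @export
coupled_tau_slow <- function(tau_fast) {
  10.4 + 2.8 * tau_fast
}

#' Synaptic kernel parameters
#'
#' One kernel per synapse group and channel: a fast alpha component and an
#' optional slow component. Inhibitory kernels carry negative amplitudes.
#'
#' @param w_fast Amplitude of the fast component (mV per spike, can be
#'   negative for inhibition).
#' @param tau_fast Fast time constant (ms, > 0).
#' @param w_slow Optional amplitude of the slow component; `NULL` for a
#'   single-kernel synapse.
#' @param tau_slow Slow time constant (ms). Ignored when `coupled = TRUE`, in
#'   which case it is derived as [coupled_tau_slow()] of `tau_fast`.
#' @param delay Propagation delay in ms (>= 0).
#' @param coupled Logical; couple `tau_slow` to `tau_fast`?
#' @return A `kernel_params` list.
#' @export
kernel_params <- function(w_fast, tau_fast, w_slow = NULL, tau_slow = NULL,
                          delay = 0, coupled = FALSE) {
  if (tau_fast <= 0) stop("`tau_fast` must be positive.", call. = FALSE)
  if (delay < 0) stop("`delay` must be non-negative.", call. = FALSE)
  double <- !is.null(w_slow)
  if (double) {
    if (coupled) {
      tau_slow <- coupled_tau_slow(tau_fast)
    } else if (is.null(tau_slow)) {
      stop("`tau_slow` required when `w_slow` is given and not coupled.",
        call. = FALSE
      )
    }
    if (tau_slow <= 0) stop("`tau_slow` must be positive.", call. = FALSE)
  } else {
    tau_slow <- NULL
    coupled <- FALSE
  }
  structure(
    list(
      w_fast = w_fast, tau_fast = tau_fast,
      w_slow = w_slow, tau_slow = tau_slow,
      delay = delay, coupled = coupled
    ),
    class = "kernel_params"
  )
}

# Number of lag bins needed to keep the discarded alpha tail below
# `mass_tol` of total mass; support is `horizon_tau` times the largest tau
# by default, which leaves < 1e-3 of the mass outside.
kernel_support_bins <- function(params, grid, horizon_tau = 10,
                                horizon_ms = NULL) {
  if (is.null(horizon_ms)) {
    tau_max <- max(params$tau_fast, params$tau_slow %||% 0)
    horizon_ms <- horizon_tau * tau_max + params$delay
  }
  if (horizon_ms <= params$delay) {
    stop("Kernel truncation horizon shorter than the delay.", call. = FALSE)
  }
  max(2L, as.integer(ceiling(horizon_ms / grid$dt)) + 1L)
}

#' Sample a synaptic kernel on the grid
#'
#' Evaluates the (possibly double) alpha kernel at discrete lags
#' `0, dt, 2*dt, ...`, shifted by the propagation delay. The support is
#' truncated at `horizon_tau` times the largest time constant (plus the
#' delay); at the default 10 tau the discarded tail holds less than 1e-3 of
#' the kernel mass.
#'
#' @param params A [kernel_params()].
#' @param grid A [time_grid()] (only `dt` is used).
#' @param horizon_tau Truncation horizon as a multiple of the largest tau,
#'   measured from kernel onset (the delay is always covered).
#' @param horizon_ms Optional absolute truncation horizon in ms, overriding
#'   `horizon_tau`; it is an error for it not to reach past the delay.
#' @return Numeric vector of kernel values over lags.
#' @export
build_kernel <- function(params, grid, horizon_tau = 10, horizon_ms = NULL) {
  n_lag <- kernel_support_bins(params, grid, horizon_tau, horizon_ms)
  lag <- (seq_len(n_lag) - 1) * grid$dt - params$delay
  k <- params$w_fast * alpha_kernel(lag, params$tau_fast)
  if (!is.null(params$w_slow)) {
    k <- k + params$w_slow * alpha_kernel(lag, params$tau_slow)
  }
  k
}

# Causal discrete convolution of a binned signal with a sampled kernel.
# out[t] = sum_j x[t - j + 1] * k[j]; FFT-based at a highly composite
# padded length (raw n + m - 1 can hit large prime factors and make the
# FFT orders of magnitude slower).
causal_conv <- function(x, k) {
  n <- length(x)
  m <- length(k)
  np <- stats::nextn(n + m - 1, 2)
  fx <- stats::fft(c(x, numeric(np - n)))
  fk <- stats::fft(c(k, numeric(np - m)))
  out <- Re(stats::fft(fx * fk, inverse = TRUE)) / np
  out[seq_len(n)]
}

# Reusable half of the convolution: the padded FFT of a fixed signal.
# `reserve` bounds the kernel lengths the transform can serve.
precompute_conv <- function(x, reserve = 8192L) {
  n <- length(x)
  np <- stats::nextn(n + reserve, 2)
  list(fx = stats::fft(c(x, numeric(np - n))), n = n, np = np, x = x)
}

causal_conv_pre <- function(pre, k) {
  m <- length(k)
  if (m > pre$np - pre$n + 1L) {
    return(causal_conv(pre$x, k)) # kernel outlives the reserved padding
  }
  fk <- stats::fft(c(k, numeric(pre$np - m)))
  out <- Re(stats::fft(pre$fx * fk, inverse = TRUE)) / pre$np
  out[seq_len(pre$n)]
}

#' Filter a spike train with a synaptic kernel
#'
#' Computes the per-synapse filtered signal: the spike train (binned to the
#' grid) convolved with the sampled kernel, including the propagation delay.
#' The operation is linear in the spike train; an empty train yields an
#' all-zero signal.
#'
#' @param times Spike times in ms (within the grid span), or an integer
#'   vector of per-bin counts of length `grid$n_bins`.
#' @param params A [kernel_params()].
#' @param grid A [time_grid()].
#' @param horizon_tau Kernel truncation horizon (see [build_kernel()]).
#' @return Numeric vector of length `grid$n_bins`.
#' @export
convolve_spikes <- function(times, params, grid, horizon_tau = 10) {
  counts <- if (length(times) == grid$n_bins && !is.null(attr(times, "binned"))) {
    as.numeric(times)
  } else {
    as.numeric(bin_events(times, grid))
  }
  k <- build_kernel(params, grid, horizon_tau)
  causal_conv(counts, k)
}

# Mark a counts vector so convolve_spikes treats it as already binned.
as_binned <- function(counts) {
  structure(as.numeric(counts), binned = TRUE)
}
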