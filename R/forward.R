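#' Logistic subunit nonlinearity
#'
#' The static nonlinearity applied to each subunit's summed input:
#' `1 / (1 + exp(-(y - theta)))`. Its only free parameter is the threshold
#' `theta`; the effective slope is set by the synaptic weights and subunit
#' couplings, and the output scale by the coupling of the subunit itself.
#'
#' @param y Filtered-input values.
#' @param theta Threshold, same units as `y`.
#' @return Activation in (0, 1).
#' @export
sigmoid <- function(y, theta = 0) {
  1 / (1 + exp(-(y - theta)))
}

# derivative of the logistic at activation r
sigmoid_slope <- function(r) r * (1 - r)

kernel_key <- function(subunit_id, group_id) {
  paste0("s", subunit_id, ".g", group_id)
}

# Bin and pool spike trains per (subunit, group); errors on spikes from
# synapses the architecture does not know about.
compile_hln_inputs <- function(spikes, arch, grid) {
  spikes <- tibble::as_tibble(spikes)
  if (!all(c("synapse_id", "time_ms") %in% names(spikes))) {
    stop("`spikes` needs columns `synapse_id` and `time_ms`.", call. = FALSE)
  }
  unknown <- setdiff(unique(spikes$synapse_id), arch$synapses$synapse_id)
  if (length(unknown) > 0) {
    stop(
      "Spike train(s) from synapse(s) not assigned to any subunit: ",
      paste(utils::head(sort(unknown), 10), collapse = ", "),
      if (length(unknown) > 10) ", ..." else "",
      call. = FALSE
    )
  }
  assign <- arch$synapses[, c("synapse_id", "subunit_id", "group_id")]
  spk <- dplyr::inner_join(spikes, assign, by = "synapse_id")
  groups <- dplyr::distinct(arch$synapses, .data$subunit_id, .data$group_id)
  counts <- stats::setNames(
    vector("list", nrow(groups)),
    kernel_key(groups$subunit_id, groups$group_id)
  )
  pre <- counts
  for (i in seq_len(nrow(groups))) {
    key <- kernel_key(groups$subunit_id[i], groups$group_id[i])
    tt <- spk$time_ms[spk$subunit_id == groups$subunit_id[i] &
      spk$group_id == groups$group_id[i]]
    counts[[key]] <- as.numeric(bin_events(tt, grid))
    pre[[key]] <- precompute_conv(counts[[key]])
  }
  list(counts = counts, pre = pre, grid = grid, n = grid$n_bins)
}

# round delay to the nearest grid bin (sub-bin delays are unidentifiable
# at the grid resolution)
snap_delay <- function(delay_ms, grid) {
  round(delay_ms / grid$dt) * grid$dt
}

kernel_row_params <- function(row, delay_ms) {
  kernel_params(
    w_fast = row$w_fast,
    tau_fast = row$tau_fast,
    w_slow = if (is.na(row$w_slow)) NULL else row$w_slow,
    tau_slow = if (is.na(row$tau_slow)) NULL else row$tau_slow,
    delay = delay_ms,
    coupled = isTRUE(row$coupled)
  )
}

# Full forward sweep. `cache = TRUE` additionally returns the per-kernel
# unit convolutions and per-channel activations needed by the analytic
# gradient and by pretuning.
hln_eval <- function(arch, compiled, extra_root_input = NULL,
                     cache = FALSE, horizon_tau = 10) {
  grid <- compiled$grid
  n <- compiled$n
  order_ids <- hln_eval_order(arch)
  root <- hln_root_id(arch)

  delays <- stats::setNames(
    snap_delay(arch$subunits$delay_ms, grid), arch$subunits$subunit_id
  )

  row_cache <- vector("list", nrow(arch$kernels))
  # phi per kernel row
  for (r in seq_len(nrow(arch$kernels))) {
    row <- arch$kernels[r, ]
    key <- kernel_key(row$subunit_id, row$group_id)
    cnt <- compiled$counts[[key]]
    if (is.null(cnt)) {
      stop("No pooled spike counts for kernel group ", key, call. = FALSE)
    }
    delay <- delays[[as.character(row$subunit_id)]]
    pars <- kernel_row_params(row, delay)
    n_lag <- kernel_support_bins(pars, grid, horizon_tau)
    lag <- (seq_len(n_lag) - 1) * grid$dt - delay
    pre <- compiled$pre[[key]]
    conv <- if (is.null(pre)) {
      function(k) causal_conv(cnt, k)
    } else {
      function(k) causal_conv_pre(pre, k)
    }
    a_fast <- conv(alpha_kernel(lag, pars$tau_fast))
    phi <- pars$w_fast * a_fast
    rc <- list(phi = NULL, a_fast = NULL, a_slow = NULL, d_fast = NULL,
               d_slow = NULL, tau_slow = pars$tau_slow)
    a_slow <- NULL
    if (!is.null(pars$w_slow)) {
      a_slow <- conv(alpha_kernel(lag, pars$tau_slow))
      phi <- phi + pars$w_slow * a_slow
    }
    if (cache) {
      rc$a_fast <- a_fast
      rc$a_slow <- a_slow
      rc$d_fast <- conv(alpha_kernel_dtau(lag, pars$tau_fast))
      if (!is.null(pars$w_slow)) {
        rc$d_slow <- conv(alpha_kernel_dtau(lag, pars$tau_slow))
      }
    }
    rc$phi <- phi
    row_cache[[r]] <- rc
  }

  y <- list() # [["s.ch"]] summed channel input
  act <- list() # channel activation
  rp <- list() # channel slope d(activation)/dy
  out <- list() # subunit output (sum over channels)
  for (s in order_ids) {
    ch_tbl <- arch$channels[arch$channels$subunit_id == s, ]
    total <- numeric(n)
    for (ci in seq_len(nrow(ch_tbl))) {
      ch <- ch_tbl$channel[ci]
      rows <- which(arch$kernels$subunit_id == s & arch$kernels$channel == ch)
      yv <- numeric(n)
      for (r in rows) yv <- yv + row_cache[[r]]$phi
      if (ch == 1L) {
        for (k in hln_children(arch, s)) {
          ck <- arch$subunits$coupling[arch$subunits$subunit_id == k]
          yv <- yv + ck * out[[as.character(k)]]
        }
        if (s == root && !is.null(extra_root_input)) {
          yv <- yv + extra_root_input
        }
      }
      kk <- paste0(s, ".", ch)
      y[[kk]] <- yv
      if (ch_tbl$nonlinear[ci]) {
        a <- sigmoid(yv, ch_tbl$theta[ci])
        act[[kk]] <- a
        rp[[kk]] <- sigmoid_slope(a)
      } else {
        act[[kk]] <- yv
        rp[[kk]] <- rep(1, n)
      }
      total <- total + act[[kk]]
    }
    out[[as.character(s)]] <- total
  }
  c_root <- arch$subunits$coupling[arch$subunits$subunit_id == root]
  v <- c_root * out[[as.character(root)]] + arch$v0
  if (!cache) {
    return(list(v = v))
  }
  list(
    v = v, y = y, act = act, rprime = rp, out = out,
    rows = row_cache, delays = delays, order = order_ids, root = root
  )
}

#' Forward response of an hLN model
#'
#' Evaluates the model output (the predicted somatic subthreshold membrane
#' potential, mV) for a set of presynaptic spike trains: per-synapse kernel
#' convolution, within-subunit summation, sigmoid activations, and a single
#' leaf-to-root sweep through the subunit tree. Deterministic given inputs.
#'
#' @param spikes Data frame of spike times (`synapse_id`, `time_ms`). Every
#'   `synapse_id` present must be assigned in the architecture.
#' @param arch An [hln_architecture()].
#' @param grid A [time_grid()].
#' @param extra_root_input Optional signal (length `n_bins`) added to the
#'   root subunit's channel-1 input; used by the spiking extension for
#'   adaptation currents.
#' @param horizon_tau Kernel truncation horizon (multiples of tau).
#' @return A tibble with columns `time_ms`, `v_mv`.
#' @export
hln_forward <- function(spikes, arch, grid, extra_root_input = NULL,
                        horizon_tau = 10) {
  stopifnot(inherits(arch, "hln_arch"), inherits(grid, "time_grid"))
  compiled <- compile_hln_inputs(spikes, arch, grid)
  ev <- hln_eval(arch, compiled,
    extra_root_input = extra_root_input,
    horizon_tau = horizon_tau
  )
  voltage_trace(ev$v, grid)
}

#' Somatic response amplitude of a synapse
#'
#' The effective amplitude of the somatic response to one spike at synapse
#' `i` of subunit `j`: the kernel amplitude times the subunit coupling and
#' sigmoid slope, propagated through every ancestor's coupling and slope.
#' Slopes are evaluated at an operating point; by default the mean of each
#' channel's filtered-input distribution under the supplied training input
#' (for linear channels the slope is 1 everywhere, and with no input the
#' slope of a nonlinear channel is taken at its threshold, i.e. 0.25).
#'
#' @param arch An `hln_arch`.
#' @param synapse_id Synapse to trace to the soma.
#' @param spikes Optional training spike data frame used to locate the
#'   operating point.
#' @param grid Required with `spikes`.
#' @param y_means Optional named list `"subunit.channel"` -> operating-point
#'   input value, overriding `spikes`.
#' @return Amplitude in mV (sum over channels for multiplexed subunits).
#' @export
synapse_amplitude <- function(arch, synapse_id, spikes = NULL, grid = NULL,
                              y_means = NULL) {
  syn <- arch$synapses[arch$synapses$synapse_id == synapse_id, ]
  if (nrow(syn) != 1L) {
    stop("Synapse ", synapse_id, " not found in the architecture.",
      call. = FALSE
    )
  }
  if (is.null(y_means) && !is.null(spikes)) {
    stopifnot(inherits(grid, "time_grid"))
    compiled <- compile_hln_inputs(spikes, arch, grid)
    ev <- hln_eval(arch, compiled, cache = TRUE)
    y_means <- lapply(ev$y, mean)
  }
  slope_at <- function(s, ch) {
    row <- arch$channels[arch$channels$subunit_id == s &
      arch$channels$channel == ch, ]
    if (!row$nonlinear) {
      return(1)
    }
    y_star <- if (!is.null(y_means)) {
      y_means[[paste0(s, ".", ch)]] %||% row$theta
    } else {
      row$theta
    }
    sigmoid_slope(sigmoid(y_star, row$theta))
  }
  j <- syn$subunit_id
  # own-subunit contribution, summed over channels
  own <- 0
  for (ch in arch$channels$channel[arch$channels$subunit_id == j]) {
    kr <- arch$kernels[arch$kernels$subunit_id == j &
      arch$kernels$channel == ch &
      arch$kernels$group_id == syn$group_id, ]
    w <- kr$w_fast + ifelse(is.na(kr$w_slow), 0, kr$w_slow)
    own <- own + w * slope_at(j, ch)
  }
  a <- own * arch$subunits$coupling[arch$subunits$subunit_id == j]
  # ancestors: each adds its channel-1 slope and coupling
  p <- arch$subunits$parent_id[arch$subunits$subunit_id == j]
  while (!is.na(p)) {
    a <- a * slope_at(p, 1L) *
      arch$subunits$coupling[arch$subunits$subunit_id == p]
    p <- arch$subunits$parent_id[arch$subunits$subunit_id == p]
  }
  a
}
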