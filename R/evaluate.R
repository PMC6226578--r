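#' Variance explained by a predicted voltage trace
#'
#' One minus the mean squared prediction error normalized by the variance
#' of the target: `1 - mean((v - vhat)^2) / var(v)` (population variance,
#' i.e. mean squared deviation from the mean). Equals 1 for a perfect
#' prediction, 0 for predicting the target mean, and is negative for
#' predictions worse than the mean.
#'
#' @param v Target voltage (vector or tibble with `v_mv`).
#' @param vhat Predicted voltage (same form, same grid).
#' @return Scalar variance explained (<= 1).
#' @export
variance_explained <- function(v, vhat) {
  v <- as_signal(v)
  vhat <- as_signal(vhat)
  if (length(v) != length(vhat)) {
    stop("Target and prediction have different lengths.", call. = FALSE)
  }
  varv <- mean((v - mean(v))^2)
  if (varv == 0) {
    stop("Target trace has zero variance.", call. = FALSE)
  }
  1 - mean((v - vhat)^2) / varv
}

#' Plateau probability of a membrane-potential trace
#'
#' Fraction of time the membrane potential spends strictly above a
#' threshold; used to quantify sustained dendritic depolarizations
#' (plateau potentials). Monotone non-increasing in the threshold.
#'
#' @param vm Membrane potential (vector or tibble with `v_mv`), mV.
#' @param threshold_mv Threshold (mV), default -35.
#' @return Fraction in `[0, 1]`.
#' @export
plateau_probability <- function(vm, threshold_mv = -35) {
  v <- as_signal(vm)
  mean(v > threshold_mv)
}

#' Autocorrelation decay timescale
#'
#' Computes the normalized autocorrelation of a trace (per segment,
#' averaged across segments) and fits `A * exp(-lag / tau)` to it by least
#' squares over lags up to `max_lag_ms`. The fitted `tau` summarises how
#' slowly the signal decorrelates.
#'
#' @param vm Trace (vector or tibble with `v_mv`).
#' @param dt Bin width (ms).
#' @param max_lag_ms Largest lag used in the fit (ms, default 500).
#' @param segment_s Optional segment length (s) for segment-wise averaging.
#' @return Decay constant in ms.
#' @export
autocorrelation_timescale <- function(vm, dt = 1, max_lag_ms = 500,
                                      segment_s = NULL) {
  v <- as_signal(vm)
  max_lag <- as.integer(round(max_lag_ms / dt))
  if (length(v) <= 3 * max_lag) {
    stop("Trace too short for the requested maximum lag.", call. = FALSE)
  }
  segs <- if (is.null(segment_s)) {
    list(v)
  } else {
    n_seg <- floor(length(v) * dt / (segment_s * 1000))
    if (n_seg < 1) stop("Trace shorter than one segment.", call. = FALSE)
    len <- as.integer(segment_s * 1000 / dt)
    lapply(seq_len(n_seg), function(i) v[((i - 1) * len + 1):(i * len)])
  }
  acs <- vapply(
    segs,
    function(s) {
      stats::acf(s, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
    },
    numeric(max_lag + 1)
  )
  ac <- rowMeans(acs)
  lag <- (0:max_lag) * dt
  # weighted least-squares exponential fit in (log A, log tau): the sample
  # autocorrelation noise is roughly flat across lags while the signal
  # decays, so weighting by the squared expected signal (from a pilot 1/e
  # estimate) approximates inverse relative variance and keeps the noisy
  # tail from dominating the fit
  tau0 <- lag[which(ac < exp(-1))[1]]
  if (is.na(tau0) || tau0 <= 0) tau0 <- max_lag_ms / 2
  w <- exp(-2 * lag / tau0)
  obj <- function(p) sum(w * (exp(p[1]) * exp(-lag / exp(p[2])) - ac)^2)
  opt <- stats::optim(c(0, log(tau0)), obj,
    method = "Nelder-Mead",
    control = list(maxit = 2000, reltol = 1e-12)
  )
  exp(opt$par[2])
}

#' Membrane-potential histogram
#'
#' Normalized density of membrane-potential values over uniform bins.
#'
#' @param vm Trace (vector or tibble with `v_mv`), mV.
#' @param bin_width_mv Bin width (mV, default 1).
#' @return A tibble with `bin_lo_mv`, `bin_hi_mv`, `mid_mv`, `density`
#'   (so that `sum(density) * bin_width = 1`).
#' @export
vm_histogram <- function(vm, bin_width_mv = 1) {
  if (bin_width_mv <= 0) stop("`bin_width_mv` must be positive.", call. = FALSE)
  v <- as_signal(vm)
  lo <- floor(min(v) / bin_width_mv) * bin_width_mv
  hi <- ceiling(max(v) / bin_width_mv) * bin_width_mv
  if (hi <= lo) hi <- lo + bin_width_mv
  breaks <- seq(lo, hi, by = bin_width_mv)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  tibble::tibble(
    bin_lo_mv = utils::head(breaks, -1),
    bin_hi_mv = breaks[-1],
    mid_mv = h$mids,
    density = h$density
  )
}

#' Evaluate a fitted hLN model on held-out segments
#'
#' Computes per-segment variance explained of the fit's predictions on test
#' data, together with summary statistics of the predicted membrane
#' potential (plateau probability, autocorrelation timescale, voltage
#' histogram). Errors if any test segment is the training target itself.
#'
#' @param fit An `hln_fit`.
#' @param test A list of segments, each a list with `spikes` and `voltage`
#'   (a single segment may be passed directly).
#' @param plateau_threshold_mv Threshold for [plateau_probability()].
#' @param max_lag_ms Maximum lag for [autocorrelation_timescale()] (the
#'   timescale is reported as `NA` for segments too short to support it).
#' @return An object of class `hln_eval_report`: per-segment tibble plus
#'   aggregate median/quartiles of variance explained.
#' @export
evaluate_fit <- function(fit, test, plateau_threshold_mv = -35,
                         max_lag_ms = 500) {
  stopifnot(inherits(fit, "hln_fit"))
  if (!is.null(test$spikes)) test <- list(test)
  per_seg <- purrr::map_dfr(seq_along(test), function(i) {
    seg <- test[[i]]
    target <- as_signal(seg$voltage)
    if (identical(rlang::hash(target), fit$train_hash)) {
      stop("Test segment ", i, " is the training data; train and test must be disjoint.",
        call. = FALSE
      )
    }
    pred <- hln_forward(seg$spikes, fit$arch, fit$grid)
    ts <- tryCatch(
      autocorrelation_timescale(pred, dt = fit$grid$dt, max_lag_ms = max_lag_ms),
      error = function(e) NA_real_
    )
    tibble::tibble(
      segment = i,
      variance_explained = variance_explained(target, pred),
      plateau_probability = plateau_probability(pred, plateau_threshold_mv),
      ac_timescale_ms = ts
    )
  })
  ve <- per_seg$variance_explained
  structure(
    list(
      segments = per_seg,
      ve_median = stats::median(ve),
      ve_quartiles = stats::quantile(ve, c(0.25, 0.75), names = FALSE),
      n_segments = length(test),
      histogram = vm_histogram(
        as_signal(hln_forward(test[[1]]$spikes, fit$arch, fit$grid))
      )
    ),
    class = "hln_eval_report"
  )
}

#' @export
print.hln_eval_report <- function(x, ...) {
  cat(sprintf(
    "<hln_eval_report> %d segment(s); variance explained median %.4f [%.4f, %.4f]\n",
    x$n_segments, x$ve_median, x$ve_quartiles[1], x$ve_quartiles[2]
  ))
  invisible(x)
}
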