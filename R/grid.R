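#' Discrete time grid
#'
#' All signals in the package (filtered synaptic input, membrane potential,
#' firing rates) live on a uniform time grid. Bin `k` (zero-based) spans the
#' half-open interval `[t0 + k*dt, t0 + (k+1)*dt)` and signals are sampled at
#' the bin start times `t0 + k*dt`.
#'
#' @param dt Bin width in ms. Default 1 ms.
#' @param n_bins Number of bins (>= 1).
#' @param t0 Start time in ms.
#'
#' @return An object of class `time_grid` with fields `dt`, `n_bins`, `t0`.
#' @examples
#' g <- time_grid(dt = 1, n_bins = 1000)
#' head(grid_times(g))
#' @export
time_grid <- function(dt = 1, n_bins, t0 = 0) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number (ms).", call. = FALSE)
  }
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) {
    stop("`n_bins` must be a positive integer.", call. = FALSE)
  }
  structure(list(dt = dt, n_bins = n_bins, t0 = t0), class = "time_grid")
}

#' @rdname time_grid
#' @param x A `time_grid`.
#' @export
grid_times <- function(x) {
  stopifnot(inherits(x, "time_grid"))
  x$t0 + (seq_len(x$n_bins) - 1) * x$dt
}

#' @rdname time_grid
#' @export
grid_duration <- function(x) {
  stopifnot(inherits(x, "time_grid"))
  x$n_bins * x$dt
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf(
    "<time_grid> %d bins of %g ms from t = %g ms (%.3f s)\n",
    x$n_bins, x$dt, x$t0, grid_duration(x) / 1000
  ))
  invisible(x)
}

#' Bin event times onto a time grid
#'
#' Converts event times (ms) into per-bin counts. Events must fall inside the
#' grid span; events exactly at the right edge belong to no bin and raise an
#' error.
#'
#' @param times Numeric vector of event times in ms.
#' @param grid A [time_grid()].
#' @return Integer vector of length `grid$n_bins` with event counts per bin.
#' @export
bin_events <- function(times, grid) {
  stopifnot(inherits(grid, "time_grid"))
  counts <- integer(grid$n_bins)
  if (length(times) == 0L) {
    return(counts)
  }
  idx <- floor((times - grid$t0) / grid$dt) + 1
  if (any(idx < 1 | idx > grid$n_bins)) {
    bad <- times[idx < 1 | idx > grid$n_bins]
    stop(sprintf(
      "%d event time(s) outside the grid span [%g, %g) ms, e.g. %g.",
      length(bad), grid$t0, grid$t0 + grid_duration(grid), bad[1]
    ), call. = FALSE)
  }
  tab <- tabulate(idx, nbins = grid$n_bins)
  as.integer(tab)
}

#' Voltage trace as a tibble
#'
#' Convenience constructor pairing a sampled signal with its grid times.
#'
#' @param v Numeric vector, one value per grid bin (mV).
#' @param grid A [time_grid()].
#' @return A tibble with columns `time_ms` and `v_mv`.
#' @export
voltage_trace <- function(v, grid) {
  stopifnot(inherits(grid, "time_grid"), length(v) == grid$n_bins)
  tibble::tibble(time_ms = grid_times(grid), v_mv = as.numeric(v))
}

# Extract the numeric signal from either a plain vector or a voltage tibble.
as_signal <- function(v, grid = NULL) {
  if (is.data.frame(v)) {
    if (!"v_mv" %in% names(v)) {
      stop("Voltage data frame must have a `v_mv` column.", call. = FALSE)
    }
    v <- v$v_mv
  }
  if (!is.null(grid) && length(v) != grid$n_bins) {
    stop("Signal length does not match the time grid.", call. = FALSE)
  }
  as.numeric(v)
}
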