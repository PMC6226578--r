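#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the parameters of a fitted hLN model
#'
#' One row per free parameter of the fitted architecture: kernel
#' amplitudes, log time constants, thresholds, log couplings, offset.
#'
#' @param x An `hln_fit`.
#' @param ... Unused.
#' @return A tibble with `term` and `estimate`.
#' @export
tidy.hln_fit <- function(x, ...) {
  map <- hln_par_map(x$arch, tie = "none")
  tibble::tibble(term = names(map$init), estimate = unname(map$init))
}

#' One-row summary of a fitted hLN model
#'
#' @param x An `hln_fit`.
#' @param ... Unused.
#' @return A tibble with the training MSE, median test variance explained,
#'   chosen `rho`, shared delay, parameter count, convergence flag and seed.
#' @export
glance.hln_fit <- function(x, ...) {
  tibble::tibble(
    train_mse = x$train_mse,
    test_ve_median = if (is.null(x$test_ve)) NA_real_ else stats::median(x$test_ve),
    rho = x$rho,
    delay_ms = x$delay_ms,
    n_params = hln_n_free_params(x$arch),
    converged = all(x$converged),
    seed = if (is.null(x$seed)) NA_integer_ else x$seed
  )
}

#' Plot a fitted model's prediction against the target
#'
#' Overlays the model response and the target voltage over a time window.
#'
#' @param fit An `hln_fit`.
#' @param spikes Spike data frame to predict from.
#' @param target Target voltage (tibble with `time_ms`, `v_mv`).
#' @param window_s Time window to display, in seconds (default first 2 s).
#' @return A ggplot object.
#' @export
plot_prediction <- function(fit, spikes, target, window_s = c(0, 2)) {
  pred <- hln_forward(spikes, fit$arch, fit$grid)
  df <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(target), trace = "target"),
    dplyr::mutate(pred, trace = "hLN model")
  ) |>
    dplyr::filter(
      .data$time_ms >= window_s[1] * 1000,
      .data$time_ms <= window_s[2] * 1000
    )
  ggplot2::ggplot(df, ggplot2::aes(
    .data$time_ms / 1000, .data$v_mv,
    colour = .data$trace
  )) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "time (s)", y = "membrane potential (mV)", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plot_prediction
#' @param object,x Object to plot.
#' @param ... Passed on.
#' @export
autoplot.hln_fit <- function(object, spikes = NULL, target = NULL, ...) {
  if (!is.null(spikes) && !is.null(target)) {
    return(plot_prediction(object, spikes, target, ...))
  }
  df <- tibble::tibble(
    stage = factor(names(object$stage_mse), levels = names(object$stage_mse)),
    mse = unname(object$stage_mse)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$stage, .data$mse, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = expression("training MSE (mV"^2 * ")")) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic input session
#'
#' Spike raster (a subsample of synapses, coloured by ensemble) above the
#' ensemble firing-rate traces.
#'
#' @param object An `hln_inputs` from [generate_inputs()].
#' @param max_synapses Raster subsample size.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hln_inputs <- function(object, max_synapses = 100, ...) {
  ids <- sort(unique(object$spikes$synapse_id))
  keep <- ids[seq(1, length(ids), length.out = min(max_synapses, length(ids)))]
  ras <- dplyr::filter(object$spikes, .data$synapse_id %in% keep)
  ggplot2::ggplot(ras, ggplot2::aes(
    .data$time_ms / 1000, factor(.data$synapse_id),
    colour = factor(.data$ensemble_id)
  )) +
    ggplot2::geom_point(shape = "|", size = 1, show.legend = FALSE) +
    ggplot2::labs(x = "time (s)", y = "synapse") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.y = ggplot2::element_blank(),
      panel.grid = ggplot2::element_blank()
    )
}

#' Plot the raised-cosine adaptation basis
#'
#' @param object An [raised_cosine_basis()].
#' @param ... Unused.
#' @return A ggplot object with one curve per basis function on a log lag
#'   axis.
#' @export
autoplot.adaptation_basis <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object$psi, .name_repair = ~ paste0("psi_", seq_along(.x))) |>
      dplyr::mutate(lag_ms = object$lag_ms),
    -"lag_ms",
    names_to = "basis", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(
    .data$lag_ms, .data$value,
    colour = .data$basis
  )) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time since spike (ms)", y = "basis value") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation report
#'
#' Variance explained per held-out segment.
#'
#' @param object An `hln_eval_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hln_eval_report <- function(object, ...) {
  ggplot2::ggplot(
    object$segments,
    ggplot2::aes(factor(.data$segment), .data$variance_explained)
  ) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::coord_cartesian(ylim = c(
      min(0, min(object$segments$variance_explained)), 1
    )) +
    ggplot2::labs(x = "test segment", y = "variance explained") +
    ggplot2::theme_minimal()
}
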