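#' Read and write spike trains as CSV
#'
#' Long-format spike files: comma separated with a header, columns
#' `synapse_id`, `time_ms` (ms, written with 3 decimals so files round-trip
#' bit-exactly at grid precision), `label` and `ensemble_id`. Times are
#' sorted within each synapse on load (with a warning if the file was
#' unsorted); unknown labels are an error.
#'
#' @param spikes Spike data frame.
#' @param path File path.
#' @return `read_spikes_csv()` returns a tibble; `write_spikes_csv()`
#'   returns `path` invisibly.
#' @export
write_spikes_csv <- function(spikes, path) {
  spikes <- tibble::as_tibble(spikes)
  if (!"ensemble_id" %in% names(spikes)) spikes$ensemble_id <- NA_integer_
  if (!"label" %in% names(spikes)) spikes$label <- NA_character_
  out <- spikes |>
    dplyr::mutate(time_ms = sprintf("%.3f", .data$time_ms)) |>
    dplyr::select("synapse_id", "time_ms", "label", "ensemble_id")
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @export
read_spikes_csv <- function(path) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  spk <- readr::read_csv(path,
    col_types = readr::cols(
      synapse_id = readr::col_integer(),
      time_ms = readr::col_double(),
      label = readr::col_character(),
      ensemble_id = readr::col_integer()
    )
  )
  need <- setdiff(c("synapse_id", "time_ms", "label"), names(spk))
  if (length(need) > 0) {
    stop("Spike file lacks column(s): ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  bad <- setdiff(unique(spk$label), c("excitatory", "inhibitory", NA))
  if (length(bad) > 0) {
    stop("Unknown spike label(s): ", paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  unsorted <- spk |>
    dplyr::group_by(.data$synapse_id) |>
    dplyr::summarise(ok = !is.unsorted(.data$time_ms)) |>
    dplyr::filter(!.data$ok)
  if (nrow(unsorted) > 0) {
    warning(
      "Spike times were not sorted for ", nrow(unsorted),
      " synapse(s); sorting on load."
    )
    spk <- dplyr::arrange(spk, .data$synapse_id, .data$time_ms)
  }
  spk
}

#' Read and write voltage traces as CSV
#'
#' Two columns: `time_ms` and `v_mv`.
#'
#' @param voltage Tibble with `time_ms`, `v_mv` (see [voltage_trace()]).
#' @param path File path.
#' @export
write_voltage_csv <- function(voltage, path) {
  readr::write_csv(voltage[, c("time_ms", "v_mv")], path)
  invisible(path)
}

#' @rdname write_voltage_csv
#' @export
read_voltage_csv <- function(path) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  readr::read_csv(path, col_types = readr::cols(
    time_ms = readr::col_double(), v_mv = readr::col_double()
  ))
}

#' Serialize an hLN architecture to YAML
#'
#' Writes the subunit tree, channels, kernel parameters, synapse assignment
#' and offset; [read_architecture_yaml()] reconstructs an identical
#' `hln_arch`.
#'
#' @param arch An `hln_arch`.
#' @param path File path.
#' @export
write_architecture_yaml <- function(arch, path) {
  stopifnot(inherits(arch, "hln_arch"))
  obj <- list(
    v0 = arch$v0,
    subunits = lapply(seq_len(nrow(arch$subunits)), function(i) {
      as.list(arch$subunits[i, ])
    }),
    channels = lapply(seq_len(nrow(arch$channels)), function(i) {
      as.list(arch$channels[i, ])
    }),
    kernels = lapply(seq_len(nrow(arch$kernels)), function(i) {
      as.list(arch$kernels[i, ])
    }),
    synapses = lapply(seq_len(nrow(arch$synapses)), function(i) {
      as.list(arch$synapses[i, ])
    })
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_architecture_yaml
#' @export
read_architecture_yaml <- function(path) {
  if (!file.exists(path)) stop("No such file: ", path, call. = FALSE)
  obj <- yaml::read_yaml(path)
  row_bind <- function(rows) {
    purrr::map_dfr(rows, function(r) {
      tibble::as_tibble(lapply(r, function(x) if (is.null(x)) NA else x))
    })
  }
  arch <- structure(
    list(
      subunits = row_bind(obj$subunits) |>
        dplyr::mutate(
          subunit_id = as.integer(.data$subunit_id),
          parent_id = as.integer(.data$parent_id),
          coupling = as.numeric(.data$coupling),
          delay_ms = as.numeric(.data$delay_ms)
        ),
      channels = row_bind(obj$channels) |>
        dplyr::mutate(
          subunit_id = as.integer(.data$subunit_id),
          channel = as.integer(.data$channel),
          nonlinear = as.logical(.data$nonlinear),
          theta = as.numeric(.data$theta)
        ),
      kernels = row_bind(obj$kernels) |>
        dplyr::mutate(
          subunit_id = as.integer(.data$subunit_id),
          channel = as.integer(.data$channel),
          group_id = as.integer(.data$group_id),
          w_fast = as.numeric(.data$w_fast),
          w_slow = as.numeric(.data$w_slow),
          tau_fast = as.numeric(.data$tau_fast),
          tau_slow = as.numeric(.data$tau_slow),
          coupled = as.logical(.data$coupled)
        ),
      synapses = row_bind(obj$synapses) |>
        dplyr::mutate(
          synapse_id = as.integer(.data$synapse_id),
          subunit_id = as.integer(.data$subunit_id),
          group_id = as.integer(.data$group_id),
          label = as.character(.data$label),
          position_class = as.character(.data$position_class)
        ),
      v0 = obj$v0
    ),
    class = "hln_arch"
  )
  validate_hln_arch(arch)
  arch
}

#' Serialize a fit result to JSON
#'
#' Writes the fitted parameters, per-stage training losses, configuration
#' hash and seed.
#'
#' @param fit An `hln_fit`.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "hln_fit"))
  obj <- list(
    parameters = generics::tidy(fit),
    stage_mse = as.list(fit$stage_mse),
    train_mse = fit$train_mse,
    test_ve = fit$test_ve,
    rho = fit$rho,
    delay_ms = fit$delay_ms,
    seed = fit$seed,
    config_hash = rlang::hash(fit$config)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run the full generate / simulate / fit / evaluate pipeline
#'
#' A self-contained, reproducible run: synthesize in-vivo-like inputs,
#' simulate a reference ("teacher") hLN model on them to obtain the target
#' voltage, fit a model of the same architecture to the training segment,
#' and evaluate it on an independently generated test segment. All
#' artifacts are written under `out_dir`, each JSON embedding the seed and
#' a hash of the configuration that produced it, and a `run_log.txt`
#' records per-stage wall times and seeds.
#'
#' @param config A list (or path to a YAML file) with elements:
#'   `seed` (integer); `arch` (path to an architecture YAML written by
#'   [write_architecture_yaml()]); optional `generator` (arguments to
#'   [ensemble_config()]); optional `duration_s` (default 48); optional
#'   `fit` (arguments to [fit_config()]).
#' @param out_dir Output directory (created if missing).
#' @return The evaluation report, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  t_all <- Sys.time()
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("Config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("Config must set `seed`.", call. = FALSE)
  if (is.null(config$arch)) {
    stop("Config must reference an architecture file (`arch`).",
      call. = FALSE
    )
  }
  if (!file.exists(config$arch)) {
    stop("Architecture file not found: ", config$arch, call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(config)
  seed <- as.integer(config$seed)
  log_path <- file.path(out_dir, "run_log.txt")
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  log_line("pipeline seed=%d config_hash=%s", seed, cfg_hash)

  arch <- read_architecture_yaml(config$arch)
  gen_args <- config$generator %||% list()
  gcfg <- do.call(ensemble_config, gen_args)
  duration_s <- config$duration_s %||% 48

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- force(expr)
    log_line(
      "stage=%s wall_s=%.2f", name,
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    res
  }

  train <- stage("generate_train", generate_inputs(gcfg,
    duration_s = duration_s, seed = seed
  ))
  test <- stage("generate_test", generate_inputs(gcfg,
    duration_s = duration_s, seed = seed + 1L
  ))
  log_line("seeds train=%d test=%d", seed, seed + 1L)
  write_spikes_csv(train$spikes, file.path(out_dir, "spikes_train.csv"))
  write_spikes_csv(test$spikes, file.path(out_dir, "spikes_test.csv"))

  v_train <- stage(
    "simulate_teacher_train",
    hln_forward(train$spikes, arch, train$grid)
  )
  v_test <- stage(
    "simulate_teacher_test",
    hln_forward(test$spikes, arch, test$grid)
  )
  write_voltage_csv(v_train, file.path(out_dir, "voltage_train.csv"))
  write_voltage_csv(v_test, file.path(out_dir, "voltage_test.csv"))

  fit_args <- config$fit %||% list()
  fit_args$seed <- seed
  fcfg <- do.call(fit_config, fit_args)
  fit <- stage("fit", fit_hln(
    train$spikes, v_train, arch, train$grid,
    config = fcfg,
    test = list(list(spikes = test$spikes, voltage = v_test))
  ))
  write_fit_json(fit, file.path(out_dir, "fit.json"))

  report <- stage("evaluate", evaluate_fit(
    fit, list(list(spikes = test$spikes, voltage = v_test))
  ))
  jsonlite::write_json(
    list(
      seed = seed, config_hash = cfg_hash,
      variance_explained = report$segments$variance_explained,
      ve_median = report$ve_median,
      plateau_probability = report$segments$plateau_probability,
      ac_timescale_ms = report$segments$ac_timescale_ms
    ),
    file.path(out_dir, "evaluation.json"),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  log_line(
    "done wall_s=%.2f",
    as.numeric(difftime(Sys.time(), t_all, units = "secs"))
  )
  invisible(report)
}
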