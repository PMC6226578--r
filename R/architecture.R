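#' Hierarchical linear-nonlinear (hLN) architecture
#'
#' An hLN model is a rooted tree of subunits. Each subunit linearly filters
#' the spike trains of the synapses assigned to it (one [kernel_params()] set
#' per synapse group and channel), adds the coupled outputs of its child
#' subunits, and passes the total through a logistic sigmoid (or through the
#' identity for a linear subunit). The root subunit's output, scaled by its
#' coupling and shifted by the offset `v0`, models the somatic subthreshold
#' membrane potential.
#'
#' Multiplexed subunits have two channels: the same spike trains are filtered
#' by two independent kernel sets and passed through two independent
#' sigmoids whose outputs are summed. Child subunits feed channel 1.
#'
#' @param subunits Data frame with columns `subunit_id` (integer),
#'   `parent_id` (integer, `NA` for the root) and optionally `coupling`
#'   (default 1), `delay_ms` (shared synaptic delay, default 0),
#'   `nonlinear` (default `TRUE`), `theta` (sigmoid threshold, default 0),
#'   `n_channels` (1 or 2, default 1) and `theta2` (channel-2 threshold).
#' @param synapses Data frame with columns `synapse_id`, `subunit_id`,
#'   `label` (`"excitatory"` or `"inhibitory"`) and optionally `group_id`
#'   (parameter-tying group within the subunit; defaults to one group per
#'   label) and `position_class` (`"proximal"`, `"middle"`, `"distal"`).
#' @param kernels Optional data frame overriding the default kernels, with
#'   columns `subunit_id`, `channel`, `group_id`, `w_fast`, `tau_fast` and
#'   optionally `w_slow`, `tau_slow`, `coupled`. By default each group gets a
#'   single alpha kernel (excitatory `w_fast = 0.1`, inhibitory `-0.1`,
#'   `tau_fast = 10` ms).
#' @param v0 Offset in mV (resting potential of the model output).
#'
#' @return An object of class `hln_arch`.
#' @examples
#' syn <- tibble::tibble(
#'   synapse_id = 1:4,
#'   subunit_id = 1L,
#'   label = c("excitatory", "excitatory", "excitatory", "inhibitory")
#' )
#' arch <- hln_architecture(
#'   subunits = tibble::tibble(subunit_id = 1L, parent_id = NA, nonlinear = FALSE),
#'   synapses = syn, v0 = -70
#' )
#' arch
#' @export
hln_architecture <- function(subunits, synapses, kernels = NULL, v0 = 0) {
  subunits <- tibble::as_tibble(subunits)
  synapses <- tibble::as_tibble(synapses)

  need <- setdiff(c("subunit_id", "parent_id"), names(subunits))
  if (length(need) > 0) {
    stop("`subunits` lacks column(s): ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  defaults <- list(
    coupling = 1, delay_ms = 0, nonlinear = TRUE, theta = 0,
    n_channels = 1L, theta2 = NA_real_
  )
  for (nm in names(defaults)) {
    if (!nm %in% names(subunits)) subunits[[nm]] <- defaults[[nm]]
  }
  subunits <- dplyr::mutate(
    subunits,
    subunit_id = as.integer(.data$subunit_id),
    parent_id = as.integer(.data$parent_id),
    n_channels = as.integer(.data$n_channels)
  )

  if (anyDuplicated(subunits$subunit_id)) {
    stop("Duplicate subunit ids.", call. = FALSE)
  }
  root <- subunits$subunit_id[is.na(subunits$parent_id)]
  if (length(root) != 1L) {
    stop("Architecture must have exactly one root subunit (parent_id = NA).",
      call. = FALSE
    )
  }
  bad_parent <- setdiff(
    subunits$parent_id[!is.na(subunits$parent_id)], subunits$subunit_id
  )
  if (length(bad_parent) > 0) {
    stop("Unknown parent subunit id(s): ", paste(bad_parent, collapse = ", "),
      call. = FALSE
    )
  }

  need <- setdiff(c("synapse_id", "subunit_id", "label"), names(synapses))
  if (length(need) > 0) {
    stop("`synapses` lacks column(s): ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  if (!all(synapses$label %in% c("excitatory", "inhibitory"))) {
    stop("Synapse labels must be 'excitatory' or 'inhibitory'.", call. = FALSE)
  }
  if (anyDuplicated(synapses$synapse_id)) {
    stop("Each synapse must be assigned to exactly one subunit.", call. = FALSE)
  }
  if (!all(synapses$subunit_id %in% subunits$subunit_id)) {
    stop("Synapse assigned to unknown subunit.", call. = FALSE)
  }
  if (!"group_id" %in% names(synapses)) {
    # default tying: one group per label within each subunit
    synapses$group_id <- as.integer(factor(synapses$label,
      levels = c("excitatory", "inhibitory")
    ))
  }
  if (!"position_class" %in% names(synapses)) {
    synapses$position_class <- NA_character_
  }
  synapses <- dplyr::mutate(
    synapses,
    synapse_id = as.integer(.data$synapse_id),
    subunit_id = as.integer(.data$subunit_id),
    group_id = as.integer(.data$group_id)
  )
  mixed <- synapses |>
    dplyr::distinct(.data$subunit_id, .data$group_id, .data$label) |>
    dplyr::count(.data$subunit_id, .data$group_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(mixed) > 0) {
    stop("A synapse group mixes excitatory and inhibitory synapses.",
      call. = FALSE
    )
  }

  channels <- subunits |>
    dplyr::rowwise() |>
    dplyr::reframe(
      subunit_id = .data$subunit_id,
      channel = seq_len(.data$n_channels),
      nonlinear = .data$nonlinear,
      theta = c(.data$theta, .data$theta2)[seq_len(.data$n_channels)]
    )
  channels$theta[is.na(channels$theta)] <- 0

  group_tbl <- synapses |>
    dplyr::distinct(.data$subunit_id, .data$group_id, .data$label)
  if (is.null(kernels)) {
    kernels <- channels |>
      dplyr::select("subunit_id", "channel") |>
      dplyr::inner_join(group_tbl, by = "subunit_id") |>
      dplyr::mutate(
        w_fast = ifelse(.data$label == "excitatory", 0.1, -0.1),
        w_slow = NA_real_,
        tau_fast = 10,
        tau_slow = NA_real_,
        coupled = FALSE
      ) |>
      dplyr::select(-"label")
  } else {
    kernels <- tibble::as_tibble(kernels)
    for (nm in c("w_slow", "tau_slow")) {
      if (!nm %in% names(kernels)) kernels[[nm]] <- NA_real_
    }
    if (!"coupled" %in% names(kernels)) kernels$coupled <- FALSE
    kernels <- dplyr::mutate(
      kernels,
      subunit_id = as.integer(.data$subunit_id),
      channel = as.integer(.data$channel),
      group_id = as.integer(.data$group_id)
    )
    expect <- channels |>
      dplyr::select("subunit_id", "channel") |>
      dplyr::inner_join(
        dplyr::distinct(group_tbl, .data$subunit_id, .data$group_id),
        by = "subunit_id", relationship = "many-to-many"
      )
    missing <- dplyr::anti_join(expect, kernels,
      by = c("subunit_id", "channel", "group_id")
    )
    if (nrow(missing) > 0) {
      stop("Missing kernel parameters for ",
        nrow(missing), " (subunit, channel, group) combination(s).",
        call. = FALSE
      )
    }
  }
  kernels <- dplyr::mutate(
    kernels,
    tau_slow = ifelse(.data$coupled, coupled_tau_slow(.data$tau_fast),
      .data$tau_slow
    )
  )

  arch <- structure(
    list(
      subunits = subunits[, c(
        "subunit_id", "parent_id", "coupling", "delay_ms"
      )],
      channels = channels,
      kernels = kernels,
      synapses = synapses[, c(
        "synapse_id", "subunit_id", "group_id", "label", "position_class"
      )],
      v0 = v0
    ),
    class = "hln_arch"
  )
  validate_hln_arch(arch)
  arch
}

validate_hln_arch <- function(arch) {
  # cycle check via repeated parent hops
  parent <- stats::setNames(
    arch$subunits$parent_id, arch$subunits$subunit_id
  )
  for (s in arch$subunits$subunit_id) {
    seen <- integer(0)
    cur <- s
    while (!is.na(parent[[as.character(cur)]])) {
      cur <- parent[[as.character(cur)]]
      if (cur %in% seen || cur == s) {
        stop("Subunit tree contains a cycle.", call. = FALSE)
      }
      seen <- c(seen, cur)
    }
  }
  if (any(arch$subunits$coupling <= 0)) {
    stop("Subunit couplings must be positive.", call. = FALSE)
  }
  invisible(arch)
}

hln_root_id <- function(arch) {
  arch$subunits$subunit_id[is.na(arch$subunits$parent_id)]
}

# subunit ids ordered leaves-first (children always before parents)
hln_eval_order <- function(arch) {
  depth <- function(id) {
    d <- 0L
    p <- arch$subunits$parent_id[arch$subunits$subunit_id == id]
    while (!is.na(p)) {
      d <- d + 1L
      p <- arch$subunits$parent_id[arch$subunits$subunit_id == p]
    }
    d
  }
  ids <- arch$subunits$subunit_id
  ids[order(-vapply(ids, depth, integer(1)))]
}

hln_children <- function(arch, id) {
  arch$subunits$subunit_id[!is.na(arch$subunits$parent_id) &
    arch$subunits$parent_id == id]
}

#' @export
print.hln_arch <- function(x, ...) {
  nl <- x$channels |>
    dplyr::filter(.data$nonlinear) |>
    nrow()
  cat(sprintf(
    "<hln_arch> %d subunit(s), %d synapse(s) in %d group(s), %d nonlinear channel(s), v0 = %g mV\n",
    nrow(x$subunits), nrow(x$synapses),
    nrow(dplyr::distinct(x$synapses, .data$subunit_id, .data$group_id)),
    nl, x$v0
  ))
  invisible(x)
}

#' Single-subunit hLN architecture
#'
#' Convenience constructor for the canonical "point neuron" model: one
#' subunit holding every synapse, grouped either by excitatory/inhibitory
#' label or by a supplied `group_id` column.
#'
#' @param synapses Data frame with `synapse_id`, `label` and optionally
#'   `group_id`, `position_class`, `ensemble_id`.
#' @param nonlinear Should the output subunit have a sigmoid nonlinearity?
#' @param v0 Offset (mV).
#' @param delay_ms Shared synaptic delay (ms).
#' @return An `hln_arch`.
#' @export
hln_single_subunit <- function(synapses, nonlinear = FALSE, v0 = 0,
                               delay_ms = 0) {
  synapses <- tibble::as_tibble(synapses)
  synapses$subunit_id <- 1L
  hln_architecture(
    subunits = tibble::tibble(
      subunit_id = 1L, parent_id = NA_integer_,
      nonlinear = nonlinear, delay_ms = delay_ms
    ),
    synapses = synapses,
    v0 = v0
  )
}

#' Parameter count of the canonical hLN configuration
#'
#' For a single-kernel model with a nonlinear output subunit the number of
#' free parameters is `1 + 3 * n_syn + 2 * m`: the offset, then amplitude,
#' time constant and delay per independently fitted synapse group, then
#' threshold and coupling per subunit. For other configurations (double
#' kernels, linear output, multiplexing, shared delays) the optimizer
#' enumerates its free parameters explicitly; see [hln_n_free_params()].
#'
#' @param arch An `hln_arch`, or `NULL` when `n_syn`/`m` are given directly.
#' @param n_syn Number of independently fitted synapse groups.
#' @param m Number of subunits.
#' @return Integer parameter count.
#' @examples
#' count_params(n_syn = 13, m = 1) # 42
#' @export
count_params <- function(arch = NULL, n_syn = NULL, m = NULL) {
  if (!is.null(arch)) {
    stopifnot(inherits(arch, "hln_arch"))
    n_syn <- nrow(dplyr::distinct(
      arch$synapses, .data$subunit_id, .data$group_id
    ))
    m <- nrow(arch$subunits)
  }
  as.integer(1 + 3 * n_syn + 2 * m)
}

#' Exact free-parameter count of the optimizer
#'
#' Enumerates the parameters actually optimized for an architecture
#' (amplitudes and log time constants per kernel component, thresholds per
#' nonlinear channel, log couplings, the offset; delays are per-subunit and
#' fitted by grid search, counted once per subunit).
#'
#' @param arch An `hln_arch`.
#' @param tie Kernel-shape tying mode, as in the staged fit.
#' @return Integer count.
#' @export
hln_n_free_params <- function(arch, tie = c("none", "taus_by_label")) {
  tie <- match.arg(tie)
  map <- hln_par_map(arch, tie = tie)
  length(map$init) + nrow(arch$subunits) # + per-subunit delay
}
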