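#' Fitting configuration
#'
#' Controls the staged least-squares fit of an hLN model: the near-linear
#' initialisation grid, delay search, optimizer tolerances and the prior.
#'
#' @param rho_grid Scaling factors for pretuning the subunit nonlinearities;
#'   the subunit input SD is set to `1/rho`. Default `1:8`.
#' @param delay_grid_ms Candidate shared synaptic delays searched in the
#'   coupled stage (delays are grid-valued, not gradient-fitted).
#' @param init_tau Initial kernel time constant (ms) for the coupled stage.
#' @param maxit Maximum BFGS iterations per stage.
#' @param reltol Relative convergence tolerance passed to [stats::optim()].
#' @param prior_sd Log-scale SD of the log-normal prior on kernel amplitudes
#'   and time constants in the decoupled stage.
#' @param prior_weight Weight of the prior penalty relative to the mean
#'   squared error; default `1 / n_bins` (unit observation noise).
#' @param use_prior `"auto"` activates the prior only when the number of
#'   independently fitted synapse groups exceeds the number of subunits;
#'   `TRUE`/`FALSE` force it.
#' @param horizon_tau Kernel truncation horizon.
#' @param seed Optional integer recorded with the fit.
#' @return A `fit_config` list.
#' @export
fit_config <- function(rho_grid = 1:8, delay_grid_ms = c(0, 1, 2),
                       init_tau = 10, maxit = 250, reltol = 1e-10,
                       prior_sd = 0.5, prior_weight = NULL,
                       use_prior = "auto", horizon_tau = 10, seed = NULL) {
  stopifnot(length(rho_grid) >= 1, all(rho_grid > 0))
  stopifnot(maxit >= 1, reltol > 0, prior_sd > 0)
  structure(
    list(
      rho_grid = rho_grid, delay_grid_ms = delay_grid_ms,
      init_tau = init_tau, maxit = maxit, reltol = reltol,
      prior_sd = prior_sd, prior_weight = prior_weight,
      use_prior = use_prior, horizon_tau = horizon_tau, seed = seed
    ),
    class = "fit_config"
  )
}

# ---- parameter packing -----------------------------------------------------

# Enumerate the free parameters of an architecture as a named vector plus
# bookkeeping tables linking parameter names to kernel rows / channels /
# subunits. `tie = "taus_by_label"` shares the (log) time constants across
# all kernel rows with the same synapse label, as in the middle fitting
# stage.
hln_par_map <- function(arch, tie = c("none", "taus_by_label")) {
  tie <- match.arg(tie)
  root <- hln_root_id(arch)
  labels <- arch$synapses |>
    dplyr::distinct(.data$subunit_id, .data$group_id, .data$label)
  kern <- arch$kernels |>
    dplyr::left_join(labels, by = c("subunit_id", "group_id")) |>
    dplyr::mutate(row = dplyr::row_number())
  rowkey <- paste0("s", kern$subunit_id, ".c", kern$channel, ".g", kern$group_id)
  kern$par_wf <- paste0("w_fast.", rowkey)
  kern$par_ws <- ifelse(is.na(kern$w_slow), NA, paste0("w_slow.", rowkey))
  shape_key <- if (tie == "taus_by_label") {
    substr(kern$label, 1, 3)
  } else {
    rowkey
  }
  kern$par_ltf <- paste0("ltau_fast.", shape_key)
  kern$par_lts <- ifelse(
    is.na(kern$w_slow) | kern$coupled, NA, paste0("ltau_slow.", shape_key)
  )

  thetas <- arch$channels |>
    dplyr::filter(.data$nonlinear) |>
    dplyr::mutate(par = paste0("theta.s", .data$subunit_id, ".c", .data$channel))

  root_nl <- any(arch$channels$nonlinear[arch$channels$subunit_id == root])
  coup_ids <- arch$subunits$subunit_id[
    !is.na(arch$subunits$parent_id) |
      (arch$subunits$subunit_id == root & root_nl)
  ]
  coup <- tibble::tibble(
    subunit_id = coup_ids,
    par = paste0("lcoupling.s", coup_ids)
  )

  init <- c(v0 = arch$v0)
  init[kern$par_wf] <- kern$w_fast
  for (i in seq_len(nrow(kern))) {
    if (!is.na(kern$par_ws[i])) init[kern$par_ws[i]] <- kern$w_slow[i]
    init[kern$par_ltf[i]] <- log(kern$tau_fast[i])
    if (!is.na(kern$par_lts[i])) init[kern$par_lts[i]] <- log(kern$tau_slow[i])
  }
  if (nrow(thetas) > 0) init[thetas$par] <- thetas$theta
  for (i in seq_len(nrow(coup))) {
    init[coup$par[i]] <- log(
      arch$subunits$coupling[arch$subunits$subunit_id == coup$subunit_id[i]]
    )
  }
  list(init = init, kern = kern, thetas = thetas, coup = coup, root = root)
}

# Write a parameter vector back into an architecture.
hln_unpack <- function(arch, map, par) {
  arch$v0 <- unname(par[["v0"]])
  k <- map$kern
  arch$kernels$w_fast <- unname(par[k$par_wf])
  for (i in seq_len(nrow(k))) {
    if (!is.na(k$par_ws[i])) arch$kernels$w_slow[i] <- par[[k$par_ws[i]]]
    arch$kernels$tau_fast[i] <- exp(par[[k$par_ltf[i]]])
    arch$kernels$tau_slow[i] <- if (isTRUE(arch$kernels$coupled[i])) {
      coupled_tau_slow(arch$kernels$tau_fast[i])
    } else if (!is.na(k$par_lts[i])) {
      exp(par[[k$par_lts[i]]])
    } else {
      arch$kernels$tau_slow[i]
    }
  }
  if (nrow(map$thetas) > 0) {
    for (i in seq_len(nrow(map$thetas))) {
      sel <- arch$channels$subunit_id == map$thetas$subunit_id[i] &
        arch$channels$channel == map$thetas$channel[i]
      arch$channels$theta[sel] <- par[[map$thetas$par[i]]]
    }
  }
  for (i in seq_len(nrow(map$coup))) {
    sel <- arch$subunits$subunit_id == map$coup$subunit_id[i]
    arch$subunits$coupling[sel] <- exp(par[[map$coup$par[i]]])
  }
  arch
}

# ---- prior -----------------------------------------------------------------

#' Log-normal prior on kernel amplitudes and time constants
#'
#' In the decoupled stage, where each synapse group has its own kernel, a
#' log-normal prior on the per-group amplitudes and time constants prevents
#' overfitting. Within a subunit the somatic response amplitude of a synapse
#' is proportional to its kernel amplitude (the coupling and sigmoid-slope
#' gain is shared), so the prior is parameterised directly on `log|w|` and
#' `log(tau)`, with means taken from the preceding (coupled) stage.
#'
#' @param mu Named numeric vector of prior means: names are parameter names
#'   (`w_fast.*`, `w_slow.*` compared on `log|w|`; `ltau_*` compared
#'   directly).
#' @param sd Log-scale standard deviation (> 0).
#' @param weight Penalty weight relative to the MSE term.
#' @return A `prior_spec`.
#' @export
prior_spec <- function(mu, sd = 0.5, weight = 1) {
  stopifnot(is.numeric(mu), !is.null(names(mu)), sd > 0, weight >= 0)
  structure(list(mu = mu, sd = sd, weight = weight), class = "prior_spec")
}

prior_from_map <- function(map, init, sd, weight) {
  k <- map$kern
  nm_w <- c(k$par_wf, k$par_ws[!is.na(k$par_ws)])
  nm_t <- unique(c(k$par_ltf, k$par_lts[!is.na(k$par_lts)]))
  mu <- c(
    stats::setNames(log(pmax(abs(init[nm_w]), 1e-6)), nm_w),
    init[nm_t]
  )
  prior_spec(mu, sd = sd, weight = weight)
}

prior_penalty <- function(par, prior) {
  if (is.null(prior) || prior$weight == 0) {
    return(list(value = 0, grad = NULL))
  }
  val <- 0
  grad <- stats::setNames(numeric(length(prior$mu)), names(prior$mu))
  for (nm in names(prior$mu)) {
    x <- par[[nm]]
    if (startsWith(nm, "w_")) {
      z <- log(max(abs(x), 1e-12)) - prior$mu[[nm]]
      val <- val + z^2 / (2 * prior$sd^2)
      grad[[nm]] <- z / (prior$sd^2 * x)
    } else {
      z <- x - prior$mu[[nm]]
      val <- val + z^2 / (2 * prior$sd^2)
      grad[[nm]] <- z / prior$sd^2
    }
  }
  list(value = prior$weight * val, grad = prior$weight * grad)
}

# ---- objective -------------------------------------------------------------

# Value-and-gradient of the penalized MSE, with a one-deep memo so optim's
# separate fn/gr calls at the same point cost one evaluation.
make_hln_objective <- function(arch, compiled, target, map, prior = NULL,
                               horizon_tau = 10) {
  n <- compiled$n
  memo <- new.env(parent = emptyenv())
  memo$par <- NULL
  memo$best <- NULL

  compute <- function(par) {
    arch2 <- hln_unpack(arch, map, par)
    ev <- hln_eval(arch2, compiled, cache = TRUE, horizon_tau = horizon_tau)
    resid <- ev$v - target
    mse <- mean(resid^2)
    g <- (2 / n) * resid

    grad <- stats::setNames(numeric(length(par)), names(par))
    grad[["v0"]] <- sum(g)

    root <- map$root
    c_of <- stats::setNames(
      arch2$subunits$coupling, arch2$subunits$subunit_id
    )
    parent_of <- stats::setNames(
      arch2$subunits$parent_id, arch2$subunits$subunit_id
    )
    dv_dout <- list()
    dv_dy <- list()
    for (s in rev(ev$order)) { # root first
      sc <- as.character(s)
      dv_dout[[sc]] <- if (s == root) {
        rep(c_of[[sc]], n)
      } else {
        dv_dy[[paste0(parent_of[[sc]], ".1")]] * c_of[[sc]]
      }
      for (ch in arch2$channels$channel[arch2$channels$subunit_id == s]) {
        kk <- paste0(s, ".", ch)
        dv_dy[[kk]] <- dv_dout[[sc]] * ev$rprime[[kk]]
      }
    }

    # thresholds
    if (nrow(map$thetas) > 0) {
      for (i in seq_len(nrow(map$thetas))) {
        s <- map$thetas$subunit_id[i]
        kk <- paste0(s, ".", map$thetas$channel[i])
        grad[[map$thetas$par[i]]] <-
          -sum(g * dv_dout[[as.character(s)]] * ev$rprime[[kk]])
      }
    }
    # couplings (log scale)
    for (i in seq_len(nrow(map$coup))) {
      s <- map$coup$subunit_id[i]
      sc <- as.character(s)
      d <- if (s == root) {
        sum(g * ev$out[[sc]])
      } else {
        sum(g * dv_dy[[paste0(parent_of[[sc]], ".1")]] * ev$out[[sc]])
      }
      grad[[map$coup$par[i]]] <- d * c_of[[sc]]
    }
    # kernels
    k <- map$kern
    for (i in seq_len(nrow(k))) {
      rc <- ev$rows[[k$row[i]]]
      gy <- g * dv_dy[[paste0(k$subunit_id[i], ".", k$channel[i])]]
      wf <- arch2$kernels$w_fast[k$row[i]]
      ws <- arch2$kernels$w_slow[k$row[i]]
      tf <- arch2$kernels$tau_fast[k$row[i]]
      grad[[k$par_wf[i]]] <- grad[[k$par_wf[i]]] + sum(gy * rc$a_fast)
      if (!is.na(k$par_ws[i])) {
        grad[[k$par_ws[i]]] <- grad[[k$par_ws[i]]] + sum(gy * rc$a_slow)
      }
      dphi_dtf <- wf * rc$d_fast
      if (isTRUE(arch2$kernels$coupled[k$row[i]]) && !is.na(ws)) {
        dphi_dtf <- dphi_dtf + 2.8 * ws * rc$d_slow
      }
      grad[[k$par_ltf[i]]] <- grad[[k$par_ltf[i]]] + tf * sum(gy * dphi_dtf)
      if (!is.na(k$par_lts[i])) {
        ts <- arch2$kernels$tau_slow[k$row[i]]
        grad[[k$par_lts[i]]] <- grad[[k$par_lts[i]]] +
          ts * sum(gy * ws * rc$d_slow)
      }
    }

    pen <- prior_penalty(par, prior)
    value <- mse + pen$value
    if (!is.null(pen$grad)) {
      grad[names(pen$grad)] <- grad[names(pen$grad)] + pen$grad
    }
    res <- list(value = value, grad = grad, mse = mse)
    if (is.null(memo$best) || value < memo$best$value) {
      memo$best <- list(value = value, mse = mse, par = par)
    }
    memo$par <- par
    memo$res <- res
    res
  }

  get <- function(par) {
    if (!is.null(memo$par) && identical(unname(par), unname(memo$par))) {
      return(memo$res)
    }
    compute(par)
  }
  list(
    fn = function(par) get(par)$value,
    gr = function(par) get(par)$grad,
    best = function() memo$best
  )
}

#' Penalized mean-squared-error loss of an hLN model
#'
#' The fitting objective: the mean squared deviation between the target
#' voltage and the model response, `mean((v - vhat)^2)` in mV^2, plus the
#' negative log-prior penalty when a prior is supplied. The analytic
#' gradient with respect to every free parameter is available.
#'
#' @param arch An `hln_arch` (carrying the parameters to evaluate).
#' @param spikes Spike data frame.
#' @param target Target voltage: numeric vector or tibble with `v_mv`,
#'   sampled on `grid`.
#' @param grid A [time_grid()].
#' @param prior Optional [prior_spec()].
#' @param gradient Return the gradient too?
#' @param tie Kernel-shape tying mode used to name the parameters.
#' @return The scalar loss, or (with `gradient = TRUE`) a list with `value`,
#'   `gradient` (named) and `mse`.
#' @export
hln_loss <- function(arch, spikes, target, grid, prior = NULL,
                     gradient = FALSE, tie = "none") {
  target <- as_signal(target)
  if (length(target) != grid$n_bins) {
    stop("Target voltage and time grid have different lengths.", call. = FALSE)
  }
  compiled <- compile_hln_inputs(spikes, arch, grid)
  map <- hln_par_map(arch, tie = tie)
  obj <- make_hln_objective(arch, compiled, target, map, prior = prior)
  val <- obj$fn(map$init)
  if (!gradient) {
    return(val)
  }
  list(value = val, gradient = obj$gr(map$init), mse = obj$best()$mse)
}

# ---- stage machinery -------------------------------------------------------

run_bfgs <- function(arch, compiled, target, tie, prior, config) {
  map <- hln_par_map(arch, tie = tie)
  obj <- make_hln_objective(arch, compiled, target, map,
    prior = prior, horizon_tau = config$horizon_tau
  )
  # evaluate the starting point first so `best` is never worse than it
  obj$fn(map$init)
  opt <- stats::optim(
    par = map$init, fn = obj$fn, gr = obj$gr, method = "BFGS",
    control = list(maxit = config$maxit, reltol = config$reltol)
  )
  # optim can end on a worse iterate than the best seen; keep the best
  best <- obj$best()
  list(
    arch = hln_unpack(arch, map, best$par),
    value = best$value,
    mse = best$mse,
    converged = opt$convergence == 0
  )
}

# OLS for the linear-in-amplitude parameters (w per group, v0) of an
# all-linear architecture at fixed kernel shapes; robust initialisation.
ols_init_amplitudes <- function(arch, compiled, target, config) {
  map <- hln_par_map(arch, tie = "taus_by_label")
  k <- map$kern
  cols <- list()
  for (i in seq_len(nrow(k))) {
    row <- arch$kernels[k$row[i], ]
    delay <- snap_delay(
      arch$subunits$delay_ms[arch$subunits$subunit_id == row$subunit_id],
      compiled$grid
    )
    pars <- kernel_row_params(
      dplyr::mutate(row, w_fast = 1, w_slow = ifelse(is.na(.data$w_slow), NA, 1)),
      delay
    )
    n_lag <- kernel_support_bins(pars, compiled$grid, config$horizon_tau)
    lag <- (seq_len(n_lag) - 1) * compiled$grid$dt - delay
    cnt <- compiled$counts[[kernel_key(row$subunit_id, row$group_id)]]
    cols[[k$par_wf[i]]] <- causal_conv(cnt, alpha_kernel(lag, row$tau_fast))
    if (!is.na(k$par_ws[i])) {
      cols[[k$par_ws[i]]] <- causal_conv(cnt, alpha_kernel(lag, row$tau_slow))
    }
  }
  x <- do.call(cbind, cols)
  fit <- stats::lm.fit(cbind(1, x), target)
  beta <- fit$coefficients
  arch$v0 <- unname(beta[1])
  w <- beta[-1]
  w[is.na(w)] <- 0
  for (nm in names(cols)) {
    i <- which(k$par_wf == nm)
    if (length(i) == 1) arch$kernels$w_fast[k$row[i]] <- w[[nm]]
    i <- which(!is.na(k$par_ws) & k$par_ws == nm)
    if (length(i) == 1) arch$kernels$w_slow[k$row[i]] <- w[[nm]]
  }
  arch
}

#' Coupled (stage-1) fit: shared kernels, single linear subunit
#'
#' Fits the simplest hLN model: one subunit with a linear output in which
#' all excitatory synapses share one kernel (amplitude, time constant,
#' delay) and all inhibitory synapses another. Amplitudes and the offset are
#' initialised by least squares at the starting time constant, then all
#' parameters are refined by BFGS; the shared delay is chosen by grid
#' search. The result initialises the more complex models of the later
#' stages.
#'
#' @param spikes Spike data frame with `synapse_id`, `time_ms`, `label`.
#' @param target Target voltage (vector or tibble with `v_mv`).
#' @param grid A [time_grid()].
#' @param config A [fit_config()].
#' @param synapses Optional synapse table; defaults to the distinct
#'   (`synapse_id`, `label`) pairs present in `spikes`.
#' @return A list with the fitted `arch`, `train_mse`, the chosen
#'   `delay_ms`, and `converged`.
#' @export
fit_stage_coupled <- function(spikes, target, grid, config = fit_config(),
                              synapses = NULL) {
  target <- as_signal(target, grid)
  if (is.null(synapses)) {
    if (!"label" %in% names(spikes)) {
      stop("`spikes` needs a `label` column (or pass `synapses`).",
        call. = FALSE
      )
    }
    synapses <- dplyr::distinct(
      tibble::as_tibble(spikes), .data$synapse_id, .data$label
    )
  }
  best <- NULL
  for (delay in config$delay_grid_ms) {
    arch0 <- hln_single_subunit(synapses,
      nonlinear = FALSE,
      v0 = mean(target), delay_ms = delay
    )
    arch0$kernels$tau_fast <- config$init_tau
    compiled <- compile_hln_inputs(spikes, arch0, grid)
    arch0 <- ols_init_amplitudes(arch0, compiled, target, config)
    res <- run_bfgs(arch0, compiled, target,
      tie = "taus_by_label",
      prior = NULL, config = config
    )
    if (is.null(best) || res$value < best$value) {
      best <- res
      best$delay_ms <- delay
    }
  }
  list(
    arch = best$arch, train_mse = best$value,
    delay_ms = best$delay_ms, converged = best$converged
  )
}

# Seed the target architecture's kernels and delays from the coupled fit.
transfer_coupled <- function(arch, coupled) {
  lab <- coupled$arch$synapses |>
    dplyr::distinct(.data$group_id, .data$label)
  kv <- coupled$arch$kernels |>
    dplyr::inner_join(lab, by = "group_id") |>
    dplyr::select("label",
      cw = "w_fast", ctau = "tau_fast"
    )
  labels <- arch$synapses |>
    dplyr::distinct(.data$subunit_id, .data$group_id, .data$label)
  for (r in seq_len(nrow(arch$kernels))) {
    row <- arch$kernels[r, ]
    lbl <- labels$label[labels$subunit_id == row$subunit_id &
      labels$group_id == row$group_id]
    src <- kv[kv$label == lbl, ]
    if (nrow(src) == 0) src <- tibble::tibble(cw = 0.05, ctau = 10)
    if (is.na(row$w_slow)) {
      arch$kernels$w_fast[r] <- src$cw
      arch$kernels$tau_fast[r] <- src$ctau
    } else {
      arch$kernels$w_fast[r] <- 0.6 * src$cw
      arch$kernels$w_slow[r] <- 0.4 * src$cw
      arch$kernels$tau_fast[r] <- src$ctau
      # slow component enters at the coupled offset whether or not it
      # stays tied during optimization
      arch$kernels$tau_slow[r] <- coupled_tau_slow(src$ctau)
    }
  }
  arch$subunits$delay_ms <- coupled$delay_ms
  arch$subunits$coupling <- rep(1, nrow(arch$subunits))
  arch$channels$theta <- rep(0, nrow(arch$channels))
  arch$v0 <- coupled$arch$v0
  arch
}

#' Pre-tune subunit nonlinearities toward linear integration
#'
#' Initialises a hierarchical model from kernel parameters learned by a
#' simpler (linear) model: each subunit's synaptic weights (and the
#' couplings of its children) are rescaled so that the distribution of its
#' total input under the training spike trains is centred on the sigmoid
#' midpoint with standard deviation `1/rho`, while the somatic response
#' amplitude of each synapse is left unchanged by compensating the subunit's
#' own output coupling (the logistic slope at the midpoint is 1/4). Larger
#' `rho` confines the input to a narrower, more linear region of the
#' sigmoid. The output offset is adjusted so the mean response is preserved.
#'
#' @param arch An `hln_arch` with transferred kernel parameters.
#' @param spikes Training spike data frame.
#' @param grid A [time_grid()].
#' @param rho Scaling factor (> 0).
#' @param horizon_tau Kernel truncation horizon.
#' @return The rescaled `hln_arch`.
#' @export
pretune_nonlinearities <- function(arch, spikes, grid, rho,
                                   horizon_tau = 10) {
  stopifnot(rho > 0)
  compiled <- compile_hln_inputs(spikes, arch, grid)
  # reference: the linear integration the pretuned model approximates
  lin <- arch
  lin$channels$nonlinear <- rep(FALSE, nrow(lin$channels))
  v_before <- hln_eval(lin, compiled, horizon_tau = horizon_tau)$v
  for (s in hln_eval_order(arch)) {
    ch_tbl <- arch$channels[arch$channels$subunit_id == s, ]
    scale1 <- NULL
    for (ci in seq_len(nrow(ch_tbl))) {
      if (!ch_tbl$nonlinear[ci]) next
      ch <- ch_tbl$channel[ci]
      ev <- hln_eval(arch, compiled, cache = TRUE, horizon_tau = horizon_tau)
      yv <- ev$y[[paste0(s, ".", ch)]]
      s_y <- stats::sd(yv)
      if (!is.finite(s_y) || s_y < 1e-12) {
        stop("Subunit ", s, " channel ", ch,
          " has a degenerate (zero-variance) input distribution.",
          call. = FALSE
        )
      }
      sc <- 1 / (rho * s_y)
      sel <- arch$kernels$subunit_id == s & arch$kernels$channel == ch
      arch$kernels$w_fast[sel] <- sc * arch$kernels$w_fast[sel]
      arch$kernels$w_slow[sel] <- sc * arch$kernels$w_slow[sel]
      if (ch == 1L) {
        for (k in hln_children(arch, s)) {
          ks <- arch$subunits$subunit_id == k
          arch$subunits$coupling[ks] <- sc * arch$subunits$coupling[ks]
        }
        scale1 <- sc
      }
      if (is.null(scale1)) scale1 <- sc
      arch$channels$theta[arch$channels$subunit_id == s &
        arch$channels$channel == ch] <- sc * mean(yv)
    }
    if (!is.null(scale1)) {
      ss <- arch$subunits$subunit_id == s
      arch$subunits$coupling[ss] <-
        arch$subunits$coupling[ss] / (0.25 * scale1)
    }
  }
  v_after <- hln_eval(arch, compiled, horizon_tau = horizon_tau)$v
  arch$v0 <- arch$v0 + mean(v_before) - mean(v_after)
  arch
}

#' Staged fit of an hLN model
#'
#' The full fitting schedule: (1) a coupled single-subunit linear fit with
#' shared kernels per synapse label; (2) transfer of the learned kernels
#' into the target architecture and, for each `rho` in the configured grid,
#' pre-tuning of the subunit nonlinearities toward linear integration
#' followed by BFGS optimization (time constants still shared per label);
#' the candidate with the lowest training error wins, ties going to the
#' smaller `rho`; (3) decoupling of the per-group kernels with a log-normal
#' prior (activated when groups outnumber subunits) and a final BFGS pass.
#' Training error can only improve across stages because each stage starts
#' from the previous stage's solution and the optimizer keeps its best
#' iterate.
#'
#' @param spikes Training spike data frame (`synapse_id`, `time_ms`,
#'   `label`).
#' @param target Training voltage (vector or tibble with `v_mv`).
#' @param arch Target [hln_architecture()].
#' @param grid A [time_grid()].
#' @param config A [fit_config()].
#' @param test Optional held-out data: a list of segments, each a list with
#'   elements `spikes` and `voltage`, used for cross-validated variance
#'   explained.
#' @return An object of class `hln_fit`: the fitted architecture, per-stage
#'   training MSE, the chosen `rho` and delay, per-segment test variance
#'   explained, and the seed recorded from `config`.
#' @export
fit_hln <- function(spikes, target, arch, grid, config = fit_config(),
                    test = NULL) {
  stopifnot(inherits(arch, "hln_arch"), inherits(grid, "time_grid"))
  target <- as_signal(target, grid)
  spikes <- tibble::as_tibble(spikes)

  stage_mse <- c()
  coupled <- fit_stage_coupled(spikes, target, grid, config,
    synapses = dplyr::distinct(arch$synapses, .data$synapse_id, .data$label)
  )
  stage_mse["coupled"] <- coupled$train_mse

  arch1 <- transfer_coupled(arch, coupled)
  compiled <- compile_hln_inputs(spikes, arch1, grid)

  any_nl <- any(arch$channels$nonlinear)
  rho_best <- NA_real_
  if (any_nl) {
    best <- NULL
    for (rho in config$rho_grid) {
      cand <- pretune_nonlinearities(arch1, spikes, grid, rho,
        horizon_tau = config$horizon_tau
      )
      res <- run_bfgs(cand, compiled, target,
        tie = "taus_by_label",
        prior = NULL, config = config
      )
      if (is.null(best) || res$value < best$value - 1e-15) {
        best <- res
        rho_best <- rho
      }
    }
    stage2 <- best
  } else {
    stage2 <- run_bfgs(arch1, compiled, target,
      tie = "taus_by_label",
      prior = NULL, config = config
    )
  }
  stage_mse["pretuned"] <- stage2$value

  arch2 <- stage2$arch
  n_groups <- nrow(dplyr::distinct(
    arch$synapses, .data$subunit_id, .data$group_id
  ))
  m <- nrow(arch$subunits)
  use_prior <- if (identical(config$use_prior, "auto")) {
    n_groups > m
  } else {
    isTRUE(config$use_prior)
  }
  map3 <- hln_par_map(arch2, tie = "none")
  prior <- if (use_prior) {
    w <- config$prior_weight %||% (1 / grid$n_bins)
    prior_from_map(map3, map3$init, sd = config$prior_sd, weight = w)
  } else {
    NULL
  }
  stage3 <- run_bfgs(arch2, compiled, target,
    tie = "none",
    prior = prior, config = config
  )
  stage_mse["decoupled"] <- stage3$mse

  fit <- structure(
    list(
      arch = stage3$arch,
      grid = grid,
      stage_mse = stage_mse,
      train_mse = stage3$mse,
      rho = rho_best,
      delay_ms = coupled$delay_ms,
      coupled = coupled,
      prior = prior,
      converged = c(
        coupled = coupled$converged,
        pretuned = stage2$converged, decoupled = stage3$converged
      ),
      seed = config$seed,
      config = config,
      test_ve = NULL,
      train_hash = rlang::hash(target)
    ),
    class = "hln_fit"
  )
  if (!is.null(test)) {
    if (!is.null(test$spikes)) test <- list(test)
    fit$test_ve <- vapply(test, function(seg) {
      pred <- hln_forward(seg$spikes, fit$arch, grid,
        horizon_tau = config$horizon_tau
      )
      variance_explained(seg$voltage, pred)
    }, numeric(1))
  }
  fit
}

#' @export
print.hln_fit <- function(x, ...) {
  cat("<hln_fit>\n")
  cat("  stage training MSE (mV^2):",
    paste(sprintf("%s=%.4g", names(x$stage_mse), x$stage_mse),
      collapse = ", "
    ), "\n"
  )
  if (!is.na(x$rho)) cat("  chosen rho:", x$rho, "\n")
  cat("  shared delay:", x$delay_ms, "ms\n")
  if (!is.null(x$test_ve)) {
    cat(sprintf(
      "  test variance explained: median %.4f (%d segment%s)\n",
      stats::median(x$test_ve), length(x$test_ve),
      if (length(x$test_ve) == 1) "" else "s"
    ))
  }
  invisible(x)
}
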