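#' Ornstein-Uhlenbeck parameters for firing-rate fluctuations
#'
#' Slow rate fluctuations shared by all synapses of an ensemble: a
#' mean-reverting Gaussian process decaying toward the state-dependent
#' equilibrium rate with time constant `tau_ms`, with a state-dependent
#' stationary standard deviation. Set both SDs to 0 to disable the
#' fluctuations.
#'
#' @param tau_ms Time constant (ms), default 500.
#' @param sd_background Stationary SD in the background state (Hz).
#' @param sd_elevated Stationary SD in the elevated state (Hz).
#' @return An `ou_params` list.
#' @export
ou_params <- function(tau_ms = 500, sd_background = 2.5, sd_elevated = 10) {
  stopifnot(tau_ms > 0, sd_background >= 0, sd_elevated >= 0)
  structure(
    list(
      tau_ms = tau_ms, sd_background = sd_background,
      sd_elevated = sd_elevated
    ),
    class = "ou_params"
  )
}

#' Inhibitory rate-tracking rule
#'
#' Inhibitory inputs are untuned but track excitation: their rate is an
#' affine function of the instantaneous mean excitatory rate, anchored at
#' `rate_all_background` Hz when every excitatory ensemble sits at its
#' background rate and `rate_all_elevated` Hz when every ensemble is
#' elevated.
#'
#' @param rate_all_background Anchor rate (Hz) at all-background excitation.
#' @param rate_all_elevated Anchor rate (Hz) at all-elevated excitation.
#' @return An `inhibition_rule` list.
#' @export
inhibition_rule <- function(rate_all_background = 20,
                            rate_all_elevated = 30) {
  structure(
    list(
      rate_all_background = rate_all_background,
      rate_all_elevated = rate_all_elevated
    ),
    class = "inhibition_rule"
  )
}

#' In-vivo-like input generator configuration
#'
#' Describes the statistical structure of the synthetic presynaptic input:
#' orientation-tuned excitatory ensembles that switch synchronously between
#' a background and an elevated firing rate, shared OU rate fluctuations
#' within each ensemble, inhomogeneous Poisson spiking, and an inhibitory
#' population whose rate tracks the mean excitatory rate.
#'
#' @param n_ensembles Number of excitatory ensembles (default 13).
#' @param n_exc Total number of excitatory synapses, distributed as evenly
#'   as possible across ensembles (default 629).
#' @param n_inh Number of inhibitory synapses (default 120).
#' @param background_rate Background excitatory rate (Hz, default 5).
#' @param elevated_rate Elevated excitatory rate (Hz, default 20).
#' @param omega_on_range On-switching rate range (Hz) across orientations,
#'   default `c(0.5, 14)`: 14 Hz at the preferred orientation, 0.5 Hz at the
#'   orthogonal one.
#' @param omega_off Off-switching rate (Hz, default 20), orientation
#'   independent.
#' @param max_active_ms Hard cap on active-state duration (ms, default 150).
#' @param pref_mu_deg,pref_sd_deg Preferred orientations are drawn from
#'   Normal(`pref_mu_deg`, `pref_sd_deg`) and rounded to the nearest
#'   multiple of 22.5 degrees (defaults 0 and 33).
#' @param ou An [ou_params()].
#' @param inhibition An [inhibition_rule()].
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(n_ensembles = 13, n_exc = 629, n_inh = 120,
                            background_rate = 5, elevated_rate = 20,
                            omega_on_range = c(0.5, 14), omega_off = 20,
                            max_active_ms = 150,
                            pref_mu_deg = 0, pref_sd_deg = 33,
                            ou = ou_params(),
                            inhibition = inhibition_rule()) {
  stopifnot(
    n_ensembles >= 1, n_exc >= n_ensembles, n_inh >= 0,
    background_rate > 0, elevated_rate > 0,
    length(omega_on_range) == 2, omega_on_range[1] <= omega_on_range[2],
    omega_off > 0, max_active_ms > 0
  )
  structure(
    list(
      n_ensembles = as.integer(n_ensembles), n_exc = as.integer(n_exc),
      n_inh = as.integer(n_inh),
      background_rate = background_rate, elevated_rate = elevated_rate,
      omega_on_range = omega_on_range, omega_off = omega_off,
      max_active_ms = max_active_ms,
      pref_mu_deg = pref_mu_deg, pref_sd_deg = pref_sd_deg,
      ou = ou, inhibition = inhibition
    ),
    class = "ensemble_config"
  )
}

#' Orientation tuning of the on-switching rate
#'
#' The rate at which an ensemble switches into its elevated state varies
#' sinusoidally with the angular distance between the stimulus and the
#' ensemble's preferred orientation on the 180-degree orientation cycle:
#' `omega_on = mid + half_range * cos(2 * dtheta)`, giving the upper anchor
#' at the preferred orientation and the lower anchor at the orthogonal one.
#'
#' @param preferred_deg Preferred orientation (degrees).
#' @param stimulus_deg Stimulus orientation (degrees); vectorised.
#' @param omega_on_range Anchors in Hz, `c(lo, hi)`.
#' @return On-rate(s) in Hz.
#' @export
orientation_on_rate <- function(preferred_deg, stimulus_deg,
                                omega_on_range = c(0.5, 14)) {
  dtheta <- (stimulus_deg - preferred_deg) * pi / 180
  mid <- mean(omega_on_range)
  half <- diff(omega_on_range) / 2
  mid + half * cos(2 * dtheta)
}

#' Sample an active-state duration
#'
#' Active-state durations are exponential with rate `omega_off`, truncated
#' by capping at `max_ms` (durations beyond the cap are set to the cap, not
#' resampled).
#'
#' @param n Number of durations.
#' @param omega_off Off-switching rate (Hz).
#' @param max_ms Duration cap (ms).
#' @param seed Optional seed.
#' @return Durations in ms, all `<= max_ms`.
#' @export
sample_active_durations <- function(n, omega_off = 20, max_ms = 150,
                                    seed = NULL) {
  draw <- function() pmin(stats::rexp(n, rate = omega_off) * 1000, max_ms)
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Sample a two-state switching sequence
#'
#' Alternating background/elevated periods in continuous time, binned to a
#' grid: background durations are exponential with rate `omega_on`,
#' elevated durations exponential with rate `omega_off` capped at
#' `max_active_ms`. `omega_on = 0` yields an all-background trace. The
#' sequence can be continued across calls (piecewise-constant `omega_on`)
#' via `init_state` and `init_active_elapsed`.
#'
#' @param omega_on On-switching rate (Hz, >= 0).
#' @param omega_off Off-switching rate (Hz, > 0).
#' @param duration_ms Length of the sequence (ms).
#' @param max_active_ms Active-state duration cap (ms).
#' @param dt Bin width (ms).
#' @param init_state Starting state (`"background"` or `"elevated"`).
#' @param init_active_elapsed Time (ms) already spent in the current active
#'   state, counted against the cap.
#' @param seed Optional seed.
#' @return A list: `state` (integer vector per bin, 0 background /
#'   1 elevated), `periods` (tibble of completed and ongoing periods),
#'   `final_state`, `final_active_elapsed`.
#' @export
sample_state_sequence <- function(omega_on, omega_off, duration_ms,
                                  max_active_ms = 150, dt = 1,
                                  init_state = "background",
                                  init_active_elapsed = 0, seed = NULL) {
  stopifnot(duration_ms > 0, omega_off > 0, omega_on >= 0)
  draw <- function() {
    edges <- numeric(0) # switch times
    states <- character(0)
    t <- 0
    st <- init_state
    elapsed <- if (st == "elevated") init_active_elapsed else 0
    t_start <- numeric(0)
    dur <- numeric(0)
    period_state <- character(0)
    while (t < duration_ms) {
      if (st == "background") {
        d <- if (omega_on > 0) stats::rexp(1, omega_on) * 1000 else Inf
      } else {
        d <- min(stats::rexp(1, omega_off) * 1000, max_active_ms - elapsed)
      }
      t_start <- c(t_start, t)
      dur <- c(dur, d)
      period_state <- c(period_state, st)
      t <- t + d
      st <- if (st == "background") "elevated" else "background"
      elapsed <- 0
    }
    # bin: state occupying each bin start
    n_bins <- as.integer(round(duration_ms / dt))
    bin_t <- (seq_len(n_bins) - 1) * dt
    idx <- findInterval(bin_t, c(0, cumsum(dur)), rightmost.closed = FALSE)
    state <- as.integer(period_state[pmin(idx, length(period_state))] ==
      "elevated")
    last <- length(dur)
    overshoot <- t - duration_ms
    final_state <- period_state[last]
    final_elapsed <- if (final_state == "elevated") {
      (if (last == 1) init_active_elapsed else 0) + dur[last] - overshoot
    } else {
      0
    }
    list(
      state = state,
      periods = tibble::tibble(
        state = period_state, t_start_ms = t_start, duration_ms = dur
      ),
      final_state = final_state,
      final_active_elapsed = final_elapsed
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Ornstein-Uhlenbeck firing-rate trace around state-dependent equilibria
#'
#' Exact discretisation of the OU process: the latent rate decays toward
#' the equilibrium of the current state (`background_rate` or
#' `elevated_rate`) with the configured time constant and state-dependent
#' stationary SD. The latent process is propagated unclipped; emitted rates
#' are clipped at 0 Hz (negative rates are meaningless; at the default SDs
#' the clipping bias is negligible). With both SDs zero the trace equals
#' the state-dependent equilibrium exactly.
#'
#' @param state Integer vector per bin (0 background / 1 elevated).
#' @param background_rate,elevated_rate Equilibrium rates (Hz).
#' @param ou An [ou_params()].
#' @param dt Bin width (ms), much smaller than `ou$tau_ms`.
#' @param init Optional initial latent rate (Hz); defaults to the
#'   equilibrium of the first state.
#' @param seed Optional seed.
#' @return Rate trace (Hz), one value per bin.
#' @export
sample_ou_rates <- function(state, background_rate = 5, elevated_rate = 20,
                            ou = ou_params(), dt = 1, init = NULL,
                            seed = NULL) {
  draw <- function() {
    n <- length(state)
    mu <- ifelse(state == 1, elevated_rate, background_rate)
    sdv <- ifelse(state == 1, ou$sd_elevated, ou$sd_background)
    if (all(sdv == 0)) {
      return(mu)
    }
    a <- exp(-dt / ou$tau_ms)
    b <- sqrt(1 - a^2)
    z <- stats::rnorm(n)
    r <- numeric(n)
    r[1] <- if (is.null(init)) mu[1] + sdv[1] * b * 0 else init
    if (n > 1) {
      for (t in 2:n) {
        r[t] <- mu[t] + (r[t - 1] - mu[t]) * a + sdv[t] * b * z[t]
      }
    }
    pmax(r, 0)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Inhibitory population rate from the mean excitatory rate
#'
#' Affine tracking rule: the instantaneous mean excitatory rate is mapped
#' linearly so that the all-background value lands on
#' `rule$rate_all_background` and the all-elevated value on
#' `rule$rate_all_elevated`.
#'
#' @param mean_exc_rate Mean excitatory rate trace (Hz).
#' @param rule An [inhibition_rule()].
#' @param background_rate,elevated_rate The excitatory anchor rates (Hz).
#' @return Inhibitory rate trace (Hz).
#' @export
inhibitory_rate <- function(mean_exc_rate, rule = inhibition_rule(),
                            background_rate = 5, elevated_rate = 20) {
  slope <- (rule$rate_all_elevated - rule$rate_all_background) /
    (elevated_rate - background_rate)
  pmax(
    rule$rate_all_background + slope * (mean_exc_rate - background_rate),
    0
  )
}

#' Sample spikes from an inhomogeneous Poisson process
#'
#' Per-bin Poisson counts with mean `rate * dt`; the expected total count
#' equals the integral of the rate. Spike times are stamped at bin centres
#' (multiple spikes in one bin share a timestamp).
#'
#' @param rate_hz Rate trace (Hz), one value per bin.
#' @param grid A [time_grid()].
#' @param seed Optional seed.
#' @return Numeric vector of spike times (ms).
#' @export
sample_poisson_spikes <- function(rate_hz, grid, seed = NULL) {
  stopifnot(length(rate_hz) == grid$n_bins, all(rate_hz >= 0))
  draw <- function() {
    counts <- stats::rpois(grid$n_bins, rate_hz * grid$dt / 1000)
    rep(grid_times(grid) + grid$dt / 2, counts)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a full synthetic input session
#'
#' Builds an in-vivo-like stimulation session: an orientation schedule
#' (by default one 3 s block of each of the 16 orientations, 48 s total),
#' per-ensemble synchronized two-state switching with orientation-tuned
#' on-rates, a shared OU rate fluctuation per ensemble, inhomogeneous
#' Poisson spikes per synapse, and inhibitory synapses firing at the
#' tracking rate. All latent traces are returned alongside the spikes.
#'
#' @param config An [ensemble_config()].
#' @param duration_s Session length in seconds; defaults to the schedule
#'   length.
#' @param orientations_deg Stimulus orientations; default the 16 multiples
#'   of 22.5 degrees.
#' @param block_s Length of each orientation block (s, default 3).
#' @param dt Bin width (ms, default 1).
#' @param seed Integer seed; the session is fully reproducible given the
#'   seed.
#' @return An object of class `hln_inputs`: a list with `spikes` (tibble:
#'   `synapse_id`, `time_ms`, `label`, `ensemble_id`), `synapses` (synapse
#'   table), `states` (tibble: `time_ms`, `ensemble_id`, `state`), `rates`
#'   (tibble: `time_ms`, `ensemble_id`, `rate_hz`, with `ensemble_id = 0`
#'   for the inhibitory population), `ensembles` (preferred orientations),
#'   `schedule`, `grid`, `config`, `seed`.
#' @export
generate_inputs <- function(config = ensemble_config(), duration_s = NULL,
                            orientations_deg = seq(0, 337.5, by = 22.5),
                            block_s = 3, dt = 1, seed = 1) {
  stopifnot(inherits(config, "ensemble_config"))
  run <- function() {
    schedule <- tibble::tibble(
      block = seq_along(orientations_deg),
      orientation_deg = orientations_deg,
      t_start_ms = (seq_along(orientations_deg) - 1) * block_s * 1000,
      t_end_ms = seq_along(orientations_deg) * block_s * 1000
    )
    total_ms <- if (is.null(duration_s)) {
      max(schedule$t_end_ms)
    } else {
      duration_s * 1000
    }
    schedule <- dplyr::filter(schedule, .data$t_start_ms < total_ms)
    schedule$t_end_ms <- pmin(schedule$t_end_ms, total_ms)
    grid <- time_grid(dt = dt, n_bins = round(total_ms / dt))

    ne <- config$n_ensembles
    pref <- round(
      stats::rnorm(ne, config$pref_mu_deg, config$pref_sd_deg) / 22.5
    ) * 22.5
    sizes <- rep(config$n_exc %/% ne, ne)
    extra <- config$n_exc %% ne
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1

    exc_syn <- tibble::tibble(
      synapse_id = seq_len(config$n_exc),
      label = "excitatory",
      ensemble_id = rep(seq_len(ne), sizes)
    )
    inh_syn <- tibble::tibble(
      synapse_id = config$n_exc + seq_len(config$n_inh),
      label = "inhibitory",
      ensemble_id = 0L
    )

    states <- matrix(0L, nrow = grid$n_bins, ncol = ne)
    rates <- matrix(0, nrow = grid$n_bins, ncol = ne)
    for (e in seq_len(ne)) {
      st <- "background"
      elapsed <- 0
      s_all <- integer(0)
      for (b in seq_len(nrow(schedule))) {
        w_on <- orientation_on_rate(
          pref[e], schedule$orientation_deg[b], config$omega_on_range
        )
        seg <- sample_state_sequence(
          omega_on = w_on, omega_off = config$omega_off,
          duration_ms = schedule$t_end_ms[b] - schedule$t_start_ms[b],
          max_active_ms = config$max_active_ms, dt = dt,
          init_state = st, init_active_elapsed = elapsed
        )
        s_all <- c(s_all, seg$state)
        st <- seg$final_state
        elapsed <- seg$final_active_elapsed
      }
      states[, e] <- s_all[seq_len(grid$n_bins)]
      rates[, e] <- sample_ou_rates(
        states[, e],
        background_rate = config$background_rate,
        elevated_rate = config$elevated_rate,
        ou = config$ou, dt = dt
      )
    }

    spk <- vector("list", config$n_exc + config$n_inh)
    for (i in seq_len(config$n_exc)) {
      e <- exc_syn$ensemble_id[i]
      tt <- sample_poisson_spikes(rates[, e], grid)
      spk[[i]] <- tibble::tibble(
        synapse_id = exc_syn$synapse_id[i], time_ms = tt,
        label = "excitatory", ensemble_id = e
      )
    }
    # mean excitatory rate weighted by ensemble sizes
    mean_exc <- as.numeric(rates %*% sizes) / sum(sizes)
    inh_rate <- inhibitory_rate(
      mean_exc, config$inhibition,
      background_rate = config$background_rate,
      elevated_rate = config$elevated_rate
    )
    for (j in seq_len(config$n_inh)) {
      i <- config$n_exc + j
      tt <- sample_poisson_spikes(inh_rate, grid)
      spk[[i]] <- tibble::tibble(
        synapse_id = inh_syn$synapse_id[j], time_ms = tt,
        label = "inhibitory", ensemble_id = 0L
      )
    }
    spikes <- dplyr::bind_rows(spk)

    times <- grid_times(grid)
    structure(
      list(
        spikes = spikes,
        synapses = dplyr::bind_rows(exc_syn, inh_syn),
        states = tibble::tibble(
          time_ms = rep(times, ne),
          ensemble_id = rep(seq_len(ne), each = grid$n_bins),
          state = as.integer(states)
        ),
        rates = dplyr::bind_rows(
          tibble::tibble(
            time_ms = rep(times, ne),
            ensemble_id = rep(seq_len(ne), each = grid$n_bins),
            rate_hz = as.numeric(rates)
          ),
          tibble::tibble(
            time_ms = times, ensemble_id = 0L, rate_hz = inh_rate
          )
        ),
        ensembles = tibble::tibble(
          ensemble_id = seq_len(ne), preferred_deg = pref, n_synapses = sizes
        ),
        schedule = schedule,
        grid = grid,
        config = config,
        seed = seed
      ),
      class = "hln_inputs"
    )
  }
  withr::with_seed(seed, run())
}

#' @export
print.hln_inputs <- function(x, ...) {
  cat(sprintf(
    "<hln_inputs> %d excitatory + %d inhibitory synapses, %d ensembles, %.1f s, %d spikes (seed %s)\n",
    x$config$n_exc, x$config$n_inh, x$config$n_ensembles,
    grid_duration(x$grid) / 1000, nrow(x$spikes), format(x$seed)
  ))
  invisible(x)
}
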