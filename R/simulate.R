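# Synthetic dielectric fed-batch runs: culture ODE + spectral forward model.

# Integrate viable/dead/debris dynamics piecewise between discontinuities
# (death onset, bolus dilutions), returning states at `times`.
solve_culture <- function(culture, disturb, times) {
  derivs <- function(t, state, p) {
    growth <- p$mu_max * state[["v"]] *
      (1 - (state[["v"]] + state[["d"]] + state[["b"]]) / p$capacity)
    death <- if (t >= p$death_onset) p$death_rate * state[["v"]] else 0
    lysis <- p$lysis_rate * state[["d"]]
    list(c(v = growth - death, d = death - lysis, b = lysis))
  }
  breaks <- sort(unique(c(0, culture$death_onset, disturb$bolus_times,
                          culture$duration)))
  breaks <- breaks[breaks >= 0 & breaks <= culture$duration]
  state <- c(v = culture$inoculum, d = 0, b = 0)
  out <- matrix(NA_real_, length(times), 3,
                dimnames = list(NULL, c("v", "d", "b")))
  out[times == 0, ] <- rep(state, each = sum(times == 0))
  for (k in seq_len(length(breaks) - 1)) {
    t0 <- breaks[k]; t1 <- breaks[k + 1]
    sel <- which(times > t0 & times <= t1)
    leg_times <- sort(unique(c(t0, times[sel], t1)))
    sol <- deSolve::lsoda(state, leg_times, derivs, culture,
                          rtol = 1e-8, atol = 1e-10)
    if (length(sel)) {
      out[sel, ] <- sol[match(times[sel], sol[, "time"]), c("v", "d", "b")]
    }
    state <- sol[nrow(sol), c("v", "d", "b")]
    ib <- match(t1, disturb$bolus_times)
    if (!is.na(ib)) {
      state <- state * (1 - disturb$bolus_fractions[ib])
      # report post-dilution state at the bolus timestamp
      hit <- which(times == t1)
      if (length(hit)) out[hit, ] <- rep(state, each = length(hit))
    }
  }
  out
}

# Noise-free spectral forward model on pF/cm scale.
clean_spectra <- function(clone, v, debris, freqs, debris_fc) {
  resp_cells <- dispersion_response(freqs, clone$critical_frequency_cells,
                                    clone$cole_cole_alpha)
  resp_debris <- dispersion_response(freqs, debris_fc, clone$cole_cole_alpha)
  clone$per_cell_capacitance * outer(v, resp_cells) +
    clone$debris_amplitude * outer(debris, resp_debris)
}

#' Simulate one synthetic fed-batch run
#'
#' Generates a complete fed-batch data set: a dense online capacitance
#' spectrum time series (17 channels by default), sparse offline
#' VCC/TCC/viability counts with measurement noise, and the noise-free
#' ground-truth VCC on the online grid. The spectrum at time t is
#' `per_cell_capacitance * VCC(t) * D(f; fc_cells) +
#'  debris_amplitude * Debris(t) * D(f; fc_debris)` plus baseline drift,
#' bubble-burst transients and multiplicative noise, where `D` is the
#' low-pass [dispersion_response()].
#'
#' @param clone A [clone_profile()].
#' @param culture A [culture_params()].
#' @param disturb A [disturbance_spec()].
#' @param sampling List with `online_interval` (h, default 0.5),
#'   `offline_interval` (h, default 12; must be >= online interval) and
#'   `offline_cv` (measurement CV of offline counts, default 0.05).
#' @param seed Integer seed; fixes all randomness in the run.
#' @param run_id Optional run identifier.
#'
#' @return A [fermentation_run()] with `online`, `offline` and `truth`
#'   tables.
#' @export
simulate_run <- function(clone = clone_profile(),
                         culture = culture_params(),
                         disturb = disturbance_spec(),
                         sampling = list(),
                         seed = 1L,
                         run_id = NULL) {
  sampling <- modifyList(
    list(online_interval = 0.5, offline_interval = 12, offline_cv = 0.05),
    sampling)
  if (sampling$offline_interval < sampling$online_interval) {
    abort("`offline_interval` must not be shorter than `online_interval`.",
          class = "capsense_argument_error")
  }
  run_id <- run_id %||% sprintf("%s-s%d", clone$name, as.integer(seed))
  freqs <- make_frequency_grid()
  t_on <- seq(0, culture$duration, by = sampling$online_interval)
  t_off <- seq(0, culture$duration, by = sampling$offline_interval)
  t_all <- sort(unique(c(t_on, t_off)))
  states <- solve_culture(culture, disturb, t_all)
  withr::with_seed(as.integer(seed), {
    debris_fc <- clone$debris_critical_frequency
    if (disturb$debris_fc_cv > 0) {
      sdlog <- sqrt(log(1 + disturb$debris_fc_cv^2))
      debris_fc <- debris_fc * exp(rnorm(1, -sdlog^2 / 2, sdlog))
      debris_fc <- max(debris_fc, clone$critical_frequency_cells * 1.05)
    }
    ion <- match(t_on, t_all)
    spec <- clean_spectra(clone, states[ion, "v"], states[ion, "b"],
                          freqs, debris_fc)
    # Run-specific baseline drift (electrode/grounding artifacts),
    # weighted toward the high-frequency channels where the instrument
    # fingerprint lives; scale set by drift_rate at the top channel.
    if (disturb$drift_rate > 0) {
      spec <- spec + rnorm(1, 0, disturb$drift_rate) *
        outer(t_on, freqs / max(freqs))
    }
    if (length(disturb$bubble_burst_times)) {
      dip <- rep(0, length(t_on))
      for (j in seq_along(disturb$bubble_burst_times)) {
        dip <- dip + disturb$bubble_depth[j] *
          exp(-((t_on - disturb$bubble_burst_times[j]) /
                  disturb$bubble_width[j])^2)
      }
      spec <- spec * pmax(0, 1 - dip)
    }
    if (disturb$noise_cv > 0) {
      spec <- spec * (1 + disturb$noise_cv *
                        matrix(rnorm(length(spec)), nrow(spec)))
    }
    if (disturb$noise_floor > 0) {
      spec <- spec + disturb$noise_floor *
        matrix(rnorm(length(spec)), nrow(spec))
    }
    spec <- pmax(spec, 0)
    ioff <- match(t_off, t_all)
    v_off <- states[ioff, "v"]
    t_cc <- states[ioff, "v"] + states[ioff, "d"]
    cv <- sampling$offline_cv
    vcc_meas <- pmax(v_off * (1 + cv * rnorm(length(v_off))), 1e-6)
    tcc_meas <- pmax(t_cc * (1 + cv * rnorm(length(t_cc))), vcc_meas)
    online <- tibble(time_h = t_on)
    online[frequency_labels()] <- as.data.frame(spec)
    offline <- tibble(
      time_h = t_off,
      vcc_1e5_per_ml = vcc_meas,
      tcc_1e5_per_ml = tcc_meas,
      viability_pct = pmin(100, vcc_meas / tcc_meas * 100))
    truth <- tibble(time_h = t_on, vcc_true = states[ion, "v"])
    fermentation_run(online, offline, truth = truth, run_id = run_id,
                     clone = clone$name, scale = "synthetic")
  })
}

# Deterministic sub-seed derivation from one root seed.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max - 1L, n))
}

# Lognormal jitter of selected culture parameters for fleet realism.
jitter_culture <- function(culture, cv, seed) {
  if (cv <= 0) return(culture)
  withr::with_seed(as.integer(seed), {
    sdlog <- sqrt(log(1 + cv^2))
    culture$mu_max <- culture$mu_max * exp(rnorm(1, -sdlog^2 / 2, sdlog))
    onset <- culture$death_onset * exp(rnorm(1, -sdlog^2 / 2, sdlog))
    culture$death_onset <- min(onset, 0.9 * culture$duration)
  })
  culture
}

#' Simulate a fleet of runs for one clone
#'
#' @param clone A [clone_profile()].
#' @param culture Shared [culture_params()]; `param_jitter_cv` applies
#'   per-run lognormal jitter to `mu_max` and `death_onset`.
#' @param n_runs Number of runs.
#' @param seed Root seed; all per-run seeds derive from it.
#' @param disturb A [disturbance_spec()].
#' @param sampling See [simulate_run()].
#' @param param_jitter_cv Run-to-run CV of jittered culture parameters.
#'
#' @return List of [fermentation_run()] objects.
#' @export
simulate_fleet <- function(clone, culture = culture_params(), n_runs = 5,
                           seed = 1L, disturb = disturbance_spec(),
                           sampling = list(), param_jitter_cv = 0.05) {
  if (n_runs == 0) return(list())
  seeds <- matrix(derive_seeds(seed, 2L * n_runs), ncol = 2)
  purrr::map(seq_len(n_runs), function(i) {
    cult_i <- jitter_culture(culture, param_jitter_cv, seeds[i, 1])
    simulate_run(clone, cult_i, disturb, sampling, seed = seeds[i, 2],
                 run_id = sprintf("%s-%02d", clone$name, i))
  })
}

#' Generate a matched clone pair for transfer studies
#'
#' Produces two fleets whose only systematic difference is the
#' per-cell capacitance amplitude: the second clone's amplitude is
#' `amplitude_ratio` times the base clone's. A model calibrated on the
#' base fleet therefore over- or under-estimates the second fleet's VCC
#' by that factor, which the kappa transfer corrects.
#'
#' @param base Base [clone_profile()].
#' @param amplitude_ratio Multiplier (> 0) on `per_cell_capacitance` for
#'   the second clone.
#' @param shared Shared [culture_params()].
#' @param n_runs_each Runs per fleet.
#' @param seed Root seed.
#' @inheritParams simulate_fleet
#'
#' @return List with elements `base` and `other`, each a list of runs.
#' @export
generate_clone_pair <- function(base = clone_profile(),
                                amplitude_ratio = 1 / 0.69,
                                shared = culture_params(),
                                n_runs_each = 3,
                                seed = 1L,
                                disturb = disturbance_spec(),
                                sampling = list(),
                                param_jitter_cv = 0.05) {
  if (amplitude_ratio <= 0) {
    abort("`amplitude_ratio` must be > 0.", class = "capsense_argument_error")
  }
  other <- base
  other$per_cell_capacitance <- base$per_cell_capacitance * amplitude_ratio
  other$name <- paste0(base$name, "-x")
  seeds <- derive_seeds(seed, 2L)
  list(
    base = simulate_fleet(base, shared, n_runs_each, seeds[1], disturb,
                          sampling, param_jitter_cv),
    other = simulate_fleet(other, shared, n_runs_each, seeds[2], disturb,
                           sampling, param_jitter_cv))
}
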