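#' Clone-specific dielectric profile
#'
#' Each CHO clone presents a characteristic capacitance response: an
#' amplitude per viable cell and a beta-dispersion midpoint set by cell
#' size and membrane properties. Sub-cellular debris released by lysis
#' polarizes too, but — being much smaller — disperses at a higher
#' critical frequency, which is why late-process high-frequency channels
#' track debris rather than viable cells.
#'
#' Units: capacitance in pF/cm, concentrations in 1e5 cells/mL (debris in
#' 1e5 cell-equivalents/mL), frequencies in MHz.
#'
#' @param per_cell_capacitance Low-frequency capacitance per unit VCC
#'   (pF/cm per 1e5 cells/mL). Must be > 0.
#' @param critical_frequency_cells Dispersion midpoint of viable cells (MHz).
#' @param cole_cole_alpha Dispersion broadening in `[0, 1)`.
#' @param debris_critical_frequency Dispersion midpoint of debris (MHz);
#'   must exceed `critical_frequency_cells`.
#' @param debris_amplitude Capacitance per unit debris (pF/cm per 1e5
#'   cell-equivalents/mL). May be 0 to switch debris off.
#' @param name Optional clone tag.
#'
#' @return An object of class `clone_profile`.
#' @export
clone_profile <- function(per_cell_capacitance = 0.7,
                          critical_frequency_cells = 1.2,
                          cole_cole_alpha = 0.1,
                          debris_critical_frequency = 6,
                          debris_amplitude = 0.3,
                          name = "cloneA") {
  if (per_cell_capacitance <= 0) {
    abort("`per_cell_capacitance` must be > 0.", class = "capsense_argument_error")
  }
  if (debris_amplitude < 0) {
    abort("`debris_amplitude` must be >= 0.", class = "capsense_argument_error")
  }
  if (critical_frequency_cells <= 0 ||
      debris_critical_frequency <= critical_frequency_cells) {
    abort("`debris_critical_frequency` must exceed `critical_frequency_cells` > 0.",
          class = "capsense_argument_error")
  }
  if (cole_cole_alpha < 0 || cole_cole_alpha >= 1) {
    abort("`cole_cole_alpha` must lie in [0, 1).", class = "capsense_argument_error")
  }
  structure(
    list(per_cell_capacitance = per_cell_capacitance,
         critical_frequency_cells = critical_frequency_cells,
         cole_cole_alpha = cole_cole_alpha,
         debris_critical_frequency = debris_critical_frequency,
         debris_amplitude = debris_amplitude,
         name = name),
    class = "clone_profile")
}

#' Fed-batch culture dynamics parameters
#'
#' Logistic growth with crowding on total accumulated biomass
#' (viable + dead + debris cell-equivalents), first-order death switched
#' on at `death_onset`, and first-order lysis converting dead cells to
#' sub-cellular debris. This is the simplest ODE set producing the
#' canonical fed-batch phenomenology: VCC rises, peaks, then declines
#' while debris accumulates.
#'
#' @param mu_max Maximum specific growth rate (1/h).
#' @param capacity Logistic ceiling on total biomass (1e5 cells/mL).
#' @param death_onset Time at which first-order death switches on (h).
#' @param death_rate First-order death rate after onset (1/h).
#' @param lysis_rate First-order dead-to-debris lysis rate (1/h).
#' @param duration Total process duration (h).
#' @param inoculum Seeding density (1e5 cells/mL); typical seeding is
#'   3–10 in these units.
#'
#' @return An object of class `culture_params`.
#' @export
culture_params <- function(mu_max = 0.045,
                           capacity = 160,
                           death_onset = 144,
                           death_rate = 0.02,
                           lysis_rate = 0.03,
                           duration = 336,
                           inoculum = 5) {
  if (!(duration > death_onset && death_onset > 0)) {
    abort("Need duration > death_onset > 0.", class = "capsense_argument_error")
  }
  if (any(c(mu_max, capacity, death_rate, lysis_rate, inoculum) <= 0)) {
    abort("Rates, capacity and inoculum must be positive.",
          class = "capsense_argument_error")
  }
  structure(
    list(mu_max = mu_max, capacity = capacity, death_onset = death_onset,
         death_rate = death_rate, lysis_rate = lysis_rate,
         duration = duration, inoculum = inoculum),
    class = "culture_params")
}

#' Process disturbance specification
#'
#' Disturbances superimposed on the clean dielectric signal: bolus feed
#' additions (step dilution of all biomass states), bubble-burst
#' transients (short multiplicative dips of the whole spectrum),
#' slow additive baseline drift, and multiplicative channel noise.
#' `debris_fc_cv` adds run-to-run lognormal variation of the debris
#' dispersion midpoint, emulating the run-specific high-frequency
#' fingerprint of real broths.
#'
#' @param bolus_times Times (h) of bolus feed additions.
#' @param bolus_fractions Dilution fraction per bolus, each in (0, 1).
#' @param bubble_burst_times Times (h) of bubble-burst transients.
#' @param bubble_depth Fractional capacitance drop at transient peak.
#' @param bubble_width Gaussian width of the transient (h).
#' @param drift_rate Scale (sd, pF/cm per h) of the run-specific random
#'   baseline drift slope (0 disables).
#' @param noise_cv Multiplicative noise CV on every spectral reading.
#' @param noise_floor Additive Gaussian noise sd (pF/cm) on every
#'   reading — the probe's resolution floor. It dominates the
#'   high-frequency channels, whose signals are numerically small, so
#'   they carry mostly noise.
#' @param debris_fc_cv Lognormal CV of the per-run debris critical
#'   frequency (0 disables).
#'
#' @return An object of class `disturbance_spec`.
#' @export
disturbance_spec <- function(bolus_times = c(96, 144, 192, 240),
                             bolus_fractions = 0.02,
                             bubble_burst_times = c(60, 200),
                             bubble_depth = 0.04,
                             bubble_width = 0.3,
                             drift_rate = 0.05,
                             noise_cv = 0.015,
                             noise_floor = 0.5,
                             debris_fc_cv = 0.1) {
  bolus_fractions <- rep_len(bolus_fractions, length(bolus_times))
  bubble_depth <- rep_len(bubble_depth, length(bubble_burst_times))
  bubble_width <- rep_len(bubble_width, length(bubble_burst_times))
  if (length(bolus_times) && any(bolus_fractions <= 0 | bolus_fractions >= 1)) {
    abort("Bolus dilution fractions must lie in (0, 1).",
          class = "capsense_argument_error")
  }
  if (noise_cv < 0 || noise_floor < 0 || debris_fc_cv < 0) {
    abort("`noise_cv`, `noise_floor` and `debris_fc_cv` must be >= 0.",
          class = "capsense_argument_error")
  }
  structure(
    list(bolus_times = bolus_times, bolus_fractions = bolus_fractions,
         bubble_burst_times = bubble_burst_times, bubble_depth = bubble_depth,
         bubble_width = bubble_width, drift_rate = drift_rate,
         noise_cv = noise_cv, noise_floor = noise_floor,
         debris_fc_cv = debris_fc_cv),
    class = "disturbance_spec")
}

#' Disturbance-free specification
#'
#' Convenience constructor for clean scenarios (no boluses, no
#' transients, no drift, no noise, fixed debris midpoint).
#'
#' @return A `disturbance_spec` with every disturbance switched off.
#' @export
disturbance_none <- function() {
  disturbance_spec(bolus_times = numeric(), bolus_fractions = numeric(),
                   bubble_burst_times = numeric(), bubble_depth = numeric(),
                   bubble_width = numeric(), drift_rate = 0,
                   noise_cv = 0, noise_floor = 0, debris_fc_cv = 0)
}
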