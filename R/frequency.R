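#' Probe excitation frequency grid
#'
#' Scanning capacitance probes excite the broth at a fixed ladder of
#' radio frequencies. The grid used throughout this package is
#' logarithmically spaced, which reproduces the conventional 17-channel
#' scan from 0.3 to 10 MHz in which channel 10 sits at 2.16 MHz — the
#' upper edge of the transferable low-frequency window.
#'
#' @param n Number of frequencies (default 17).
#' @param fmin,fmax Lowest and highest excitation frequency in MHz
#'   (defaults 0.3 and 10).
#'
#' @return Numeric vector of length `n`, strictly increasing, with
#'   `fmin` and `fmax` as endpoints.
#' @examples
#' make_frequency_grid()[10] # ~2.16 MHz
#' @export
make_frequency_grid <- function(n = 17, fmin = 0.3, fmax = 10) {
  if (!is.numeric(n) || length(n) != 1 || n < 2 || n != round(n)) {
    abort("`n` must be a single integer >= 2.", class = "capsense_argument_error")
  }
  if (!is.numeric(fmin) || !is.numeric(fmax) || fmin <= 0 || fmax <= fmin) {
    abort("Need 0 < fmin < fmax.", class = "capsense_argument_error")
  }
  fmin * (fmax / fmin)^((seq_len(n) - 1L) / (n - 1L))
}

#' Channel labels for a frequency grid
#'
#' @param n Number of channels.
#' @return Character vector `"fq01"..."fqNN"`.
#' @export
frequency_labels <- function(n = 17) sprintf("fq%02d", seq_len(n))

#' Low-pass dispersion response of a polarizable particle population
#'
#' Relative capacitance contribution of a particle population at
#' excitation frequency `f`, given the dispersion midpoint (critical
#' frequency) `fc`. The shape is the real part of a Cole-Cole relaxation
#' term; with `alpha = 0` it reduces to the Debye form
#' `1 / (1 + (f/fc)^2)`. Larger `alpha` broadens the dispersion.
#' Viable cells have a lower critical frequency than sub-cellular
#' debris, so high-frequency channels are relatively debris-dominated.
#'
#' @param f Excitation frequency in MHz (vectorised).
#' @param fc Critical frequency in MHz.
#' @param alpha Broadening exponent in `[0, 1)`.
#'
#' @return Values in `(0, 1]`, monotonically non-increasing in `f`.
#' @examples
#' dispersion_response(1.2, 1.2, 0) # Debye midpoint: 0.5
#' @export
dispersion_response <- function(f, fc, alpha = 0) {
  if (any(f <= 0) || fc <= 0) {
    abort("`f` and `fc` must be positive.", class = "capsense_argument_error")
  }
  if (length(alpha) != 1 || alpha < 0 || alpha >= 1) {
    abort("`alpha` must lie in [0, 1).", class = "capsense_argument_error")
  }
  x <- (f / fc)^(1 - alpha)
  s <- sin(alpha * pi / 2)
  (1 + x * s) / (1 + 2 * x * s + x^2)
}
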