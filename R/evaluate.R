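# Error statistics, acceptance verdict, phase splitting and the
# fleet-level transfer experiment.

#' Root mean square error
#'
#' Sample RMSE with an n-1 denominator:
#' `sqrt(sum((y - y_hat)^2) / (n - 1))`.
#'
#' @param y Measured values (1e5 cells/mL).
#' @param y_hat Estimated values, same length.
#' @return Non-negative scalar; 0 iff `y == y_hat`.
#' @export
rmse <- function(y, y_hat) {
  if (length(y) != length(y_hat) || length(y) < 2) {
    abort("`y` and `y_hat` must have equal length >= 2.",
          class = "capsense_argument_error")
  }
  sqrt(sum((y - y_hat)^2) / (length(y) - 1))
}

#' Coefficient of variation of the RMSE (percent)
#'
#' `CVRMSE = RMSE / mean(y_hat) * 100`. The denominator is the mean of
#' the ESTIMATED VCC — the convention this acceptance statistic was
#' defined with; set `denominator = "measured"` for the more common
#' mean-of-measurements variant.
#'
#' @inheritParams rmse
#' @param denominator `"estimated"` (default) or `"measured"`.
#' @return CVRMSE in percent.
#' @export
cvrmse <- function(y, y_hat, denominator = c("estimated", "measured")) {
  denominator <- match.arg(denominator)
  m <- if (denominator == "estimated") mean(y_hat) else mean(y)
  if (!is.finite(m) || m <= 0) {
    abort("CVRMSE denominator (mean VCC) must be positive.",
          class = "capsense_degenerate_error")
  }
  rmse(y, y_hat) / m * 100
}

#' Model acceptance verdict from phase-resolved CVRMSE
#'
#' A model is accepted when whole-process CVRMSE is at most 33 percent
#' and exponential-phase CVRMSE at most 25 percent; rejected outright
#' when whole-process CVRMSE exceeds the absolute 50 percent limit; and
#' questionable in between.
#'
#' @param cvrmse_whole Whole-process CVRMSE (percent).
#' @param cvrmse_exponential Exponential-phase CVRMSE (percent).
#' @return One of `"accepted"`, `"questionable"`, `"rejected"`
#'   (vectorised).
#' @export
classify_acceptance <- function(cvrmse_whole, cvrmse_exponential) {
  if (any(cvrmse_whole < 0 | cvrmse_exponential < 0)) {
    abort("CVRMSE values must be >= 0.", class = "capsense_argument_error")
  }
  dplyr::case_when(
    cvrmse_whole > 50 ~ "rejected",
    cvrmse_whole <= 33 & cvrmse_exponential <= 25 ~ "accepted",
    .default = "questionable")
}

#' Split offline samples into exponential and whole-process phases
#'
#' The exponential growth phase runs from inoculation up to (and
#' including) the offline sample with maximum measured VCC; the whole
#' process phase is every sample.
#'
#' @param run A [fermentation_run()] with >= 3 offline samples.
#' @return List with integer index sets `exponential` and `whole` into
#'   the offline table.
#' @export
split_phases <- function(run) {
  stopifnot(inherits(run, "fermentation_run"))
  v <- run$offline$vcc_1e5_per_ml
  if (length(v) < 3) {
    abort("Need >= 3 offline samples to split phases.",
          class = "capsense_argument_error")
  }
  peak <- which.max(v)
  if (peak == 1) {
    warn("VCC declines from the first sample; exponential phase is that sample only.")
  }
  list(exponential = seq_len(peak), whole = seq_along(v))
}

#' Evaluate an estimator on one run
#'
#' Computes RMSE and phase-resolved CVRMSE at the offline timestamps
#' (where measured VCC exists without interpolation error) and the
#' acceptance verdict. Estimates are taken at the nearest online
#' timestamp to each offline sample.
#'
#' @param model A `pls_vcc`, `transferred_pls` or `dualmode_lr`.
#' @param run A [fermentation_run()].
#' @param denominator Passed to [cvrmse()].
#' @return One-row tibble: `run_id`, `model_type`, `n_points`,
#'   `n_exponential`, `rmse`, `cvrmse_whole`, `cvrmse_exponential`,
#'   `verdict`.
#' @export
evaluate_model <- function(model, run,
                           denominator = c("estimated", "measured")) {
  denominator <- match.arg(denominator)
  phases <- split_phases(run)
  pts <- predict_at_offline(model, run)
  expo <- pts$time_h <= run$offline$time_h[max(phases$exponential)]
  cw <- cvrmse(pts$y, pts$x_hat, denominator)
  ce <- if (sum(expo) >= 2) {
    cvrmse(pts$y[expo], pts$x_hat[expo], denominator)
  } else NA_real_
  tibble(run_id = run$run_id,
         model_type = class(model)[1],
         n_points = nrow(pts),
         n_exponential = sum(expo),
         rmse = rmse(pts$y, pts$x_hat),
         cvrmse_whole = cw,
         cvrmse_exponential = ce,
         r_squared = 1 - sum((pts$y - pts$x_hat)^2) /
           sum((pts$y - mean(pts$y))^2),
         verdict = classify_acceptance(cw, if (is.na(ce)) cw else ce))
}

#' Fit on one fleet, kappa-transfer to another, and evaluate
#'
#' The complete transfer workflow: fit the windowed PLS model on the
#' pooled training fleet, estimate kappa for each validation run, and
#' report phase-resolved CVRMSE with the acceptance verdict per run,
#' plus fleet summary statistics (mean, sd, max).
#'
#' @param train_fleet,validation_fleet Non-empty lists of
#'   [fermentation_run()] objects.
#' @param window Frequency window (default `1:10`).
#' @param scaling_mode Passed to [fit_pls()].
#' @param n_components Passed to [fit_pls()].
#' @param lag_time,min_samples,mode Passed to [estimate_kappa()].
#' @param transfer If `FALSE`, the base model is applied directly
#'   (no kappa adaptation).
#' @param denominator Passed to [cvrmse()].
#' @return List of class `transfer_experiment`: `model`, `reports`
#'   (one row per validation run), `summary`, `kappas`.
#' @export
run_transfer_experiment <- function(train_fleet, validation_fleet,
                                    window = 1:10,
                                    scaling_mode = "mean_center",
                                    n_components = NULL,
                                    lag_time = 6, min_samples = 3,
                                    mode = "regression",
                                    transfer = TRUE,
                                    denominator = "estimated") {
  if (!length(train_fleet) || !length(validation_fleet)) {
    abort("Training and validation fleets must be non-empty.",
          class = "capsense_argument_error")
  }
  model <- fit_pls(purrr::map(train_fleet, spline_align), window,
                   scaling_mode, n_components)
  kappas <- numeric(0)
  reports <- purrr::map_dfr(validation_fleet, function(run) {
    m <- model
    if (transfer) {
      m <- estimate_kappa(model, run, lag_time, min_samples, mode)
      kappas <<- c(kappas, m$kappa)
    }
    evaluate_model(m, run, denominator)
  })
  summary <- reports |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean_cvrmse_whole = mean(.data$cvrmse_whole),
      sd_cvrmse_whole = sd(.data$cvrmse_whole),
      max_cvrmse_whole = max(.data$cvrmse_whole),
      mean_cvrmse_exponential = mean(.data$cvrmse_exponential, na.rm = TRUE),
      max_cvrmse_exponential = max(.data$cvrmse_exponential, na.rm = TRUE),
      n_accepted = sum(.data$verdict == "accepted"))
  structure(list(model = model, reports = reports, summary = summary,
                 kappas = kappas),
            class = "transfer_experiment")
}

#' @export
print.transfer_experiment <- function(x, ...) {
  cat("<transfer_experiment>\n")
  print(x$model)
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
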