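# Calibration transfer between clones/scales via the attenuation
# factor kappa: yhat = kappa * xhat + d, with xhat the foreign model's
# estimate.

# Base-model estimates at the offline timestamps, via direct evaluation
# at the nearest online point (no interpolation of the spectra). Points
# farther than one online sampling interval from any online timestamp
# are dropped.
predict_at_offline <- function(model, run) {
  t_on <- run$online$time_h
  step <- if (length(t_on) > 1) stats::median(diff(t_on)) else Inf
  idx <- purrr::map_int(run$offline$time_h,
                        ~ which.min(abs(t_on - .x)))
  ok <- abs(t_on[idx] - run$offline$time_h) <= step
  est <- predict_vcc(model, run$online[idx, , drop = FALSE])$vcc_est
  tibble(time_h = run$offline$time_h,
         y = run$offline$vcc_1e5_per_ml,
         x_hat = est)[ok, , drop = FALSE]
}

# Least-squares (kappa, d) from qualifying samples under either mode.
solve_kappa <- function(samples, lag_time, min_samples, mode, anchor) {
  qual <- samples[samples$time_h >= lag_time, , drop = FALSE]
  if (nrow(qual) < min_samples) {
    abort(sprintf(
      "Only %d offline sample(s) at t >= %g h; need at least %d.",
      nrow(qual), lag_time, min_samples),
      class = "capsense_insufficient_data")
  }
  if (mode == "regression") {
    fit <- lm(y ~ x_hat, data = qual)
    kappa <- unname(coef(fit)[2]); d <- unname(coef(fit)[1])
  } else {
    dx <- qual$x_hat - anchor$x_hat
    dy <- qual$y - anchor$y
    kappa <- sum(dx * dy) / sum(dx^2)
    d <- anchor$y - kappa * anchor$x_hat
  }
  if (!is.finite(kappa) || kappa <= 0) {
    abort(sprintf("Estimated kappa = %.4g is not positive; transfer failed.",
                  kappa),
          class = "capsense_transfer_failure")
  }
  list(kappa = kappa, d = d, n = nrow(qual))
}

#' Estimate the attenuation factor kappa for a new run
#'
#' Re-uses a PLS model fitted on a foreign clone/scale by estimating the
#' dimensionless slope kappa (and offset d) of
#' `yhat = kappa * xhat + d`, where `xhat` is the foreign model's VCC
#' estimate at the new run's offline sampling times. Because early
#' process events (pH regulation, aeration, drifts) can corrupt the
#' first hours, samples before `lag_time` are excluded.
#'
#' Two estimation modes: `"regression"` fits kappa and d jointly by
#' least squares; `"offset_anchored"` fixes d from the single
#' inoculation sample (the one-measurement-at-inoculation workflow) and
#' fits kappa through that anchor.
#'
#' @param base A fitted [fit_pls()] model.
#' @param run The new clone's [fermentation_run()].
#' @param lag_time Ignore samples before this time (h, default 6).
#' @param min_samples Minimum qualifying samples (default 3).
#' @param mode `"regression"` (default) or `"offset_anchored"`.
#'
#' @return An object of class `transferred_pls`; its `trace` records
#'   the kappa estimate at each update.
#' @export
estimate_kappa <- function(base, run, lag_time = 6, min_samples = 3,
                           mode = c("regression", "offset_anchored")) {
  mode <- match.arg(mode)
  stopifnot(inherits(base, "pls_vcc"), inherits(run, "fermentation_run"))
  samples <- predict_at_offline(base, run)
  anchor <- samples[1, , drop = FALSE]
  est <- solve_kappa(samples, lag_time, min_samples, mode, anchor)
  structure(
    list(base = base, kappa = est$kappa, offset = est$d, mode = mode,
         lag_time = lag_time, min_samples = min_samples,
         n_samples = est$n,
         samples = samples, anchor = anchor,
         trace = tibble(time_h = max(samples$time_h[samples$time_h >= lag_time]),
                        kappa = est$kappa),
         run_id = run$run_id,
         .online = run$online),
    class = "transferred_pls")
}

#' Update kappa online with a new offline sample
#'
#' Re-estimates kappa (and, in regression mode, d) from all qualifying
#' samples including the new one, and appends the estimate to the kappa
#' trace. Earlier trace entries are never rewritten, so logged estimates
#' for past timestamps stand.
#'
#' @param tm A `transferred_pls` from [estimate_kappa()].
#' @param new_sample List or one-row data frame with `time_h` and
#'   `vcc_1e5_per_ml` (the new offline count).
#' @return The updated `transferred_pls`.
#' @export
update_kappa_online <- function(tm, new_sample) {
  stopifnot(inherits(tm, "transferred_pls"))
  if (is.null(tm$.online)) {
    abort("This transferred model was restored without its run spectra; online update unavailable.",
          class = "capsense_argument_error")
  }
  t_new <- new_sample$time_h
  y_new <- new_sample$vcc_1e5_per_ml %||% new_sample$vcc
  if (is.null(t_new) || is.null(y_new)) {
    abort("`new_sample` needs `time_h` and `vcc_1e5_per_ml`.",
          class = "capsense_argument_error")
  }
  if (t_new <= max(tm$samples$time_h)) {
    abort("Offline samples must arrive in time order.",
          class = "capsense_argument_error")
  }
  if (t_new < tm$lag_time) {
    abort(sprintf("Sample at %g h precedes the lag time (%g h).",
                  t_new, tm$lag_time),
          class = "capsense_argument_error")
  }
  t_on <- tm$.online$time_h
  i <- which.min(abs(t_on - t_new))
  x_new <- predict_vcc(tm$base, tm$.online[i, , drop = FALSE])$vcc_est
  tm$samples <- dplyr::bind_rows(tm$samples,
                                 tibble(time_h = t_new, y = y_new,
                                        x_hat = x_new))
  est <- solve_kappa(tm$samples, tm$lag_time, tm$min_samples, tm$mode,
                     tm$anchor)
  tm$kappa <- est$kappa; tm$offset <- est$d; tm$n_samples <- est$n
  tm$trace <- dplyr::bind_rows(tm$trace,
                               tibble(time_h = t_new, kappa = est$kappa))
  tm
}

#' @export
predict_vcc.transferred_pls <- function(model, new_data) {
  out <- predict_vcc(model$base, new_data)
  out$vcc_est <- model$kappa * out$vcc_est + model$offset
  out
}

#' @export
predict.transferred_pls <- function(object, newdata, ...) {
  predict_vcc(object, newdata)
}

#' Predict VCC with a transferred model
#'
#' Elementwise `yhat = kappa * xhat + d` on top of the base model's
#' estimate.
#'
#' @param tm A `transferred_pls`.
#' @param new_data Spectra input as in [predict_vcc()].
#' @return Tibble with `time_h` and `vcc_est`.
#' @export
predict_transferred <- function(tm, new_data) predict_vcc(tm, new_data)

#' @export
print.transferred_pls <- function(x, ...) {
  cat(sprintf(
    "<transferred_pls> kappa %.4f, offset %.3f (%s, lag %g h, %d samples)\n",
    x$kappa, x$offset, x$mode, x$lag_time, x$n_samples))
  print(x$base)
  invisible(x)
}

#' @export
tidy.transferred_pls <- function(x, ...) {
  tibble(term = c("kappa", "offset"),
         estimate = c(x$kappa, x$offset))
}

#' @export
glance.transferred_pls <- function(x, ...) {
  tibble(kappa = x$kappa, offset = x$offset, mode = x$mode,
         lag_time_h = x$lag_time, n_samples = x$n_samples)
}
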