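# SIMPLS estimator for VCC from capacitance spectra, plus the
# single-frequency dual-mode linear baseline.

# SIMPLS (de Jong 1993) for univariate y. X must already be
# centered/scaled and y centered. Score vectors are normalized to unit
# length; loadings P and the orthonormal basis V deflate the
# cross-covariance vector S rather than X itself.
simpls_fit <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  total_ssx <- sum(X^2)
  S <- crossprod(X, y)
  R <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); V <- matrix(0, p, ncomp)
  Q <- numeric(ncomp); ssx <- numeric(ncomp)
  Tm <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    r <- S
    t_ <- drop(X %*% r)
    nt2 <- sum(t_^2)
    if (!is.finite(nt2) || nt2 <= 1e-12 * max(total_ssx, 1)) {
      abort(sprintf("Requested %d components but X has rank < %d.",
                    ncomp, a),
            class = "capsense_rank_error")
    }
    nt <- sqrt(nt2)
    t_ <- t_ / nt
    r <- r / nt
    p_ <- crossprod(X, t_)
    q_ <- sum(y * t_)
    v <- p_
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, p_)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; P[, a] <- p_; V[, a] <- v
    Q[a] <- q_; ssx[a] <- sum(p_^2); Tm[, a] <- t_
  }
  list(coef_scaled = drop(R %*% Q),
       x_variance_pct = cumsum(ssx) / total_ssx * 100,
       scores = Tm)
}

pool_aligned <- function(train) {
  if (inherits(train, "aligned_vcc") || is.data.frame(train)) train <- list(train)
  run_ids <- purrr::map_chr(train, ~ attr(.x, "run_id") %||% NA_character_)
  list(data = dplyr::bind_rows(purrr::map(train, as_tibble)),
       run_ids = run_ids)
}

#' Fit the multi-frequency PLS estimator of VCC
#'
#' Fits the prediction model
#' `yhat = a1*c1 + a2*c2 + ... + aF*cF + d`
#' by SIMPLS on the scaled, pooled training rows, where `a_i` are the
#' capacitance values (pF/cm) of the retained frequency window and
#' `c_i` the regression coefficients in (cm x 1e5)/(pF mL). The
#' coefficients are back-mapped to raw capacitance units, so the fitted
#' model applies directly to unscaled spectra and serializes in
#' human-readable form. `y` is centered only (never scaled), in both
#' scaling modes.
#'
#' By convention, models with three or more predictor frequencies use
#' three latent components (which capture over 99 percent of the
#' spectral variance on typical fed-batch data); with fewer than three
#' frequencies the component count drops to the number of frequencies.
#'
#' @param train An `aligned_vcc` tibble (from [spline_align()]) or a
#'   list of them, pooled row-wise.
#' @param window Integer vector of retained channel indices (contiguous
#'   from 1); default the published transferable window `1:10`.
#' @param scaling_mode `"mean_center"` (default) or `"standardize"`.
#' @param n_components Number of latent components; default
#'   `min(3, length(window))`.
#'
#' @return An object of class `pls_vcc`.
#' @export
fit_pls <- function(train, window = 1:10,
                    scaling_mode = c("mean_center", "standardize"),
                    n_components = NULL) {
  scaling_mode <- match.arg(scaling_mode)
  pooled <- pool_aligned(train)
  dat <- pooled$data
  cols <- sprintf("fq%02d", window)
  check_columns(dat, c("vcc", cols), "training")
  F_ <- length(window)
  n_components <- n_components %||% min(3L, F_)
  n <- nrow(dat)
  if (n < n_components + 1) {
    abort("Need at least n_components + 1 pooled training rows.",
          class = "capsense_argument_error")
  }
  if (n_components > F_) {
    abort("`n_components` cannot exceed the window size.",
          class = "capsense_argument_error")
  }
  X <- as.matrix(dat[cols])
  y <- dat$vcc
  scaling <- fit_scaling(X, scaling_mode)
  Xs <- apply_scaling(X, scaling)
  ybar <- mean(y)
  fit <- simpls_fit(Xs, y - ybar, n_components)
  coefs <- setNames(fit$coef_scaled / scaling$sd, cols)
  intercept <- ybar - sum(coefs * scaling$mean)
  yhat <- drop(X %*% coefs) + intercept
  r2 <- 1 - sum((y - yhat)^2) / sum((y - ybar)^2)
  structure(
    list(frequency_window = as.integer(window),
         scaling = scaling,
         n_components = as.integer(n_components),
         coefficients = coefs,
         intercept = intercept,
         x_variance_pct = fit$x_variance_pct,
         r_squared_train = r2,
         metadata = list(run_ids = pooled$run_ids,
                         clone = attr(if (is.data.frame(train)) train else train[[1]],
                                      "clone") %||% NA_character_,
                         n_train = n)),
    class = "pls_vcc")
}

# Extract the spectra table from run / aligned / plain tibble input.
spectra_table <- function(new_data) {
  if (inherits(new_data, "fermentation_run")) return(new_data$online)
  as_tibble(new_data)
}

#' Predict VCC from capacitance spectra
#'
#' Applies a fitted estimator to new spectra: the linear form
#' `sum(c_i * a_i) + d`. Estimates are reported raw — negative values
#' are not clipped, so downstream evaluation sees the unmodified
#' estimator.
#'
#' @param model A `pls_vcc`, `dualmode_lr` or `transferred_pls` object.
#' @param new_data A [fermentation_run()] (its online table is used) or
#'   a tibble containing the required `fq` columns and optionally
#'   `time_h`.
#'
#' @return Tibble with `time_h` (if available) and `vcc_est`.
#' @export
predict_vcc <- function(model, new_data) {
  UseMethod("predict_vcc")
}

#' @export
predict_vcc.pls_vcc <- function(model, new_data) {
  dat <- spectra_table(new_data)
  cols <- names(model$coefficients)
  missing <- setdiff(cols, names(dat))
  if (length(missing)) {
    abort(sprintf("Spectra are missing window channel(s): %s",
                  paste(missing, collapse = ", ")),
          class = "capsense_schema_error")
  }
  est <- drop(as.matrix(dat[cols]) %*% model$coefficients) + model$intercept
  out <- tibble(vcc_est = est)
  if ("time_h" %in% names(dat)) out <- tibble(time_h = dat$time_h,
                                              vcc_est = est)
  out
}

#' @export
predict.pls_vcc <- function(object, newdata, ...) predict_vcc(object, newdata)

#' @export
print.pls_vcc <- function(x, ...) {
  cat(sprintf("<pls_vcc> SIMPLS, %d components, window 1:%d (%s)\n",
              x$n_components, max(x$frequency_window), x$scaling$mode))
  cat(sprintf("  training R^2 %.4f; X-variance (cum) %s%%\n",
              x$r_squared_train,
              paste(sprintf("%.2f", x$x_variance_pct), collapse = "/")))
  invisible(x)
}

#' @export
tidy.pls_vcc <- function(x, ...) {
  freqs <- make_frequency_grid()
  tibble(term = c(names(x$coefficients), "(Intercept)"),
         frequency_mhz = c(freqs[x$frequency_window], NA_real_),
         estimate = c(unname(x$coefficients), x$intercept))
}

#' @export
glance.pls_vcc <- function(x, ...) {
  tibble(n_components = x$n_components,
         n_frequencies = length(x$frequency_window),
         r.squared = x$r_squared_train,
         x_variance_pct = tail(x$x_variance_pct, 1),
         nobs = x$metadata$n_train)
}

#' Fit the single-frequency dual-mode linear baseline
#'
#' Ordinary least squares of VCC on the dual-mode signal: the working
#' frequency channel (the manufacturer standard, nearest 1 MHz) minus
#' the highest-frequency channel, which subtracts the broth background.
#' Calibration may be restricted to the exponential growth phase (up to
#' peak VCC), the common practice for linear capacitance calibration.
#'
#' @param train An `aligned_vcc` tibble for one run.
#' @param working_frequency Channel index; default the grid frequency
#'   nearest 1 MHz (channel 6 on the standard grid).
#' @param calibration_phase `"exponential_only"` (default) or
#'   `"whole_run"`.
#'
#' @return An object of class `dualmode_lr`.
#' @export
fit_linear_baseline <- function(train,
                                working_frequency = NULL,
                                calibration_phase = c("exponential_only",
                                                      "whole_run")) {
  calibration_phase <- match.arg(calibration_phase)
  dat <- as_tibble(train)
  chans <- grep("^fq\\d+$", names(dat), value = TRUE)
  chan_nums <- as.integer(sub("fq", "", chans))
  if (is.null(working_frequency)) {
    # channel on the standard grid nearest the 1 MHz manufacturer default
    freqs <- make_frequency_grid(max(chan_nums))[chan_nums]
    working_frequency <- chan_nums[which.min(abs(log(freqs)))]
  }
  reference <- max(chan_nums)
  if (!working_frequency %in% chan_nums) {
    abort("`working_frequency` channel not present in the data.",
          class = "capsense_argument_error")
  }
  if (working_frequency == reference) {
    abort("Working frequency must differ from the reference (highest) channel.",
          class = "capsense_argument_error")
  }
  if (calibration_phase == "exponential_only") {
    t_peak <- dat$time_h[which.max(dat$vcc)]
    dat <- dat[dat$time_h <= t_peak, , drop = FALSE]
  }
  if (nrow(dat) < 2) {
    abort("Need >= 2 calibration rows.", class = "capsense_argument_error")
  }
  u <- dat[[sprintf("fq%02d", working_frequency)]] -
    dat[[sprintf("fq%02d", reference)]]
  if (sd(u) == 0) {
    abort("Dual-mode regressor is constant.",
          class = "capsense_degenerate_column")
  }
  fit <- lm(dat$vcc ~ u)
  r2 <- 1 - sum(fit$residuals^2) / sum((dat$vcc - mean(dat$vcc))^2)
  structure(
    list(working_frequency = as.integer(working_frequency),
         reference_frequency = as.integer(reference),
         slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = r2,
         calibration_phase = calibration_phase,
         n_calibration = nrow(dat)),
    class = "dualmode_lr")
}

#' @export
predict_vcc.dualmode_lr <- function(model, new_data) {
  dat <- spectra_table(new_data)
  wf <- sprintf("fq%02d", model$working_frequency)
  rf <- sprintf("fq%02d", model$reference_frequency)
  missing <- setdiff(c(wf, rf), names(dat))
  if (length(missing)) {
    abort(sprintf("Spectra are missing channel(s): %s",
                  paste(missing, collapse = ", ")),
          class = "capsense_schema_error")
  }
  est <- model$slope * (dat[[wf]] - dat[[rf]]) + model$intercept
  if ("time_h" %in% names(dat)) tibble(time_h = dat$time_h, vcc_est = est)
  else tibble(vcc_est = est)
}

#' @export
predict.dualmode_lr <- function(object, newdata, ...) predict_vcc(object, newdata)

#' @export
print.dualmode_lr <- function(x, ...) {
  cat(sprintf(
    "<dualmode_lr> fq%02d - fq%02d, slope %.4g, intercept %.4g (R^2 %.4f, %s)\n",
    x$working_frequency, x$reference_frequency, x$slope, x$intercept,
    x$r_squared, x$calibration_phase))
  invisible(x)
}

#' Serialize / restore fitted models as JSON
#'
#' Models are written in raw capacitance units so the stored
#' coefficients are directly interpretable and portable; doubles are
#' written with 17 significant digits for an exact round trip.
#'
#' @param model A `pls_vcc` or `transferred_pls`.
#' @param path Output file.
#' @return `write_model` returns `path` invisibly; `read_model` the
#'   restored model.
#' @export
write_model <- function(model, path) {
  payload <- if (inherits(model, "transferred_pls")) {
    list(type = "transferred_pls",
         base = model_payload(model$base),
         kappa = model$kappa,
         offset = model$offset,
         mode = model$mode,
         lag_time_h = model$lag_time,
         kappa_trace = model$trace)
  } else {
    model_payload(model)
  }
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

model_payload <- function(model) {
  stopifnot(inherits(model, "pls_vcc"))
  list(type = "pls_vcc",
       frequency_window = model$frequency_window,
       scaling = list(mode = model$scaling$mode,
                      means = as.list(model$scaling$mean),
                      sds = as.list(model$scaling$sd)),
       n_components = model$n_components,
       coefficients = as.list(model$coefficients),
       intercept = model$intercept,
       x_variance_pct = model$x_variance_pct,
       r_squared_train = model$r_squared_train,
       metadata = model$metadata)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Model file not found: %s", path),
          class = "capsense_format_error")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "transferred_pls")) {
    base <- restore_pls(obj$base)
    structure(
      list(base = base,
           kappa = obj$kappa,
           offset = obj$offset,
           mode = obj$mode,
           lag_time = obj$lag_time_h,
           trace = as_tibble(obj$kappa_trace)),
      class = "transferred_pls")
  } else {
    restore_pls(obj)
  }
}

restore_pls <- function(obj) {
  structure(
    list(frequency_window = as.integer(obj$frequency_window),
         scaling = structure(list(mode = obj$scaling$mode,
                                  mean = unlist(obj$scaling$means),
                                  sd = unlist(obj$scaling$sds)),
                             class = "scaling_params"),
         n_components = as.integer(obj$n_components),
         coefficients = unlist(obj$coefficients),
         intercept = obj$intercept,
         x_variance_pct = obj$x_variance_pct,
         r_squared_train = obj$r_squared_train,
         metadata = obj$metadata),
    class = "pls_vcc")
}
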