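# Column scaling, cross-run capacitance maps, frequency-window selection.

#' Fit column scaling parameters
#'
#' Capacitance channels are scaled before PLS: mean centering (the more
#' common choice for these models) or standardization to unit variance.
#' The fitted constants are stored so new data are always scaled with
#' the training constants.
#'
#' @param X Data frame or matrix of predictor columns (>= 2 rows).
#' @param mode `"mean_center"` or `"standardize"`.
#' @return An object of class `scaling_params` with per-column `mean`
#'   and `sd` (`sd` identically 1 for mean centering).
#' @export
fit_scaling <- function(X, mode = c("mean_center", "standardize")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (nrow(X) < 2) {
    abort("Need >= 2 rows to fit scaling.", class = "capsense_argument_error")
  }
  mu <- colMeans(X)
  s <- rep(1, ncol(X))
  if (mode == "standardize") {
    s <- apply(X, 2, sd)
    degenerate <- which(s <= 0 | !is.finite(s))
    if (length(degenerate)) {
      abort(sprintf("Constant column(s) under standardize: %s",
                    paste(degenerate, collapse = ", ")),
            class = "capsense_degenerate_column")
    }
  }
  structure(list(mode = mode, mean = mu, sd = s), class = "scaling_params")
}

#' @rdname fit_scaling
#' @param params A fitted `scaling_params`.
#' @export
apply_scaling <- function(X, params) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, params$mean, "-"), 2, params$sd, "/")
}

#' @rdname fit_scaling
#' @export
inverse_scaling <- function(X, params) {
  X <- as.matrix(X)
  sweep(sweep(X, 2, params$sd, "*"), 2, params$mean, "+")
}

# Min-max rescale with explicit constants; constant columns map to 0.
rescale01 <- function(x, lo, hi) {
  if (hi <= lo) return(rep(0, length(x)))
  (x - lo) / (hi - lo)
}

#' Build a cross-run capacitance map
#'
#' A capacitance map is a heat-map-ready table in which every channel is
#' min-max normalized over the pooled runs (the global per-channel
#' maximum maps to 1), with a normalized VCC column alongside. It lets
#' an operator spot channels whose late-run signal tracks debris rather
#' than viable cells before any model is built.
#'
#' @param runs List of [fermentation_run()] objects (>= 1).
#' @return A long tibble of class `capacitance_map` with columns
#'   `run_id`, `time_h`, `channel` (`"vcc"` first, then `fq01`...),
#'   `value` (raw) and `value_norm` in `[0, 1]`; normalization constants
#'   in attribute `norm_constants`.
#' @export
build_capacitance_map <- function(runs) {
  if (!is.list(runs) || length(runs) == 0 ||
      !all(purrr::map_lgl(runs, inherits, "fermentation_run"))) {
    abort("`runs` must be a non-empty list of fermentation_run objects.",
          class = "capsense_argument_error")
  }
  long <- purrr::map_dfr(runs, function(run) {
    al <- spline_align(run)
    tidyr::pivot_longer(
      as_tibble(al),
      cols = -"time_h", names_to = "channel", values_to = "value") |>
      dplyr::mutate(run_id = run$run_id, .before = 1)
  })
  consts <- long |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(lo = min(.data$value), hi = max(.data$value),
                     .groups = "drop")
  long <- long |>
    dplyr::left_join(consts, by = "channel") |>
    dplyr::group_by(.data$channel) |>
    dplyr::mutate(value_norm = rescale01(.data$value, .data$lo[1], .data$hi[1])) |>
    dplyr::ungroup() |>
    dplyr::select(-"lo", -"hi") |>
    dplyr::mutate(channel = factor(.data$channel,
                                   levels = c("vcc", sort(setdiff(unique(.data$channel), "vcc")))))
  attr(long, "norm_constants") <- consts
  class(long) <- c("capacitance_map", class(long))
  long
}

#' Select the transferable frequency window
#'
#' Windows are contiguous and anchored at channel 1 (lowest frequency),
#' mirroring the ablation convention `1:17`, `1:10`, ... In `"fixed"`
#' mode the published transferable window `1:10` (0.3–2.16 MHz) is
#' returned regardless of the data. In `"data_driven"` mode — an
#' automated stand-in for the visual capacitance-map inspection — the
#' longest prefix `1:k` is retained such that every retained channel's
#' Pearson correlation with splined VCC, averaged over runs, is at
#' least `threshold`.
#'
#' @param runs List of [fermentation_run()] objects.
#' @param mode `"fixed"` or `"data_driven"`.
#' @param threshold Minimum mean correlation (default 0.8).
#' @return Integer vector of retained channel indices (`1:k`), with the
#'   per-channel mean correlations in attribute `mean_correlation`
#'   (data-driven mode).
#' @export
select_frequencies <- function(runs, mode = c("fixed", "data_driven"),
                               threshold = 0.8) {
  mode <- match.arg(mode)
  if (mode == "fixed") return(1:10)
  if (!length(runs)) {
    abort("`runs` must be non-empty for data-driven selection.",
          class = "capsense_argument_error")
  }
  cors <- purrr::map(runs, function(run) {
    al <- spline_align(run)
    X <- as.matrix(al[, grep("^fq\\d+$", names(al)), drop = FALSE])
    apply(X, 2, function(col) {
      if (sd(col) == 0 || sd(al$vcc) == 0) return(NA_real_)
      cor(col, al$vcc)
    })
  })
  mean_cor <- colMeans(do.call(rbind, cors), na.rm = TRUE)
  declining <- purrr::map_lgl(runs, function(run) {
    v <- run$offline$vcc_1e5_per_ml
    which.max(v) < length(v)
  })
  if (!any(declining)) {
    warn(paste("No run shows a decline phase; data-driven selection is",
               "only meaningful when debris is present."))
  }
  below <- which(mean_cor < threshold)
  k <- if (length(below)) below[1] - 1L else length(mean_cor)
  if (k < 1) {
    warn("No channel reaches the correlation threshold; retaining channel 1.")
    k <- 1L
  }
  structure(seq_len(k), mean_correlation = mean_cor)
}
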