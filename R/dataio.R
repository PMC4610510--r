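#' Fed-batch run container
#'
#' Holds one fed-batch fermentation: the dense online capacitance
#' spectrum table, the sparse offline cell-count table, and (for
#' synthetic runs) the noise-free ground-truth VCC.
#'
#' @param online Tibble with `time_h` and capacitance columns
#'   `fq01`...`fqNN` (pF/cm), time strictly increasing.
#' @param offline Tibble with `time_h`, `vcc_1e5_per_ml` and optionally
#'   `tcc_1e5_per_ml`, `viability_pct`.
#' @param truth Optional tibble with `time_h`, `vcc_true` on the online
#'   grid.
#' @param run_id,clone,scale Metadata tags.
#'
#' @return An object of class `fermentation_run`.
#' @export
fermentation_run <- function(online, offline, truth = NULL,
                             run_id = "run", clone = NA_character_,
                             scale = NA_character_) {
  online <- as_tibble(online)
  offline <- as_tibble(offline)
  check_columns(online, c("time_h", grep("^fq\\d+$", names(online), value = TRUE)),
                "online")
  if (!any(grepl("^fq\\d+$", names(online)))) {
    abort("Online table has no capacitance columns (fq01...).",
          class = "capsense_format_error")
  }
  check_columns(offline, c("time_h", "vcc_1e5_per_ml"), "offline")
  check_times(online$time_h, "online")
  check_times(offline$time_h, "offline")
  check_finite(online, "online")
  check_finite(offline, "offline")
  if (!is.null(truth)) {
    truth <- as_tibble(truth)
    check_columns(truth, c("time_h", "vcc_true"), "truth")
  }
  structure(
    list(run_id = run_id, clone = clone, scale = scale,
         online = online, offline = offline, truth = truth),
    class = "fermentation_run")
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s table is missing column(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "capsense_format_error")
  }
  invisible(df)
}

check_times <- function(t, what) {
  if (length(t) > 1 && any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1
    abort(sprintf("%s table: time_h not strictly increasing at row %d.",
                  what, bad),
          class = "capsense_format_error")
  }
  invisible(t)
}

check_finite <- function(df, what) {
  for (nm in names(df)) {
    bad <- which(!is.finite(df[[nm]]))
    if (length(bad)) {
      abort(sprintf("%s table: non-finite value in column '%s', row %d.",
                    what, nm, bad[1]),
            class = "capsense_format_error")
    }
  }
  invisible(df)
}

#' @export
print.fermentation_run <- function(x, ...) {
  cat(sprintf("<fermentation_run> %s (clone %s, scale %s)\n",
              x$run_id, x$clone, x$scale))
  cat(sprintf("  online : %d timepoints x %d channels, %.1f-%.1f h\n",
              nrow(x$online), sum(grepl("^fq", names(x$online))),
              min(x$online$time_h), max(x$online$time_h)))
  cat(sprintf("  offline: %d samples, peak VCC %.1f x1e5/mL\n",
              nrow(x$offline), max(x$offline$vcc_1e5_per_ml)))
  if (!is.null(x$truth)) cat("  ground truth present\n")
  invisible(x)
}

#' Write a run to CSV files
#'
#' Writes `<run_id>_online.csv`, `<run_id>_offline.csv` and, when ground
#' truth is present, `<run_id>_truth.csv` into `dir`.
#'
#' @param run A [fermentation_run()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "fermentation_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(online = file.path(dir, paste0(run$run_id, "_online.csv")),
             offline = file.path(dir, paste0(run$run_id, "_offline.csv")))
  readr::write_csv(run$online, paths[["online"]])
  readr::write_csv(run$offline, paths[["offline"]])
  if (!is.null(run$truth)) {
    paths[["truth"]] <- file.path(dir, paste0(run$run_id, "_truth.csv"))
    readr::write_csv(run$truth, paths[["truth"]])
  }
  invisible(paths)
}

#' Read a run from CSV files
#'
#' Accepts either a path prefix (`<prefix>_online.csv` etc. must exist)
#' or a named vector/list with elements `online`, `offline` and
#' optionally `truth`.
#'
#' @param paths Path prefix or named paths.
#' @param run_id,clone,scale Metadata; `run_id` defaults to the prefix
#'   basename.
#' @return A [fermentation_run()].
#' @export
read_run <- function(paths, run_id = NULL, clone = NA_character_,
                     scale = NA_character_) {
  if (is.character(paths) && length(paths) == 1 && is.null(names(paths))) {
    prefix <- sub("_online\\.csv$", "", paths)
    paths <- c(online = paste0(prefix, "_online.csv"),
               offline = paste0(prefix, "_offline.csv"))
    tr <- paste0(prefix, "_truth.csv")
    if (file.exists(tr)) paths[["truth"]] <- tr
    run_id <- run_id %||% basename(prefix)
  }
  paths <- as.list(paths)
  for (p in unlist(paths[c("online", "offline")])) {
    if (!file.exists(p)) {
      abort(sprintf("File not found: %s", p), class = "capsense_format_error")
    }
  }
  rd <- function(p) readr::read_csv(p, show_col_types = FALSE,
                                    progress = FALSE)
  truth <- if (!is.null(paths$truth)) rd(paths$truth)
  fermentation_run(rd(paths$online), rd(paths$offline), truth = truth,
                   run_id = run_id %||% "run", clone = clone, scale = scale)
}

#' Align sparse offline VCC to the dense online grid
#'
#' Offline VCC counts arrive every several hours while capacitance is
#' logged near-continuously. For model fitting, offline VCC is
#' interpolated to the online timestamps by a cubic interpolating
#' spline (which preserves the curvy character of VCC between samples),
#' evaluated only inside the convex hull of the offline times — no
#' extrapolation.
#'
#' @param run A [fermentation_run()] with at least 2 offline samples.
#' @param window Optional `c(t_start, t_end)` (h) further restricting
#'   the aligned range; must lie within the offline time span.
#'
#' @return A tibble of class `aligned_vcc` with columns `time_h`, `vcc`
#'   (splined, 1e5 cells/mL) and the capacitance channels.
#' @export
spline_align <- function(run, window = NULL) {
  stopifnot(inherits(run, "fermentation_run"))
  to <- run$offline$time_h
  yo <- run$offline$vcc_1e5_per_ml
  if (length(to) < 2) {
    abort("Need at least 2 offline samples to align.",
          class = "capsense_insufficient_data")
  }
  lo <- min(to); hi <- max(to)
  if (!is.null(window)) {
    if (length(window) != 2 || window[1] >= window[2] ||
        window[1] < lo || window[2] > hi) {
      abort("`window` must lie within the offline time span.",
            class = "capsense_range_error")
    }
    lo <- window[1]; hi <- window[2]
  }
  keep <- run$online$time_h >= lo & run$online$time_h <= hi
  tq <- run$online$time_h[keep]
  y <- if (length(to) == 2) {
    approx(to, yo, xout = tq)$y
  } else {
    spline(to, yo, xout = tq, method = "fmm")$y
  }
  out <- tibble(time_h = tq, vcc = y)
  out <- dplyr::bind_cols(
    out, run$online[keep, grep("^fq\\d+$", names(run$online)), drop = FALSE])
  attr(out, "run_id") <- run$run_id
  attr(out, "clone") <- run$clone
  class(out) <- c("aligned_vcc", class(out))
  out
}
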