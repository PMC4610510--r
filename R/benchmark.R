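# Reproducible end-to-end synthetic benchmark: two clone fleets,
# bidirectional kappa transfer, linear baseline, model-selection ladder.

#' Default benchmark configuration
#'
#' The study conditions of the bundled synthetic benchmark: a
#' debris-heavy 14-day fed-batch (online every 30 min, offline every
#' 12 h, offline count CV 5 percent), two clones differing only in
#' per-cell capacitance amplitude by 1/0.69, five training and six
#' validation runs per clone, window 1:10 with mean centering and three
#' components, kappa regression with a 6 h lag.
#'
#' @param path Optional YAML file whose entries override the defaults.
#' @return Nested configuration list.
#' @export
benchmark_config <- function(path = NULL) {
  cfg <- list(
    clone = list(per_cell_capacitance = 0.7, critical_frequency_cells = 1.2,
                 cole_cole_alpha = 0.1, debris_critical_frequency = 6,
                 debris_amplitude = 0.3, name = "cloneA"),
    amplitude_ratio = 1 / 0.69,
    debris_fc_ratio = 0.6,
    culture = list(mu_max = 0.045, capacity = 160, death_onset = 144,
                   death_rate = 0.02, lysis_rate = 0.03, duration = 336,
                   inoculum = 5),
    disturb = list(bolus_times = c(96, 144, 192, 240), bolus_fractions = 0.02,
                   bubble_burst_times = c(60, 200), bubble_depth = 0.04,
                   bubble_width = 0.3, drift_rate = 0.05, noise_cv = 0.015,
                   noise_floor = 0.5, debris_fc_cv = 0.1),
    sampling = list(online_interval = 0.5, offline_interval = 12,
                    offline_cv = 0.05),
    n_train = 5, n_validation = 6,
    window = 1:10, scaling_mode = "mean_center", n_components = 3,
    lag_time = 6, min_samples = 3, kappa_mode = "regression",
    param_jitter_cv = 0.05)
  if (!is.null(path)) {
    if (!file.exists(path)) {
      abort(sprintf("Config file not found: %s", path),
            class = "capsense_format_error")
    }
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  cfg
}

config_objects <- function(cfg) {
  list(clone = do.call(clone_profile, cfg$clone),
       culture = do.call(culture_params, cfg$culture),
       disturb = do.call(disturbance_spec, cfg$disturb))
}

#' Run the synthetic transfer benchmark
#'
#' Simulates training and validation fleets for two clones whose only
#' systematic difference is the per-cell capacitance amplitude, then
#' evaluates the model-selection ladder on the cross-clone validation
#' runs: exponential- and whole-run-calibrated dual-mode linear
#' baselines, direct (un-adapted) PLS transfer with the full and the
#' restricted frequency window, and kappa-adapted transfer with both
#' windows. The kappa-adapted windowed transfer is run in both
#' directions (A-model on clone-B runs and vice versa).
#'
#' @param config A [benchmark_config()] list.
#' @param seed Root seed; every simulated run and jitter derives from it.
#' @return List of class `capsense_benchmark` with `fleets`, `reports`
#'   (per-direction transfer experiments), `lr_reports`, `same_clone`,
#'   `ladder` and `metrics`.
#' @export
run_benchmark <- function(config = benchmark_config(), seed = 1L) {
  obj <- config_objects(config)
  clone_a <- obj$clone
  clone_b <- clone_a
  clone_b$per_cell_capacitance <- clone_a$per_cell_capacitance *
    config$amplitude_ratio
  # clone-specific debris signature: each clone presents its own
  # high-frequency fingerprint
  clone_b$debris_critical_frequency <- clone_a$debris_critical_frequency *
    (config$debris_fc_ratio %||% 1)
  clone_b$name <- "cloneB"
  seeds <- derive_seeds(seed, 4L)
  fleet <- function(clone, n, s) {
    simulate_fleet(clone, obj$culture, n, s, obj$disturb, config$sampling,
                   config$param_jitter_cv)
  }
  fleets <- list(
    a_train = fleet(clone_a, config$n_train, seeds[1]),
    a_val = fleet(clone_a, config$n_validation, seeds[2]),
    b_train = fleet(clone_b, config$n_train, seeds[3]),
    b_val = fleet(clone_b, config$n_validation, seeds[4]))

  tx <- function(train, val, window, transfer) {
    run_transfer_experiment(
      train, val, window = window, scaling_mode = config$scaling_mode,
      n_components = config$n_components, lag_time = config$lag_time,
      min_samples = config$min_samples, mode = config$kappa_mode,
      transfer = transfer)
  }
  ab <- tx(fleets$a_train, fleets$b_val, config$window, TRUE)
  ba <- tx(fleets$b_train, fleets$a_val, config$window, TRUE)
  ab_full <- tx(fleets$a_train, fleets$b_val, 1:17, TRUE)
  ba_full <- tx(fleets$b_train, fleets$a_val, 1:17, TRUE)
  ab_raw <- tx(fleets$a_train, fleets$b_val, config$window, FALSE)
  ab_full_raw <- tx(fleets$a_train, fleets$b_val, 1:17, FALSE)
  same_clone <- purrr::map_dfr(fleets$a_val,
                               ~ evaluate_model(ab$model, .x))

  val_runs <- c(fleets$b_val, fleets$a_val)
  lr_eval <- function(phase) {
    purrr::map_dfr(val_runs, function(run) {
      al <- spline_align(run)
      m <- fit_linear_baseline(al, calibration_phase = phase)
      dplyr::mutate(evaluate_model(m, run), lr_r_squared = m$r_squared)
    })
  }
  lr_expo <- lr_eval("exponential_only")
  lr_whole <- lr_eval("whole_run")

  ladder <- tibble(
    variant = c("lr_exponential", "lr_whole", "pls_1_17_raw",
                "pls_window_raw", "pls_1_17_kappa", "pls_window_kappa"),
    mean_cvrmse_whole = c(
      mean(lr_expo$cvrmse_whole[seq_along(fleets$b_val)]),
      mean(lr_whole$cvrmse_whole[seq_along(fleets$b_val)]),
      ab_full_raw$summary$mean_cvrmse_whole,
      ab_raw$summary$mean_cvrmse_whole,
      ab_full$summary$mean_cvrmse_whole,
      ab$summary$mean_cvrmse_whole))

  bidir <- dplyr::bind_rows(ab$reports, ba$reports)
  bidir_full <- dplyr::bind_rows(ab_full$reports, ba_full$reports)
  metrics <- list(
    max_whole_cvrmse_transfer = max(ab$reports$cvrmse_whole),
    max_expo_cvrmse_transfer = max(ab$reports$cvrmse_exponential),
    x_variance_pct_3pc = tail(ab$model$x_variance_pct, 1),
    max_whole_cvrmse_bidirectional = max(bidir$cvrmse_whole),
    mean_whole_cvrmse_bidirectional = mean(bidir$cvrmse_whole),
    mean_lr_whole_cvrmse = mean(lr_expo$cvrmse_whole),
    min_lr_exponential_r2 = min(lr_expo$lr_r_squared),
    min_same_clone_r2 = min(same_clone$r_squared),
    mean_kappa_ab = mean(ab$kappas),
    mean_kappa_ba = mean(ba$kappas),
    mean_whole_cvrmse_bidirectional_full = mean(bidir_full$cvrmse_whole),
    window_ablation_delta = mean(bidir_full$cvrmse_whole) -
      mean(bidir$cvrmse_whole))

  structure(
    list(config = config, seed = seed, fleets = fleets,
         reports = list(ab = ab, ba = ba, ab_full = ab_full,
                        ba_full = ba_full, ab_raw = ab_raw,
                        ab_full_raw = ab_full_raw),
         same_clone = same_clone,
         lr_reports = list(exponential = lr_expo, whole = lr_whole),
         ladder = ladder, metrics = metrics),
    class = "capsense_benchmark")
}

#' @export
print.capsense_benchmark <- function(x, ...) {
  cat(sprintf("<capsense_benchmark> seed %d\n", x$seed))
  print(as.data.frame(x$ladder), row.names = FALSE)
  cat("\nkey metrics:\n")
  for (nm in names(x$metrics)) {
    cat(sprintf("  %-32s %8.3f\n", nm, x$metrics[[nm]]))
  }
  invisible(x)
}
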