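clean_pair <- function(ratio, seed, n_each = 1) {
  generate_clone_pair(clone_profile(debris_amplitude = 0),
                      amplitude_ratio = ratio,
                      shared = quick_culture(), n_runs_each = n_each,
                      seed = seed, disturb = near_clean_disturb(),
                      sampling = list(offline_cv = 0.01),
                      param_jitter_cv = 0.02)
}

fit_on <- function(runs, window = 1:10) {
  fit_pls(purrr::map(runs, spline_align), window = window)
}

test_that("self-transfer recovers kappa close to one", {
  fleet <- simulate_fleet(clone_profile(debris_amplitude = 0),
                          quick_culture(), n_runs = 3, seed = 40,
                          disturb = near_clean_disturb(),
                          sampling = list(offline_cv = 0.01),
                          param_jitter_cv = 0.02)
  m <- fit_on(fleet[1:2])
  tm <- estimate_kappa(m, fleet[[3]])
  expect_equal(tm$kappa, 1, tolerance = 0.1)
})

test_that("kappa times the amplitude ratio is one on clean clone pairs", {
  for (case in list(list(ratio = 1 / 0.69, seeds = 1:3),
                    list(ratio = 2, seeds = 4:6))) {
    for (s in case$seeds) {
      pair <- clean_pair(case$ratio, seed = 50 + s, n_each = 2)
      m <- fit_on(pair$base)
      tm <- estimate_kappa(m, pair$other[[1]])
      expect_lt(abs(tm$kappa * case$ratio - 1), 0.05)
    }
  }
})

test_that("transfer demands enough qualifying samples and positive kappa", {
  pair <- clean_pair(1, seed = 61)
  run <- pair$other[[1]]
  truncated <- fermentation_run(run$online, run$offline[1:3, ],
                                run_id = "short")
  # samples at 0, 12, 24 h: only two at or beyond the 6 h lag
  m <- fit_on(pair$base)
  expect_error(estimate_kappa(m, truncated, lag_time = 6, min_samples = 3),
               class = "capsense_insufficient_data")
  # measured VCC falling while the estimate rises gives a pathological
  # (non-positive) slope
  rising <- structure(list(frequency_window = 1L,
                           coefficients = c(fq01 = 1), intercept = 0),
                      class = "pls_vcc")
  flipped <- fermentation_run(
    tibble::tibble(time_h = 0:20, fq01 = seq(10, 50, 2)),
    tibble::tibble(time_h = seq(0, 20, 4),
                   vcc_1e5_per_ml = seq(60, 10, -10)),
    run_id = "flipped")
  expect_error(estimate_kappa(rising, flipped, lag_time = 2),
               class = "capsense_transfer_failure")
})

test_that("feeding samples one-by-one matches the batch estimate", {
  pair <- clean_pair(1 / 0.69, seed = 70)
  m <- fit_on(pair$base)
  run <- pair$other[[1]]
  batch <- estimate_kappa(m, run)
  head_run <- fermentation_run(run$online, run$offline[1:5, ],
                               run_id = run$run_id)
  tm <- estimate_kappa(m, head_run)
  for (i in 6:nrow(run$offline)) {
    tm <- update_kappa_online(tm, run$offline[i, ])
  }
  expect_equal(tm$kappa, batch$kappa, tolerance = 1e-9)
  expect_equal(tm$offset, batch$offset, tolerance = 1e-9)
  # trace: one entry per update, converging toward the true reciprocal
  # (offline count noise allows small non-monotone wiggles)
  expect_equal(nrow(tm$trace), 1 + nrow(run$offline) - 5)
  err <- abs(tm$trace$kappa * (1 / 0.69) - 1)
  expect_lt(err[length(err)], err[1] + 0.02)
  expect_lt(err[length(err)], 0.05)
})

test_that("online updates reject out-of-order (hence pre-lag) samples", {
  pair <- clean_pair(1, seed = 71)
  m <- fit_on(pair$base)
  run <- pair$other[[1]]
  tm <- estimate_kappa(m, run)
  # a sample before the lag time is always behind the qualifying
  # samples already used, so both guards reject it
  expect_error(update_kappa_online(tm, list(time_h = 1, vcc_1e5_per_ml = 5)),
               class = "capsense_argument_error")
  expect_error(update_kappa_online(tm, list(time_h = max(tm$samples$time_h),
                                            vcc_1e5_per_ml = 5)),
               class = "capsense_argument_error")
})

test_that("transferred prediction is the affine map of the base estimate", {
  pair <- clean_pair(1, seed = 72)
  m <- fit_on(pair$base)
  run <- pair$other[[1]]
  base_pred <- predict_vcc(m, run)$vcc_est
  tm <- estimate_kappa(m, run)
  tm$kappa <- 1; tm$offset <- 0
  expect_equal(predict_transferred(tm, run)$vcc_est, base_pred)
  tm$kappa <- 0.5; tm$offset <- 2
  expect_equal(predict_transferred(tm, run)$vcc_est, 0.5 * base_pred + 2)
  # correlation with ground truth is invariant under the affine transfer
  expect_equal(cor(run$truth$vcc_true, 0.5 * base_pred + 2),
               cor(run$truth$vcc_true, base_pred), tolerance = 1e-12)
})

test_that("transfers compose: A-to-B and B-to-A kappas are reciprocal", {
  pair <- clean_pair(1 / 0.69, seed = 73, n_each = 2)
  m_a <- fit_on(pair$base)
  m_b <- fit_on(pair$other)
  k_ab <- estimate_kappa(m_a, pair$other[[2]])$kappa
  k_ba <- estimate_kappa(m_b, pair$base[[2]])$kappa
  expect_equal(k_ab * k_ba, 1, tolerance = 0.1)
})

test_that("offset-anchored mode pins the intercept at inoculation", {
  pair <- clean_pair(1 / 0.69, seed = 74)
  m <- fit_on(pair$base)
  run <- pair$other[[1]]
  tm <- estimate_kappa(m, run, mode = "offset_anchored")
  x0 <- tm$anchor$x_hat
  y0 <- tm$anchor$y
  expect_equal(tm$kappa * x0 + tm$offset, y0, tolerance = 1e-9)
  expect_lt(abs(tm$kappa * (1 / 0.69) - 1), 0.1)
})

test_that("transferred models serialize with their kappa trace", {
  pair <- clean_pair(1 / 0.69, seed = 75)
  m <- fit_on(pair$base)
  tm <- estimate_kappa(m, pair$other[[1]])
  path <- withr::local_tempfile(fileext = ".json")
  write_model(tm, path)
  back <- read_model(path)
  expect_identical(back$kappa, tm$kappa)
  expect_identical(back$offset, tm$offset)
  expect_identical(back$base$coefficients, tm$base$coefficients)
  run <- pair$other[[1]]
  expect_identical(predict_vcc(back, run), predict_vcc(tm, run))
})
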