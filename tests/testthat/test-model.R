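test_that("an exactly linear response is recovered with full components", {
  inst <- random_aligned(40, 3, seed = 101, noise_sd = 0)
  m <- fit_pls(inst$data, window = 1:3, n_components = 3)
  expect_equal(unname(m$coefficients), inst$beta, tolerance = 1e-8)
  expect_equal(m$r_squared_train, 1, tolerance = 1e-10)
})

test_that("SIMPLS at full rank equals least squares on 100 random instances", {
  for (i in 1:100) {
    inst <- random_aligned(20, 4, seed = 1000 + i)
    m <- fit_pls(inst$data, window = 1:4, n_components = 4)
    Xc <- scale(inst$X, scale = FALSE)
    beta_ols <- ols_coefficients(Xc, inst$y - mean(inst$y))
    pred_pls <- predict_vcc(m, inst$data)$vcc_est
    pred_ols <- drop(Xc %*% beta_ols) + mean(inst$y)
    expect_equal(pred_pls, pred_ols, tolerance = 1e-8)
  }
})

test_that("SIMPLS agrees with an independent NIPALS implementation", {
  for (i in 1:40) {
    inst <- random_aligned(30, 6, seed = 2000 + i)
    ncomp <- 1 + (i %% 4)
    m <- fit_pls(inst$data, window = 1:6, n_components = ncomp)
    Xc <- scale(inst$X, scale = FALSE)
    beta_nip <- nipals_coefficients(Xc, inst$y - mean(inst$y), ncomp)
    pred_nip <- drop(Xc %*% beta_nip) + mean(inst$y)
    pred_pls <- predict_vcc(m, inst$data)$vcc_est
    expect_equal(pred_pls, pred_nip, tolerance = 1e-6)
  }
})

test_that("training error is non-increasing in the component count", {
  inst <- random_aligned(50, 6, seed = 77, noise_sd = 0.5)
  errs <- purrr::map_dbl(1:6, function(a) {
    m <- fit_pls(inst$data, window = 1:6, n_components = a)
    rmse(inst$y, predict_vcc(m, inst$data)$vcc_est)
  })
  expect_true(all(diff(errs) <= 1e-10))
})

test_that("raw-unit coefficients equal scaling-then-predicting in scaled space", {
  inst <- random_aligned(30, 5, seed = 55)
  for (mode in c("mean_center", "standardize")) {
    m <- fit_pls(inst$data, window = 1:5, scaling_mode = mode,
                 n_components = 3)
    Xs <- apply_scaling(inst$X, m$scaling)
    coef_scaled <- m$coefficients * m$scaling$sd
    pred_scaled <- drop(Xs %*% coef_scaled) + mean(inst$y)
    expect_equal(predict_vcc(m, inst$data)$vcc_est, pred_scaled,
                 tolerance = 1e-9)
  }
})

test_that("component count follows the window-size convention", {
  inst <- random_aligned(30, 5, seed = 66)
  expect_equal(fit_pls(inst$data, window = 1:5)$n_components, 3L)
  expect_equal(fit_pls(inst$data, window = 1:2)$n_components, 2L)
  expect_equal(fit_pls(inst$data, window = 1)$n_components, 1L)
  expect_error(fit_pls(inst$data, window = 1:3, n_components = 4),
               class = "capsense_argument_error")
  # rank-deficient X cannot support the requested components
  dup <- inst$data
  dup$fq02 <- dup$fq01
  dup$fq03 <- dup$fq01
  expect_error(fit_pls(dup, window = 1:3, n_components = 3),
               class = "capsense_rank_error")
})

test_that("prediction is the plain linear form in capacitance units", {
  m <- structure(list(frequency_window = 1L,
                      coefficients = c(fq01 = -1.5),
                      intercept = 200),
                 class = "pls_vcc")
  expect_equal(predict_vcc(m, tibble::tibble(fq01 = 100))$vcc_est, 50)
  m0 <- structure(list(frequency_window = 1:2,
                       coefficients = c(fq01 = 0, fq02 = 0),
                       intercept = 7),
                  class = "pls_vcc")
  expect_equal(predict_vcc(m0, tibble::tibble(fq01 = 1:3, fq02 = 4:6))$vcc_est,
               rep(7, 3))
  expect_error(predict_vcc(m, tibble::tibble(fq02 = 1)),
               class = "capsense_schema_error")
})

test_that("models serialize to JSON and restore exactly", {
  inst <- random_aligned(30, 5, seed = 88)
  m <- fit_pls(inst$data, window = 1:5, scaling_mode = "standardize")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_identical(back$coefficients, m$coefficients)
  expect_identical(back$intercept, m$intercept)
  expect_identical(back$scaling$mean, m$scaling$mean)
  expect_identical(predict_vcc(back, inst$data), predict_vcc(m, inst$data))
  expect_error(read_model("/nonexistent.json"),
               class = "capsense_format_error")
})

test_that("tidy and glance expose terms and fit statistics", {
  inst <- random_aligned(30, 5, seed = 99)
  m <- fit_pls(inst$data, window = 1:5)
  td <- tidy(m)
  expect_equal(td$term, c(sprintf("fq%02d", 1:5), "(Intercept)"))
  expect_equal(td$estimate, c(unname(m$coefficients), m$intercept))
  gl <- glance(m)
  expect_equal(gl$n_components, 3L)
  expect_equal(gl$nobs, 30L)
})

test_that("dual-mode baseline recovers an exact linear relation", {
  u <- seq(0, 10, length.out = 20)
  dat <- tibble::tibble(time_h = seq_len(20), vcc = 2 * u + 1,
                        fq06 = u + 5, fq17 = 5)
  names(dat) <- c("time_h", "vcc", "fq06", "fq17")
  m <- fit_linear_baseline(dat, calibration_phase = "whole_run")
  expect_equal(m$working_frequency, 6L)
  expect_equal(m$reference_frequency, 17L)
  expect_equal(m$slope, 2, tolerance = 1e-10)
  expect_equal(m$intercept, 1, tolerance = 1e-8)
  cst <- tibble::tibble(time_h = 1:5, vcc = 1:5, fq06 = 1, fq17 = 1)
  expect_error(fit_linear_baseline(cst, calibration_phase = "whole_run"),
               class = "capsense_degenerate_column")
})

test_that("dual-mode baseline excels in the exponential phase but
           overestimates a debris-heavy decline", {
  clean <- quick_clean_run(seed = 14)
  m <- fit_linear_baseline(spline_align(clean))
  expect_gte(m$r_squared, 0.99)
  run <- simulate_run(clone_profile(debris_amplitude = 0.3),
                      quick_culture(), disturbance_none(),
                      sampling = list(offline_cv = 0), seed = 14)
  lr <- fit_linear_baseline(spline_align(run))
  pts <- capsense:::predict_at_offline(lr, run)
  peak_t <- run$offline$time_h[which.max(run$offline$vcc_1e5_per_ml)]
  late <- pts$time_h > peak_t
  expect_true(all(pts$x_hat[late] > pts$y[late]))
})
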