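test_that("identical seeds give bit-identical runs, different seeds differ", {
  r1 <- simulate_run(seed = 11, culture = quick_culture())
  r2 <- simulate_run(seed = 11, culture = quick_culture())
  r3 <- simulate_run(seed = 12, culture = quick_culture())
  expect_identical(r1$online, r2$online)
  expect_identical(r1$offline, r2$offline)
  expect_identical(r1$truth, r2$truth)
  expect_false(identical(r1$online, r3$online))
})

test_that("clean spectra are exact scalar multiples of ground-truth VCC", {
  clone <- clone_profile(debris_amplitude = 0)
  run <- simulate_run(clone, quick_culture(), disturbance_none(),
                      sampling = list(offline_cv = 0), seed = 3)
  v <- run$truth$vcc_true
  expect_equal(cor(run$online$fq01, v), 1, tolerance = 1e-12)
  # channel ratios equal the dispersion-response ratios in closed form
  g <- make_frequency_grid()
  resp <- dispersion_response(g, clone$critical_frequency_cells,
                              clone$cole_cole_alpha)
  for (j in c(2, 7, 17)) {
    expect_equal(run$online[[sprintf("fq%02d", j)]] / run$online$fq01,
                 rep(resp[j] / resp[1], length(v)), tolerance = 1e-9)
  }
})

test_that("culture dynamics rise, decline and conserve biomass", {
  culture <- quick_culture()
  run <- simulate_run(clone_profile(), culture, disturbance_none(),
                      sampling = list(offline_cv = 0), seed = 5)
  v <- run$truth$vcc_true
  peak <- which.max(v)
  expect_gt(peak, 1)
  expect_lt(peak, length(v))
  expect_lt(v[length(v)], 0.8 * v[peak])
  # offline TCC equals viable + dead exactly when counts are noise-free,
  # so TCC >= VCC and viability is consistent
  off <- run$offline
  expect_true(all(off$tcc_1e5_per_ml >= off$vcc_1e5_per_ml - 1e-9))
  expect_equal(off$viability_pct,
               pmin(100, off$vcc_1e5_per_ml / off$tcc_1e5_per_ml * 100))
  # conservation: d(V + D + B)/dt is the logistic growth term alone
  states <- capsense:::solve_culture(culture, disturbance_none(),
                                     seq(0, culture$duration, 0.5))
  total <- rowSums(states)
  growth <- culture$mu_max * states[, "v"] * (1 - total / culture$capacity)
  dt_total <- diff(total) / 0.5
  expect_equal(dt_total, (growth[-1] + growth[-length(growth)]) / 2,
               tolerance = 1e-3)
  expect_true(all(diff(states[, "b"]) >= -1e-9))
})

test_that("debris dominates the top channel late in the run", {
  clone_hi <- clone_profile(debris_amplitude = 0.3)
  clone_lo <- clone_profile(debris_amplitude = 0.05)
  run_hi <- simulate_run(clone_hi, quick_culture(), disturbance_none(),
                         sampling = list(offline_cv = 0), seed = 8)
  run_lo <- simulate_run(clone_lo, quick_culture(), disturbance_none(),
                         sampling = list(offline_cv = 0), seed = 8)
  n <- nrow(run_hi$online)
  # increasing debris amplitude raises end-of-run FQ17 and leaves the
  # ground truth untouched
  expect_gt(run_hi$online$fq17[n], run_lo$online$fq17[n])
  expect_identical(run_hi$truth, run_lo$truth)
  # late divergence: normalized FQ17 stays high after normalized VCC fell
  norm <- function(x) x / max(x)
  expect_gt(norm(run_hi$online$fq17)[n], norm(run_hi$truth$vcc_true)[n])
})

test_that("sampling grids have the expected density and are validated", {
  run <- simulate_run(culture = culture_params(), seed = 2)
  expect_equal(nrow(run$online), 673)
  expect_equal(nrow(run$offline), 29)
  expect_error(simulate_run(sampling = list(online_interval = 2,
                                            offline_interval = 1)),
               class = "capsense_argument_error")
})

test_that("clone pairs differ only by the per-cell amplitude", {
  pair <- generate_clone_pair(clone_profile(debris_amplitude = 0),
                              amplitude_ratio = 1 / 0.69,
                              shared = quick_culture(), n_runs_each = 2,
                              seed = 21, disturb = disturbance_none(),
                              param_jitter_cv = 0)
  # with jitter off and no noise, spectra scale exactly by the ratio
  # for matched seeds' ground truth
  m_base <- mean(purrr::map_dbl(pair$base, ~ max(.x$online$fq01) /
                                  max(.x$truth$vcc_true)))
  m_other <- mean(purrr::map_dbl(pair$other, ~ max(.x$online$fq01) /
                                   max(.x$truth$vcc_true)))
  expect_equal(m_other / m_base, 1 / 0.69, tolerance = 1e-6)
  empty <- generate_clone_pair(n_runs_each = 0, seed = 1)
  expect_length(empty$base, 0)
  expect_length(empty$other, 0)
  expect_error(generate_clone_pair(amplitude_ratio = 0),
               class = "capsense_argument_error")
})
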