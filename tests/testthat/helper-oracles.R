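# Independent reference implementations used only as test oracles.

# Ordinary least squares via the normal equations.
ols_coefficients <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# Classical NIPALS PLS1 with X-deflation; returns regression
# coefficients in the (already scaled/centered) input space.
nipals_coefficients <- function(X, y, ncomp) {
  E <- X; f <- y
  p <- ncol(X)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    w <- w / sqrt(sum(w^2))
    t_ <- drop(E %*% w)
    tt <- sum(t_^2)
    p_ <- drop(crossprod(E, t_)) / tt
    q[a] <- sum(f * t_) / tt
    E <- E - tcrossprod(t_, p_)
    f <- f - q[a] * t_
    W[, a] <- w; P[, a] <- p_
  }
  drop(W %*% solve(crossprod(P, W), q))
}

# Random regression instance on the aligned-table layout.
random_aligned <- function(n, p, seed, noise_sd = 0.1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    beta <- rnorm(p)
    y <- drop(X %*% beta) + rnorm(n, sd = noise_sd)
    out <- tibble::tibble(time_h = seq_len(n), vcc = y)
    out[sprintf("fq%02d", seq_len(p))] <- as.data.frame(X)
    list(data = out, X = X, y = y, beta = beta)
  })
}

# Clean transfer scenario: no debris interference or disturbances,
# just a whiff of spectral measurement noise so the spectra have full
# column rank (noise-free channels are exact multiples of VCC).
near_clean_disturb <- function(noise_cv = 0.005) {
  disturbance_spec(bolus_times = numeric(), bolus_fractions = numeric(),
                   bubble_burst_times = numeric(), bubble_depth = numeric(),
                   bubble_width = numeric(), drift_rate = 0,
                   noise_cv = noise_cv, noise_floor = 0, debris_fc_cv = 0)
}

# Short fed-batch for fast unit tests (still rises and declines).
quick_culture <- function(...) {
  culture_params(duration = 168, death_onset = 96, ...)
}

quick_clean_run <- function(seed = 1, clone = clone_profile(),
                            culture = quick_culture(), offline_cv = 0) {
  simulate_run(clone, culture, disturbance_none(),
               sampling = list(offline_cv = offline_cv), seed = seed)
}
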