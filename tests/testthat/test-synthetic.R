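test_that("decay-trace generator is exact at sigma = 0 and seeded", {
  n0 <- 4.2e16; alpha <- 2.3e-11
  cfg0 <- synthetic_config(seed = 3, sigma = 0)
  tr <- make_decay_trace(n0, alpha, cfg0)
  # after the 100 ns rise the trace equals the analytic curve exactly
  post <- tr$times >= 1e-7
  expect_equal(tr$signal[post],
               analytic_decay(n0, alpha, tr$times[post] - 1e-7))
  # linear rise to the peak
  expect_equal(tr$signal[tr$times < 1e-7],
               n0 * tr$times[tr$times < 1e-7] / 1e-7)
  # ground truth embedded
  expect_equal(tr$metadata$ground_truth$n0, n0)
  expect_equal(tr$metadata$ground_truth$tau,
               predicted_lifetime(n0, alpha))
  # same seed -> identical; different seed -> different
  cfg <- synthetic_config(seed = 11, sigma = 0.05)
  expect_identical(make_decay_trace(n0, alpha, cfg)$signal,
                   make_decay_trace(n0, alpha, cfg)$signal)
  cfg2 <- synthetic_config(seed = 12, sigma = 0.05)
  expect_false(identical(make_decay_trace(n0, alpha, cfg)$signal,
                         make_decay_trace(n0, alpha, cfg2)$signal))
})

test_that("generator/estimator roundtrip recovers the lifetime", {
  n0 <- 4.2e16; alpha <- 2.3e-11
  tr <- make_decay_trace(n0, alpha, synthetic_config(seed = 1, sigma = 0))
  res <- fit_lifetime(tr, "hyperbolic_fit")
  tau_true <- predicted_lifetime(n0, alpha)
  expect_lt(abs(res$tau - tau_true) / tau_true, 1e-3)
})

test_that("pulse trains decay quadratically between seeded deposits", {
  alpha <- 2.3e-11; f <- 35000
  # single pulse reduces to a plain decay with no rise ramp
  cfg <- synthetic_config(seed = 5, sigma = 0, sampling_interval = 2e-8)
  tr1 <- make_pulse_train(4.2e16, alpha, f, n_pulses = 1, cfg)
  expect_equal(tr1$signal, analytic_decay(4.2e16, alpha, tr1$times))
  expect_equal(tr1$metadata$pulse_onsets, 0)
  # well-separated pulses: pre-pulse residual < 2% of the per-pulse yield
  n0 <- 1e17
  tr3 <- make_pulse_train(n0, alpha, f, n_pulses = 3, cfg)
  onset2 <- tr3$metadata$pulse_onsets[2]
  pre2 <- max(tr3$signal[tr3$times < onset2 - 1e-9][
    sum(tr3$times < onset2 - 1e-9)])
  expect_lt(analytic_decay(n0, alpha, 1 / f) / n0, 0.02)
  expect_lt(pre2 / n0, 0.03)
  # time-averaged density matches the duty-cycle closed form
  Tp <- 1 / f
  mean_pred <- log(1 + alpha * 4.2e16 * Tp) / (alpha * Tp)
  expect_equal(mean(tr1$signal), mean_pred, tolerance = 0.02)
})

test_that("depth datasets invert back to their ground truth", {
  mu <- log(4.2 / 0.8) / 0.4        # through 4.2e16 at 2 mm, 0.8e16 at 6 mm
  G0 <- 4.2e16 * exp(mu * 0.2)
  cfg0 <- synthetic_config(seed = 2, sigma = 0)
  ds <- make_depth_dataset(G0, mu, depths_mm = c(2, 4, 6), cfg = cfg0)
  # the 4 mm value is the geometric mean of the 2 and 6 mm values
  expect_equal(ds$truth$density_cm3[2], sqrt(4.2e16 * 0.8e16),
               tolerance = 1e-6)
  # noiseless Beer-Lambert inversion reproduces the truth exactly
  inv <- vapply(seq_len(nrow(ds$measurements)), function(i) {
    m <- ds$measurements[i, ]
    density_from_absorption(absorption_measurement(
      m$I0, m$IV, m$path_cm, m$sigma_cm2))
  }, numeric(1))
  expect_equal(inv, ds$truth$density_cm3, tolerance = 1e-12)
  # mu = 0 collapses all depths onto G0
  flat <- make_depth_dataset(1e16, 0, depths_mm = 1:5, cfg = cfg0)
  expect_equal(flat$truth$density_cm3, rep(1e16, 5))
})

test_that("pH current series is linear in hydroxide density", {
  cfg0 <- synthetic_config(seed = 4, sigma = 0)
  s <- make_ph_current_series(c(5, 7, 9), cfg = cfg0)
  # [OH-] ratios 1e-9 : 1e-7 : 1e-5 M -> currents 1 : 100 : 10000
  expect_equal(s$current_A / s$current_A[1], c(1, 100, 10000),
               tolerance = 1e-9)
  # strictly increasing in pH at sigma = 0
  s2 <- make_ph_current_series(seq(3, 11, by = 1), cfg = cfg0)
  expect_true(all(diff(s2$current_A) > 0))
  # seeded determinism
  cfgn <- synthetic_config(seed = 9, sigma = 0.05)
  expect_identical(make_ph_current_series(c(5, 7, 9), cfg = cfgn),
                   make_ph_current_series(c(5, 7, 9), cfg = cfgn))
})

test_that("derived seeds are deterministic, label-separated and 31-bit", {
  expect_identical(derive_seed(1, "decay_trace"), derive_seed(1, "decay_trace"))
  expect_false(derive_seed(1, "decay_trace") == derive_seed(1, "pulse_train"))
  expect_false(derive_seed(1, "decay_trace") == derive_seed(2, "decay_trace"))
  for (s in c(1, 1000, 2^31 - 2))
    expect_lt(derive_seed(s, "x"), 2^31)
})
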