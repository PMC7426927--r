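test_that("envelope of a pure sinusoid equals its amplitude away from edges", {
  fs <- 200
  t <- (seq_len(30 * fs) - 1) / fs
  env <- instantaneous_amplitude(3 * cos(2 * pi * 10 * t), edge_samples = fs)
  interior <- !attr(env, "edge")
  expect_lt(max(abs(env[interior] - 3)) / 3, 0.01)
  expect_equal(as.numeric(instantaneous_amplitude(numeric(1000))), rep(0, 1000))
})

test_that("envelope recovers an amplitude-modulated carrier's modulator", {
  fs <- 200
  t <- (seq_len(30 * fs) - 1) / fs
  mod <- 1 + 0.5 * cos(2 * pi * 1 * t)
  env <- instantaneous_amplitude(mod * cos(2 * pi * 10 * t), edge_samples = fs)
  interior <- !attr(env, "edge")
  rmse <- sqrt(mean((env[interior] - mod[interior])^2))
  expect_lt(rmse / mean(mod), 0.02)
})

test_that("coupling correlation satisfies the exact linear identities", {
  slow <- mk_slow(amp = 1)
  expect_lt(abs(cfc_correlation(slow, 5 + 2 * slow) - 1), 1e-9)
  expect_lt(abs(cfc_correlation(slow, 5 - 2 * slow) + 1), 1e-9)
  t <- (seq_along(slow) - 1) / 200
  expect_lt(abs(cfc_correlation(cos(2 * pi * t), 5 + sin(2 * pi * t))), 1e-9)
})

test_that("coupling correlation is scale-invariant and antisymmetric", {
  set.seed(31)
  slow <- mk_slow(amp = 40)
  env <- 10 + 0.3 * slow + rnorm(length(slow))
  r0 <- cfc_correlation(slow, env)
  expect_lt(abs(cfc_correlation(slow * 7.3, env) - r0), 1e-12)
  expect_lt(abs(cfc_correlation(slow, env * 0.002) - r0), 1e-12)
  # negating the envelope fluctuation flips the sign exactly
  flipped <- mean(env) - (env - mean(env))
  expect_equal(cfc_correlation(slow, flipped), -r0)
})

test_that("zero-variance inputs give an explicit undefined result", {
  slow <- mk_slow()
  expect_warning(r <- cfc_correlation(slow, rep(4, length(slow))), "undefined")
  expect_true(is.na(r))
  expect_warning(cfc_correlation(numeric(100), rnorm(100)), "undefined")
  expect_error(cfc_correlation(slow, rnorm(10)), "equal length")
})

test_that("noisy-envelope correlation matches its closed-form expectation", {
  # env = c + k*slow + noise(sd sigma): E[r] ~ k*sd_V / sqrt(k^2 sd_V^2 + sigma^2)
  slow <- mk_slow(amp = 2)
  k <- 0.5; sigma <- 1.5
  sd_V <- sqrt(mean(slow^2))
  expected <- k * sd_V / sqrt(k^2 * sd_V^2 + sigma^2)
  rs <- vapply(1:200, function(s) {
    env <- 10 + k * slow + with_seed_local(500 + s, rnorm(length(slow), sd = sigma))
    oracle_corr(slow, env)  # brute-force oracle
  }, numeric(1))
  expect_lt(abs(mean(rs) - expected), 2 * sd(rs) / sqrt(length(rs)))
  # implementation agrees with the oracle draw by draw
  env1 <- 10 + k * slow + with_seed_local(501, rnorm(length(slow), sd = sigma))
  expect_equal(cfc_correlation(slow, env1), oracle_corr(slow, env1),
               tolerance = 1e-14)
})

test_that("stacking concatenates rather than averages correlations", {
  set.seed(77)
  slow1 <- mk_slow(amp = 5); slow2 <- mk_slow(amp = 60)
  p1 <- list(slow = slow1, env = 3 + 0.4 * slow1 + rnorm(length(slow1), sd = 2))
  p2 <- list(slow = slow2, env = 8 - 0.1 * slow2 + rnorm(length(slow2), sd = 2))
  p3 <- list(slow = slow1, env = 5 + 0.05 * slow1 + rnorm(length(slow1), sd = 6))
  pairs <- list(p1, p2, p3)
  r_stack <- stacked_correlation(pairs)
  expect_equal(r_stack, oracle_stacked(pairs), tolerance = 1e-14)
  mean_of_r <- mean(vapply(pairs, function(p) oracle_corr(p$slow, p$env),
                           numeric(1)))
  # heteroscedastic segments: the two summaries genuinely differ
  expect_gt(abs(r_stack - mean_of_r), 0.05)
  # duplication invariance
  expect_equal(stacked_correlation(list(p1, p1)), stacked_correlation(list(p1)),
               tolerance = 1e-14)
  # antisymmetric construction cancels to zero
  m <- mean(p1$env)
  p1_flip <- list(slow = p1$slow, env = m - (p1$env - m))
  expect_lt(abs(stacked_correlation(list(p1, p1_flip))), 1e-12)
  expect_error(stacked_correlation(list()), "empty")
})

test_that("mean vector matches its analytic values", {
  fs <- 200
  phi <- Arg(exp(1i * 2 * pi * 1 * (seq_len(30 * fs) - 1) / fs))  # whole cycles
  mv0 <- mean_vector(rep(2, length(phi)), phi)
  expect_lt(attr(mv0, "magnitude"), 1e-6 * 2)
  mv1 <- mean_vector(1 + cos(phi), phi)
  expect_lt(Mod(unclass(mv1) - 0.5), 1e-3)
  expect_lt(abs(attr(mv1, "preferred_phase")), 1e-3)
  mv2 <- mean_vector(1 - cos(phi), phi)
  expect_lt(Mod(unclass(mv2) + 0.5), 1e-3)
  expect_lt(abs(abs(attr(mv2, "preferred_phase")) - pi), 1e-3)
  expect_error(mean_vector(1:5, 1:4), "equal length")
})

test_that("envelopes concentrate at the slow-wave peak or trough", {
  # on modulated synthetic components the preferred phase sits near 0
  # (peakmax) or pi (troughmax) in >= 90% of epochs; measured with a
  # sinusoidal slow wave, where instantaneous phase is well defined --
  # waveform skew biases phase estimates (the reason the coupling metric
  # correlates against the voltage rather than the phase)
  cfg <- synthetic_config(n_channels = 1,
                          level_schedule = data.frame(label = "A",
                                                      duration_s = 300, dose = 1),
                          slow_amplitude_uV = 50, waveform_skew = 0,
                          coupling_plan = list(list(channels = 1, level = "A",
                                                    band = c(8, 10), depth = 0.7)),
                          broadband_noise_sd_uV = 2, sensor_noise_sd_uV = 0.5,
                          seed = 91)
  out <- generate_session(cfg)
  x <- out$recording$data[1, ]
  fs <- 200
  slow <- zero_phase_bandpass(x, fs, band_spec(0.1, 4, 0.5))
  env <- Mod(slowmod:::band_analytic(x, fs, band_spec(8, 10, 1)))
  phi <- slow_phase(slow)
  span <- filter_half_span(band_spec(0.1, 4, 0.5), fs)
  ok <- 0L
  starts <- seq(span + 1, length(x) - span - 30 * fs, by = 30 * fs)
  for (s0 in starts) {
    idx <- s0:(s0 + 30 * fs - 1)
    mv <- mean_vector(env[idx], phi[idx])
    ph <- attr(mv, "preferred_phase")
    if (min(abs(ph), abs(abs(ph) - pi)) <= pi / 8) ok <- ok + 1L
  }
  expect_gte(ok / length(starts), 0.9)
})

test_that("coupling sign is robust to slow-wave shape", {
  # fixed depth, skew in {0, 0.25, 0.5}: the recovered sign never changes
  signs <- matrix(NA_real_, 20, 3)
  for (s in 1:20) {
    for (k in 1:3) {
      skew <- c(0, 0.25, 0.5)[k]
      cfg <- synthetic_config(n_channels = 1,
                              level_schedule = data.frame(label = "A",
                                                          duration_s = 60,
                                                          dose = 1),
                              slow_amplitude_uV = 50, waveform_skew = skew,
                              seed = 600 + s)
      slow <- generate_slow_wave(cfg, 1, "A")
      comp <- generate_modulated_component(slow, c(8, 10), -0.6, 2,
                                           seed = 700 + s)
      env <- Mod(slowmod:::band_analytic(comp, 200, band_spec(8, 10, 1)))
      signs[s, k] <- sign(cfc_correlation(slow, env))
    }
  }
  expect_true(all(signs == -1))
})

test_that("modulogram entries agree with direct correlation", {
  cfg <- synthetic_config(n_channels = 2,
                          level_schedule = data.frame(label = "A",
                                                      duration_s = 180, dose = 1),
                          coupling_plan = list(list(channels = 1:2, level = "A",
                                                    band = c(4, 50), depth = 0.6)),
                          seed = 14)
  out <- generate_session(cfg)
  rec <- out$recording
  bank <- design_filter_bank()
  mg <- compute_modulogram(rec, bank, locations = 1, window_s = 30)
  expect_s3_class(mg, "modulogram")
  expect_true(all(mg >= -1 & mg <= 1, na.rm = TRUE))
  # single-location window equals cfc_correlation on that window
  fs <- rec$sample_rate_hz
  x <- rec$data[1, ]
  slow <- zero_phase_bandpass(x, fs, bank$slow_band)
  b <- bank$high_bands[[5]]
  env <- Mod(slowmod:::band_analytic(x, fs, b))
  w <- 3  # interior window, no edge clamping
  idx <- (2 * 30 * fs + 1):(3 * 30 * fs)
  expect_equal(mg[5, w], cfc_correlation(slow[idx], env[idx]), tolerance = 1e-12)
  # broadband peakmax level: nearly all cells positive
  expect_gt(mean(mg > 0), 0.9)
})

test_that("masked windows are flagged missing in the modulogram", {
  mask <- matrix(FALSE, 1, 180 * 200)
  mask[1, (35 * 200):(40 * 200)] <- TRUE
  cfg <- synthetic_config(n_channels = 1,
                          level_schedule = data.frame(label = "A",
                                                      duration_s = 180, dose = 0),
                          seed = 15)
  out <- generate_session(cfg)
  rec <- out$recording
  rec$artifact_mask <- mask
  mg <- compute_modulogram(rec, design_filter_bank(), window_s = 30)
  expect_true(all(is.na(mg[, 2])))   # window covering 30-60 s
  expect_false(anyNA(mg[, 3]))
})

test_that("null coupling stays inside the derived null band", {
  cfg <- synthetic_preset("null", n_channels = 2, level_duration_s = 120,
                          seed = 44)
  out <- generate_session(cfg)
  rec <- out$recording
  bank <- design_filter_bank()
  fs <- rec$sample_rate_hz
  x <- rec$data[1, ]
  slow <- zero_phase_bandpass(x, fs, bank$slow_band)
  mg <- compute_modulogram(rec, bank, locations = 1, window_s = 30)
  env <- Mod(slowmod:::band_analytic(x, fs, bank$high_bands[[10]]))
  thr <- 2 * null_r_sd(slow[1:(30 * fs)], env[1:(30 * fs)], fs = fs)
  expect_gte(mean(abs(mg) < thr, na.rm = TRUE), 0.9)
})
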