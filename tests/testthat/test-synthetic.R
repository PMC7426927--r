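cfg_plain <- function(amp = 50) {
  synthetic_config(n_channels = 1,
                   level_schedule = data.frame(label = "A", duration_s = 30,
                                               dose = 0),
                   slow_amplitude_uV = amp, slow_jitter = 0,
                   waveform_skew = 0, seed = 11)
}

test_that("unskewed slow wave is a pure zero-mean sinusoid", {
  cfg <- cfg_plain()
  s <- generate_slow_wave(cfg, 1, "A")
  expect_length(s, 30 * 200)
  expect_lt(abs(diff(range(s)) - 100) / 100, 0.01)   # peak-to-peak 100 uV
  expect_lt(abs(mean(s)), 1e-9)
  # matches a sinusoid exactly
  t <- (seq_along(s) - 1) / 200
  expect_equal(s, 50 * sin(2 * pi * 1 * t) - mean(50 * sin(2 * pi * t)),
               tolerance = 1e-12)
})

test_that("skewed slow wave keeps zero mean and stays in the slow band", {
  cfg <- synthetic_config(n_channels = 1,
                          level_schedule = data.frame(label = "A",
                                                      duration_s = 60, dose = 0),
                          slow_amplitude_uV = 50, waveform_skew = 0.5, seed = 4)
  s <- generate_slow_wave(cfg, 1, "A")
  expect_lt(abs(mean(s)), 1e-9)
  expect_lt(power_fraction_above(s, 200, 4), 0.01)
})

test_that("degenerate and invalid slow-wave inputs behave", {
  cfg <- cfg_plain(amp = 0)
  expect_equal(generate_slow_wave(cfg, 1, "A"), rep(0, 6000))
  expect_error(generate_slow_wave(cfg, 1, "Nope"), "Nope")
})

test_that("modulated component couples its envelope with the planned sign", {
  slow <- mk_slow(dur = 60)
  for (depth in c(0.8, -0.8)) {
    comp <- generate_modulated_component(slow, c(8, 16), depth, base_sd = 2,
                                         seed = 21, fs = 200)
    env <- instantaneous_amplitude(comp)
    r <- cfc_correlation(slow, as.numeric(env))
    expect_equal(sign(r), sign(depth))
    expect_gt(abs(r), 0.3)
  }
  expect_error(generate_modulated_component(slow, c(8, 16), 1.2, 2, 1),
               "negative")
})

test_that("unmodulated components show no systematic coupling", {
  slow <- mk_slow(dur = 30)
  rs <- vapply(1:100, function(s) {
    comp <- generate_modulated_component(slow, c(8, 16), 0, 2, seed = 1000 + s)
    cfc_correlation(slow, as.numeric(instantaneous_amplitude(comp)))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 2 * sd(rs) / sqrt(length(rs)))
})

test_that("planned coupling signs are recovered from single components", {
  # |depth| = 0.5, sensor noise at half the component scale, 300 s
  slow <- mk_slow(dur = 300)
  hits <- 0L
  for (s in 1:100) {
    comp <- generate_modulated_component(slow, c(8, 10), 0.5, 2, seed = 2000 + s)
    x <- comp + with_seed_local(3000 + s, rnorm(length(comp), sd = 1))
    env <- Mod(slowmod:::band_analytic(x, 200, band_spec(8, 10, 1)))
    if (sign(cfc_correlation(slow, env)) > 0) hits <- hits + 1L
  }
  expect_gte(hits, 95)
})

test_that("sessions are deterministic and bookkeep their ground truth", {
  cfg <- synthetic_preset("propofol", n_channels = 8, level_duration_s = 30,
                          seed = 5)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$map, b$truth$map)

  tm <- a$truth$map
  grp <- a$truth$groups
  # posterior channels: broadband peakmax at UncLow only
  post <- tm[tm$channel %in% grp$posterior & tm$level == "UncLow", ]
  expect_true(all(post$sign == 1))
  base <- tm[tm$level == "Baseline", ]
  expect_true(all(base$sign == 0))
  # frontal alpha troughmax at Sedation lives in the band containing 11 Hz
  fr <- tm[tm$channel %in% grp$frontal & tm$level == "Sedation", ]
  expect_true(all(fr$sign[fr$band_low == 10] == -1))
  expect_true(all(fr$sign[fr$band_low != 10] == 0))
  # UncHigh: everything positive across all channels/bands
  uh <- tm[tm$level == "UncHigh", ]
  expect_true(all(uh$sign == 1))
})

test_that("a single channel with an empty plan has an all-zero truth map", {
  cfg <- synthetic_config(n_channels = 1,
                          level_schedule = data.frame(label = "A",
                                                      duration_s = 30, dose = 0),
                          seed = 2)
  out <- generate_session(cfg)
  expect_true(all(out$truth$map$depth == 0))
  expect_error(synthetic_config(level_schedule = data.frame()), "empty")
})

test_that("the slow component leaks negligible power above the slow band", {
  cfg <- synthetic_preset("propofol", n_channels = 2, level_duration_s = 60,
                          seed = 8)
  for (lv in cfg$level_schedule$label) {
    s <- generate_slow_wave(cfg, 1, lv)
    expect_lt(power_fraction_above(s, 200, 4), 0.01)
  }
})

test_that("artifact plans corrupt and flag the planned windows", {
  cfg <- synthetic_config(n_channels = 2,
                          level_schedule = data.frame(label = "A",
                                                      duration_s = 60, dose = 0),
                          artifact_plan = data.frame(channel = 2, start_s = 10,
                                                     end_s = 12),
                          seed = 3)
  out <- generate_session(cfg)
  m <- out$recording$artifact_mask
  expect_true(all(m[2, (10 * 200 + 1):(12 * 200)]))
  expect_false(any(m[1, ]))
  expect_gt(max(out$recording$data[2, (10 * 200 + 1):(12 * 200)]), 500)
})
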