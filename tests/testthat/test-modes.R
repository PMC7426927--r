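mk_records <- function(subjects, levels, locations, bands = seq(4, 48, by = 2),
                       seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(subjects, function(su)
    do.call(rbind, lapply(levels, function(lv)
      do.call(rbind, lapply(locations, function(lo)
        data.frame(subject = su, level = lv, location = lo,
                   band_low = bands, band_high = bands + 2,
                   r = runif(length(bands), -0.5, 0.5))))))))
}

test_that("aggregate matrix bookkeeping matches the cohort structure", {
  lv4 <- c("Baseline", "Sedation", "UncLow", "UncHigh")
  rec <- mk_records(c("s1", "s2"), lv4, c("a", "b", "c"))
  A <- assemble_aggregate(rec)
  expect_equal(dim(A), c(23L, 24L))
  # a subject lacking Sedation contributes no Sedation columns
  rec2 <- rec[!(rec$subject == "s2" & rec$level == "Sedation"), ]
  expect_equal(dim(assemble_aggregate(rec2)), c(23L, 21L))
  expect_error(assemble_aggregate(rbind(rec, rec[1, ])), "duplicate")
  expect_error(assemble_aggregate(rec[-1, ]), "incomplete")
})

test_that("rank-1 matrices are decomposed exactly with the sign convention", {
  u <- c(-5, 2, 1, 0.5); u <- u / sqrt(sum(u^2))  # largest element negative
  v <- c(3, -1, 4)
  A <- u %*% t(v)
  d <- cfc_modes(A)
  # flipped so the largest-magnitude element is positive
  expect_equal(d$modes[, 1], -u, tolerance = 1e-12)
  expect_equal(percent_energy(d, 1), 100, tolerance = 1e-9)
  # a single nonzero row concentrates the first mode on it
  B <- matrix(0, 5, 4); B[3, ] <- c(1, 2, 3, 4)
  d2 <- cfc_modes(B)
  expect_equal(d2$modes[, 1], c(0, 0, 1, 0, 0), tolerance = 1e-12)
})

test_that("singular values match an independent Gram-matrix oracle", {
  set.seed(19)
  A <- matrix(rnorm(23 * 40), 23)
  d <- cfc_modes(A)
  # oracle: eigenvalues of A'A
  ev <- sort(sqrt(pmax(eigen(t(A) %*% A, symmetric = TRUE)$values, 0)),
             decreasing = TRUE)
  expect_equal(d$singular_values, ev[seq_along(d$singular_values)],
               tolerance = 1e-8)
  # reconstruction, orthonormality, energy bookkeeping
  R <- d$modes %*% diag(d$singular_values) %*% t(d$right_factors)
  expect_lt(norm(R - A, "F") / norm(A, "F"), 1e-8)
  G <- t(d$modes) %*% d$modes
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-10)
  expect_equal(sum(d$percent_energy), 100, tolerance = 1e-9)
  expect_equal(sum(d$singular_values^2), norm(A, "F")^2,
               tolerance = 1e-9 * norm(A, "F")^2)
  # sign rule: every mode's largest-magnitude element is positive
  for (j in seq_along(d$singular_values)) {
    m <- d$modes[, j]
    expect_gte(m[which.max(abs(m))], 0)
  }
  expect_true(all(diff(d$percent_energy) <= 1e-12))
})

test_that("percent energy follows the singular values", {
  d <- list(singular_values = c(2, 1), percent_energy = 100 * c(4, 1) / 5)
  class(d) <- "cfc_modes"
  expect_equal(percent_energy(d, 1), 80)
  expect_equal(percent_energy(d, 2), 20)
  expect_error(percent_energy(d, 3), "out of range")
  dd <- cfc_modes(diag(4))  # all-equal singular values
  expect_equal(dd$percent_energy, rep(25, 4))
})

test_that("non-centered PCA is sensitive to a constant coupling offset", {
  set.seed(23)
  A <- matrix(rnorm(23 * 30, sd = 0.1), 23)
  off <- A + 0.5  # constant frequency-profile offset
  m1 <- cfc_modes(A)$modes[, 1]
  m2 <- cfc_modes(off)$modes[, 1]
  expect_gt(max(abs(m1 - m2)), 0.05)  # centered PCA would be blind to this
})

test_that("projections respect orthonormality and preserve norms", {
  set.seed(29)
  A <- matrix(rnorm(23 * 40), 23)
  d <- cfc_modes(A)
  cvec <- c(2, -1, 0.5)
  P1 <- predict(d, d$modes[, 1] %*% t(cvec))
  expect_equal(as.numeric(P1[1, ]), cvec, tolerance = 1e-10)
  expect_lt(max(abs(P1[-1, ])), 1e-10)
  P2 <- predict(d, d$modes[, 2] %*% t(cvec))
  expect_lt(max(abs(P2[1, ])), 1e-10)
  B <- matrix(rnorm(23 * 7), 23)
  PB <- predict(d, B)
  expect_equal(sqrt(colSums(PB^2)), sqrt(colSums(B^2)), tolerance = 1e-10)
  expect_error(predict(d, matrix(0, 10, 2)), "mismatch")
})

test_that("region stacking is consistent with single-location analysis", {
  cfg <- synthetic_config(n_channels = 2,
                          level_schedule = data.frame(
                            label = c("A", "B"), duration_s = 90, dose = 0:1),
                          coupling_plan = list(list(channels = 1:2, level = "B",
                                                    band = c(4, 50), depth = 0.6)),
                          seed = 33)
  out <- generate_session(cfg)
  rec <- out$recording
  bank <- design_filter_bank()
  eps <- list(A = select_epochs(rec, "A", 2, 30), B = select_epochs(rec, "B", 2, 30))
  # a region of one location equals that location's level-based records
  rg1 <- region_coupling(rec, bank, list(solo = 1L), eps)
  rec1 <- level_coupling_records(rec, bank, eps, locations = 1L)
  expect_equal(rg1$r, rec1$r, tolerance = 1e-12)
  # a region of two identical signals equals the single-location result
  rec_dup <- rec
  rec_dup$data[2, ] <- rec_dup$data[1, ]
  rg2 <- region_coupling(rec_dup, bank, list(pair = 1:2), eps)
  rg_single <- region_coupling(rec_dup, bank, list(pair = 1L), eps)
  expect_equal(rg2$r, rg_single$r, tolerance = 1e-10)
  expect_error(region_coupling(rec, bank, list(a = 1:2, b = 2L), eps),
               "more than one region")
})

test_that("one-pass session analysis matches the standalone operations", {
  cfg <- synthetic_preset("propofol", n_channels = 4, level_duration_s = 60,
                          seed = 55)
  out <- generate_session(cfg)
  rec <- out$recording
  bank <- design_filter_bank()
  eps <- lapply(rec$levels$label, function(lv) select_epochs(rec, lv, 2, 30))
  names(eps) <- rec$levels$label
  res <- analyze_session_coupling(rec, bank, eps,
                                  region_map = list(grp = c(1L, 3L)))
  solo <- level_coupling_records(rec, bank, eps, subject = "s1")
  expect_equal(res$records$r, solo$r, tolerance = 1e-12)
  rg <- region_coupling(rec, bank, list(grp = c(1L, 3L)), eps)
  expect_equal(res$regions$r, rg$r, tolerance = 1e-12)
  topo <- level_topography(rec, bank, eps[["UncHigh"]])
  got <- res$summary_topography
  expect_equal(as.numeric(topo),
               got$r[got$level == "UncHigh"][match(names(topo),
                 got$location[got$level == "UncHigh"])],
               tolerance = 1e-12)
})

test_that("missing levels yield flagged empty topographies", {
  rec <- session_recording(matrix(rnorm(2 * 6000), 2), 200,
                           channel_positions = synthetic_positions(2))
  topo <- level_topography(rec, design_filter_bank(), epochs = NULL)
  expect_true(attr(topo, "missing_level"))
  expect_length(topo, 0)
})

test_that("subject bootstrap CIs behave on degenerate and simple inputs", {
  pr <- data.frame(subject = paste0("s", 1:5), level = "UncLow",
                   location = "posterior", value = 2.5)
  ci <- bootstrap_subject_ci(pr, n_boot = 200, seed = 1)
  expect_equal(ci$lower, 2.5)
  expect_equal(ci$upper, 2.5)
  pr2 <- data.frame(subject = c("a", "b"), level = "x", location = "y",
                    value = c(1, 3))
  ci2 <- bootstrap_subject_ci(pr2, n_boot = 500, seed = 2)
  expect_gte(ci2$lower, 1); expect_lte(ci2$upper, 3)
  expect_true(ci2$lower <= ci2$mean && ci2$mean <= ci2$upper)
  expect_error(bootstrap_subject_ci(pr[1, ], 100, 1), "at least 2")
  # determinism
  expect_identical(bootstrap_subject_ci(pr2, 500, seed = 9),
                   bootstrap_subject_ci(pr2, 500, seed = 9))
})

test_that("a broadband cohort yields one dominant all-positive mode", {
  recs <- list()
  for (s in 1:2) {
    cfg <- synthetic_preset("broadband-only", n_channels = 8,
                            level_duration_s = 60, seed = 800 + s)
    out <- generate_session(cfg)
    rec <- laplacian_reference(out$recording)
    eps <- lapply(rec$levels$label, function(lv) select_epochs(rec, lv, 2, 30))
    names(eps) <- rec$levels$label
    recs[[s]] <- analyze_session_coupling(rec, design_filter_bank(), eps,
                                          subject = paste0("s", s))$records
  }
  A <- assemble_aggregate(do.call(rbind, recs))
  d <- cfc_modes(A)
  m1 <- d$modes[, 1]
  expect_true(all(m1 > 0))
  expect_lt(sd(m1) / mean(m1), 0.5)
  expect_gt(d$percent_energy[1], max(d$percent_energy[-1]))
})
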