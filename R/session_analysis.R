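# Per-channel coupling sums over a set of time windows: the shared engine
# behind modulograms, level topographies, region coupling and the aggregate
# matrix.  For each channel it computes, from one FFT of the session, the
# slow-band voltage and every amplitude band's envelope, then accumulates
# V'A, V'V and A'A per (channel, band, window) with the envelope centered
# within each window.  Any downstream quantity is a ratio of sums over a
# subset of channels/windows, which is exactly the vertical-stacking rule.
cfc_window_sums <- function(recording, bank, windows,
                            channels = seq_len(nrow(recording$data)),
                            include_summary = FALSE) {
  fs <- recording$sample_rate_hz
  n <- ncol(recording$data)
  half <- filter_half_span(bank$slow_band, fs)
  lo_valid <- half + 1L
  hi_valid <- n - half
  if (hi_valid <= lo_valid)
    stop("recording shorter than the slow-band filter span", call. = FALSE)
  bands <- bank$high_bands
  if (include_summary) bands <- c(bands, list(bank$summary_band))
  nb <- length(bands)
  nw <- nrow(windows)
  nch <- length(channels)

  win_idx <- lapply(seq_len(nw), function(w) {
    i0 <- max(lo_valid, as.integer(floor(windows$start_s[w] * fs)) + 1L)
    i1 <- min(hi_valid, as.integer(round(windows$end_s[w] * fs)))
    if (i1 - i0 + 1L < 2L) integer(0) else i0:i1
  })

  VA <- array(NA_real_, c(nch, nb, nw))
  AA <- array(NA_real_, c(nch, nb, nw))
  VV <- matrix(NA_real_, nch, nw)
  ok <- matrix(FALSE, nch, nw)

  H2s_scaled <- NULL
  for (ci in seq_len(nch)) {
    ch <- channels[ci]
    x <- recording$data[ch, ]
    sp <- session_spectrum(x, fs, bank)
    if (is.null(H2s_scaled))
      H2s_scaled <- fir_response_sq(bank$slow_band, fs, sp$nfft) / sp$nfft
    slow <- Re(fft(sp$X * H2s_scaled, inverse = TRUE))[seq_len(n)]
    mask_ch <- if (!is.null(recording$artifact_mask)) recording$artifact_mask[ch, ]
    for (w in seq_len(nw)) {
      idx <- win_idx[[w]]
      ok[ci, w] <- length(idx) > 0 &&
        (is.null(mask_ch) || !any(mask_ch[idx]))
      if (ok[ci, w]) VV[ci, w] <- sum(slow[idx]^2)
    }
    # equal-length clean windows can be summed as matrix columns
    wl <- lengths(win_idx)
    fast <- which(ok[ci, ] & wl == wl[which(ok[ci, ])[1]])
    slow_w <- NULL; idx_all <- NULL; m <- 0L
    if (length(fast)) {
      idx_all <- unlist(win_idx[fast], use.names = FALSE)
      m <- wl[fast[1]]
      slow_w <- matrix(slow[idx_all], m)
      s_sum <- .colSums(slow_w, m, length(fast))
    }
    # one spectral workspace per channel, re-zeroed band by band
    Y <- complex(sp$nfft)
    prev_idx <- NULL
    for (b in seq_len(nb)) {
      bs <- fir_analytic_sparse(bands[[b]], fs, sp$nfft)
      if (!is.null(prev_idx)) Y[prev_idx] <- 0
      Y[bs$idx] <- sp$X[bs$idx] * bs$val
      prev_idx <- bs$idx
      env <- Mod(fft(Y, inverse = TRUE))
      if (length(fast)) {
        env_w <- matrix(env[idx_all], m)
        e_mean <- .colMeans(env_w, m, length(fast))
        env_w <- env_w - rep(e_mean, each = m)
        AA[ci, b, fast] <- .colSums(env_w * env_w, m, length(fast))
        VA[ci, b, fast] <- .colSums(slow_w * env_w, m, length(fast))
      }
      rest <- which(ok[ci, ] & !(seq_len(nw) %in% fast))
      for (w in rest) {
        idx <- win_idx[[w]]
        a <- env[idx] - mean(env[idx])
        AA[ci, b, w] <- sum(a^2)
        VA[ci, b, w] <- sum(slow[idx] * a)
      }
    }
  }
  list(VA = VA, AA = AA, VV = VV, ok = ok, channels = channels,
       bands = bands, windows = windows,
       n_per_window = vapply(win_idx, length, integer(1)))
}

# stacked r from summed pieces; NA when the stack is empty or degenerate
r_from_sums <- function(va, vv, aa) {
  den <- sqrt(sum(vv)) * sqrt(sum(aa))
  if (!is.finite(den) || den == 0) return(NA_real_)
  sum(va) / den
}

#' Session modulogram
#'
#' The coupling correlation between the slow wave and every amplitude band,
#' for every `window_s`-second interval of the session, stacked vertically
#' across the requested locations within each window. Windows that overlap
#' the artifact mask on a channel omit that channel; windows with no clean
#' channel are `NA`.
#'
#' @param recording a preprocessed `session_recording`.
#' @param bank a `filter_bank`.
#' @param locations channel indices to stack (default all).
#' @param window_s window length in seconds (default 30).
#' @return object of class `modulogram`: a bands x windows matrix of
#'   correlations with band labels and window start times attached.
#' @export
compute_modulogram <- function(recording, bank = design_filter_bank(),
                               locations = seq_len(nrow(recording$data)),
                               window_s = 30) {
  fs <- recording$sample_rate_hz
  dur <- ncol(recording$data) / fs
  starts <- seq(0, dur - window_s, by = window_s)
  windows <- data.frame(start_s = starts, end_s = starts + window_s)
  s <- cfc_window_sums(recording, bank, windows, channels = locations)
  nb <- length(s$bands); nw <- nrow(windows)
  r <- matrix(NA_real_, nb, nw)
  for (w in seq_len(nw)) {
    use <- which(s$ok[, w])
    if (!length(use)) next
    for (b in seq_len(nb))
      r[b, w] <- r_from_sums(s$VA[use, b, w], s$VV[use, w], s$AA[use, b, w])
  }
  structure(r, band_labels = band_labels(bank),
            band_centers = band_centers(bank),
            window_start_s = starts, window_s = window_s,
            class = "modulogram")
}

#' @export
print.modulogram <- function(x, ...) {
  cat(sprintf("<modulogram> %d bands x %d windows (%g s), r in [%.3f, %.3f]\n",
              nrow(x), ncol(x), attr(x, "window_s"),
              min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

#' @export
plot.modulogram <- function(x, zlim = c(-1, 1) * max(abs(x), na.rm = TRUE), ...) {
  cols <- grDevices::hcl.colors(64, "Blue-Red 3")
  graphics::image(attr(x, "window_start_s"), attr(x, "band_centers"),
                  t(unclass(x)), col = cols, zlim = zlim,
                  xlab = "time (s)", ylab = "amplitude band center (Hz)", ...)
  invisible(x)
}

#' Level-based coupling topography
#'
#' One stacked correlation per channel, over the level's selected epochs
#' (e.g. 10 x 30 s = 300 s of data per value), between the slow wave and the
#' envelope of a single band (default the 8-16 Hz summary band, filtered
#' directly at 8-16 Hz).
#'
#' @param recording a `session_recording`.
#' @param bank a `filter_bank`.
#' @param epochs an `epoch_set` from [select_epochs()], or `NULL`/empty for
#'   a missing level (returns an empty, flagged result).
#' @param band a `band_spec` (default the bank's summary band).
#' @param locations channel indices (default all).
#' @return named numeric vector of correlations (class
#'   `coupling_topography`); attribute `missing_level = TRUE` when the level
#'   was absent.
#' @export
level_topography <- function(recording, bank = design_filter_bank(),
                             epochs, band = bank$summary_band,
                             locations = seq_len(nrow(recording$data))) {
  if (is.null(epochs) || !nrow(epochs)) {
    out <- setNames(numeric(0), character(0))
    return(structure(out, missing_level = TRUE, class = "coupling_topography"))
  }
  one_band <- bank
  one_band$high_bands <- list(band)
  s <- cfc_window_sums(recording, one_band, epochs, channels = locations)
  r <- vapply(seq_along(locations), function(ci) {
    use <- which(s$ok[ci, ])
    if (!length(use)) return(NA_real_)
    r_from_sums(s$VA[ci, 1, use], s$VV[ci, use], s$AA[ci, 1, use])
  }, numeric(1))
  structure(setNames(r, recording$channel_labels[locations]),
            missing_level = FALSE, band = band, class = "coupling_topography")
}

#' @export
print.coupling_topography <- function(x, ...) {
  if (isTRUE(attr(x, "missing_level"))) {
    cat("<coupling_topography> missing level (no epochs)\n")
  } else {
    cat(sprintf("<coupling_topography> %d locations, r in [%.3f, %.3f]\n",
                length(x), min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  }
  invisible(x)
}

#' Level-based coupling records for every channel and band
#'
#' The level-based analysis: for each requested level, each channel and each
#' amplitude band, the stacked correlation over that level's epochs. These
#' records are the rows from which the aggregate coupling matrix is
#' assembled.
#'
#' @param recording a `session_recording`.
#' @param bank a `filter_bank`.
#' @param epochs_by_level named list (level label -> `epoch_set`).
#' @param locations channel indices (default all).
#' @param subject subject identifier stored in the records.
#' @return data.frame with columns `subject`, `level`, `location`,
#'   `band_low`, `band_high`, `r`, `n_samples`.
#' @export
level_coupling_records <- function(recording, bank = design_filter_bank(),
                                   epochs_by_level, locations = seq_len(nrow(recording$data)),
                                   subject = "s1") {
  out <- list()
  for (lv in names(epochs_by_level)) {
    ep <- epochs_by_level[[lv]]
    if (is.null(ep) || !nrow(ep)) next
    s <- cfc_window_sums(recording, bank, ep, channels = locations)
    nb <- length(s$bands)
    for (ci in seq_along(locations)) {
      use <- which(s$ok[ci, ])
      r <- vapply(seq_len(nb), function(b) {
        if (!length(use)) return(NA_real_)
        r_from_sums(s$VA[ci, b, use], s$VV[ci, use], s$AA[ci, b, use])
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        subject = subject, level = lv,
        location = recording$channel_labels[locations[ci]],
        band_low = vapply(s$bands, function(b) b$low_hz, numeric(1)),
        band_high = vapply(s$bands, function(b) b$high_hz, numeric(1)),
        r = r, n_samples = sum(s$n_per_window[use]))
    }
  }
  do.call(rbind, out)
}

#' Region-stacked coupling
#'
#' Combines all locations of a region: the epochs of every location in the
#' region are stacked vertically into one pair of `V`/`A` vectors per
#' (region, band, level), giving a single correlation per cell rather than
#' an average of per-location correlations.
#'
#' @param recording a `session_recording`.
#' @param bank a `filter_bank`.
#' @param region_map named list, region name -> channel indices; every
#'   location may belong to at most one region.
#' @param epochs_by_level named list (level label -> `epoch_set`).
#' @param subject subject identifier stored in the records.
#' @return data.frame with columns `subject`, `level`, `location` (the
#'   region name), `band_low`, `band_high`, `r`, `n_samples`. Regions with
#'   no locations are flagged with `NA` correlations.
#' @export
region_coupling <- function(recording, bank = design_filter_bank(),
                            region_map, epochs_by_level, subject = "s1") {
  all_idx <- unlist(region_map, use.names = FALSE)
  if (anyDuplicated(all_idx))
    stop("a location is assigned to more than one region", call. = FALSE)
  out <- list()
  for (lv in names(epochs_by_level)) {
    ep <- epochs_by_level[[lv]]
    if (is.null(ep) || !nrow(ep)) next
    for (rg in names(region_map)) {
      idx <- region_map[[rg]]
      if (!length(idx)) {
        out[[length(out) + 1L]] <- data.frame(
          subject = subject, level = lv, location = rg,
          band_low = vapply(bank$high_bands, function(b) b$low_hz, numeric(1)),
          band_high = vapply(bank$high_bands, function(b) b$high_hz, numeric(1)),
          r = NA_real_, n_samples = 0L)
        next
      }
      s <- cfc_window_sums(recording, bank, ep, channels = idx)
      nb <- length(s$bands)
      r <- vapply(seq_len(nb), function(b) {
        use <- which(s$ok)
        if (!length(use)) return(NA_real_)
        r_from_sums(s$VA[, b, ][use], s$VV[use], s$AA[, b, ][use])
      }, numeric(1))
      out[[length(out) + 1L]] <- data.frame(
        subject = subject, level = lv, location = rg,
        band_low = vapply(s$bands, function(b) b$low_hz, numeric(1)),
        band_high = vapply(s$bands, function(b) b$high_hz, numeric(1)),
        r = r, n_samples = sum(s$n_per_window) * length(idx))
    }
  }
  do.call(rbind, out)
}
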