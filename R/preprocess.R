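#' Zero-phase bandpass filter and downsample a recording
#'
#' Filters every channel with the band's zero-phase FIR (see
#' [zero_phase_bandpass()]), then decimates to `target_rate` by keeping every
#' `fs/target_rate`-th sample. The bandpass itself removes everything above
#' the new Nyquist (precondition `target_rate >= 2 * (high + transition)`),
#' so decimation after filtering is alias-free. Level annotations are in
#' seconds and carry over; the artifact mask is collapsed blockwise (a
#' decimated sample is bad when any raw sample in its block was bad).
#'
#' @param recording a `session_recording`.
#' @param band a `band_spec`.
#' @param target_rate output sampling rate (Hz); must divide the input rate.
#' @return a band-limited `session_recording` at `target_rate`.
#' @export
bandpass_downsample <- function(recording, band, target_rate = recording$sample_rate_hz) {
  fs <- recording$sample_rate_hz
  if (target_rate < 2 * (band$high_hz + band$transition_hz))
    stop("target_rate too low for this band (aliasing)", call. = FALSE)
  fac <- fs / target_rate
  if (abs(fac - round(fac)) > 1e-9)
    stop("target_rate must divide the sampling rate", call. = FALSE)
  fac <- as.integer(round(fac))
  filt <- t(apply(recording$data, 1, zero_phase_bandpass, fs = fs, band = band))
  idx <- seq(1L, ncol(filt), by = fac)
  rec <- recording
  rec$data <- filt[, idx, drop = FALSE]
  rec$sample_rate_hz <- target_rate
  if (!is.null(recording$artifact_mask)) {
    m <- recording$artifact_mask
    nblk <- length(idx)
    out <- matrix(FALSE, nrow(m), nblk)
    for (b in seq_len(nblk)) {
      lo <- idx[b]
      hi <- min(lo + fac - 1L, ncol(m))
      out[, b] <- matrixStats_any(m[, lo:hi, drop = FALSE])
    }
    rec$artifact_mask <- out
  }
  rec
}

matrixStats_any <- function(m) rowSums(m) > 0

#' Threshold-based artifact mask
#'
#' Flags samples whose absolute amplitude exceeds `amp_uV`, and flat stretches
#' (zero variance over `flat_s`-second windows), then dilates each flagged
#' region by `pad_s` seconds. A deterministic stand-in for visual artifact
#' rejection.
#'
#' @param recording a `session_recording`.
#' @param amp_uV absolute amplitude threshold in microvolts (default 500).
#' @param flat_s window length for the flatline check, seconds.
#' @param pad_s dilation half-width, seconds.
#' @return logical channels x samples matrix (`TRUE` = artifact).
#' @export
detect_artifacts <- function(recording, amp_uV = 500, flat_s = 1, pad_s = 0.5) {
  fs <- recording$sample_rate_hz
  d <- recording$data
  mask <- abs(d) > amp_uV
  w <- max(2L, as.integer(round(flat_s * fs)))
  nblk <- ncol(d) %/% w
  for (i in seq_len(nrow(d))) {
    if (nblk > 0) {
      blocks <- matrix(d[i, seq_len(nblk * w)], nrow = w)
      flat <- apply(blocks, 2, function(b) max(b) - min(b) == 0)
      if (any(flat))
        for (b in which(flat)) mask[i, ((b - 1L) * w + 1L):(b * w)] <- TRUE
    }
  }
  if (pad_s > 0 && any(mask)) {
    p <- as.integer(round(pad_s * fs))
    for (i in seq_len(nrow(mask))) {
      bad <- which(mask[i, ])
      if (length(bad)) {
        lo <- pmax(1L, bad - p); hi <- pmin(ncol(mask), bad + p)
        for (k in seq_along(bad)) mask[i, lo[k]:hi[k]] <- TRUE
      }
    }
  }
  mask
}

#' Detect electrically bridged channel pairs
#'
#' Channels whose whole-session pairwise correlation exceeds `threshold`
#' (default 0.999) are reported; for each bridged pair the later channel is
#' listed for removal. A simple correlation heuristic standing in for
#' dedicated bridge-detection tools.
#'
#' @param recording a `session_recording`.
#' @param threshold correlation above which a pair counts as bridged.
#' @return integer vector of channel indices to drop (possibly empty).
#' @export
detect_bridged_channels <- function(recording, threshold = 0.999) {
  cc <- suppressWarnings(cor(t(recording$data)))
  cc[!is.finite(cc)] <- 0
  drop <- integer(0)
  n <- nrow(cc)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (cc[i, j] > threshold) drop <- c(drop, j)
  sort(unique(drop))
}

#' Drop channels from a recording
#' @param recording a `session_recording`.
#' @param drop integer indices of channels to remove.
#' @return the reduced `session_recording`.
#' @export
drop_channels <- function(recording, drop) {
  if (!length(drop)) return(recording)
  keep <- setdiff(seq_len(nrow(recording$data)), drop)
  session_recording(recording$data[keep, , drop = FALSE],
                    recording$sample_rate_hz,
                    channel_labels = recording$channel_labels[keep],
                    channel_positions = if (!is.null(recording$channel_positions))
                      recording$channel_positions[keep, , drop = FALSE],
                    levels = recording$levels,
                    loc_time = recording$loc_time, roc_time = recording$roc_time,
                    burst_suppression = recording$burst_suppression,
                    artifact_mask = if (!is.null(recording$artifact_mask))
                      recording$artifact_mask[keep, , drop = FALSE])
}
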