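#' One-pass coupling analysis of a session
#'
#' Computes, in a single pass over the channels (one FFT of the session per
#' channel, reused across all bands), the level-based coupling records for
#' every (channel, band, level), the region-stacked records for every
#' (region, band, level), and the summary-band topography per level. This is
#' what the pipeline calls per subject; the standalone
#' [level_coupling_records()], [region_coupling()] and [level_topography()]
#' compute the same quantities independently and are used as cross-checks.
#'
#' @param recording a `session_recording`.
#' @param bank a `filter_bank`.
#' @param epochs_by_level named list (level label -> `epoch_set`).
#' @param region_map named list, region name -> channel indices, or `NULL`.
#' @param subject subject identifier.
#' @return list with data.frames `records` (sensor level), `regions` (or
#'   `NULL`), and `summary_topography` (per level, summary band).
#' @export
analyze_session_coupling <- function(recording, bank = design_filter_bank(),
                                     epochs_by_level, region_map = NULL,
                                     subject = "s1") {
  lv_names <- names(epochs_by_level)
  keep <- vapply(lv_names, function(lv) {
    ep <- epochs_by_level[[lv]]
    !is.null(ep) && nrow(ep) > 0
  }, logical(1))
  lv_names <- lv_names[keep]
  if (!length(lv_names)) stop("no levels with epochs", call. = FALSE)
  windows <- do.call(rbind, lapply(lv_names, function(lv) {
    ep <- as.data.frame(epochs_by_level[[lv]])
    data.frame(start_s = ep$start_s, end_s = ep$end_s, level = lv)
  }))
  s <- cfc_window_sums(recording, bank, windows, include_summary = TRUE)
  nb <- length(bank$high_bands)
  nch <- length(s$channels)
  b_lo <- vapply(bank$high_bands, function(b) b$low_hz, numeric(1))
  b_hi <- vapply(bank$high_bands, function(b) b$high_hz, numeric(1))

  agg <- function(ci_set, b, w_set) {
    use <- which(s$ok[ci_set, w_set, drop = FALSE])
    if (!length(use)) return(c(NA_real_, 0))
    va <- s$VA[ci_set, b, w_set]
    vv <- s$VV[ci_set, w_set]
    aa <- s$AA[ci_set, b, w_set]
    c(r_from_sums(va[use], vv[use], aa[use]),
      sum(rep(s$n_per_window[w_set], each = length(ci_set))[use]))
  }

  records <- list(); topo <- list(); regions <- NULL
  for (lv in lv_names) {
    w_set <- which(windows$level == lv)
    for (ci in seq_len(nch)) {
      rs <- t(vapply(seq_len(nb), function(b) agg(ci, b, w_set), numeric(2)))
      records[[length(records) + 1L]] <- data.frame(
        subject = subject, level = lv,
        location = recording$channel_labels[s$channels[ci]],
        band_low = b_lo, band_high = b_hi,
        r = rs[, 1], n_samples = as.integer(rs[1, 2]))
      st <- agg(ci, nb + 1L, w_set)
      topo[[length(topo) + 1L]] <- data.frame(
        subject = subject, level = lv,
        location = recording$channel_labels[s$channels[ci]],
        band_low = bank$summary_band$low_hz,
        band_high = bank$summary_band$high_hz,
        r = st[1], n_samples = as.integer(st[2]))
    }
  }
  if (!is.null(region_map)) {
    if (anyDuplicated(unlist(region_map, use.names = FALSE)))
      stop("a location is assigned to more than one region", call. = FALSE)
    regions <- list()
    for (lv in lv_names) {
      w_set <- which(windows$level == lv)
      for (rg in names(region_map)) {
        ci_set <- match(region_map[[rg]], s$channels)
        rs <- if (length(ci_set))
          t(vapply(seq_len(nb), function(b) agg(ci_set, b, w_set), numeric(2)))
        else matrix(c(NA_real_, 0), nb, 2, byrow = TRUE)
        regions[[length(regions) + 1L]] <- data.frame(
          subject = subject, level = lv, location = rg,
          band_low = b_lo, band_high = b_hi,
          r = rs[, 1], n_samples = as.integer(rs[1, 2]))
      }
    }
    regions <- do.call(rbind, regions)
  }
  list(records = do.call(rbind, records), regions = regions,
       summary_topography = do.call(rbind, topo))
}
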