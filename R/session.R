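#' Multichannel session recording
#'
#' The universal input container: a channels x samples voltage matrix with
#' sampling rate, channel labels and 3-D positions, and annotations (dose
#' level table, LOC/ROC times, burst-suppression flags, artifact mask).
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param sample_rate_hz sampling rate (Hz).
#' @param channel_labels character vector, one label per channel.
#' @param channel_positions numeric matrix channels x 3; finite, distinct rows.
#' @param levels data.frame with columns `label`, `start_s`, `end_s`, `dose`;
#'   contiguous, non-overlapping, within the recording.
#' @param loc_time,roc_time loss/return-of-consciousness times in seconds,
#'   or `NA` when absent.
#' @param burst_suppression character vector of level labels flagged as
#'   showing burst suppression.
#' @param artifact_mask logical matrix, same shape as `data` (`TRUE` = bad),
#'   or `NULL` for an all-clean recording.
#' @return an object of class `session_recording`.
#' @export
session_recording <- function(data, sample_rate_hz, channel_labels = NULL,
                              channel_positions = NULL, levels = NULL,
                              loc_time = NA_real_, roc_time = NA_real_,
                              burst_suppression = character(0),
                              artifact_mask = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("data must be numeric", call. = FALSE)
  nch <- nrow(data); ns <- ncol(data)
  if (is.null(channel_labels)) channel_labels <- sprintf("ch%02d", seq_len(nch))
  if (length(channel_labels) != nch)
    stop("channel_labels length must equal the number of channels", call. = FALSE)
  if (!is.null(channel_positions)) {
    channel_positions <- as.matrix(channel_positions)
    if (nrow(channel_positions) != nch || ncol(channel_positions) != 3)
      stop("channel_positions must be a channels x 3 matrix", call. = FALSE)
    if (!all(is.finite(channel_positions)))
      stop("channel_positions must be finite", call. = FALSE)
    if (anyDuplicated(round(channel_positions, 12)))
      stop("channel_positions contains duplicate positions", call. = FALSE)
  }
  dur <- ns / sample_rate_hz
  if (!is.null(levels)) {
    levels <- as.data.frame(levels)
    need <- c("label", "start_s", "end_s", "dose")
    if (!all(need %in% names(levels)))
      stop("levels needs columns label, start_s, end_s, dose", call. = FALSE)
    if (any(levels$end_s <= levels$start_s))
      stop("level durations must be positive", call. = FALSE)
    o <- order(levels$start_s)
    levels <- levels[o, , drop = FALSE]
    if (nrow(levels) > 1 &&
        any(levels$start_s[-1] < levels$end_s[-nrow(levels)] - 1e-9))
      stop("levels must be non-overlapping", call. = FALSE)
    if (min(levels$start_s) < -1e-9 || max(levels$end_s) > dur + 1e-6)
      stop("levels must lie within the recording", call. = FALSE)
  }
  if (!is.null(artifact_mask)) {
    artifact_mask <- as.matrix(artifact_mask)
    if (!identical(dim(artifact_mask), dim(data)))
      stop("artifact_mask shape must match data", call. = FALSE)
    storage.mode(artifact_mask) <- "logical"
  }
  rownames(data) <- channel_labels
  structure(list(data = data, sample_rate_hz = sample_rate_hz,
                 channel_labels = channel_labels,
                 channel_positions = channel_positions,
                 levels = levels, loc_time = loc_time, roc_time = roc_time,
                 burst_suppression = burst_suppression,
                 artifact_mask = artifact_mask),
            class = "session_recording")
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sample_rate_hz,
              ncol(x$data) / x$sample_rate_hz))
  if (!is.null(x$levels))
    cat(sprintf("  levels: %s\n", paste(x$levels$label, collapse = ", ")))
  if (!is.na(x$loc_time)) cat(sprintf("  LOC at %g s\n", x$loc_time))
  if (!is.null(x$artifact_mask))
    cat(sprintf("  artifact mask: %.2f%% of samples flagged\n",
                100 * mean(x$artifact_mask)))
  invisible(x)
}

#' @export
plot.session_recording <- function(x, channels = seq_len(min(8, nrow(x$data))),
                                   t_lim = NULL, ...) {
  t <- seq_len(ncol(x$data)) / x$sample_rate_hz
  sel <- if (is.null(t_lim)) rep(TRUE, length(t)) else t >= t_lim[1] & t <= t_lim[2]
  d <- x$data[channels, sel, drop = FALSE]
  off <- 3 * stats::median(apply(d, 1, stats::sd))
  if (!is.finite(off) || off == 0) off <- 1
  graphics::plot(range(t[sel]), c(0, (length(channels) + 1) * off), type = "n",
                 xlab = "time (s)", ylab = "", yaxt = "n", ...)
  for (i in seq_along(channels))
    graphics::lines(t[sel], d[i, ] + i * off)
  graphics::axis(2, at = seq_along(channels) * off,
                 labels = x$channel_labels[channels], las = 1)
  invisible(x)
}

# ---- plain-text interchange container -------------------------------------

fmt_full <- function(v) sprintf("%.17g", v)

#' Write a session to the plain-text interchange container
#'
#' A directory holding `meta.json` (rate, labels, positions, markers),
#' `data.csv` (samples x channels, full `%.17g` precision so doubles
#' round-trip exactly), `levels.csv` and, when present, `mask_runs.csv`
#' (run-length encoded artifact mask). Everything is plain text.
#'
#' @param recording a `session_recording`.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(recording, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(sample_rate_hz = recording$sample_rate_hz,
               channel_labels = recording$channel_labels,
               channel_positions = if (!is.null(recording$channel_positions))
                 unname(as.matrix(recording$channel_positions)),
               loc_time = if (is.na(recording$loc_time)) NULL else recording$loc_time,
               roc_time = if (is.na(recording$roc_time)) NULL else recording$roc_time,
               burst_suppression = recording$burst_suppression)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  d <- t(recording$data)
  lines <- c(paste(recording$channel_labels, collapse = ","),
             do.call(paste, c(lapply(seq_len(ncol(d)), function(j) fmt_full(d[, j])),
                              sep = ",")))
  writeLines(lines, file.path(path, "data.csv"))
  if (!is.null(recording$levels))
    write.csv(recording$levels, file.path(path, "levels.csv"), row.names = FALSE)
  if (!is.null(recording$artifact_mask) && any(recording$artifact_mask)) {
    runs <- mask_to_runs(recording$artifact_mask)
    write.csv(runs, file.path(path, "mask_runs.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a session from the interchange container
#' @param path directory written by [write_session()].
#' @return a `session_recording`.
#' @export
read_session <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  d <- as.matrix(read.csv(file.path(path, "data.csv"), check.names = FALSE))
  pos <- NULL
  if (!is.null(meta$channel_positions)) {
    pos <- matrix(as.numeric(as.matrix(meta$channel_positions)),
                  ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z")))
  }
  lv <- NULL
  lp <- file.path(path, "levels.csv")
  if (file.exists(lp)) lv <- read.csv(lp)
  mask <- NULL
  mp <- file.path(path, "mask_runs.csv")
  if (file.exists(mp)) {
    runs <- read.csv(mp)
    mask <- runs_to_mask(runs, nrow(d), length(meta$channel_labels))
  }
  session_recording(t(d), meta$sample_rate_hz,
                    channel_labels = meta$channel_labels,
                    channel_positions = pos, levels = lv,
                    loc_time = meta$loc_time %||% NA_real_,
                    roc_time = meta$roc_time %||% NA_real_,
                    burst_suppression = as.character(meta$burst_suppression %||% character(0)),
                    artifact_mask = mask)
}

mask_to_runs <- function(mask) {
  out <- list()
  for (i in seq_len(nrow(mask))) {
    r <- rle(mask[i, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (any(keep))
      out[[length(out) + 1L]] <- data.frame(channel = i,
                                            start_sample = starts[keep],
                                            end_sample = ends[keep])
  }
  if (!length(out)) return(data.frame(channel = integer(0),
                                      start_sample = integer(0),
                                      end_sample = integer(0)))
  do.call(rbind, out)
}

runs_to_mask <- function(runs, n_samples, n_channels) {
  mask <- matrix(FALSE, n_channels, n_samples)
  for (k in seq_len(nrow(runs)))
    mask[runs$channel[k], runs$start_sample[k]:runs$end_sample[k]] <- TRUE
  mask
}
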