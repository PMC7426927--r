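#' Map dose levels to the four levels of interest
#'
#' Applies the stepped-dose protocol rules: Baseline is the pre-drug period
#' (last zero-dose level before drug onset); Sedation is the level prior to
#' the one in which LOC occurred (absent when LOC fell in the first drug
#' level); Unconscious Low Dose is the first full level after LOC; and
#' Unconscious High Dose is the highest-dose level, or the level before the
#' first burst-suppression level for subjects who entered burst suppression.
#'
#' @param levels data.frame with columns `label`, `start_s`, `end_s`, `dose`,
#'   ordered in time.
#' @param loc_time loss-of-consciousness time in seconds (required).
#' @param burst_suppression character vector of level labels flagged as
#'   showing burst suppression.
#' @return named character vector with entries `Baseline`, `Sedation`,
#'   `UncLow`, `UncHigh`; `Sedation` is `NA` when no sedation period exists.
#' @examples
#' lv <- data.frame(label = paste0("L", 0:5), start_s = (0:5) * 840,
#'                  end_s = (1:6) * 840, dose = 0:5)
#' define_levels(lv, loc_time = 2100, burst_suppression = "L5")
#' @export
define_levels <- function(levels, loc_time, burst_suppression = character(0)) {
  levels <- as.data.frame(levels)
  levels <- levels[order(levels$start_s), , drop = FALSE]
  if (is.null(loc_time) || is.na(loc_time))
    stop("no LOC marker: cannot define the unconscious levels", call. = FALSE)
  drug <- which(levels$dose > 0)
  if (!length(drug) || drug[1] == 1)
    stop("schedule has no pre-drug (zero dose) period", call. = FALSE)
  baseline <- drug[1] - 1L
  loc_level <- which(levels$start_s <= loc_time & loc_time < levels$end_s)
  if (!length(loc_level))
    stop("LOC time lies outside every level", call. = FALSE)
  loc_level <- loc_level[1]
  sedation <- if (loc_level - 1L >= 1L && levels$dose[loc_level - 1L] > 0)
    loc_level - 1L else NA_integer_
  if (loc_level + 1L > nrow(levels))
    stop("no full level after LOC", call. = FALSE)
  unc_low <- loc_level + 1L
  bs <- which(levels$label %in% burst_suppression)
  unc_high <- if (length(bs)) min(bs) - 1L else which.max(levels$dose)
  if (unc_high < 1L)
    stop("burst suppression in the first level: no usable high-dose level",
         call. = FALSE)
  lab <- function(i) if (is.na(i)) NA_character_ else as.character(levels$label[i])
  c(Baseline = lab(baseline), Sedation = lab(sedation),
    UncLow = lab(unc_low), UncHigh = lab(unc_high))
}

#' Select artifact-free epochs within a level
#'
#' Deterministic earliest-first placement of `n` disjoint `duration_s`-second
#' windows inside the level, skipping any window that overlaps the artifact
#' mask on any channel.
#'
#' @param recording a `session_recording` with a level table.
#' @param level level label to select from.
#' @param n number of epochs (default 10).
#' @param duration_s epoch duration in seconds (default 30).
#' @return data.frame with columns `start_s`, `end_s` (class `epoch_set`,
#'   attributes `level` and `duration_s`).
#' @export
select_epochs <- function(recording, level, n = 10, duration_s = 30) {
  if (is.null(recording$levels))
    stop("recording has no level annotations", call. = FALSE)
  row <- which(recording$levels$label == level)
  if (!length(row))
    stop(sprintf("unknown level label '%s'", level), call. = FALSE)
  fs <- recording$sample_rate_hz
  s0 <- as.integer(ceiling(recording$levels$start_s[row] * fs)) + 1L
  s1 <- as.integer(floor(recording$levels$end_s[row] * fs))
  s1 <- min(s1, ncol(recording$data))
  bad <- if (is.null(recording$artifact_mask)) rep(FALSE, s1 - s0 + 1L)
         else colSums(recording$artifact_mask[, s0:s1, drop = FALSE]) > 0
  w <- as.integer(round(duration_s * fs))
  starts <- integer(0)
  pos <- 1L
  nn <- length(bad)
  # cumulative bad count for O(1) window checks
  cb <- c(0L, cumsum(bad))
  while (length(starts) < n && pos + w - 1L <= nn) {
    nbad <- cb[pos + w] - cb[pos]
    if (nbad == 0L) {
      starts <- c(starts, pos)
      pos <- pos + w
    } else {
      # jump past the first bad sample in the window
      firstbad <- pos + which(bad[pos:(pos + w - 1L)])[1] - 1L
      pos <- firstbad + 1L
    }
  }
  if (length(starts) < n)
    stop(sprintf("level '%s' has only %d clean %gs epochs (requested %d)",
                 level, length(starts), duration_s, n), call. = FALSE)
  out <- data.frame(start_s = (s0 - 1L + starts - 1L) / fs,
                    end_s = (s0 - 1L + starts - 1L + w) / fs)
  structure(out, level = level, duration_s = duration_s, class = c("epoch_set", "data.frame"))
}
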