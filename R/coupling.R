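#' Analytic signal via the DFT half-spectrum mask
#'
#' @param x real numeric series.
#' @return complex series whose real part is `x`, magnitude the envelope and
#'   argument the instantaneous phase.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  fft(fft(x) * analytic_mask(n), inverse = TRUE) / n
}

#' Instantaneous amplitude (envelope) of a band-limited signal
#'
#' The magnitude of the analytic signal. Samples within `edge_samples` of
#' either end are flagged in the `edge` attribute: the analytic transform
#' (and any preceding filtering) is distorted there and those samples should
#' be excluded from correlations.
#'
#' @param band_signal band-limited numeric series.
#' @param edge_samples number of samples to flag at each end (e.g. half the
#'   slow-band filter span, see [filter_half_span()]).
#' @return numeric envelope with logical attribute `edge`.
#' @export
instantaneous_amplitude <- function(band_signal, edge_samples = 0L) {
  n <- length(band_signal)
  env <- Mod(analytic_signal(band_signal))
  edge <- rep(FALSE, n)
  if (edge_samples > 0) {
    k <- min(edge_samples, n)
    edge[seq_len(k)] <- TRUE
    edge[seq.int(n - k + 1L, n)] <- TRUE
  }
  attr(env, "edge") <- edge
  env
}

#' Instantaneous phase of the slow wave
#' @param slow slow-band numeric series.
#' @return phase series in `(-pi, pi]`.
#' @export
slow_phase <- function(slow) Arg(analytic_signal(slow))

#' Signed correlation cross-frequency coupling
#'
#' The Pearson correlation between the slow voltage `V` and the
#' high-frequency instantaneous amplitude `A`:
#' `r = V'A / (sqrt(V'V) sqrt(A'A))`. The envelope is centered by
#' subtracting its mean; the slow voltage is used as-is (its expected value
#' is zero, and centering it would discard the up/down-state asymmetry the
#' metric is built to capture). Positive `r` means the envelope is largest
#' at the slow-wave peak (peakmax), negative at the trough (troughmax).
#'
#' @param slow slow-band voltage series (not centered by this function, and
#'   callers must not center it).
#' @param env envelope series, same length.
#' @param center center the envelope (default `TRUE`; set `FALSE` when the
#'   caller already centered it per epoch).
#' @return correlation in `[-1, 1]`, or `NA` (with a warning) when either
#'   vector has zero variance so the correlation is undefined.
#' @export
cfc_correlation <- function(slow, env, center = TRUE) {
  if (length(slow) != length(env))
    stop("slow and env must have equal length", call. = FALSE)
  a <- if (center) env - mean(env) else env
  den <- sqrt(sum(slow^2)) * sqrt(sum(a^2))
  if (den == 0) {
    warning("zero variance: coupling correlation undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(slow * a) / den
}

#' Stacked correlation across epochs and locations
#'
#' Concatenates (slow, envelope) pairs vertically and evaluates the
#' correlation once on the stacked vectors. Each envelope is centered within
#' its own segment before stacking. This estimates the covariance and the
#' two standard deviations over the whole stack before normalizing, and is
#' deliberately NOT the mean of per-segment correlations: segments with
#' larger slow-wave and envelope excursions carry proportionally more
#' weight.
#'
#' @param pairs list of `list(slow = , env = )` segments.
#' @return single stacked correlation (`NA` with a warning if degenerate).
#' @export
stacked_correlation <- function(pairs) {
  if (!length(pairs)) stop("empty pair list", call. = FALSE)
  V <- unlist(lapply(pairs, `[[`, "slow"), use.names = FALSE)
  A <- unlist(lapply(pairs, function(p) p$env - mean(p$env)), use.names = FALSE)
  cfc_correlation(V, A, center = FALSE)
}

#' Mean-vector phase-amplitude coupling estimate
#'
#' `mean(A * exp(1i * phi))`: a complex number whose magnitude measures the
#' strength of phase-amplitude coupling and whose argument is the preferred
#' slow-wave phase of the envelope (0 = peak, pi = trough).
#'
#' @param env envelope series.
#' @param phase slow-wave instantaneous phase series, same length.
#' @return object of class `mean_vector`: complex value with `magnitude` and
#'   `preferred_phase` attributes.
#' @export
mean_vector <- function(env, phase) {
  if (length(env) != length(phase))
    stop("env and phase must have equal length", call. = FALSE)
  mv <- mean(env * exp(1i * phase))
  structure(mv, magnitude = Mod(mv), preferred_phase = Arg(mv),
            class = "mean_vector")
}

#' @export
print.mean_vector <- function(x, ...) {
  cat(sprintf("<mean_vector> magnitude %.4g, preferred phase %.3f rad\n",
              attr(x, "magnitude"), attr(x, "preferred_phase")))
  invisible(x)
}
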