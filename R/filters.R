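#' Band specification
#'
#' A passband with explicit transition width, the unit the filter bank is
#' built from.
#'
#' @param low_hz lower passband edge (Hz), `>= 0`.
#' @param high_hz upper passband edge (Hz), `> low_hz`.
#' @param transition_hz transition band width (Hz), `> 0`.
#' @return an object of class `band_spec`.
#' @examples
#' band_spec(8, 16, 1)
#' @export
band_spec <- function(low_hz, high_hz, transition_hz = 1) {
  stopifnot_scalar_number(low_hz, "low_hz")
  stopifnot_scalar_number(high_hz, "high_hz")
  stopifnot_scalar_number(transition_hz, "transition_hz")
  if (low_hz < 0 || high_hz <= low_hz)
    stop("band edges must satisfy 0 <= low_hz < high_hz", call. = FALSE)
  if (transition_hz <= 0) stop("transition_hz must be positive", call. = FALSE)
  structure(list(low_hz = low_hz, high_hz = high_hz,
                 transition_hz = transition_hz),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %g-%g Hz (transition %g Hz)\n",
              x$low_hz, x$high_hz, x$transition_hz))
  invisible(x)
}

#' @export
format.band_spec <- function(x, ...) sprintf("%g-%g", x$low_hz, x$high_hz)

#' Design the analysis filter bank
#'
#' The bank holds one wide slow band (default 0.1-4 Hz) and a set of
#' contiguous narrow amplitude bands tiling `low_stop`-`high_stop` Hz in
#' `band_width` Hz steps (defaults give 23 bands 4-6, 6-8, ..., 48-50 Hz,
#' each with a 1 Hz transition), plus a wider summary band (default 8-16 Hz)
#' used for scalp topographies.
#'
#' @param low_stop lower edge of the tiled amplitude range (Hz).
#' @param high_stop upper edge of the tiled amplitude range (Hz).
#' @param band_width width of each amplitude band (Hz); must divide
#'   `high_stop - low_stop` exactly.
#' @param transition transition band width for the amplitude bands (Hz).
#' @param slow_band `band_spec` for the slow wave.
#' @param summary_band `band_spec` used for single-band topographies.
#' @return an object of class `filter_bank` with elements `slow_band`,
#'   `high_bands` (list of `band_spec`) and `summary_band`.
#' @examples
#' bank <- design_filter_bank()
#' length(bank$high_bands)  # 23
#' @export
design_filter_bank <- function(low_stop = 4, high_stop = 50, band_width = 2,
                               transition = 1,
                               slow_band = band_spec(0.1, 4, 0.5),
                               summary_band = band_spec(8, 16, 1)) {
  if (high_stop <= low_stop || low_stop < 0)
    stop("need high_stop > low_stop >= 0", call. = FALSE)
  n_bands <- (high_stop - low_stop) / band_width
  if (abs(n_bands - round(n_bands)) > 1e-9)
    stop(sprintf("band_width %g does not divide the range %g-%g Hz",
                 band_width, low_stop, high_stop), call. = FALSE)
  n_bands <- as.integer(round(n_bands))
  edges <- low_stop + band_width * (0:n_bands)
  high_bands <- lapply(seq_len(n_bands), function(i)
    band_spec(edges[i], edges[i + 1], transition))
  structure(list(slow_band = slow_band, high_bands = high_bands,
                 summary_band = summary_band),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> slow %s Hz; %d amplitude bands %s ... %s Hz; summary %s Hz\n",
              format(x$slow_band), length(x$high_bands),
              format(x$high_bands[[1]]),
              format(x$high_bands[[length(x$high_bands)]]),
              format(x$summary_band)))
  invisible(x)
}

#' Center frequencies of the amplitude bands
#' @param bank a `filter_bank`.
#' @return numeric vector of band centers (Hz).
#' @export
band_centers <- function(bank) {
  vapply(bank$high_bands, function(b) (b$low_hz + b$high_hz) / 2, numeric(1))
}

band_labels <- function(bank) vapply(bank$high_bands, format, character(1))

# ---- FIR kernel design and zero-phase application -------------------------

.filter_cache <- new.env(parent = emptyenv())

# Windowed-sinc (Hamming) linear-phase bandpass kernel.  Order follows the
# standard transition-width rule ceil(3.3 / (transition/fs)), rounded up to
# even so the kernel has type-I symmetry (integer group delay).
fir_kernel <- function(band, fs) {
  key <- sprintf("k|%g|%g|%g|%g", band$low_hz, band$high_hz,
                 band$transition_hz, fs)
  k <- .filter_cache[[key]]
  if (!is.null(k)) return(k)
  ord <- ceiling(3.3 / (band$transition_hz / fs))
  if (ord %% 2 == 1) ord <- ord + 1
  nyq <- fs / 2
  if (band$high_hz + band$transition_hz / 2 >= nyq)
    stop(sprintf("band %s Hz does not fit under Nyquist %g Hz",
                 format(band), nyq), call. = FALSE)
  w <- c(band$low_hz, band$high_hz) / nyq
  k <- as.numeric(signal::fir1(ord, w, type = "pass",
                               window = signal::hamming(ord + 1)))
  .filter_cache[[key]] <- k
  k
}

#' Half-span of a band's FIR kernel, in samples
#'
#' Samples within this distance of a recording edge carry filter edge
#' distortion and are excluded from correlations.
#'
#' @param band a `band_spec`.
#' @param fs sampling rate (Hz).
#' @return integer number of samples.
#' @export
filter_half_span <- function(band, fs) {
  (length(fir_kernel(band, fs)) - 1L) %/% 2L
}

# Squared magnitude response of the kernel at the FFT bins of length nfft.
# Multiplying a spectrum by this is exactly forward-backward (zero-phase)
# application of the kernel, because |H|^2 is the transform of the kernel's
# autocorrelation.
fir_response_sq <- function(band, fs, nfft) {
  key <- sprintf("H|%g|%g|%g|%g|%d", band$low_hz, band$high_hz,
                 band$transition_hz, fs, nfft)
  H2 <- .filter_cache[[key]]
  if (!is.null(H2)) return(H2)
  k <- fir_kernel(band, fs)
  if (length(k) > nfft)
    stop(sprintf("signal too short for the %s Hz filter (needs >= %d samples)",
                 format(band), length(k)), call. = FALSE)
  H2 <- Mod(fft(c(k, numeric(nfft - length(k)))))^2
  .filter_cache[[key]] <- H2
  H2
}

analytic_mask <- function(nfft) {
  m <- numeric(nfft)
  m[1] <- 1
  if (nfft %% 2 == 0) {
    m[2:(nfft / 2)] <- 2
    m[nfft / 2 + 1] <- 1
  } else {
    m[2:((nfft + 1) / 2)] <- 2
  }
  m
}

#' Zero-phase bandpass filtering
#'
#' Applies the band's linear-phase FIR kernel forwards and backwards (net
#' phase zero), realized exactly in the frequency domain: the zero-padded
#' spectrum is multiplied by the squared magnitude response, which equals
#' linear convolution with the kernel's autocorrelation.
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param band a `band_spec`.
#' @return filtered numeric signal, same length as `x`.
#' @export
zero_phase_bandpass <- function(x, fs, band) {
  n <- length(x)
  k <- fir_kernel(band, fs)
  if (n < length(k))
    stop(sprintf("recording (%d samples) shorter than the %s Hz filter span (%d samples)",
                 n, format(band), length(k)), call. = FALSE)
  nfft <- next_fast_len(n + length(k))
  H2 <- fir_response_sq(band, fs, nfft)
  X <- fft(c(x, numeric(nfft - n)))
  Re(fft(X * H2, inverse = TRUE))[seq_len(n)] / nfft
}

# Sparse analytic response: |H|^2 times the half-spectrum mask, stored as
# (bin indices, values) with the squared response truncated where it falls
# below 1e-10 of its peak (deep in the Hamming stopband).  Makes the
# per-band spectral multiply O(passband bins) instead of O(nfft).
fir_analytic_sparse <- function(band, fs, nfft) {
  key <- sprintf("S|%g|%g|%g|%g|%d", band$low_hz, band$high_hz,
                 band$transition_hz, fs, nfft)
  sp <- .filter_cache[[key]]
  if (!is.null(sp)) return(sp)
  Ha <- fir_response_sq(band, fs, nfft) * analytic_mask(nfft)
  idx <- which(Ha > 1e-10 * max(Ha))
  sp <- list(idx = idx, val = Ha[idx] / nfft)  # 1/nfft of the inverse FFT folded in
  .filter_cache[[key]] <- sp
  sp
}

# Analytic signal of the zero-phase band-filtered x: the half-spectrum mask
# is applied together with |H|^2 so one inverse FFT yields both the filtered
# signal (real part) and its envelope/phase.
band_analytic <- function(x, fs, band, X = NULL, nfft = NULL) {
  n <- length(x)
  k <- fir_kernel(band, fs)
  if (n < length(k))
    stop(sprintf("recording (%d samples) shorter than the %s Hz filter span (%d samples)",
                 n, format(band), length(k)), call. = FALSE)
  if (is.null(nfft)) nfft <- next_fast_len(n + length(k))
  if (is.null(X)) X <- fft(c(x, numeric(nfft - n)))
  sp <- fir_analytic_sparse(band, fs, nfft)
  Y <- complex(nfft)
  Y[sp$idx] <- X[sp$idx] * sp$val
  fft(Y, inverse = TRUE)[seq_len(n)]
}

# One FFT of the padded signal, reusable across all bands of a bank.
session_spectrum <- function(x, fs, bank) {
  spans <- c(length(fir_kernel(bank$slow_band, fs)),
             vapply(bank$high_bands, function(b) length(fir_kernel(b, fs)),
                    numeric(1)),
             length(fir_kernel(bank$summary_band, fs)))
  nfft <- next_fast_len(length(x) + max(spans))
  list(X = fft(c(x, numeric(nfft - length(x)))), nfft = nfft, n = length(x))
}
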