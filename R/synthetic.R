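#' Synthetic channel positions on the upper unit hemisphere
#'
#' Fibonacci-lattice layout: approximately uniform coverage of the scalp
#' hemisphere for any channel count. Axes: +x right, +y anterior, +z up.
#'
#' @param n number of channels.
#' @return n x 3 matrix of unit-sphere coordinates.
#' @export
synthetic_positions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 0.05 + (1 - 0.05) * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Anterior/posterior channel groups from positions
#'
#' @param positions channels x 3 matrix with +y anterior.
#' @param frac fraction of the y-range used as the frontal/posterior cut.
#' @return list with integer index vectors `frontal`, `posterior`, `all`.
#' @export
channel_groups <- function(positions, frac = 0.25) {
  y <- positions[, 2]
  list(frontal = which(y > frac), posterior = which(y < -frac),
       all = seq_len(nrow(positions)))
}

#' Configuration for the synthetic session generator
#'
#' Defines a stepped-dose session with fully known slow-wave coupling
#' structure. The defaults describe the standard validation cohort: 32
#' channels at 200 Hz, four 2-minute levels (Baseline, Sedation, Unconscious
#' Low Dose, Unconscious High Dose), a ~1 Hz skewed slow wave whose amplitude
#' grows with dose, an 11 Hz alpha rhythm, and an independent band-limited
#' Gaussian background in every 2 Hz amplitude band whose envelope can be
#' modulated by the slow wave with a per-(channel set, level, band) signed
#' depth: positive depth couples the envelope to the slow-wave peak
#' (peakmax), negative to the trough (troughmax).
#'
#' @param n_channels number of channels.
#' @param channel_positions channels x 3 matrix; defaults to
#'   [synthetic_positions()].
#' @param sample_rate_hz sampling rate (Hz, default 200).
#' @param level_schedule data.frame with columns `label`, `duration_s`,
#'   `dose`, in order.
#' @param slow_freq_hz nominal slow-wave frequency (Hz).
#' @param slow_jitter fractional slow-frequency wander in `[0, 1)`.
#' @param slow_amplitude_uV slow-wave amplitude: a single number, a vector
#'   named by level label, or a channels x levels matrix.
#' @param waveform_skew non-sinusoidality in `[0, 1)`: the sinusoid's phase
#'   is warped monotonically, which sharpens one flank while keeping the
#'   waveform's energy inside the slow band.
#' @param alpha_freq_hz alpha carrier frequency (Hz).
#' @param alpha_amplitude_uV alpha carrier amplitude.
#' @param coupling_plan list of entries, each a list with `channels`
#'   (integer indices or a group name `"frontal"`, `"posterior"`, `"all"`),
#'   `level` (label), `band` (`c(low, high)` Hz), `depth` in `[-1, 1]`, and
#'   `kind` (`"noise"` to modulate every 2 Hz background band inside `band`,
#'   `"sinusoid"` to modulate the alpha carrier).
#' @param broadband_noise_sd_uV background noise scale, defined at 10 Hz;
#'   per-band scale follows a 1/f power profile.
#' @param sensor_noise_sd_uV white sensor noise scale.
#' @param artifact_plan data.frame with columns `channel`, `start_s`,
#'   `end_s`: windows corrupted with a large-amplitude step and flagged in
#'   the artifact mask. `NULL` for none.
#' @param bank the `filter_bank` whose 2 Hz tiling the background follows.
#' @param keep_slow_trace store the generated slow component per channel in
#'   the ground truth (memory-heavy for large cohorts).
#' @param seed master integer seed; all randomness is derived from it through
#'   named substreams, so identical configurations reproduce identical
#'   sessions.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_channels = 32,
                             channel_positions = synthetic_positions(n_channels),
                             sample_rate_hz = 200,
                             level_schedule = data.frame(
                               label = c("Baseline", "Sedation", "UncLow", "UncHigh"),
                               duration_s = 120,
                               dose = c(0, 1, 2, 4)),
                             slow_freq_hz = 1, slow_jitter = 0.1,
                             slow_amplitude_uV = c(Baseline = 10, Sedation = 20,
                                                   UncLow = 40, UncHigh = 60),
                             waveform_skew = 0.25,
                             alpha_freq_hz = 11, alpha_amplitude_uV = 5,
                             coupling_plan = list(),
                             broadband_noise_sd_uV = 2,
                             sensor_noise_sd_uV = 1,
                             artifact_plan = NULL,
                             bank = design_filter_bank(),
                             keep_slow_trace = FALSE,
                             seed = 1L) {
  level_schedule <- as.data.frame(level_schedule)
  if (!nrow(level_schedule)) stop("level_schedule is empty", call. = FALSE)
  if (any(level_schedule$duration_s <= 0))
    stop("level durations must be positive", call. = FALSE)
  if (anyDuplicated(level_schedule$label))
    stop("level labels must be unique", call. = FALSE)
  if (waveform_skew < 0 || waveform_skew >= 1)
    stop("waveform_skew must lie in [0, 1)", call. = FALSE)
  if (slow_jitter < 0 || slow_jitter >= 1)
    stop("slow_jitter must lie in [0, 1)", call. = FALSE)
  for (e in coupling_plan) {
    if (abs(e$depth) > 1)
      stop(sprintf("coupling depth %g outside [-1, 1]: envelope would be negative",
                   e$depth), call. = FALSE)
    if (!e$level %in% level_schedule$label)
      stop(sprintf("coupling plan names unknown level '%s'", e$level), call. = FALSE)
  }
  structure(list(n_channels = n_channels, channel_positions = channel_positions,
                 sample_rate_hz = sample_rate_hz, level_schedule = level_schedule,
                 slow_freq_hz = slow_freq_hz, slow_jitter = slow_jitter,
                 slow_amplitude_uV = slow_amplitude_uV,
                 waveform_skew = waveform_skew,
                 alpha_freq_hz = alpha_freq_hz,
                 alpha_amplitude_uV = alpha_amplitude_uV,
                 coupling_plan = coupling_plan,
                 broadband_noise_sd_uV = broadband_noise_sd_uV,
                 sensor_noise_sd_uV = sensor_noise_sd_uV,
                 artifact_plan = artifact_plan, bank = bank,
                 keep_slow_trace = keep_slow_trace,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf("<synthetic_config> %d channels @ %g Hz, %d levels (%s), %d coupling entries, seed %d\n",
              x$n_channels, x$sample_rate_hz, nrow(x$level_schedule),
              paste(x$level_schedule$label, collapse = ", "),
              length(x$coupling_plan), x$seed))
  invisible(x)
}

resolve_channels <- function(spec, config) {
  if (is.character(spec)) {
    g <- channel_groups(config$channel_positions)
    if (!spec %in% names(g))
      stop(sprintf("unknown channel group '%s'", spec), call. = FALSE)
    g[[spec]]
  } else as.integer(spec)
}

slow_amp_for <- function(config, channel, level) {
  a <- config$slow_amplitude_uV
  li <- match(level, config$level_schedule$label)
  if (is.matrix(a)) return(a[channel, li])
  if (!is.null(names(a)) && level %in% names(a)) return(unname(a[level]))
  if (length(a) == 1) return(unname(a))
  unname(a[li])
}

#' Generate a channel's slow-wave component for one level
#'
#' A sinusoid at the nominal slow frequency, with smooth fractional
#' frequency wander (`slow_jitter`) and a monotone phase warp
#' (`waveform_skew`) that makes the waveform non-sinusoidal while keeping
#' its harmonics low enough to stay essentially inside the slow band. The
#' series has zero time-average over the level; `waveform_skew = 0` and
#' `slow_jitter = 0` give a pure sinusoid.
#'
#' @param config a `synthetic_config`.
#' @param channel channel index.
#' @param level level label (must exist in the schedule).
#' @return numeric voltage series of the level's duration.
#' @export
generate_slow_wave <- function(config, channel, level) {
  li <- match(level, config$level_schedule$label)
  if (is.na(li))
    stop(sprintf("unknown level label '%s'", level), call. = FALSE)
  fs <- config$sample_rate_hz
  n <- as.integer(round(config$level_schedule$duration_s[li] * fs))
  amp <- slow_amp_for(config, channel, level)
  f0 <- config$slow_freq_hz
  jit <- config$slow_jitter
  with_seed(substream_seed(config$seed, "slow", channel, level), {
    tt <- (seq_len(n) - 1) / fs
    if (jit > 0) {
      z <- numeric(n)
      for (k in 1:3)
        z <- z + sin(2 * pi * runif(1, 0.02, 0.08) * tt + runif(1, 0, 2 * pi))
      z <- z / max(abs(z), 1e-12)
      finst <- f0 * (1 + jit * z)
    } else finst <- rep(f0, n)
    theta <- 2 * pi * (cumsum(finst) - finst[1]) / fs +
      if (jit > 0) runif(1, 0, 2 * pi) else 0
    x <- amp * sin(theta + config$waveform_skew * sin(theta))
    x - mean(x)
  })
}

#' Generate one slow-wave-modulated component
#'
#' Realizes the coupling mechanism: a band-limited carrier (Gaussian noise
#' band-limited to `band`, or a sinusoid) whose instantaneous envelope is
#' `base * (1 + depth * s_hat(t))`, where `s_hat` is the slow wave rescaled
#' to `[-1, 1]`. Positive `depth` yields peakmax coupling, negative
#' troughmax, zero an unmodulated component.
#'
#' @param slow slow-wave voltage series.
#' @param band `c(low, high)` passband in Hz (noise carrier).
#' @param depth signed modulation depth in `[-1, 1]`.
#' @param base_sd carrier scale: standard deviation for noise, amplitude for
#'   a sinusoid.
#' @param seed integer seed.
#' @param fs sampling rate (Hz).
#' @param kind `"noise"` or `"sinusoid"`.
#' @param carrier_freq sinusoid frequency (defaults to the band center).
#' @return numeric voltage series the length of `slow`.
#' @export
generate_modulated_component <- function(slow, band, depth, base_sd, seed,
                                         fs = 200, kind = c("noise", "sinusoid"),
                                         carrier_freq = mean(band)) {
  kind <- match.arg(kind)
  if (abs(depth) > 1)
    stop(sprintf("|depth| = %g > 1: modulated envelope would be negative",
                 abs(depth)), call. = FALSE)
  n <- length(slow)
  x <- with_seed(seed, {
    if (kind == "noise") {
      bandlimited_noise(n, fs, band[1], band[2], base_sd)
    } else {
      ph <- runif(1, 0, 2 * pi)
      base_sd * sin(2 * pi * carrier_freq * (seq_len(n) - 1) / fs + ph)
    }
  })
  x * modulation_gain(slow, depth)
}

modulation_gain <- function(slow, depth) {
  m <- max(abs(slow))
  if (m < 1e-12 || depth == 0) return(rep(1, length(slow)))
  1 + depth * slow / m
}

# Exactly band-limited stationary Gaussian noise via a brick-wall DFT mask.
bandlimited_noise <- function(n, fs, low, high, sd_target) {
  w <- rnorm(n)
  X <- fft(w)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)  # fold to [0, fs/2]
  keep <- freq >= low & freq <= high
  X[!keep] <- 0
  x <- Re(fft(X, inverse = TRUE)) / n
  s <- sd(x)
  if (s < 1e-15) return(numeric(n))
  x * (sd_target / s)
}

#' Generate a full synthetic session with ground truth
#'
#' Assembles per channel: the slow wave (concatenated over levels), one
#' independent band-limited Gaussian background per 2 Hz amplitude band with
#' a 1/f power profile and plan-controlled envelope modulation, an alpha
#' carrier on channels named in sinusoid plan entries, white sensor noise,
#' and any planned artifact steps. Annotations carry the level table, a
#' LOC marker at the start of the first level labeled `UncLow` (when
#' present), and the artifact mask.
#'
#' @param config a `synthetic_config`.
#' @return list with elements `recording` (a `session_recording`) and
#'   `truth` (a `ground_truth`: per-(channel, band, level) coupling sign and
#'   depth, channel groups, markers).
#' @export
generate_session <- function(config) {
  sched <- config$level_schedule
  fs <- config$sample_rate_hz
  n_lv <- nrow(sched)
  ns_lv <- as.integer(round(sched$duration_s * fs))
  n <- sum(ns_lv)
  lv_end <- cumsum(ns_lv)
  lv_start <- lv_end - ns_lv + 1L
  bank <- config$bank
  centers <- band_centers(bank)
  n_bands <- length(centers)
  band_lo <- vapply(bank$high_bands, function(b) b$low_hz, numeric(1))
  band_hi <- vapply(bank$high_bands, function(b) b$high_hz, numeric(1))

  # resolve plan to per-(channel, band, level) depth arrays
  depth_noise <- array(0, c(config$n_channels, n_bands, n_lv))
  depth_alpha <- matrix(0, config$n_channels, n_lv)  # sinusoid modulation
  has_alpha <- rep(FALSE, config$n_channels)
  for (e in config$coupling_plan) {
    chs <- resolve_channels(e$channels, config)
    li <- match(e$level, sched$label)
    kind <- e$kind %||% "noise"
    if (kind == "noise") {
      bsel <- which(band_lo >= e$band[1] - 1e-9 & band_hi <= e$band[2] + 1e-9)
      for (ch in chs) depth_noise[ch, bsel, li] <- depth_noise[ch, bsel, li] + e$depth
    } else {
      depth_alpha[chs, li] <- depth_alpha[chs, li] + e$depth
      has_alpha[chs] <- TRUE
    }
  }
  if (any(abs(depth_noise) > 1) || any(abs(depth_alpha) > 1))
    stop("overlapping coupling plan entries push |depth| beyond 1", call. = FALSE)

  sd_band <- config$broadband_noise_sd_uV * (centers / 10)^(-0.5)
  alpha_band <- which(band_lo < config$alpha_freq_hz & config$alpha_freq_hz < band_hi)

  data <- matrix(0, config$n_channels, n)
  slow_traces <- if (config$keep_slow_trace) vector("list", config$n_channels)
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)
  bins <- lapply(seq_len(n_bands), function(b)
    which(freq >= band_lo[b] & freq <= band_hi[b]))
  for (ch in seq_len(config$n_channels)) {
    slow <- unlist(lapply(sched$label, function(lv)
      generate_slow_wave(config, ch, lv)), use.names = FALSE)
    x <- slow
    # per-band background: disjoint frequency bands of one white-noise
    # spectrum are independent, so a single FFT per channel serves all
    # bands; two real band series are recovered per inverse FFT by packing
    # one into the real and one into the imaginary part
    W <- with_seed(substream_seed(config$seed, "bb", ch), fft(rnorm(n)))
    # slow wave rescaled to [-1, 1] per level, shared by all bands
    s_hat <- numeric(n)
    for (li in seq_len(n_lv)) {
      seg <- lv_start[li]:lv_end[li]
      m <- max(abs(slow[seg]))
      s_hat[seg] <- if (m < 1e-12) 0 else slow[seg] / m
    }
    add_band <- function(x, xb, b, sd_emp) {
      # accumulate the scaled band into x in one pass, then correct only
      # the level segments that carry envelope modulation
      sc <- if (sd_emp > 1e-15) sd_band[b] / sd_emp else 0
      x <- x + xb * sc
      for (li in seq_len(n_lv)) {
        d <- depth_noise[ch, b, li]
        if (d != 0) {
          seg <- lv_start[li]:lv_end[li]
          x[seg] <- x[seg] + (sc * d) * (xb[seg] * s_hat[seg])
        }
      }
      x
    }
    for (b in seq(1L, n_bands, by = 2L)) {
      Z <- complex(n)
      Z[bins[[b]]] <- W[bins[[b]]]
      if (b + 1L <= n_bands)
        Z[bins[[b + 1L]]] <- Z[bins[[b + 1L]]] + 1i * W[bins[[b + 1L]]]
      zb <- fft(Z, inverse = TRUE) / n
      # Parseval: the empirical sd of each band series from its spectrum
      sd1 <- sqrt(sum(Mod(W[bins[[b]]])^2) / n^2)
      x <- add_band(x, Re(zb), b, sd1)
      if (b + 1L <= n_bands) {
        sd2 <- sqrt(sum(Mod(W[bins[[b + 1L]]])^2) / n^2)
        x <- add_band(x, Im(zb), b + 1L, sd2)
      }
    }
    if (has_alpha[ch]) {
      ph <- with_seed(substream_seed(config$seed, "alphaph", ch), runif(1, 0, 2 * pi))
      carrier <- config$alpha_amplitude_uV *
        sin(2 * pi * config$alpha_freq_hz * (seq_len(n) - 1) / fs + ph)
      g <- rep(1, n)
      for (li in seq_len(n_lv)) {
        d <- depth_alpha[ch, li]
        if (d != 0) {
          seg <- lv_start[li]:lv_end[li]
          g[seg] <- modulation_gain(slow[seg], d)
        }
      }
      x <- x + carrier * g
    }
    x <- x + with_seed(substream_seed(config$seed, "sensor", ch),
                       rnorm(n) * config$sensor_noise_sd_uV)
    data[ch, ] <- x
    if (config$keep_slow_trace) slow_traces[[ch]] <- slow
  }

  mask <- NULL
  if (!is.null(config$artifact_plan) && nrow(config$artifact_plan)) {
    mask <- matrix(FALSE, config$n_channels, n)
    for (k in seq_len(nrow(config$artifact_plan))) {
      ap <- config$artifact_plan[k, ]
      s0 <- max(1L, as.integer(round(ap$start_s * fs)) + 1L)
      s1 <- min(n, as.integer(round(ap$end_s * fs)))
      data[ap$channel, s0:s1] <- data[ap$channel, s0:s1] + 800
      mask[ap$channel, s0:s1] <- TRUE
    }
  }

  levels_df <- data.frame(label = sched$label,
                          start_s = (lv_start - 1L) / fs,
                          end_s = lv_end / fs,
                          dose = sched$dose)
  loc_time <- if ("UncLow" %in% sched$label)
    levels_df$start_s[match("UncLow", sched$label)] else NA_real_

  rec <- session_recording(data, fs,
                           channel_positions = config$channel_positions,
                           levels = levels_df, loc_time = loc_time,
                           artifact_mask = mask)

  # ground-truth bookkeeping: full (channel x band x level) grid
  grid <- expand.grid(channel = seq_len(config$n_channels),
                      band = seq_len(n_bands), level = seq_len(n_lv))
  depth_total <- depth_noise
  if (length(alpha_band))
    for (li in seq_len(n_lv))
      depth_total[, alpha_band, li] <- depth_total[, alpha_band, li] +
        depth_alpha[, li]
  dep <- depth_total[cbind(grid$channel, grid$band, grid$level)]
  truth_map <- data.frame(channel = grid$channel,
                          band_low = band_lo[grid$band],
                          band_high = band_hi[grid$band],
                          level = sched$label[grid$level],
                          depth = dep, sign = sign(dep))
  truth <- structure(list(map = truth_map,
                          groups = channel_groups(config$channel_positions),
                          loc_time = loc_time, roc_time = NA_real_,
                          burst_suppression = character(0),
                          slow_trace = if (config$keep_slow_trace) slow_traces),
                     class = "ground_truth")
  list(recording = rec, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  nz <- x$map[x$map$depth != 0, ]
  cat(sprintf("<ground_truth> %d (channel, band, level) cells, %d with planned coupling\n",
              nrow(x$map), nrow(nz)))
  if (nrow(nz)) {
    agg <- unique(nz[, c("level", "sign")])
    for (i in seq_len(nrow(agg)))
      cat(sprintf("  %s: %s coupling present\n", agg$level[i],
                  if (agg$sign[i] > 0) "peakmax" else "troughmax"))
  }
  invisible(x)
}

#' Write ground truth to JSON
#' @param truth a `ground_truth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(list(map = truth$map, groups = truth$groups,
                            loc_time = truth$loc_time,
                            burst_suppression = truth$burst_suppression),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Named synthetic presets
#'
#' Three standard validation scenarios:
#' \describe{
#'   \item{`propofol`}{frontal alpha troughmax during Sedation, posterior
#'     broadband peakmax at Unconscious Low Dose, global broadband peakmax
#'     (plus frontal alpha peakmax) at Unconscious High Dose.}
#'   \item{`null`}{no coupling anywhere: every envelope is independent of
#'     the slow wave.}
#'   \item{`broadband-only`}{equal-depth broadband peakmax on all channels
#'     at every drug level; used to validate recovery of a single broadband
#'     principal frequency mode.}
#' }
#'
#' @param name preset name.
#' @param n_channels channels per subject.
#' @param level_duration_s seconds per dose level.
#' @param seed master seed.
#' @param ... further arguments passed to [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
synthetic_preset <- function(name = c("propofol", "null", "broadband-only"),
                             n_channels = 32, level_duration_s = 120,
                             seed = 1L, ...) {
  name <- match.arg(name)
  plan <- switch(name,
    "propofol" = list(
      list(channels = "frontal", level = "Sedation", band = c(8, 14),
           depth = -0.6, kind = "sinusoid"),
      list(channels = "posterior", level = "UncLow", band = c(4, 50),
           depth = 0.6, kind = "noise"),
      list(channels = "all", level = "UncHigh", band = c(4, 50),
           depth = 0.7, kind = "noise"),
      list(channels = "frontal", level = "UncHigh", band = c(8, 14),
           depth = 0.6, kind = "sinusoid")),
    "null" = list(),
    "broadband-only" = list(
      list(channels = "all", level = "Sedation", band = c(4, 50),
           depth = 0.6, kind = "noise"),
      list(channels = "all", level = "UncLow", band = c(4, 50),
           depth = 0.6, kind = "noise"),
      list(channels = "all", level = "UncHigh", band = c(4, 50),
           depth = 0.6, kind = "noise")))
  synthetic_config(n_channels = n_channels,
                   level_schedule = data.frame(
                     label = c("Baseline", "Sedation", "UncLow", "UncHigh"),
                     duration_s = level_duration_s,
                     dose = c(0, 1, 2, 4)),
                   coupling_plan = plan, seed = seed, ...)
}
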