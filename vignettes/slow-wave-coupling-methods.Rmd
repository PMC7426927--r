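---
title: "Slow-wave cross-frequency coupling and principal frequency modes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow-wave cross-frequency coupling and principal frequency modes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowmod)
```

## The problem

Under propofol anesthesia the EEG develops a large slow wave (0.1–4 Hz),
understood as a scalp-level surrogate of alternating cortical up-states
(active, depolarized) and down-states (silent, hyperpolarized). When a
cortical region's population activity becomes entrained to these states,
its *broadband* high-frequency power waxes and wanes with the slow wave.
`slowmod` quantifies this entrainment, compresses its frequency structure
into a small number of principal modes, and tracks where on the head (or in
a set of user-supplied source locations) each mode is expressed as the
anesthetic dose is stepped up.

## The coupling metric

For one location, one amplitude band and one stretch of data, the metric is
the Pearson correlation between the slow-band voltage $V$ and the
instantaneous amplitude $A$ of the band-limited high-frequency signal:

$$ r = \frac{V^\top A}{\sqrt{V^\top V}\,\sqrt{A^\top A}} $$

with two deliberate asymmetries in the centering:

* $A$ (the envelope, from the magnitude of the analytic signal) is centered
  by subtracting its mean **within each 30 s epoch**;
* $V$ is **not** centered: its expected value is already zero, and its sign
  carries the up/down-state semantics. Consumers of `SlowSeries` must not
  center it.

Positive $r$ means the envelope is largest at the slow-wave peak
("peakmax"), negative at the trough ("troughmax"). A correlation against
the raw slow *voltage* — rather than against an estimated slow-wave *phase*
— is used because the anesthetic slow wave is irregular in shape and
frequency, and phase estimates inherit that irregularity. The package's
tests make this concrete: with a skewed (non-sinusoidal but strictly
band-limited) slow wave, mean-vector preferred phases shift systematically
by several tenths of a radian, while the sign of $r$ is unchanged across
skew levels 0, 0.25 and 0.5 in 100 of 100 simulated components.

**Averaging by stacking.** To average over epochs, electrodes or source
locations, the segments are concatenated ("stacked vertically") into one
$V$ and one $A$ vector and the correlation is evaluated once. This
estimates the covariance and the two standard deviations over the whole
stack before normalizing; it is *not* the mean of per-segment correlations,
and the two genuinely differ on heteroscedastic data (segments with larger
slow waves carry more weight). `stacked_correlation()` implements the
contract; every aggregated quantity in the package (modulograms,
topographies, region coupling) reduces to it.

**Undefined correlations.** A zero-variance $V$ or centered $A$ makes $r$
undefined; the package returns `NA` with a warning rather than 0, because 0
would masquerade as "no coupling".

## Preprocessing

* **Filter bank.** One slow band (0.1–4 Hz) plus 23 amplitude bands tiling
  4–50 Hz in 2 Hz steps with 1 Hz transitions, and a wider 8–16 Hz summary
  band used for topographies (filtered directly at 8–16 Hz, not assembled
  from the 2 Hz bands).
* **FIR design.** Windowed-sinc (Hamming) kernels; order
  $\lceil 3.3/\Delta f_{norm}\rceil$ rounded to even, the standard
  conservative choice for a ~53 dB stopband. Zero phase is realized by
  applying the kernel forwards and backwards; in this package that is
  computed exactly in the frequency domain by multiplying the zero-padded
  spectrum with the squared magnitude response (the transform of the
  kernel's autocorrelation), which is identical to linear-convolution
  `filtfilt` and far cheaper at session length. Squared responses below
  $10^{-10}$ of their peak (deep in the stopband) are truncated to zero.
* **Slow-band transition.** The slow band uses a 0.5 Hz transition (6.6 s
  kernel at 200 Hz). A 1 Hz transition, as used for the amplitude bands,
  would leak DC through the 0.1 Hz edge; a much narrower one would consume
  too much of each recording in filter edges.
* **Edge handling.** Filtering is performed on the whole session, so epochs
  interior to the recording carry no filter edge artifacts; samples within
  half the slow-band kernel span of the recording boundary are excluded
  from all correlations.
* **Downsampling** (for high-rate input) decimates after the bandpass;
  the bandpass itself removes everything above the target Nyquist.
* **Laplacian reference.** Each channel minus the mean of its first nearest
  neighbors, applied after filtering (the two operations are linear and
  commute; the test suite asserts the commutation). "First nearest
  neighbors" is made precise by a mutual-closeness rule: $j$ neighbors $i$
  when $\|i-j\| \le 1.25\times$ the distance from $i$ to its single nearest
  channel, symmetrized by union. The rule is deterministic,
  montage-agnostic, and on a regular grid admits exactly the lattice
  neighbors.
* **Artifacts and bridges.** Visual artifact rejection is replaced by a
  testable rule — absolute amplitude above 500 µV or a flat second marks a
  window — and bridged electrodes by a whole-session correlation threshold
  (> 0.999 drops the later channel of the pair).
* **Levels and epochs.** The four levels of interest follow the stepped-dose
  protocol rules (`define_levels()`): Baseline before drug onset, Sedation
  the level before the one containing LOC (absent when LOC falls in the
  first drug level), Unconscious Low Dose the first full level after LOC,
  Unconscious High Dose the highest-dose level or the level before burst
  suppression. Epochs are placed earliest-first, disjoint, skipping the
  artifact mask — a deterministic stand-in for an unspecified manual
  choice.

## Principal frequency modes

Level-based coupling values are assembled into $A(f, i)$ — rows the 23
amplitude bands, columns all (subject, level, location) triples — and
decomposed by **non-centered PCA**, i.e. a plain SVD $A = USV^\top$ with no
mean subtraction. Non-centering is a scientific choice, not a shortcut: the
origin (no coupling at any frequency) is the meaningful reference point,
and subtracting the grand mean coupling profile would destroy the mapping
of positive values to peakmax. The test suite verifies the distinction by
showing mode 1 responds to a constant coupling offset that centered PCA
would remove.

Each mode is sign-fixed so that its largest-magnitude element is positive
(ties broken toward the lowest frequency); this is the only reading of the
sign convention under which a flip can ever be required, and it preserves
peakmax/troughmax semantics. Mode $j$ explains
$100\, S_{jj}^2 / \sum_k S_{kk}^2$ percent of the total energy.

Location-resolved patterns (source locations or regions; the package treats
them as opaque "locations") are projected onto the sensor-derived modes,
$P = U^\top A^{src}$; the first row of $P$ is the broadband coupling score.
Region coupling stacks all epochs of all locations in the region into one
$V$/$A$ pair per (region, band, level). Uncertainty across subjects is
quantified by a bootstrap over subjects (default 2000 resamples, seeded);
subjects missing a level (e.g. no Sedation period) are simply absent from
that cell's mean, mirroring the 8-of-10 accounting such cohorts produce.
The interval uses Hesterberg's *expanded percentile* quantile levels,
$\Phi(-\sqrt{n/(n-1)}\,t_{0.975,\,n-1})$, rather than the plain 2.5/97.5
percentiles: at ~10 subjects the plain percentile interval covers a known
mean only about 91% of the time, while the expanded interval restores ~95%
coverage — verified by simulation (500 cohorts) in the acceptance suite.
`method = "percentile"` is available for the uncorrected interval.

## The synthetic session generator

Because the human EEG this analysis was designed for is not publicly
deposited, the package ships a generator whose sessions have *fully known*
coupling structure, so the entire chain can be validated end to end.

Each channel is a sum of:

* a **slow wave**: a sinusoid at nominally 1 Hz with smooth ±10% frequency
  wander and a monotone phase warp `waveform_skew` $\in [0,1)$,
  $\sin(\theta + s\,\sin\theta)$, which sharpens one flank while keeping
  harmonic energy negligible above 4 Hz (< 1% of power at $s = 0.5$;
  asserted in tests). Amplitude grows with dose (10/20/40/60 µV across the
  four default levels). Slow waves are generated independently per channel;
  real slow waves are spatially coherent traveling waves, but independence
  is required for a nearest-neighbor Laplacian to leave slow-band content
  in place, and the coupling metric never uses cross-channel slow-wave
  structure.
* a **broadband background**: one independent band-limited Gaussian noise
  per 2 Hz amplitude band (from disjoint frequency bands of a single
  white-noise spectrum, hence exactly independent), with a $1/f$ power
  profile anchored at 2 µV at 10 Hz. Per-band independence is what makes
  per-band modulation depth directly controllable.
* an **alpha carrier** (11 Hz sinusoid, 5 µV) on channels named in
  sinusoid-type plan entries. 11 Hz places the carrier strictly inside the
  10–12 Hz analysis band rather than on a band edge.
* **white sensor noise** (1 µV) and optional large-amplitude artifact steps
  with a matching mask entry.

Coupling is imposed by multiplying a carrier by $1 + d\,\hat s(t)$, where
$\hat s$ is the channel's slow wave rescaled to $[-1, 1]$ per level and
$d \in [-1, 1]$ the planned depth (positive = peakmax). The generator
rejects $|d| > 1$, which would make an envelope negative. Every random
draw flows from one master seed through named substreams, so identical
configurations reproduce identical sessions byte for byte.

The `propofol` preset encodes the study's spatial progression: frontal
alpha troughmax during Sedation ($d = -0.6$), posterior-only broadband
peakmax at Unconscious Low Dose ($+0.6$), and global broadband peakmax
(plus frontal alpha peakmax) at Unconscious High Dose ($+0.7$). `null` has
no coupling anywhere; `broadband-only` couples all 23 bands at equal depth
on all channels, the scenario under which the first principal mode should
be flat, all-positive and dominant.

**What the generator does not emulate** — and therefore what passing tests
do not establish about real data: spatially coherent/traveling slow waves,
burst suppression, realistic artifact physics, volume conduction and
source-localization geometry, non-stationarity within a level, and any
biophysical (neural-mass) dynamics. The generator validates the *analysis
chain*, not the neuroscience.

**Amplitude scales** are order-of-magnitude EEG values (tens of µV slow, a
few µV alpha, ~1 µV sensor noise); they are exposed in
`synthetic_config()` and not claimed to be calibrated to any particular
recording system.

## Numerical choices

* FFT lengths are padded to 5-smooth sizes chosen to avoid long runs of
  factor 2, which R's mixed-radix FFT handles slowly.
* The analytic signal uses the standard DFT half-spectrum mask (DC and
  Nyquist bins kept at unit weight).
* Envelope/window sums are accumulated as per-(channel, band, window)
  partial sums $V^\top A$, $V^\top V$, $A^\top A$; any stacked correlation
  is then a ratio of sums over a subset, which makes the one-pass pipeline
  engine and the standalone operations agree to near machine precision
  (asserted at $10^{-12}$).
* Windows overlapping a channel's artifact mask are dropped from that
  channel's stack (omission, not imputation); windows with no clean channel
  are reported `NA`.
* Zero-variance guards return `NA` with a warning, never silent zeros.

## Problem sizes used by the test and acceptance suites

The validation cohort is 6 subjects × 32 channels × 4 levels × 2 minutes
per level at 200 samples/s, with 4 × 30 s epochs tiling each level (the
10 × 30 s level-based scope of long recordings is exercised separately on
12-minute synthetic levels, where `select_epochs()` defaults to n = 10).
The state-recovery study repeats the full pipeline on 10 independent
cohorts; waveform-shape robustness uses 100 seeds × 3 skew levels; the
bootstrap coverage check uses 500 simulated 10-subject cohorts. These sizes
were chosen so a complete cohort analysis remains a sub-minute computation
on a single CPU while every recovered quantity (sign maps, mode structure,
projections, coverage) is estimated with comfortable margins.

## Known limitations

* The package consumes pre-localized band-limited time series for source
  analyses; it performs no forward modelling or inverse estimation.
* Readers are provided for the plain-text interchange container and CSV
  annotation tables; proprietary EEG container formats are out of scope.
* No statistical significance testing of individual coupling values is
  offered (none is defined for this metric here); uncertainty is reported
  only at the level of subject bootstrap CIs on mode projections.
* `detect_artifacts()` and `detect_bridged_channels()` are deliberately
  simple, testable heuristics, not replacements for careful data review.
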