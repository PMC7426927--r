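# slowmod

Signed cross-frequency coupling between the anesthetic slow wave and
high-frequency EEG amplitude, and its decomposition into principal
frequency modes.

## What it is for

Under propofol, the EEG develops a large 0.1–4 Hz slow wave — a scalp-level
surrogate of cortical up/down-states. When a region's population activity
becomes entrained to those states, its broadband high-frequency power rises
and falls with the slow wave. `slowmod` is for researchers who want to
quantify that entrainment across frequency, space, and anesthetic depth:

* **Coupling metric** — the Pearson correlation between the slow-band
  voltage `V` and the instantaneous amplitude `A` of each 2 Hz band between
  4 and 50 Hz,

  `r = V'A / (sqrt(V'V) * sqrt(A'A))`,

  with `A` centered per 30 s epoch and `V` left uncentered. Positive `r`:
  amplitude peaks at the slow-wave peak (*peakmax*); negative: at the
  trough (*troughmax*). Averages over epochs, electrodes, or source
  locations are computed by stacking the segments vertically into one
  `V`/`A` pair, never by averaging per-segment correlations.
* **Preprocessing** — zero-phase FIR filter bank (0.1–4 Hz slow band, 23
  amplitude bands tiling 4–50 Hz), downsampling, first-nearest-neighbor
  surface Laplacian, threshold-based artifact masks, bridged-channel
  detection, stepped-dose level definitions and artifact-free epoch
  selection.
* **Principal frequency modes** — non-centered PCA (`A = USV'`, no mean
  subtraction) of the aggregate coupling-by-frequency matrix over all
  (subject, level, electrode) columns; percent energy per mode; projection
  of location-resolved coupling patterns onto the sensor modes
  (`P = U'A_source`, first row = broadband coupling score); percentile
  bootstrap CIs across subjects.
* **Synthetic sessions** — a stepped-dose EEG generator with fully known,
  per-(channel, band, level) coupling signs and depths, so the entire chain
  is validated end to end against ground truth.

## Worked example

Simulate a 6-subject cohort with the study-like coupling progression
(frontal alpha troughmax during sedation, posterior broadband peakmax at
low unconscious dose, global broadband peakmax at high dose) and run the
full pipeline:

```r
library(slowmod)
res <- run_pipeline(run_config(preset = "propofol", n_subjects = 6,
                               n_channels = 32, seed = 42))
res
#> <cfc_pipeline> preset 'propofol': 6 subjects x 32 channels, seed 42
#>   aggregate matrix: 23 bands x 768 observations
#>   mode energies: 88.7%, 1.6%, 0.6%
#>   mean mode-1 projection Baseline  frontal   -0.007
#>   mean mode-1 projection Sedation  frontal   -0.041
#>   mean mode-1 projection UncHigh   frontal    0.953
#>   mean mode-1 projection UncLow    frontal   -0.006
#>   mean mode-1 projection Baseline  posterior  0.011
#>   mean mode-1 projection Sedation  posterior -0.000
#>   mean mode-1 projection UncHigh   posterior  0.963
#>   mean mode-1 projection UncLow    posterior  0.885
```

Reading the output: the first principal frequency mode (all-positive across
the 23 bands, ~89% of total energy) is the broadband coupling pattern. Its
projection is near zero everywhere at Baseline and Sedation, strongly
positive over posterior channels only at Unconscious Low Dose (~0.89), and
strongly positive over both regions at Unconscious High Dose (~0.95) — the
two distinct unconscious states the generator planted, recovered from the
raw simulated voltages. `res$ci` holds subject-bootstrap 95% intervals for
each (level, region) mean, `res$fit` the mode decomposition (with `print`,
`summary`, `coef`, `predict`, `plot`, `screeplot` methods), and
`res$records` the tidy per-(subject, level, channel, band) coupling table.

Individual stages are exported on their own (`design_filter_bank()`,
`zero_phase_bandpass()`, `laplacian_reference()`, `select_epochs()`,
`cfc_correlation()`, `stacked_correlation()`, `compute_modulogram()`,
`level_topography()`, `region_coupling()`, `assemble_aggregate()`,
`cfc_modes()`, `bootstrap_subject_ci()`, ...), and a thin command-line
front end ships in `inst/cli/slowmod`.

## Method notes

See the methods vignette
(`vignettes/slow-wave-coupling-methods.Rmd`) for the model, the
preprocessing contracts, the generator's design and its deliberate
unrealisms, and all numerical choices.
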