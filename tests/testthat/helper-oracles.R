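# Independent brute-force oracles used to freeze expected values.  These
# deliberately avoid the package's own code paths.

# Direct evaluation of the signed-correlation metric on raw vectors:
# envelope centered by its mean, slow voltage left as-is.
oracle_corr <- function(V, A_raw) {
  A <- A_raw - mean(A_raw)
  sum(V * A) / (sqrt(sum(V^2)) * sqrt(sum(A^2)))
}

# Stacked variant: per-segment envelope centering, then one evaluation on
# the concatenation.
oracle_stacked <- function(pairs) {
  V <- unlist(lapply(pairs, `[[`, "slow"))
  A <- unlist(lapply(pairs, function(p) p$env - mean(p$env)))
  sum(V * A) / (sqrt(sum(V^2)) * sqrt(sum(A^2)))
}

# Fraction of periodogram power above a frequency threshold.
power_fraction_above <- function(x, fs, f0) {
  n <- length(x)
  p <- Mod(fft(x))^2
  freq <- (seq_len(n) - 1) * fs / n
  freq <- pmin(freq, fs - freq)
  sum(p[freq > f0]) / sum(p)
}

within_rec <- function(rec, newdata) { rec$data <- newdata; rec }

with_seed_local <- function(seed, expr) { set.seed(seed); expr }

# A pure zero-mean sinusoidal slow wave over whole periods.
mk_slow <- function(f = 1, amp = 50, dur = 30, fs = 200) {
  amp * sin(2 * pi * f * (seq_len(dur * fs) - 1) / fs)
}

# Approximate null standard deviation of the coupling correlation between
# two independent autocorrelated series: Var(r) ~ (1/n) * sum_tau
# rho_V(tau) * rho_A(tau) (Bartlett).  Used to set conservative null bands.
null_r_sd <- function(V, A, max_lag_s = 5, fs = 200) {
  L <- min(length(V) - 1, round(max_lag_s * fs))
  aV <- stats::acf(V, lag.max = L, plot = FALSE)$acf[, 1, 1]
  aA <- stats::acf(A, lag.max = L, plot = FALSE)$acf[, 1, 1]
  s <- sum(aV * aA) * 2 - aV[1] * aA[1]
  sqrt(max(s, 1) / length(V))
}
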