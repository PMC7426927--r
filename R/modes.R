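#' Assemble the aggregate coupling matrix
#'
#' Combines level-based coupling records into the frequency x observation
#' matrix `A(f, i)`: rows are the amplitude bands in frequency order,
#' columns are (subject, level, location) triples. Subjects lacking a level
#' (e.g. no Sedation period) simply contribute no columns for it.
#'
#' @param records data.frame with columns `subject`, `level`, `location`,
#'   `band_low`, `band_high`, `r` (level-based scope, one row per band per
#'   triple).
#' @param levels level labels to include, in order.
#' @return numeric matrix of class `aggregate_coupling` with
#'   `band_low`/`band_high` attributes and an `index` attribute (data.frame
#'   of the column triples).
#' @export
assemble_aggregate <- function(records,
                               levels = c("Baseline", "Sedation", "UncLow", "UncHigh")) {
  records <- records[records$level %in% levels, , drop = FALSE]
  if (!nrow(records)) stop("no records for the requested levels", call. = FALSE)
  bands <- unique(records[, c("band_low", "band_high")])
  bands <- bands[order(bands$band_low), , drop = FALSE]
  nb <- nrow(bands)
  band_key <- paste(records$band_low, records$band_high)
  band_pos <- match(band_key, paste(bands$band_low, bands$band_high))
  trip <- paste(records$subject, records$level, records$location, sep = "|")
  cols <- unique(data.frame(subject = records$subject, level = records$level,
                            location = records$location, key = trip,
                            stringsAsFactors = FALSE))
  # order columns by level (given order), then subject, then location
  cols <- cols[order(match(cols$level, levels), cols$subject, cols$location), ]
  A <- matrix(NA_real_, nb, nrow(cols),
              dimnames = list(paste0(bands$band_low, "-", bands$band_high),
                              cols$key))
  cpos <- match(trip, cols$key)
  for (k in seq_len(nrow(records))) {
    if (!is.na(A[band_pos[k], cpos[k]]))
      stop(sprintf("duplicate record for (%s, %s, %s) band %s-%s Hz",
                   records$subject[k], records$level[k], records$location[k],
                   records$band_low[k], records$band_high[k]), call. = FALSE)
    A[band_pos[k], cpos[k]] <- records$r[k]
  }
  bad <- which(colSums(is.na(A)) > 0)
  if (length(bad))
    stop(sprintf("incomplete frequency coverage for column(s): %s",
                 paste(colnames(A)[head(bad, 5)], collapse = ", ")), call. = FALSE)
  structure(A, band_low = bands$band_low, band_high = bands$band_high,
            index = cols[, c("subject", "level", "location")],
            class = c("aggregate_coupling", "matrix", "array"))
}

#' Principal frequency modes by non-centered PCA
#'
#' Fits the singular value decomposition `A = U S V'` of the aggregate
#' coupling matrix without any mean subtraction, so the decomposition
#' partitions total energy (squared coupling) rather than variance: the
#' origin — no coupling at any frequency — keeps its meaning, and a mode's
#' sign pattern keeps the peakmax/troughmax semantics of the coupling
#' values. Each mode (column of `U`) is flipped as necessary so that its
#' largest-magnitude element is positive (ties broken toward the lowest
#' frequency), preserving positive = peakmax.
#'
#' @param A an `aggregate_coupling` matrix (or any frequency x observation
#'   numeric matrix).
#' @return an object of class `cfc_modes` with elements `modes` (U,
#'   orthonormal columns), `singular_values`, `right_factors` (V),
#'   `percent_energy`, and the frequency/column metadata.
#' @seealso [percent_energy()], [predict.cfc_modes()], [screeplot.cfc_modes()]
#' @export
cfc_modes <- function(A) {
  A <- as.matrix(A)
  if (!length(A) || any(!is.finite(A)))
    stop("A must be a non-empty matrix with no missing entries", call. = FALSE)
  s <- svd(A)
  U <- s$u; V <- s$v; d <- s$d
  for (j in seq_along(d)) {
    i_star <- which.max(abs(U[, j]))
    if (U[i_star, j] < 0) {
      U[, j] <- -U[, j]
      V[, j] <- -V[, j]
    }
  }
  pe <- 100 * d^2 / sum(d^2)
  rownames(U) <- rownames(A)
  structure(list(modes = U, singular_values = d, right_factors = V,
                 percent_energy = pe,
                 band_low = attr(A, "band_low"),
                 band_high = attr(A, "band_high"),
                 index = attr(A, "index"), n_obs = ncol(A)),
            class = "cfc_modes")
}

#' @export
print.cfc_modes <- function(x, ...) {
  k <- min(3, length(x$singular_values))
  cat(sprintf("<cfc_modes> %d frequency bands, %d observations\n",
              nrow(x$modes), x$n_obs))
  cat(sprintf("  percent energy: %s%s\n",
              paste(sprintf("mode %d = %.1f%%", seq_len(k),
                            x$percent_energy[seq_len(k)]), collapse = ", "),
              if (length(x$singular_values) > k) ", ..." else ""))
  invisible(x)
}

#' @export
summary.cfc_modes <- function(object, n_modes = 3, ...) {
  k <- min(n_modes, length(object$singular_values))
  m1 <- object$modes[, 1]
  out <- list(percent_energy = object$percent_energy[seq_len(k)],
              first_mode = m1,
              first_mode_all_positive = all(m1 > 0),
              first_mode_cv = sd(m1) / mean(m1))
  class(out) <- "summary.cfc_modes"
  out
}

#' @export
print.summary.cfc_modes <- function(x, ...) {
  cat("Principal frequency modes (non-centered PCA)\n")
  cat(sprintf("  energy: %s\n",
              paste(sprintf("%.1f%%", x$percent_energy), collapse = ", ")))
  cat(sprintf("  first mode: all entries positive = %s, CV = %.3f\n",
              x$first_mode_all_positive, x$first_mode_cv))
  invisible(x)
}

#' @export
coef.cfc_modes <- function(object, n_modes = ncol(object$modes), ...) {
  object$modes[, seq_len(n_modes), drop = FALSE]
}

#' Percent of total energy captured by one mode
#'
#' `100 * S(j,j)^2 / sum_k S(k,k)^2`.
#'
#' @param decomp a `cfc_modes` object.
#' @param j mode index.
#' @return percentage in `[0, 100]`.
#' @export
percent_energy <- function(decomp, j) {
  if (j < 1 || j > length(decomp$singular_values))
    stop(sprintf("mode index %s out of range 1..%d", j,
                 length(decomp$singular_values)), call. = FALSE)
  decomp$percent_energy[j]
}

#' Project coupling patterns onto the principal frequency modes
#'
#' `P = U' A_source`: row j of `P` is the projection of each observation's
#' coupling-by-frequency pattern onto mode j. With the sensor-derived modes
#' applied to location-resolved (source/region) patterns, the first row is
#' the broadband coupling score: positive = broadband peakmax, negative =
#' broadband troughmax.
#'
#' @param object a `cfc_modes` fit.
#' @param newdata frequency x observation matrix on the same frequency axis
#'   (same row count and, when named, same row order).
#' @param n_modes number of mode rows to return (default all).
#' @param ... unused.
#' @return matrix of class `cfc_projection` (modes x observations) with the
#'   column `index` attribute of `newdata` carried over.
#' @export
predict.cfc_modes <- function(object, newdata, n_modes = ncol(object$modes), ...) {
  B <- as.matrix(newdata)
  if (nrow(B) != nrow(object$modes))
    stop(sprintf("frequency-axis mismatch: modes have %d bands, newdata %d rows",
                 nrow(object$modes), nrow(B)), call. = FALSE)
  if (!is.null(rownames(B)) && !is.null(rownames(object$modes)) &&
      !identical(rownames(B), rownames(object$modes)))
    stop("frequency-axis mismatch: row (band) labels differ", call. = FALSE)
  P <- t(object$modes[, seq_len(n_modes), drop = FALSE]) %*% B
  rownames(P) <- paste0("mode", seq_len(n_modes))
  structure(P, index = attr(newdata, "index"),
            class = c("cfc_projection", "matrix", "array"))
}

#' @rdname predict.cfc_modes
#' @param decomp a `cfc_modes` fit.
#' @param A_source frequency x observation matrix of location-resolved
#'   coupling patterns.
#' @export
project_onto_modes <- function(decomp, A_source, n_modes = ncol(decomp$modes)) {
  predict(decomp, A_source, n_modes = n_modes)
}

#' @export
plot.cfc_modes <- function(x, n_modes = 3, ...) {
  k <- min(n_modes, ncol(x$modes))
  fc <- if (!is.null(x$band_low)) (x$band_low + x$band_high) / 2
        else seq_len(nrow(x$modes))
  graphics::matplot(fc, x$modes[, seq_len(k), drop = FALSE], type = "b",
                    pch = 16, lty = 1, xlab = "amplitude band center (Hz)",
                    ylab = "mode coefficient", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright",
                   sprintf("mode %d (%.1f%%)", seq_len(k), x$percent_energy[seq_len(k)]),
                   col = seq_len(k), pch = 16, bty = "n")
  invisible(x)
}

#' @importFrom stats screeplot
#' @export
screeplot.cfc_modes <- function(x, n_modes = length(x$singular_values), ...) {
  k <- min(n_modes, length(x$singular_values))
  graphics::barplot(x$percent_energy[seq_len(k)],
                    names.arg = seq_len(k), xlab = "mode",
                    ylab = "percent energy", ...)
  invisible(x)
}

#' Subject-level bootstrap confidence intervals for mode projections
#'
#' Bootstrap across subjects: subjects are resampled with replacement
#' `n_boot` times; for each resample the per-cell (level x region) mean
#' projection is recomputed over the drawn subjects (subjects missing a
#' cell, e.g. no Sedation, are skipped in that cell's mean), and quantiles
#' of the resampled means form the 95% interval. By default the quantile
#' levels are the *expanded* percentile levels
#' `pnorm(-sqrt(n/(n-1)) * qt(0.975, n-1))` (Hesterberg's small-sample
#' correction): at cohort sizes of ~10 subjects the plain 2.5/97.5
#' percentile interval covers a known mean only ~91% of the time, while the
#' expanded interval restores ~95% coverage. `method = "percentile"` gives
#' the uncorrected interval.
#'
#' @param projections data.frame with columns `subject`, `level`,
#'   `location`, `value` (typically first-mode projections).
#' @param n_boot number of bootstrap resamples (default 2000).
#' @param seed integer seed; the result is deterministic given it.
#' @param method `"expanded"` (default) or `"percentile"`.
#' @return data.frame with columns `level`, `location`, `mean`, `lower`,
#'   `upper`, `n_subjects`, plus `n_boot`/`seed` attributes.
#' @export
bootstrap_subject_ci <- function(projections, n_boot = 2000, seed = 1L,
                                 method = c("expanded", "percentile")) {
  method <- match.arg(method)
  subjects <- unique(projections$subject)
  if (length(subjects) < 2)
    stop("bootstrap across subjects needs at least 2 subjects", call. = FALSE)
  cells <- unique(projections[, c("level", "location")])
  M <- matrix(NA_real_, length(subjects), nrow(cells))
  for (k in seq_len(nrow(projections))) {
    i <- match(projections$subject[k], subjects)
    j <- which(cells$level == projections$level[k] &
               cells$location == projections$location[k])
    M[i, j] <- projections$value[k]
  }
  obs_mean <- colMeans(M, na.rm = TRUE)
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      draw <- sample.int(length(subjects), replace = TRUE)
      colMeans(M[draw, , drop = FALSE], na.rm = TRUE)
    }, numeric(nrow(cells)))
  })
  boot <- matrix(draws, nrow = nrow(cells))  # cells x n_boot
  alpha <- if (method == "expanded") {
    n_sub <- length(subjects)
    pnorm(-sqrt(n_sub / (n_sub - 1)) * qt(0.975, n_sub - 1))
  } else 0.025
  qs <- apply(boot, 1, quantile, probs = c(alpha, 1 - alpha), na.rm = TRUE)
  out <- data.frame(level = cells$level, location = cells$location,
                    mean = obs_mean, lower = unname(qs[1, ]),
                    upper = unname(qs[2, ]),
                    n_subjects = colSums(!is.na(M)),
                    row.names = NULL)
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- seed
  out
}
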