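#' Pipeline run configuration
#'
#' Bundles every knob of a full synthetic-cohort run: the preset scenario,
#' cohort size, montage size, level duration, epoch selection, referencing,
#' mode and bootstrap settings, output directory and the single master seed
#' from which all randomness is derived.
#'
#' @param preset synthetic scenario name (see [synthetic_preset()]).
#' @param n_subjects cohort size.
#' @param n_channels channels per subject.
#' @param level_duration_s seconds per dose level.
#' @param epochs_per_level epochs selected per level (the default 4 tiles a
#'   2-minute level exactly; use 10 with levels of 300 s or more).
#' @param epoch_s epoch duration, seconds.
#' @param bank a `filter_bank`.
#' @param reference `"laplacian"` or `"none"`.
#' @param n_modes modes retained for reporting.
#' @param n_boot bootstrap resamples for subject CIs.
#' @param out output directory for CSV/JSON results, or `NULL` to skip
#'   writing.
#' @param seed master integer seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(preset = "propofol", n_subjects = 6, n_channels = 32,
                       level_duration_s = 120, epochs_per_level = 4,
                       epoch_s = 30, bank = design_filter_bank(),
                       reference = c("laplacian", "none"), n_modes = 3,
                       n_boot = 2000, out = NULL, seed = 1L) {
  reference <- match.arg(reference)
  if (epochs_per_level * epoch_s > level_duration_s)
    stop(sprintf("%d x %g s epochs do not fit in %g s levels",
                 epochs_per_level, epoch_s, level_duration_s), call. = FALSE)
  structure(list(preset = preset, n_subjects = n_subjects,
                 n_channels = n_channels, level_duration_s = level_duration_s,
                 epochs_per_level = epochs_per_level, epoch_s = epoch_s,
                 bank = bank, reference = reference, n_modes = n_modes,
                 n_boot = n_boot, out = out, seed = as.integer(seed)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' generate -> preprocess (artifact mask, bridged-channel check, Laplacian
#' reference) -> epoch selection -> coupling (level-based records per
#' channel/band, region-stacked records, summary-band topography) ->
#' non-centered PCA of the sensor aggregate matrix -> projection of the
#' region patterns onto the modes -> subject bootstrap CIs, with per-stage
#' error context and (optionally) CSV/JSON outputs plus a manifest that
#' makes the run reproducible bit for bit.
#'
#' @param config a `run_config`.
#' @return an object of class `cfc_pipeline`: list with `records`,
#'   `regions`, `summary_topography`, `truth` (per-subject ground-truth
#'   maps), `A` (sensor aggregate matrix), `fit` (`cfc_modes`),
#'   `projections` (first-mode data.frame), `ci`, and `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  levels4 <- c("Baseline", "Sedation", "UncLow", "UncHigh")
  all_records <- list(); all_regions <- list(); all_topo <- list()
  truths <- list()
  for (s in seq_len(config$n_subjects)) {
    sid <- sprintf("s%02d", s)
    sess <- stage("simulate", {
      cfg <- synthetic_preset(config$preset, n_channels = config$n_channels,
                              level_duration_s = config$level_duration_s,
                              seed = substream_seed(config$seed, "subject", s),
                              bank = config$bank)
      generate_session(cfg)
    })
    rec <- sess$recording
    truths[[sid]] <- sess$truth
    rec <- stage("preprocess", {
      mask <- detect_artifacts(rec)
      if (!is.null(rec$artifact_mask)) mask <- mask | rec$artifact_mask
      rec$artifact_mask <- if (any(mask)) mask else NULL
      bridged <- detect_bridged_channels(rec)
      if (length(bridged)) rec <- drop_channels(rec, bridged)
      if (config$reference == "laplacian") rec <- laplacian_reference(rec)
      rec
    })
    epochs <- stage("epoch selection", {
      eps <- lapply(rec$levels$label, function(lv)
        select_epochs(rec, lv, n = config$epochs_per_level,
                      duration_s = config$epoch_s))
      names(eps) <- rec$levels$label
      eps[intersect(levels4, names(eps))]
    })
    res <- stage("coupling", {
      groups <- channel_groups(rec$channel_positions)
      analyze_session_coupling(rec, config$bank, epochs,
                               region_map = groups[c("frontal", "posterior")],
                               subject = sid)
    })
    all_records[[sid]] <- res$records
    all_regions[[sid]] <- res$regions
    all_topo[[sid]] <- res$summary_topography
  }
  records <- do.call(rbind, all_records)
  regions <- do.call(rbind, all_regions)
  topo <- do.call(rbind, all_topo)
  rownames(records) <- rownames(regions) <- rownames(topo) <- NULL

  A <- stage("aggregate", assemble_aggregate(records, levels = levels4))
  fit <- stage("modes", cfc_modes(A))
  A_src <- stage("aggregate regions", assemble_aggregate(regions, levels = levels4))
  P <- stage("projection", predict(fit, A_src, n_modes = config$n_modes))
  idx <- attr(A_src, "index")
  projections <- data.frame(idx, value = as.numeric(P[1, ]))
  ci <- stage("bootstrap", bootstrap_subject_ci(
    projections, n_boot = config$n_boot,
    seed = substream_seed(config$seed, "bootstrap")))

  result <- structure(list(records = records, regions = regions,
                           summary_topography = topo, truth = truths,
                           A = A, fit = fit, A_source = A_src,
                           projections = projections, ci = ci,
                           config = config),
                      class = "cfc_pipeline")
  if (!is.null(config$out)) stage("write outputs", write_pipeline(result))
  result
}

#' @export
print.cfc_pipeline <- function(x, ...) {
  cat(sprintf("<cfc_pipeline> preset '%s': %d subjects x %d channels, seed %d\n",
              x$config$preset, x$config$n_subjects, x$config$n_channels,
              x$config$seed))
  cat(sprintf("  aggregate matrix: %d bands x %d observations\n",
              nrow(x$A), ncol(x$A)))
  cat(sprintf("  mode energies: %s\n",
              paste(sprintf("%.1f%%", x$fit$percent_energy[1:min(3, length(x$fit$percent_energy))]),
                    collapse = ", ")))
  cm <- stats::aggregate(value ~ level + location, x$projections, mean)
  for (i in seq_len(nrow(cm)))
    cat(sprintf("  mean mode-1 projection %-9s %-9s % .3f\n",
                cm$level[i], cm$location[i], cm$value[i]))
  invisible(x)
}

#' @export
summary.cfc_pipeline <- function(object, ...) {
  print(object)
  cat("\nSubject-bootstrap 95% CIs (first mode):\n")
  print(object$ci, row.names = FALSE)
  invisible(object)
}

write_pipeline <- function(result) {
  out <- result$config$out
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) write.csv(d, file.path(out, f), row.names = FALSE)
  wcsv(result$records, "coupling_records.csv")
  wcsv(result$regions, "region_coupling.csv")
  wcsv(result$summary_topography, "summary_topography.csv")
  Adf <- data.frame(band = rownames(result$A), unclass(result$A),
                    check.names = FALSE)
  wcsv(Adf, "aggregate_matrix.csv")
  U <- result$fit$modes
  wcsv(data.frame(band = rownames(U),
                  setNames(as.data.frame(U[, seq_len(result$config$n_modes)]),
                           paste0("mode", seq_len(result$config$n_modes)))),
       "modes.csv")
  wcsv(data.frame(mode = seq_along(result$fit$percent_energy),
                  singular_value = result$fit$singular_values,
                  percent_energy = result$fit$percent_energy), "energies.csv")
  wcsv(result$projections, "projections.csv")
  wcsv(result$ci, "bootstrap_ci.csv")
  cfgl <- result$config
  cfgl$bank <- list(slow = format(cfgl$bank$slow_band),
                    n_high_bands = length(cfgl$bank$high_bands),
                    summary = format(cfgl$bank$summary_band))
  files <- c("coupling_records.csv", "region_coupling.csv",
             "summary_topography.csv", "aggregate_matrix.csv", "modes.csv",
             "energies.csv", "projections.csv", "bootstrap_ci.csv")
  sums <- tools::md5sum(file.path(out, files))
  names(sums) <- files
  manifest <- list(config = unclass(cfgl), seed = result$config$seed,
                   package_version = as.character(packageVersion("slowmod")),
                   r_version = R.version.string,
                   file_md5 = as.list(sums))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  invisible(out)
}
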