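# End-to-end orchestration: simulate a labeled cohort to WAV + manifest,
# batch-extract features at both MFCC frequency bounds, and produce the
# statistical report (descriptive table, AUC table, correlation screen,
# model selection). Every stochastic step is seeded; a run is reproducible
# byte-for-byte given the same config.

#' Assemble and validate a pipeline run configuration
#'
#' @param out_dir output directory for the run.
#' @param n_per_cell,groups,sexes,group_severity,noise_band_hz,duration_s
#'   cohort design, see [cohort_spec()].
#' @param sample_rate_hz synthesis/analysis rate (Hz).
#' @param seed master RNG seed for the run.
#' @param discard_s,keep_s,strict segmentation settings.
#' @param fmax_hz_list,fmin_hz,n_filters,n_coeff,mel_variant MFCC settings.
#' @param er_split_hz,er_fmax_hz Energy Ratio bands.
#' @param n_boot,alpha bootstrap settings.
#' @param correlation_method `"spearman"` or `"pearson"`.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       n_per_cell = 30, groups = c("control", "case"),
                       sexes = c("male", "female"),
                       group_severity = NULL, noise_band_hz = NULL,
                       duration_s = 4.5, sample_rate_hz = 32000, seed = 1,
                       discard_s = 0.75, keep_s = 2.5, strict = FALSE,
                       fmax_hz_list = c(8000, 12000), fmin_hz = 133,
                       n_filters = 40, n_coeff = 13, mel_variant = "slaney",
                       er_split_hz = 4000, er_fmax_hz = 12000,
                       n_boot = 2000, alpha = 0.05,
                       correlation_method = "spearman") {
  if (max(fmax_hz_list, er_fmax_hz) > sample_rate_hz / 2) {
    phon_stop("insufficientBandwidth",
              "sample_rate_hz too low for the requested fmax")
  }
  cfg <- as.list(environment())
  if (is.null(cfg$group_severity)) {
    cfg$group_severity <- formals(cohort_spec)$group_severity
    cfg$group_severity <- eval(cfg$group_severity)
  }
  structure(cfg, class = "run_config")
}

write_resolved_config <- function(config, out_dir) {
  cfg <- unclass(config)
  cfg$group_severity <- lapply(cfg$group_severity, as.list)
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = 10, null = "null",
                       pretty = TRUE)
}

#' Simulate a cohort and write WAV files plus a manifest
#'
#' @param config a [run_config()].
#' @return invisibly, list with `manifest_path`, `wav_dir`, `manifest`.
#' @export
run_simulate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  wav_dir <- file.path(config$out_dir, "wav")
  dir.create(wav_dir, recursive = TRUE, showWarnings = FALSE)
  write_resolved_config(config, config$out_dir)
  spec <- cohort_spec(n_per_cell = config$n_per_cell, groups = config$groups,
                      sexes = config$sexes,
                      group_severity = config$group_severity,
                      sample_rate_hz = config$sample_rate_hz,
                      duration_s = config$duration_s,
                      noise_band_hz = config$noise_band_hz,
                      seed = config$seed)
  cohort <- simulate_cohort(spec)
  paths <- vapply(cohort$recordings, function(rec) {
    p <- file.path(wav_dir, paste0(rec$metadata$subject_id, ".wav"))
    write_wav(rec$samples, rec$sample_rate_hz, p)
    p
  }, character(1))
  manifest <- cohort$manifest
  manifest$wav_path <- paths
  manifest_path <- file.path(config$out_dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(list(manifest_path = manifest_path, wav_dir = wav_dir,
                 manifest = manifest))
}

#' Extract features for every recording in a manifest
#'
#' Reads each WAV listed in the manifest, segments it and extracts the full
#' feature row; per-recording failures are recorded in the run manifest
#' without aborting the batch. WAVs whose rate differs from the configured
#' analysis rate are resampled (and rejected when their bandwidth cannot
#' support the configured `er_fmax_hz`).
#'
#' @param config a [run_config()].
#' @param manifest optional manifest data.frame; defaults to
#'   `out_dir/manifest.csv`.
#' @return invisibly, list with `features_path`, `features`,
#'   `run_manifest`.
#' @export
run_extract <- function(config, manifest = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(manifest)) {
    manifest <- read.csv(file.path(config$out_dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  }
  recordings <- lapply(seq_len(nrow(manifest)), function(i) {
    path <- manifest$wav_path[i]
    tryCatch({
      wav <- read_wav(path)
      if (wav$sample_rate_hz < 2 * config$er_fmax_hz) {
        phon_stop("insufficientBandwidth",
                  "%s: %d Hz cannot support fmax %d Hz", path,
                  wav$sample_rate_hz, config$er_fmax_hz)
      }
      if (wav$sample_rate_hz != config$sample_rate_hz) {
        frac <- resample_fraction(config$sample_rate_hz, wav$sample_rate_hz)
        wav$samples <- as.numeric(
          signal::resample(wav$samples, frac[1], frac[2]))
        wav$sample_rate_hz <- config$sample_rate_hz
      }
      list(samples = wav$samples, sample_rate_hz = wav$sample_rate_hz,
           metadata = list(subject_id = manifest$subject_id[i]))
    }, error = function(e) {
      list(samples = NULL, sample_rate_hz = NA,
           metadata = list(subject_id = manifest$subject_id[i]),
           read_error = conditionMessage(e))
    })
  })
  ok <- vapply(recordings, function(r) is.null(r$read_error), logical(1))
  res <- cohort_features(recordings[ok], discard_s = config$discard_s,
                         keep_s = config$keep_s, strict = config$strict,
                         fmax_hz_list = config$fmax_hz_list,
                         fmin_hz = config$fmin_hz,
                         n_filters = config$n_filters,
                         n_coeff = config$n_coeff,
                         er_split_hz = config$er_split_hz,
                         er_fmax_hz = config$er_fmax_hz,
                         mel_variant = config$mel_variant)
  run_manifest <- res$run_manifest
  if (any(!ok)) {
    bad <- do.call(rbind, lapply(recordings[!ok], function(r) {
      data.frame(subject_id = r$metadata$subject_id, status = "error",
                 message = r$read_error, stringsAsFactors = FALSE)
    }))
    run_manifest <- rbind(run_manifest, bad)
  }
  features_path <- file.path(config$out_dir, "features.csv")
  if (!is.null(res$features)) {
    write.csv(res$features, features_path, row.names = FALSE)
  }
  write.csv(run_manifest, file.path(config$out_dir, "run_manifest.csv"),
            row.names = FALSE)
  invisible(list(features_path = features_path, features = res$features,
                 run_manifest = run_manifest))
}

resample_fraction <- function(target, source) {
  g <- function(a, b) if (b == 0) a else g(b, a %% b)
  d <- g(target, source)
  c(target / d, source / d)
}

#' Run the statistical report over extracted features
#'
#' Joins features with subject metadata, then produces: descriptive mean/SD
#' tables, per-sex AUC with bootstrap CIs for the three headline metrics
#' (MFCC2 at each fmax and the Energy Ratio), the correlation screen of
#' interpretable features against the MFCC block, and AIC model selection
#' for MFCC2. Written as `report/report.json` plus CSVs.
#'
#' @param config a [run_config()].
#' @param features,metadata optional data.frames; default to the run's
#'   `features.csv` / `manifest.csv`.
#' @return invisibly, the report list.
#' @export
run_analyze <- function(config, features = NULL, metadata = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(features)) {
    features <- read.csv(file.path(config$out_dir, "features.csv"),
                         stringsAsFactors = FALSE)
  }
  if (is.null(metadata)) {
    metadata <- read.csv(file.path(config$out_dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  }
  unmatched <- setdiff(features$subject_id, metadata$subject_id)
  if (length(unmatched) > 0) {
    phon_stop("joinError", "no metadata for subject(s): %s",
              paste(unmatched, collapse = ", "))
  }
  meta_cols <- intersect(c("subject_id", "group", "sex", "age", "dataset"),
                         names(metadata))
  tab <- merge(metadata[, meta_cols, drop = FALSE], features,
               by = "subject_id")
  tags <- vapply(config$fmax_hz_list, fmax_tag, character(1))
  metrics <- c(paste0("mfcc_mn_2_", tags), "er_db")
  report <- list(
    descriptive = descriptive_table(tab, metrics,
                                    by = c("dataset", "sex", "group"))
  )
  two_groups <- length(unique(tab$group)) == 2
  if (two_groups) {
    auc_rows <- list()
    for (sx in unique(tab$sex)) {
      sub <- tab[tab$sex == sx, ]
      if (length(unique(sub$group)) < 2) next
      for (m in metrics) {
        rr <- bootstrap_auc_ci(sub[[m]], sub$group, n_boot = config$n_boot,
                               alpha = config$alpha,
                               seed = child_seed(config$seed, 31L))
        auc_rows[[length(auc_rows) + 1L]] <- data.frame(
          metric = m, sex = sx, auc = rr$auc, ci_low = rr$ci_low,
          ci_high = rr$ci_high, n_controls = rr$n_controls,
          n_cases = rr$n_cases, stringsAsFactors = FALSE)
      }
    }
    report$auc <- do.call(rbind, auc_rows)
  } else {
    phon_warn("single group present: AUC analysis skipped")
  }
  mfcc_cols <- grep("^mfcc_(mn|sd)_", names(tab), value = TRUE)
  other_cols <- setdiff(names(tab)[vapply(tab, is.numeric, logical(1))],
                        c(mfcc_cols, "age", "retained_s"))
  screen <- NULL
  if (nrow(tab) >= 10) {
    screen <- correlation_screen(tab, mfcc_cols, other_cols,
                                 method = config$correlation_method)
    report$correlation <- list(method = screen$method,
                               retained = screen$retained)
  } else {
    phon_warn("fewer than 10 subjects: correlation screen skipped")
  }
  sel_factors <- intersect(c("sex", "group", "age", "dataset"), names(tab))
  # a factor must vary to enter the candidate models
  sel_factors <- sel_factors[vapply(sel_factors, function(f) {
    length(unique(tab[[f]])) >= 2
  }, logical(1))]
  sel <- ols_aic_select(tab, paste0("mfcc_mn_2_", tags[length(tags)]),
                        factors = sel_factors)
  report$model_selection <- list(
    response = sel$best$response,
    selected_factors = sel$best$factor_set,
    aic = sel$best$aic,
    coefficients = as.data.frame(sel$best$coefficients),
    candidates = data.frame(
      factors = vapply(sel$fits, function(f)
        paste(f$factor_set, collapse = "+"), character(1)),
      aic = vapply(sel$fits, function(f) f$aic, numeric(1)))
  )
  report_dir <- file.path(config$out_dir, "report")
  dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(report, file.path(report_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, dataframe = "rows",
                       pretty = TRUE)
  if (!is.null(screen)) {
    write.csv(as.data.frame(screen$matrix),
              file.path(report_dir, "correlation_screen.csv"))
  }
  write.csv(report$descriptive, file.path(report_dir, "descriptive.csv"),
            row.names = FALSE)
  if (!is.null(report$auc)) {
    write.csv(report$auc, file.path(report_dir, "auc.csv"),
              row.names = FALSE)
  }
  invisible(report)
}

#' Run the full pipeline: simulate, extract, analyze
#'
#' @param config a [run_config()].
#' @return invisibly, the analysis report.
#' @export
run_all <- function(config) {
  run_simulate(config)
  run_extract(config)
  run_analyze(config)
}
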