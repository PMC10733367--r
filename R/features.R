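# One-stop feature extraction for a single analysis segment: MFCC summaries
# at each requested upper frequency bound, the Energy Ratio, and the
# interpretable voice-quality / spectral-shape features, flattened to a
# single row for the cohort table.

#' Extract the full feature row for one phonation segment
#'
#' @param segment `phonation_segment`.
#' @param fmax_hz_list upper MFCC frequency bounds to compute, tagged in the
#'   column names as `_8k`, `_12k`, ... (default `c(8000, 12000)`).
#' @param fmin_hz lower MFCC frequency bound (default 133 Hz).
#' @param n_filters,n_coeff mel filterbank size and cepstral order.
#' @param er_split_hz,er_fmax_hz Energy Ratio band edges.
#' @param mel_variant mel-scale formula (see [build_mel_filterbank()]).
#' @param frame_s,hop_s STFT framing for the MFCC/shape features (s).
#' @return one-row data.frame: `mfcc_mn_1.._<tag>`, `mfcc_sd_1.._<tag>`,
#'   `er_db`, voice-quality columns, `contrast_<lo>_<hi>_mn/sd`,
#'   `flatness_mn/sd`, `rms_mn_db`, `rms_sd_db`, `retained_s`.
#' @export
extract_features <- function(segment, fmax_hz_list = c(8000, 12000),
                             fmin_hz = 133, n_filters = 40, n_coeff = 13,
                             er_split_hz = 4000, er_fmax_hz = 12000,
                             mel_variant = "slaney",
                             frame_s = 0.025, hop_s = 0.010) {
  fs <- segment$sample_rate_hz
  n_fft <- next_pow2(round(frame_s * fs))
  row <- list()
  for (fmax in fmax_hz_list) {
    fb <- build_mel_filterbank(fs, n_fft, n_filters, fmin_hz, fmax,
                               variant = mel_variant)
    sm <- mfcc_summary(mfcc_frames(segment, fb, frame_s, hop_s, n_coeff))
    tag <- fmax_tag(fmax)
    for (k in seq_len(n_coeff)) {
      row[[sprintf("mfcc_mn_%d_%s", k, tag)]] <- sm$mfcc_mn[k]
      row[[sprintf("mfcc_sd_%d_%s", k, tag)]] <- sm$mfcc_sd[k]
    }
  }
  er <- energy_ratio_db(welch_psd(segment), er_split_hz, er_fmax_hz)
  row$er_db <- er$er_db

  vq <- voice_quality_set(segment)
  row <- c(row, unclass(vq))

  ct <- spectral_contrast_octave(segment, frame_s = frame_s, hop_s = hop_s)
  for (i in seq_len(nrow(ct))) {
    nm <- sprintf("contrast_%d_%d", round(ct$low_hz[i]), round(ct$high_hz[i]))
    row[[paste0(nm, "_mn")]] <- ct$contrast_mn_db[i]
    row[[paste0(nm, "_sd")]] <- ct$contrast_sd_db[i]
  }
  row <- c(row, spectral_flatness(segment, frame_s, hop_s),
           rms_intensity_db(segment, frame_s, hop_s))
  row$retained_s <- segment$retained_s
  as.data.frame(row)
}

fmax_tag <- function(fmax_hz) {
  if (fmax_hz %% 1000 == 0) sprintf("%dk", fmax_hz %/% 1000)
  else sprintf("%dhz", round(fmax_hz))
}

#' Segment and extract features for a whole cohort of recordings
#'
#' Applies [extract_phonation()] then [extract_features()] to each
#' recording; failures are isolated per recording and reported in the run
#' manifest rather than aborting the batch.
#'
#' @param recordings list of `labeled_recording` (or lists with `samples`,
#'   `sample_rate_hz`, `metadata$subject_id`).
#' @param discard_s,keep_s segmentation parameters.
#' @param strict error on short retained segments (see
#'   [extract_phonation()]).
#' @param ... passed to [extract_features()].
#' @return list: `features` (data.frame, one row per analyzable recording,
#'   keyed by `subject_id`) and `run_manifest` (data.frame: subject_id,
#'   status, message).
#' @export
cohort_features <- function(recordings, discard_s = 0.75, keep_s = 2.5,
                            strict = FALSE, ...) {
  feats <- list(); statuses <- list()
  for (i in seq_along(recordings)) {
    rec <- recordings[[i]]
    id <- rec$metadata$subject_id %||% sprintf("R%03d", i)
    res <- tryCatch({
      seg <- extract_phonation(rec, discard_s, keep_s, strict = strict)
      fr <- extract_features(seg, ...)
      fr <- cbind(data.frame(subject_id = id, stringsAsFactors = FALSE), fr)
      list(status = "ok", message = "", row = fr)
    },
    noVoicedSegment = function(e) list(status = "no_voiced_segment",
                                       message = conditionMessage(e), row = NULL),
    segmentTooShort = function(e) list(status = "too_short",
                                       message = conditionMessage(e), row = NULL),
    error = function(e) list(status = "error",
                             message = conditionMessage(e), row = NULL))
    statuses[[i]] <- data.frame(subject_id = id, status = res$status,
                                message = res$message,
                                stringsAsFactors = FALSE)
    if (!is.null(res$row)) feats[[length(feats) + 1L]] <- res$row
  }
  list(features = if (length(feats)) do.call(rbind, feats) else NULL,
       run_manifest = do.call(rbind, statuses))
}
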