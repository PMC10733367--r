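# Voiced-region detection and analysis-segment extraction. The analysis
# convention: within the longest contiguous voiced run, the first 0.75 s is
# discarded (onset transient) and the following 2.5 s retained.

#' Frame-level voicing and pitch-candidate track
#'
#' Periodicity is the maximum normalized autocorrelation over lags in the f0
#' search range; a frame is voiced iff periodicity >= `voicing_threshold`
#' and its RMS is above a silence floor (1% of the loudest frame).
#'
#' @param samples numeric waveform (or a list with `samples` and
#'   `sample_rate_hz`).
#' @param sample_rate_hz sampling rate; ignored when `samples` carries one.
#' @param frame_s,hop_s analysis frame length and hop (s).
#' @param f0_range_hz two-element f0 search range (Hz).
#' @param voicing_threshold periodicity threshold in `[0, 1]`.
#' @return data.frame of class `voicing_track`: `frame_times_s`,
#'   `periodicity`, `f0_candidate_hz`, `voiced`.
#' @export
voicing_track <- function(samples, sample_rate_hz = NULL, frame_s = 0.04,
                          hop_s = 0.01, f0_range_hz = c(60, 500),
                          voicing_threshold = 0.45) {
  if (is.list(samples)) {
    sample_rate_hz <- samples$sample_rate_hz
    samples <- samples$samples
  }
  if (length(samples) == 0) phon_stop("invalidInput", "empty audio")
  fs <- sample_rate_hz
  flen <- round(frame_s * fs); hlen <- round(hop_s * fs)
  if (length(samples) < 2L * flen - hlen) {
    phon_stop("invalidInput", "recording shorter than two frames")
  }
  frames <- frame_signal(samples, flen, hlen)
  times <- frame_times(length(samples), flen, hlen, fs)
  lag_min <- max(2L, floor(fs / f0_range_hz[2]))
  lag_max <- min(flen - 1L, ceiling(fs / f0_range_hz[1]))
  res <- apply(frames, 2, function(fr) {
    acn <- norm_autocorr(fr, lag_min, lag_max)
    if (all(!is.finite(acn))) return(c(0, NA_real_))
    i <- which.max(acn)
    c(acn[i], fs / (lag_min + i - 1L))
  })
  rmsv <- apply(frames, 2, rms)
  floor_rms <- max(1e-7, 0.01 * max(rmsv))
  out <- data.frame(
    frame_times_s = times,
    periodicity = pmin(pmax(res[1, ], 0), 1),
    f0_candidate_hz = res[2, ]
  )
  out$voiced <- out$periodicity >= voicing_threshold & rmsv >= floor_rms
  attr(out, "frame_s") <- flen / fs
  class(out) <- c("voicing_track", "data.frame")
  out
}

# Normalized autocorrelation over a lag range: r(L) =
# sum(x_t x_{t+L}) / sqrt(sum over head * sum over tail). Equals 1 for a
# frame that is exactly periodic at lag L. The cross term is computed by
# FFT (linear autocorrelation via zero padding); the energy terms by
# cumulative sums.
norm_autocorr <- function(fr, lag_min, lag_max) {
  n <- length(fr)
  fr <- fr - mean(fr)
  nf <- next_pow2(2L * n)
  ac <- Re(fft(Mod(fft(c(fr, rep(0, nf - n))))^2, inverse = TRUE)) / nf
  csum <- cumsum(fr^2)
  lags <- lag_min:lag_max
  e_head <- csum[n - lags]
  e_tail <- csum[n] - csum[lags]
  den <- sqrt(e_head * e_tail)
  r <- ac[lags + 1L] / den
  r[!is.finite(r)] <- NA_real_
  r
}

#' Extract the analysis segment from a recording
#'
#' Locates the longest contiguous voiced run (bridging silent gaps up to
#' `bridge_s`), discards the first `discard_s`, and keeps up to `keep_s` of
#' what follows. When less than `keep_s` remains, the available portion
#' (if at least `min_retained_s`) is returned with a warning, or an error
#' under `strict = TRUE`.
#'
#' @param recording list with `samples` and `sample_rate_hz` (e.g. a
#'   `labeled_recording` or [read_wav()] result).
#' @param discard_s onset transient to discard (s).
#' @param keep_s analysis duration to retain (s).
#' @param min_retained_s minimum acceptable retained duration (s).
#' @param bridge_s unvoiced gaps up to this length inside a run are bridged.
#' @param strict error (rather than warn) when the retained duration falls
#'   short of `keep_s`.
#' @param ... passed to [voicing_track()].
#' @return object of class `phonation_segment`: `samples`,
#'   `sample_rate_hz`, `source_start_s`, `retained_s`.
#' @export
extract_phonation <- function(recording, discard_s = 0.75, keep_s = 2.5,
                              min_retained_s = 0.5, bridge_s = 0.1,
                              strict = FALSE, ...) {
  fs <- recording$sample_rate_hz
  x <- recording$samples
  vt <- voicing_track(x, fs, ...)
  runs <- voiced_runs(vt, bridge_s)
  if (nrow(runs) == 0) {
    phon_stop("noVoicedSegment", "no voiced segment detected")
  }
  best <- runs[which.max(runs$dur_s), ]
  frame_len_s <- attr(vt, "frame_s")
  run_start_s <- best$start_s
  run_end_s <- best$end_s + frame_len_s  # run covers the last frame too
  avail_s <- run_end_s - run_start_s - discard_s
  if (avail_s < min_retained_s) {
    phon_stop("segmentTooShort",
              "voiced run (%.2f s) too short after %.2f s discard",
              run_end_s - run_start_s, discard_s)
  }
  retained_s <- min(keep_s, avail_s)
  if (retained_s < keep_s) {
    if (strict) {
      phon_stop("segmentTooShort",
                "only %.2f s retained (< keep_s = %.2f s) in strict mode",
                retained_s, keep_s)
    }
    phon_warn("retained %.2f s of the requested %.2f s", retained_s, keep_s)
  }
  start_s <- run_start_s + discard_s
  i0 <- round(start_s * fs) + 1L
  i1 <- min(length(x), i0 + round(retained_s * fs) - 1L)
  structure(list(
    samples = x[i0:i1],
    sample_rate_hz = fs,
    source_start_s = start_s,
    retained_s = (i1 - i0 + 1L) / fs
  ), class = "phonation_segment")
}

# Contiguous voiced runs with short-gap bridging; hop inferred from times.
voiced_runs <- function(vt, bridge_s) {
  v <- vt$voiced
  if (!any(v)) return(data.frame(start_s = numeric(0), end_s = numeric(0),
                                 dur_s = numeric(0)))
  hop_s <- if (nrow(vt) > 1) vt$frame_times_s[2] - vt$frame_times_s[1] else 0.01
  max_gap <- floor(bridge_s / hop_s)
  # bridge unvoiced gaps of <= max_gap frames between voiced frames
  r <- rle(v)
  if (max_gap > 0 && length(r$lengths) > 2) {
    for (i in 2:(length(r$lengths) - 1L)) {
      if (!r$values[i] && r$lengths[i] <= max_gap) r$values[i] <- TRUE
    }
    v <- inverse.rle(r)
    r <- rle(v)
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    start_s = vt$frame_times_s[starts[keep]],
    end_s = vt$frame_times_s[ends[keep]],
    dur_s = vt$frame_times_s[ends[keep]] - vt$frame_times_s[starts[keep]]
  )
}

#' Coerce a waveform to a phonation segment without segmentation
#'
#' Wraps an already-trimmed waveform in the `phonation_segment` container so
#' feature extractors can be applied directly (useful for probes and tests).
#'
#' @param samples numeric waveform.
#' @param sample_rate_hz sampling rate (Hz).
#' @return `phonation_segment`.
#' @export
as_phonation_segment <- function(samples, sample_rate_hz) {
  structure(list(samples = as.numeric(samples),
                 sample_rate_hz = sample_rate_hz,
                 source_start_s = 0,
                 retained_s = length(samples) / sample_rate_hz),
            class = "phonation_segment")
}
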