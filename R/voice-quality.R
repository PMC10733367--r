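# Interpretable voice-quality metrics: pitch statistics, cycle-level jitter
# ('localabs') and shimmer ('local dB'), harmonics-to-noise ratio, and
# cepstral peak prominence. All are scale-invariant by construction.

#' Frame-level pitch contour
#'
#' Per-frame f0 from the maximum of the normalized autocorrelation within
#' the lag range, refined by parabolic interpolation. An octave guard keeps
#' the contour continuous: among near-maximal candidates the one closest (in
#' octaves) to the previous frame's f0 is preferred.
#'
#' @param segment `phonation_segment`.
#' @param f0_range_hz f0 search range (Hz).
#' @param frame_s,hop_s framing (s).
#' @param voicing_threshold frames below this periodicity are excluded.
#' @return data.frame of class `pitch_contour`: `frame_times_s`, `f0_hz`,
#'   `periodicity` — voiced frames only.
#' @export
pitch_contour <- function(segment, f0_range_hz = c(60, 500), frame_s = 0.04,
                          hop_s = 0.01, voicing_threshold = 0.45) {
  fs <- segment$sample_rate_hz
  flen <- round(frame_s * fs); hlen <- round(hop_s * fs)
  if (length(segment$samples) < flen + hlen) {
    phon_stop("invalidInput", "segment shorter than two pitch frames")
  }
  frames <- frame_signal(segment$samples, flen, hlen)
  times <- frame_times(length(segment$samples), flen, hlen, fs)
  lag_min <- max(2L, floor(fs / f0_range_hz[2]))
  lag_max <- min(flen - 2L, ceiling(fs / f0_range_hz[1]))
  prev_f0 <- NA_real_
  out <- matrix(NA_real_, ncol(frames), 2)
  for (i in seq_len(ncol(frames))) {
    acn <- norm_autocorr(frames[, i], lag_min, lag_max)
    if (all(!is.finite(acn))) next
    pk <- local_maxima(acn)
    if (length(pk) == 0) pk <- which.max(acn)
    best_val <- max(acn[pk])
    cand <- pk[acn[pk] >= 0.85 * best_val]
    sel <- if (!is.na(prev_f0) && length(cand) > 1) {
      f0s <- fs / (lag_min + cand - 1L)
      cand[which.min(abs(log2(f0s / prev_f0)))]
    } else {
      cand[which.max(acn[cand])]
    }
    lag <- refine_peak(acn, sel) + lag_min - 1
    val <- acn[sel]
    if (val >= voicing_threshold) {
      out[i, ] <- c(fs / lag, val)
      prev_f0 <- fs / lag
    }
  }
  voiced <- !is.na(out[, 1])
  if (!any(voiced)) phon_stop("unvoicedInput", "no voiced frames found")
  res <- data.frame(frame_times_s = times[voiced], f0_hz = out[voiced, 1],
                    periodicity = out[voiced, 2])
  class(res) <- c("pitch_contour", "data.frame")
  res
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

# parabolic interpolation of a peak index to fractional precision
refine_peak <- function(v, i) {
  if (i <= 1 || i >= length(v)) return(i)
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (abs(denom) < 1e-12) return(i)
  i + 0.5 * (v[i - 1] - v[i + 1]) / denom
}

#' Pitch summary statistics
#'
#' Mean and SD of f0 plus the semitone range `12 log2(max/min)` computed
#' after trimming the top and bottom 1% of voiced frames (outlier guard).
#'
#' @param contour a [pitch_contour()] result.
#' @param trim fraction trimmed from each tail before the range.
#' @return list: `pitch_mn_hz`, `pitch_sd_hz`, `pitch_semitone_range`.
#' @export
pitch_stats <- function(contour, trim = 0.01) {
  f0 <- sort(contour$f0_hz)
  k <- floor(trim * length(f0))
  if (length(f0) > 2 * k + 1) f0 <- f0[(k + 1):(length(f0) - k)]
  list(pitch_mn_hz = mean(contour$f0_hz),
       pitch_sd_hz = stats::sd(contour$f0_hz),
       pitch_semitone_range = 12 * log2(max(f0) / min(f0)))
}

#' Glottal cycle periods and peak amplitudes
#'
#' Pitch-guided peak picking: starting from the strongest peak, successive
#' cycle marks are located within a window of the locally expected period,
#' so each mark is the maximum of `|x|` over its own cycle. The cycle peak
#' amplitude is that maximum, parabolically refined to sub-sample
#' precision; periods are differences of refined mark times.
#'
#' @param segment `phonation_segment`.
#' @param contour a [pitch_contour()] result for the same segment.
#' @return object of class `cycle_series`: `mark_times_s` and
#'   `peak_amplitude` (one per detected cycle), `period_s` (one per
#'   consecutive mark pair).
#' @export
cycle_series <- function(segment, contour = NULL) {
  if (is.null(contour)) contour <- pitch_contour(segment)
  fs <- segment$sample_rate_hz
  x <- segment$samples
  f0_at <- function(t) {
    i <- which.min(abs(contour$frame_times_s - t))
    contour$f0_hz[i]
  }
  t_mid <- stats::median(contour$frame_times_s)
  period0 <- round(fs / f0_at(t_mid))
  # anchor on the strongest peak near the middle
  mid <- round(t_mid * fs) + 1L
  win <- max(1L, mid - period0):min(length(x), mid + period0)
  anchor <- win[which.max(abs(x[win]))]
  marks <- anchor
  # walk forward
  pos <- anchor
  repeat {
    p <- round(fs / f0_at(pos / fs))
    lo <- pos + round(0.7 * p); hi <- pos + round(1.3 * p)
    if (hi > length(x)) break
    seg <- lo:hi
    pos <- seg[which.max(abs(x[seg]))]
    marks <- c(marks, pos)
  }
  # walk backward
  pos <- anchor
  repeat {
    p <- round(fs / f0_at(pos / fs))
    lo <- pos - round(1.3 * p); hi <- pos - round(0.7 * p)
    if (lo < 1) break
    seg <- lo:hi
    pos <- seg[which.max(abs(x[seg]))]
    marks <- c(pos, marks)
  }
  if (length(marks) < 4) phon_stop("tooFewCycles", "fewer than 3 glottal cycles")
  marks <- sort(unique(marks))
  # sub-sample refinement of each peak location on |x|
  marks_frac <- vapply(marks, function(m) refine_peak(abs(x), m), numeric(1))
  periods <- diff(marks_frac) / fs
  # the cycle's peak amplitude is the picked peak itself (each mark is the
  # maximum of |x| over its cycle); parabolic refinement of the value
  amps <- vapply(marks, function(m) {
    if (m <= 1 || m >= length(x)) return(abs(x[m]))
    v <- abs(x[(m - 1):(m + 1)])
    denom <- v[1] - 2 * v[2] + v[3]
    if (abs(denom) < 1e-12) return(v[2])
    v[2] - (v[1] - v[3])^2 / (8 * denom)
  }, numeric(1))
  structure(list(mark_times_s = (marks_frac - 1) / fs,
                 period_s = periods, peak_amplitude = amps),
            class = "cycle_series")
}

#' Jitter, 'localabs' variant
#'
#' Mean absolute difference of consecutive glottal cycle periods, in
#' seconds.
#'
#' @param cycles a [cycle_series()] result.
#' @return jitter in seconds.
#' @export
jitter_local_abs <- function(cycles) {
  p <- cycles$period_s
  if (length(p) < 3) phon_stop("tooFewCycles", "need >= 3 cycles for jitter")
  mean(abs(diff(p)))
}

#' Shimmer, 'local dB' variant
#'
#' Mean absolute base-10 log ratio (x20) of consecutive cycle peak
#' amplitudes, in dB.
#'
#' @param cycles a [cycle_series()] result.
#' @return shimmer in dB.
#' @export
shimmer_local_db <- function(cycles) {
  a <- cycles$peak_amplitude
  if (length(a) < 3) phon_stop("tooFewCycles", "need >= 3 cycles for shimmer")
  if (any(a <= 0)) phon_stop("invalidCycles", "non-positive cycle amplitude")
  mean(abs(20 * log10(a[-1] / a[-length(a)])))
}

#' Harmonics-to-noise ratio
#'
#' Per voiced frame, `r` is the normalized autocorrelation at the pitch lag
#' (parabolic-interpolated); `HNR = 10 log10(r / (1 - r))`. Mean and SD are
#' taken across voiced frames.
#'
#' @param segment `phonation_segment`.
#' @param contour optional precomputed [pitch_contour()].
#' @param frame_s,hop_s framing (s), used when `contour` is NULL.
#' @return list: `hnr_mn_db`, `hnr_sd_db`.
#' @export
harmonicity_hnr <- function(segment, contour = NULL, frame_s = 0.04,
                            hop_s = 0.01) {
  if (is.null(contour)) {
    contour <- pitch_contour(segment, frame_s = frame_s, hop_s = hop_s)
  }
  r <- pmin(pmax(contour$periodicity, 1e-6), 1 - 1e-6)
  hnr <- 10 * log10(r / (1 - r))
  list(hnr_mn_db = mean(hnr), hnr_sd_db = sd_pop(hnr))
}

#' Cepstral peak prominence
#'
#' Per frame: real cepstrum of the dB magnitude spectrum; the cepstral peak
#' is searched within the quefrency range, a least-squares line is fitted to
#' the cepstrum over that same range, and CPP is the peak height above the
#' line at the peak quefrency. Clear, strongly periodic voices have a
#' pronounced rahmonic peak and hence high CPP.
#'
#' @param segment `phonation_segment`.
#' @param frame_s,hop_s framing (s).
#' @param quefrency_range_s search window, default `1/500` to `1/60` s
#'   (i.e. f0 60-500 Hz).
#' @return list: `cpp_mn_db`, `cpp_sd_db`.
#' @export
cepstral_peak_prominence <- function(segment, frame_s = 0.04, hop_s = 0.01,
                                     quefrency_range_s = c(1 / 500, 1 / 60)) {
  fs <- segment$sample_rate_hz
  flen <- round(frame_s * fs); hlen <- round(hop_s * fs)
  n_fft <- next_pow2(2L * flen)
  frames <- frame_signal(segment$samples, flen, hlen)
  if (ncol(frames) == 0) phon_stop("invalidInput", "segment shorter than one frame")
  padded <- matrix(0, n_fft, ncol(frames))
  padded[seq_len(flen), ] <- frames * hann_window(flen)
  spec_db <- 20 * log10(pmax(abs(stats::mvfft(padded)), 1e-10))
  ceps <- Re(stats::mvfft(spec_db, inverse = TRUE)) / n_fft
  q <- (0:(n_fft - 1)) / fs
  sel <- which(q >= quefrency_range_s[1] & q <= quefrency_range_s[2])
  cpp <- apply(ceps, 2, function(cf) {
    y <- cf[sel]; xq <- q[sel]
    if (stats::sd(y) < 1e-12) {
      return(0)
    }
    ip <- which.max(y)
    fit <- stats::lm.fit(cbind(1, xq), y)
    y[ip] - (fit$coefficients[1] + fit$coefficients[2] * xq[ip])
  })
  list(cpp_mn_db = mean(cpp), cpp_sd_db = sd_pop(cpp))
}

#' All voice-quality metrics for one segment
#'
#' Convenience wrapper computing the full interpretable-feature set from a
#' single pitch analysis.
#'
#' @param segment `phonation_segment`.
#' @return list of class `voice_quality_set`: pitch stats, jitter, shimmer,
#'   HNR, CPP.
#' @export
voice_quality_set <- function(segment) {
  contour <- pitch_contour(segment)
  cycles <- cycle_series(segment, contour)
  ps <- pitch_stats(contour)
  hnr <- harmonicity_hnr(segment, contour)
  cpp <- cepstral_peak_prominence(segment)
  structure(c(ps, list(
    jitter_localabs_s = jitter_local_abs(cycles),
    shimmer_local_db = shimmer_local_db(cycles)
  ), hnr, cpp), class = "voice_quality_set")
}
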