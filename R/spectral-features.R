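# Spectral feature extraction: Welch power spectral density, the band
# Energy Ratio, mel-filterbank cepstral coefficients (MFCCs) with
# configurable frequency bounds, and spectral contrast / flatness.
#
# MFCC2 -- the half-cycle-cosine coefficient -- adds weighted low-frequency
# log energy and subtracts weighted high-frequency log energy; since
# log(a) - log(b) = log(a/b), it acts as a weighted low-to-high frequency
# energy ratio, directly comparable to the Energy Ratio metric.

#' Welch power spectral density of a phonation segment
#'
#' Averaged modified periodograms with Hann windows, one-sided density
#' normalization: the integral of `pxx` over frequency equals the mean
#' squared signal (Parseval) for a stationary input.
#'
#' @param segment `phonation_segment` (or any list with `samples` and
#'   `sample_rate_hz`).
#' @param window_s window length in seconds (default 20 ms).
#' @param overlap_fraction fractional window overlap (default 0.5).
#' @return object of class `psd`: `freqs_hz`, `pxx` (amplitude^2/Hz),
#'   `window_s`, `overlap_fraction`.
#' @export
welch_psd <- function(segment, window_s = 0.020, overlap_fraction = 0.5) {
  fs <- segment$sample_rate_hz
  x <- segment$samples
  nwin <- round(window_s * fs)
  hop <- max(1L, round(nwin * (1 - overlap_fraction)))
  if (length(x) < nwin + hop) {
    phon_stop("invalidInput", "segment shorter than two Welch windows")
  }
  w <- hann_window(nwin)
  frames <- frame_signal(x, nwin, hop) * w
  spec <- abs(stats::mvfft(frames))^2
  n_keep <- nwin %/% 2L + 1L
  pxx <- rowMeans(spec[seq_len(n_keep), , drop = FALSE]) / (fs * sum(w^2))
  # one-sided: double everything except DC (and Nyquist when nwin is even)
  scale2 <- rep(2, n_keep); scale2[1] <- 1
  if (nwin %% 2L == 0L) scale2[n_keep] <- 1
  structure(list(
    freqs_hz = (seq_len(n_keep) - 1L) * fs / nwin,
    pxx = pxx * scale2,
    window_s = window_s,
    overlap_fraction = overlap_fraction
  ), class = "psd")
}

#' Low-to-high band Energy Ratio in dB
#'
#' `ER = 10 log10( integral(pxx, 0..split) / integral(pxx, split..fmax) )`,
#' with trapezoidal integration on the PSD grid. Positive values mean the
#' spectrum is dominated by energy below `split_hz`; added aspiration noise
#' lowers ER by inflating the high band.
#'
#' @param psd a [welch_psd()] result.
#' @param split_hz band split frequency (default 4000 Hz).
#' @param fmax_hz upper integration limit (default 12000 Hz).
#' @return object of class `energy_ratio`: `er_db`, `split_hz`, `fmax_hz`.
#' @export
energy_ratio_db <- function(psd, split_hz = 4000, fmax_hz = 12000) {
  if (max(psd$freqs_hz) < fmax_hz) {
    phon_stop("insufficientBandwidth",
              "PSD extends to %.0f Hz but fmax is %.0f Hz",
              max(psd$freqs_hz), fmax_hz)
  }
  if (split_hz >= fmax_hz) phon_stop("invalidParams", "split_hz must be < fmax_hz")
  low <- trapz_band(psd$freqs_hz, psd$pxx, 0, split_hz)
  high <- trapz_band(psd$freqs_hz, psd$pxx, split_hz, fmax_hz)
  if (high <= 0) {
    phon_stop("degenerateSpectrum", "no energy in the %g-%g Hz band",
              split_hz, fmax_hz)
  }
  structure(list(er_db = 10 * log10(low / high),
                 split_hz = split_hz, fmax_hz = fmax_hz),
            class = "energy_ratio")
}

# mel-scale conversions; Slaney variant (linear below 1 kHz, logarithmic
# above) is the default, HTK (2595 log10(1 + f/700)) available.
hz_to_mel <- function(f, variant = c("slaney", "htk")) {
  variant <- match.arg(variant)
  if (variant == "htk") return(2595 * log10(1 + f / 700))
  ifelse(f < 1000, f * 3 / 200, 15 + 27 * log(f / 1000) / log(6.4))
}

mel_to_hz <- function(m, variant = c("slaney", "htk")) {
  variant <- match.arg(variant)
  if (variant == "htk") return(700 * (10^(m / 2595) - 1))
  ifelse(m < 15, m * 200 / 3, 1000 * exp(log(6.4) * (m - 15) / 27))
}

#' Build a triangular mel filterbank
#'
#' Filter centers are equally spaced on the mel scale between
#' `mel(fmin_hz)` and `mel(fmax_hz)`; each filter is a triangle between its
#' neighbours' centers, area-normalized (Slaney convention).
#'
#' @param sample_rate_hz sampling rate (Hz).
#' @param n_fft FFT length the filterbank will be applied to.
#' @param n_filters number of mel filters (default 40).
#' @param fmin_hz lower frequency bound (default 133 Hz).
#' @param fmax_hz upper frequency bound; must not exceed Nyquist.
#' @param variant mel-scale formula, `"slaney"` (default) or `"htk"`.
#' @return object of class `mel_filterbank`: `weights` (n_filters x
#'   n_bins), `center_freqs_hz`, `fmin_hz`, `fmax_hz`, `n_filters`,
#'   `bin_freqs_hz`, `variant`.
#' @export
build_mel_filterbank <- function(sample_rate_hz, n_fft, n_filters = 40,
                                 fmin_hz = 133, fmax_hz = sample_rate_hz / 2,
                                 variant = c("slaney", "htk")) {
  variant <- match.arg(variant)
  if (fmax_hz > sample_rate_hz / 2 + 1e-9) {
    phon_stop("insufficientBandwidth",
              "fmax_hz (%.0f) exceeds Nyquist (%.0f)", fmax_hz,
              sample_rate_hz / 2)
  }
  n_bins <- n_fft %/% 2L + 1L
  bin_freqs <- (seq_len(n_bins) - 1L) * sample_rate_hz / n_fft
  mels <- seq(hz_to_mel(fmin_hz, variant), hz_to_mel(fmax_hz, variant),
              length.out = n_filters + 2L)
  edges <- mel_to_hz(mels, variant)
  weights <- matrix(0, n_filters, n_bins)
  for (i in seq_len(n_filters)) {
    lo <- edges[i]; ctr <- edges[i + 1L]; hi <- edges[i + 2L]
    up <- (bin_freqs - lo) / (ctr - lo)
    down <- (hi - bin_freqs) / (hi - ctr)
    tri <- pmax(0, pmin(up, down))
    weights[i, ] <- tri * 2 / (hi - lo)  # Slaney area normalization
  }
  structure(list(weights = weights,
                 center_freqs_hz = edges[2:(n_filters + 1L)],
                 fmin_hz = fmin_hz, fmax_hz = fmax_hz,
                 n_filters = n_filters, bin_freqs_hz = bin_freqs,
                 variant = variant),
            class = "mel_filterbank")
}

# Orthonormal DCT-II matrix over the filter index; row k (1-based
# coefficient) holds cos(pi * (k-1) * (j - 0.5) / N) with (k-1) half-cycles.
dct_matrix <- function(n_coeff, n_filters) {
  j <- seq_len(n_filters) - 0.5
  m <- t(vapply(seq_len(n_coeff), function(k) {
    cos(pi * (k - 1) * j / n_filters)
  }, numeric(n_filters)))
  m <- m * sqrt(2 / n_filters)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

#' Frame-level MFCC matrix
#'
#' Per frame: Hann-windowed power spectrum, mel filterbank energies, dB
#' (`10 log10`, floored at 1e-10), then an orthonormal DCT-II across the
#' filter index. Coefficients are 1-based: MFCC1 is the constant (overall
#' energy) term; MFCC2 weights the log mel spectrum by a half cycle of
#' cosine (positive at low, negative at high frequency).
#'
#' @param segment `phonation_segment`.
#' @param filterbank a [build_mel_filterbank()] result; its `n_fft` must
#'   match `n_fft` here (i.e. build it with the same value).
#' @param frame_s,hop_s STFT frame length and hop (s).
#' @param n_coeff number of cepstral coefficients (default 13).
#' @param mel_floor floor applied to mel energies before the log.
#' @return object of class `mfcc_frames`: `coefficients` (n_frames x
#'   n_coeff), `frame_times_s`, `fmin_hz`, `fmax_hz`.
#' @export
mfcc_frames <- function(segment, filterbank, frame_s = 0.025, hop_s = 0.010,
                        n_coeff = 13, mel_floor = 1e-10) {
  fs <- segment$sample_rate_hz
  flen <- round(frame_s * fs); hlen <- round(hop_s * fs)
  n_fft <- 2L * (ncol(filterbank$weights) - 1L)
  if (flen > n_fft) {
    phon_stop("invalidParams",
              "filterbank built for n_fft = %d but frame has %d samples",
              n_fft, flen)
  }
  if (length(segment$samples) < flen) {
    phon_stop("invalidInput", "segment shorter than one MFCC frame")
  }
  frames <- frame_signal(segment$samples, flen, hlen)
  w <- hann_window(flen)
  padded <- matrix(0, n_fft, ncol(frames))
  padded[seq_len(flen), ] <- frames * w
  pow <- abs(stats::mvfft(padded))^2
  pow <- pow[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
  mel_db <- db10(filterbank$weights %*% pow, mel_floor)
  coeffs <- t(dct_matrix(n_coeff, filterbank$n_filters) %*% mel_db)
  structure(list(coefficients = coeffs,
                 frame_times_s = frame_times(length(segment$samples), flen,
                                             hlen, fs),
                 fmin_hz = filterbank$fmin_hz, fmax_hz = filterbank$fmax_hz),
            class = "mfcc_frames")
}

# Direct cosine-sum evaluation of the cepstral transform on a log mel
# spectrum: an independent slow path used to validate mfcc_frames.
mfcc_direct_oracle <- function(log_mel, n_coeff) {
  n <- length(log_mel)
  vapply(seq_len(n_coeff), function(k) {
    w <- cos(pi * (k - 1) * (seq_len(n) - 0.5) / n) * sqrt(2 / n)
    if (k == 1) w <- w / sqrt(2)
    sum(w * log_mel)
  }, numeric(1))
}

#' Per-recording MFCC summary (mean and SD across frames)
#'
#' @param frames an [mfcc_frames()] result.
#' @return object of class `mfcc_summary` with numeric vectors `mfcc_mn`
#'   and `mfcc_sd` (population SD across frames, 1-based coefficient
#'   indexing) plus the `fmax_hz` tag.
#' @export
mfcc_summary <- function(frames) {
  m <- frames$coefficients
  if (nrow(m) < 2) {
    phon_warn("single MFCC frame: SDs reported as 0")
    sds <- rep(0, ncol(m))
  } else {
    sds <- apply(m, 2, function(v) sqrt(mean((v - mean(v))^2)))
  }
  structure(list(mfcc_mn = colMeans(m), mfcc_sd = sds,
                 fmax_hz = frames$fmax_hz),
            class = "mfcc_summary")
}

#' MFCC2 cosine weights remapped to frequency in Hz
#'
#' The half-cycle cosine term over the filter index, plotted against each
#' filter's center frequency: positive at low frequencies, negative at high,
#' with a single zero crossing whose location moves up with `fmax_hz`.
#'
#' @param filterbank a [build_mel_filterbank()] result.
#' @return data.frame with `freq_hz` and `weight`.
#' @export
mfcc2_weighting_curve <- function(filterbank) {
  n <- filterbank$n_filters
  data.frame(
    freq_hz = filterbank$center_freqs_hz,
    weight = cos(pi * (seq_len(n) - 0.5) / n) * sqrt(2 / n)
  )
}

#' Octave-band spectral contrast
#'
#' Per STFT frame and band: the dB difference between the mean of the top
#' and bottom quantile of within-band spectral magnitudes (quantile
#' fraction `quantile_fraction`, at least one bin), with dB taken as
#' `10 log10` of the magnitude ratio — the convention of the widely used
#' Python implementation this feature mirrors. High contrast marks strong
#' harmonic peaks over a low noise floor; noise-like spectra score near 0.
#'
#' @param segment `phonation_segment`.
#' @param bands list of `c(low, high)` band edges in Hz; defaults to octave
#'   bands 100-200 ... 3200-6400 Hz.
#' @param frame_s,hop_s STFT framing (s).
#' @param quantile_fraction fraction of band bins in each quantile.
#' @return data.frame with one row per band: `low_hz`, `high_hz`,
#'   `contrast_mn_db`, `contrast_sd_db`.
#' @export
spectral_contrast_octave <- function(segment,
                                     bands = lapply(0:5, function(k) 100 * 2^k * c(1, 2)),
                                     frame_s = 0.025, hop_s = 0.010,
                                     quantile_fraction = 0.02) {
  fs <- segment$sample_rate_hz
  flen <- round(frame_s * fs); hlen <- round(hop_s * fs)
  n_fft <- next_pow2(flen)
  frames <- frame_signal(segment$samples, flen, hlen)
  padded <- matrix(0, n_fft, ncol(frames))
  padded[seq_len(flen), ] <- frames * hann_window(flen)
  mag <- abs(stats::mvfft(padded))
  mag <- mag[seq_len(n_fft %/% 2L + 1L), , drop = FALSE]
  bin_freqs <- (seq_len(nrow(mag)) - 1L) * fs / n_fft
  # merge bands with < 2 bins into their upper neighbour
  idx <- lapply(bands, function(b) which(bin_freqs >= b[1] & bin_freqs < b[2]))
  i <- 1L
  while (i < length(idx)) {
    if (length(idx[[i]]) < 2) {
      phon_warn("spectral contrast band %g-%g Hz has < 2 bins; merged",
                bands[[i]][1], bands[[i]][2])
      idx[[i + 1L]] <- sort(union(idx[[i]], idx[[i + 1L]]))
      bands[[i + 1L]][1] <- bands[[i]][1]
      idx[[i]] <- integer(0)
    }
    i <- i + 1L
  }
  keep <- lengths(idx) > 0
  bands <- bands[keep]; idx <- idx[keep]
  rows <- lapply(seq_along(bands), function(bi) {
    bins <- idx[[bi]]
    k <- max(1L, floor(quantile_fraction * length(bins)))
    per_frame <- apply(mag[bins, , drop = FALSE], 2, function(p) {
      s <- sort(p)
      db10(mean(tail(s, k))) - db10(mean(head(s, k)))
    })
    data.frame(low_hz = bands[[bi]][1], high_hz = bands[[bi]][2],
               contrast_mn_db = mean(per_frame),
               contrast_sd_db = sd_pop(per_frame))
  })
  do.call(rbind, rows)
}

sd_pop <- function(v) if (length(v) < 2) 0 else sqrt(mean((v - mean(v))^2))

#' Spectral flatness (Wiener entropy)
#'
#' Per STFT frame, the geometric over arithmetic mean of the power spectrum:
#' 1 for white noise, near 0 for tonal spectra.
#'
#' @param segment `phonation_segment`.
#' @param frame_s,hop_s STFT framing (s).
#' @param floor_val power floor before the geometric mean.
#' @return list with `flatness_mn` and `flatness_sd` (population SD).
#' @export
spectral_flatness <- function(segment, frame_s = 0.025, hop_s = 0.010,
                              floor_val = 1e-10) {
  fs <- segment$sample_rate_hz
  flen <- round(frame_s * fs); hlen <- round(hop_s * fs)
  n_fft <- next_pow2(flen)
  frames <- frame_signal(segment$samples, flen, hlen)
  if (ncol(frames) == 0) phon_stop("invalidInput", "segment shorter than one frame")
  padded <- matrix(0, n_fft, ncol(frames))
  padded[seq_len(flen), ] <- frames * hann_window(flen)
  pow <- abs(stats::mvfft(padded))^2
  pow <- pmax(pow[seq_len(n_fft %/% 2L + 1L), , drop = FALSE], floor_val)
  flat <- apply(pow, 2, function(p) exp(mean(log(p))) / mean(p))
  list(flatness_mn = mean(flat), flatness_sd = sd_pop(flat))
}

#' Frame RMS intensity in dB
#'
#' @param segment `phonation_segment`.
#' @param frame_s,hop_s framing (s).
#' @return list with `rms_mn_db` and `rms_sd_db` across frames
#'   (dB re full scale).
#' @export
rms_intensity_db <- function(segment, frame_s = 0.025, hop_s = 0.010) {
  fs <- segment$sample_rate_hz
  frames <- frame_signal(segment$samples, round(frame_s * fs),
                         round(hop_s * fs))
  lev <- db10(apply(frames, 2, function(f) mean(f^2)))
  list(rms_mn_db = mean(lev), rms_sd_db = sd_pop(lev))
}
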