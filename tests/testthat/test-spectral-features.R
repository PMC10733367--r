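# Welch PSD, Energy Ratio, mel filterbank, MFCCs, contrast and flatness.

test_that("Welch PSD localizes a sine and satisfies Parseval", {
  seg <- sine_segment(1000)
  psd <- welch_psd(seg)
  df <- psd$freqs_hz[2] - psd$freqs_hz[1]
  expect_lte(abs(psd$freqs_hz[which.max(psd$pxx)] - 1000), df)

  noise <- fixture_noise_segment()
  psd_n <- welch_psd(noise)
  integral <- sum(diff(psd_n$freqs_hz) *
                  (head(psd_n$pxx, -1) + tail(psd_n$pxx, -1)) / 2)
  expect_lt(abs(integral - mean(noise$samples^2)) / mean(noise$samples^2),
            0.05)

  expect_true(all(welch_psd(as_phonation_segment(numeric(FS), FS))$pxx == 0))
  expect_error(welch_psd(as_phonation_segment(numeric(100), FS)),
               class = "invalidInput")
})

test_that("Energy Ratio matches the analytic flat-spectrum value", {
  flat <- structure(list(freqs_hz = seq(0, 16000, by = 50),
                         pxx = rep(1, 321)), class = "psd")
  expect_equal(energy_ratio_db(flat)$er_db, 10 * log10(4000 / 8000),
               tolerance = 1e-6)
})

test_that("Energy Ratio rejects degenerate and band-limited spectra", {
  freqs <- seq(0, 16000, by = 50)
  lowpass <- structure(list(freqs_hz = freqs,
                            pxx = as.numeric(freqs < 4000)), class = "psd")
  expect_error(energy_ratio_db(lowpass), class = "degenerateSpectrum")
  narrow <- structure(list(freqs_hz = seq(0, 8000, by = 50),
                           pxx = rep(1, 161)), class = "psd")
  expect_error(energy_ratio_db(narrow, fmax_hz = 12000),
               class = "insufficientBandwidth")
})

test_that("mel filterbank has valid triangular structure and coverage", {
  fb <- fb12()
  expect_true(all(fb$weights >= 0))
  expect_true(all(rowSums(fb$weights) > 0))
  expect_true(all(diff(fb$center_freqs_hz) > 0))
  # every bin between fmin and fmax is covered by some filter
  inside <- fb$bin_freqs_hz > 133 & fb$bin_freqs_hz < 12000
  expect_true(all(colSums(fb$weights)[inside] > 0))
  # each filter peaks at the bin nearest its center
  for (i in c(1, 10, 25, 40)) {
    peak_bin <- which.max(fb$weights[i, ])
    expect_lt(abs(fb$bin_freqs_hz[peak_bin] - fb$center_freqs_hz[i]),
              2 * FS / 1024)
  }
  expect_gt(max(fb$center_freqs_hz), max(fb8()$center_freqs_hz))
  expect_error(build_mel_filterbank(FS, 1024, fmax_hz = 17000),
               class = "insufficientBandwidth")
})

test_that("mel-scale endpoints agree with the closed-form formulas", {
  # Slaney: linear f * 3/200 below 1 kHz, 15 + 27 ln(f/1000)/ln(6.4) above
  expect_equal(phonmark:::hz_to_mel(133, "slaney"), 133 * 3 / 200)
  expect_equal(phonmark:::hz_to_mel(12000, "slaney"),
               15 + 27 * log(12) / log(6.4))
  expect_equal(phonmark:::hz_to_mel(2000, "htk"),
               2595 * log10(1 + 2000 / 700))
  # inverses round-trip
  for (f in c(133, 800, 1000, 4000, 12000)) {
    expect_equal(phonmark:::mel_to_hz(phonmark:::hz_to_mel(f, "slaney"),
                                      "slaney"), f, tolerance = 1e-9)
    expect_equal(phonmark:::mel_to_hz(phonmark:::hz_to_mel(f, "htk"), "htk"),
                 f, tolerance = 1e-9)
  }
})

test_that("fast cepstral transform equals the direct cosine-sum oracle", {
  dct <- phonmark:::dct_matrix(13, 40)
  mel_vectors <- phonmark:::with_seed(41, {
    matrix(stats::runif(40 * 100, -20, 100), nrow = 40)
  })
  fast <- t(dct %*% mel_vectors)
  slow <- t(apply(mel_vectors, 2, phonmark:::mfcc_direct_oracle, n_coeff = 13))
  expect_lt(max(abs(fast - slow)), 1e-9)
})

test_that("MFCC coefficients k >= 2 vanish on a constant mel spectrum", {
  v <- rep(37.5, 40)
  cc <- phonmark:::dct_matrix(13, 40) %*% v
  expect_true(all(abs(cc[2:13]) < 1e-9))
  expect_gt(cc[1], 0)
})

test_that("MFCC2 is positive for low-band energy and negative for high", {
  low <- c(rep(60, 2), rep(0, 38))   # energy in the two lowest filters
  high <- c(rep(0, 38), rep(60, 2))
  dct <- phonmark:::dct_matrix(2, 40)
  expect_gt((dct %*% low)[2], 0)
  expect_lt((dct %*% high)[2], 0)
})

test_that("mfcc_frames agrees with the oracle end to end", {
  seg <- fixture_clean_segment()
  fb <- fb12()
  fr <- mfcc_frames(seg, fb)
  # recompute frame 5's log mel spectrum independently and compare
  flen <- round(0.025 * FS); hlen <- round(0.010 * FS)
  i0 <- 4 * hlen + 1
  frame <- seg$samples[i0:(i0 + flen - 1)] * phonmark:::hann_window(flen)
  spec <- (abs(stats::fft(c(frame, numeric(1024 - flen))))^2)[1:513]
  mel_db <- 10 * log10(pmax(fb$weights %*% spec, 1e-10))
  expect_equal(unname(fr$coefficients[5, ]),
               phonmark:::mfcc_direct_oracle(as.numeric(mel_db), 13),
               tolerance = 1e-9)
})

test_that("amplitude scaling shifts MFCC1 only and leaves ER unchanged", {
  seg <- fixture_clean_segment()
  seg_scaled <- as_phonation_segment(seg$samples * 3.7, FS)
  s1 <- mfcc_summary(mfcc_frames(seg, fb12()))
  s2 <- mfcc_summary(mfcc_frames(seg_scaled, fb12()))
  expect_gt(s2$mfcc_mn[1], s1$mfcc_mn[1])
  expect_lt(max(abs(s2$mfcc_mn[-1] - s1$mfcc_mn[-1])), 1e-6)
  er1 <- energy_ratio_db(welch_psd(seg))$er_db
  er2 <- energy_ratio_db(welch_psd(seg_scaled))$er_db
  expect_lt(abs(er1 - er2), 1e-6)
})

test_that("mfcc_summary computes mean and population SD per coefficient", {
  fr <- structure(list(coefficients = rbind(c(10, 4), c(10, 8)),
                       fmax_hz = 12000), class = "mfcc_frames")
  sm <- mfcc_summary(fr)
  expect_equal(sm$mfcc_mn, c(10, 6))
  expect_equal(sm$mfcc_sd, c(0, 2))  # population SD: |a - b| / 2
  one <- structure(list(coefficients = rbind(c(1, 2)), fmax_hz = 12000),
                   class = "mfcc_frames")
  expect_warning(sm1 <- mfcc_summary(one), "single")
  expect_equal(sm1$mfcc_sd, c(0, 0))
})

test_that("amplitude wobble inflates the MFCC1 standard deviation", {
  rec <- fixture_clean_recording()
  seg <- extract_phonation(rec)
  t <- seq_along(seg$samples) / FS
  wobble <- 10^((3 / 20) * sin(2 * pi * 1.5 * t))  # 3 dB slow AM
  seg_w <- as_phonation_segment(seg$samples * wobble, FS)
  sd_flat <- mfcc_summary(mfcc_frames(seg, fb12()))$mfcc_sd[1]
  sd_wob <- mfcc_summary(mfcc_frames(seg_w, fb12()))$mfcc_sd[1]
  expect_gt(sd_wob, sd_flat)
})

test_that("MFCC2 weighting curve crosses zero once, higher for fmax 12k", {
  c12 <- mfcc2_weighting_curve(fb12())
  c8 <- mfcc2_weighting_curve(fb8())
  for (cv in list(c12, c8)) {
    expect_gt(cv$weight[1], 0)
    expect_lt(cv$weight[nrow(cv)], 0)
    expect_equal(sum(diff(sign(cv$weight)) != 0), 1)
  }
  crossing <- function(cv) cv$freq_hz[which(diff(sign(cv$weight)) != 0)]
  expect_gt(crossing(c12), crossing(c8))
})

test_that("spectral contrast separates tones from noise", {
  ct_noise <- suppressWarnings(spectral_contrast_octave(fixture_noise_segment()))
  expect_true(all(ct_noise$contrast_mn_db < 15))
  # a 150 Hz tone over a -60 dB noise floor; 200 ms frames narrow the
  # window mainlobe enough to expose peak-versus-floor structure inside
  # the lowest octave band
  tone <- sine_segment(150, dur_s = 2)
  tone$samples <- tone$samples +
    phonmark:::with_seed(88, 5e-4 * stats::rnorm(length(tone$samples)))
  ct_tone <- suppressWarnings(spectral_contrast_octave(tone, frame_s = 0.2))
  lowest <- ct_tone$contrast_mn_db[ct_tone$low_hz <= 150 &
                                   ct_tone$high_hz > 150]
  highest <- ct_tone$contrast_mn_db[nrow(ct_tone)]
  expect_gt(lowest, highest + 20)
  # stationary input: contrast stable across frames
  expect_true(all(ct_tone$contrast_sd_db < 3))
})

test_that("spectral flatness is high for noise, near zero for a tone", {
  expect_gt(spectral_flatness(fixture_noise_segment())$flatness_mn, 0.3)
  expect_lt(spectral_flatness(sine_segment(440))$flatness_mn, 0.01)
  fl <- spectral_flatness(fixture_clean_segment())
  expect_true(fl$flatness_mn >= 0 && fl$flatness_mn <= 1)
})
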