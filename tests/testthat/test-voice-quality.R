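# Pitch, glottal cycles, jitter, shimmer, HNR and CPP.

test_that("pitch contour recovers the synthesis fundamental", {
  seg <- fixture_clean_segment()
  pc <- pitch_contour(seg)
  expect_lt(abs(mean(pc$f0_hz) - 115), 2)
  ps <- pitch_stats(pc)
  expect_lt(ps$pitch_sd_hz, 2)
  expect_error(pitch_contour(fixture_noise_segment()),
               class = "unvoicedInput")
})

test_that("a one-octave glide spans close to 12 semitones", {
  fs <- FS; dur <- 2
  t <- (0:(dur * fs - 1)) / fs
  f_inst <- 100 + 50 * t / dur * 2          # 100 -> 200 Hz linear
  phase <- 2 * pi * cumsum(f_inst) / fs
  seg <- as_phonation_segment(0.5 * sign(sin(phase)) *
                                (1 + 0.3 * sin(phase)), fs)
  ps <- pitch_stats(pitch_contour(seg))
  expect_true(ps$pitch_semitone_range >= 11 && ps$pitch_semitone_range <= 13)
})

test_that("cycle detection counts the expected number of glottal cycles", {
  seg <- fixture_clean_segment()
  cyc <- cycle_series(seg)
  expected <- seg$retained_s * 115
  expect_lt(abs(length(cyc$period_s) - expected) / expected, 0.05)
  expect_error(cycle_series(as_phonation_segment(numeric(FS), FS)),
               class = c("unvoicedInput"))
})

test_that("detected cycle periods track the synthesis truth", {
  gl <- glottal_source_params(100, 4.5, jitter_fraction = 0.01)
  rec <- simulate_phonation(speaker_profile("male", glottal = gl),
                            aspiration_params(0), FS, seed = 51)
  seg <- extract_phonation(rec)
  cyc <- cycle_series(seg)
  # match each detected mark to its nearest truth onset, then compare the
  # periods of consecutive matched cycles
  truth_on <- rec$truth$cycle_onsets_s - seg$source_start_s
  nearest <- vapply(cyc$mark_times_s, function(t) {
    which.min(abs(truth_on - t))
  }, integer(1))
  consec <- which(diff(nearest) == 1)
  expect_gt(length(consec), 100)
  truth_periods <- truth_on[nearest[consec] + 1L] - truth_on[nearest[consec]]
  expect_gt(stats::cor(truth_periods, cyc$period_s[consec]), 0.9)
})

test_that("jitter matches hand-computed and round-trip values", {
  mk <- function(periods) structure(list(period_s = periods,
                                         peak_amplitude = rep(1, length(periods) + 1)),
                                    class = "cycle_series")
  expect_equal(jitter_local_abs(mk(rep(0.010, 10))), 0)
  expect_equal(jitter_local_abs(mk(c(9, 11, 9, 11) / 1000)), 0.002)
  expect_error(jitter_local_abs(mk(c(0.01, 0.01))), class = "tooFewCycles")

  gl <- glottal_source_params(100, 4.5, jitter_fraction = 0.01,
                              shimmer_db = 0)
  rec <- simulate_phonation(speaker_profile("male", glottal = gl),
                            aspiration_params(0), FS, seed = 52)
  cyc <- cycle_series(extract_phonation(rec))
  truth <- mean(abs(diff(rec$truth$cycle_periods_s)))
  expect_lt(abs(jitter_local_abs(cyc) - truth) / truth, 0.20)
})

test_that("shimmer matches hand-computed and round-trip values", {
  mk <- function(amps) structure(list(period_s = rep(0.01, length(amps) - 1),
                                      peak_amplitude = amps),
                                 class = "cycle_series")
  expect_equal(shimmer_local_db(mk(rep(0.8, 10))), 0)
  expect_equal(shimmer_local_db(mk(c(1, 2, 1, 2))), 20 * log10(2),
               tolerance = 1e-12)
  expect_error(shimmer_local_db(mk(c(1, 0, 1, 2))), class = "invalidCycles")

  gl <- glottal_source_params(115, 4.5, jitter_fraction = 0,
                              shimmer_db = 0.5)
  rec <- simulate_phonation(speaker_profile("male", glottal = gl),
                            aspiration_params(0), FS, seed = 53)
  cyc <- cycle_series(extract_phonation(rec))
  ta <- rec$truth$cycle_amplitudes
  truth <- mean(abs(20 * log10(ta[-1] / ta[-length(ta)])))
  expect_lt(abs(shimmer_local_db(cyc) - truth) / truth, 0.25)
})

test_that("HNR maps r = 0.5 to 0 dB and separates voice from noise", {
  contour <- data.frame(frame_times_s = 1:5 / 100, f0_hz = rep(100, 5),
                        periodicity = rep(0.5, 5))
  hn <- harmonicity_hnr(NULL, contour = contour)
  expect_equal(hn$hnr_mn_db, 0, tolerance = 1e-9)

  clean <- simulate_phonation(speaker_profile("male"), aspiration_params(0),
                              FS, seed = 54)
  expect_gt(harmonicity_hnr(extract_phonation(clean))$hnr_mn_db, 20)

  # force evaluation on noise by supplying a nominal contour
  noise <- fixture_noise_segment()
  vt <- voicing_track(noise$samples, FS)
  forced <- data.frame(frame_times_s = vt$frame_times_s,
                       f0_hz = vt$f0_candidate_hz,
                       periodicity = vt$periodicity)
  expect_lt(harmonicity_hnr(NULL, contour = forced)$hnr_mn_db, 0)
})

test_that("CPP is higher for clean voice than noisy voice or noise", {
  clean <- extract_phonation(
    simulate_phonation(speaker_profile("male"), aspiration_params(0), FS,
                       seed = 55))
  noisy <- extract_phonation(
    simulate_phonation(speaker_profile("male"), aspiration_params(0.5), FS,
                       seed = 55))
  cpp_clean <- cepstral_peak_prominence(clean)
  cpp_noisy <- cepstral_peak_prominence(noisy)
  expect_gt(cpp_clean$cpp_mn_db, cpp_noisy$cpp_mn_db)
  expect_lt(cepstral_peak_prominence(fixture_noise_segment())$cpp_mn_db, 5)
  # a truly stationary voice (no jitter/shimmer) is stable across frames
  gl0 <- glottal_source_params(115, 4.5, jitter_fraction = 0, shimmer_db = 0)
  stationary <- extract_phonation(
    simulate_phonation(speaker_profile("male", glottal = gl0),
                       aspiration_params(0), FS, seed = 56))
  expect_lt(cepstral_peak_prominence(stationary)$cpp_sd_db, 0.5)
})

test_that("voice-quality metrics are invariant to global amplitude gain", {
  seg <- fixture_clean_segment()
  seg10 <- as_phonation_segment(seg$samples * 10, FS)
  a <- voice_quality_set(seg)
  b <- voice_quality_set(seg10)
  for (f in c("jitter_localabs_s", "shimmer_local_db", "hnr_mn_db",
              "cpp_mn_db", "pitch_mn_hz")) {
    expect_lt(abs(a[[f]] - b[[f]]), 1e-6)
  }
})
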