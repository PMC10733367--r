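# Shared fixtures, built once per test run. Everything is generated in code
# under fixed seeds; no audio is stored on disk.

FS <- 32000

# a clean male sustained /a/ (mild jitter/shimmer, light aspiration)
fixture_clean_recording <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      val <<- simulate_phonation(speaker_profile("male"),
                                 aspiration_params(0.05), FS, seed = 101)
    }
    val
  }
})

fixture_clean_segment <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- extract_phonation(fixture_clean_recording())
    val
  }
})

# seeded white-noise segment for noise-floor behaviour
fixture_noise_segment <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      x <- phonmark:::with_seed(202, stats::rnorm(FS * 2))
      val <<- as_phonation_segment(x / max(abs(x)), FS)
    }
    val
  }
})

# a pure sine segment
sine_segment <- function(freq_hz, dur_s = 1, fs = FS, amp = 0.5) {
  as_phonation_segment(amp * sin(2 * pi * freq_hz * (0:(dur_s * fs - 1)) / fs),
                       fs)
}

# brute-force AUC by pair enumeration (ties count one half)
auc_brute_force <- function(values, labels, controls) {
  pos <- values[labels == controls]
  neg <- values[labels != controls]
  s <- 0
  for (a in pos) for (b in neg) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(pos) * length(neg))
}

# the default synthetic study cohort (n = 120) with extracted features,
# built lazily and shared by the cohort-level tests
fixture_cohort_table <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      co <- simulate_cohort(cohort_spec(n_per_cell = 30, seed = 42))
      fx <- cohort_features(co$recordings)
      val <<- merge(co$manifest, fx$features, by = "subject_id")
    }
    val
  }
})

# default filterbank for MFCC tests
fb12 <- function(n_fft = 1024) build_mel_filterbank(FS, n_fft, 40, 133, 12000)
fb8 <- function(n_fft = 1024) build_mel_filterbank(FS, n_fft, 40, 133, 8000)
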