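# Source-filter synthesis of sustained /a/ phonation.
#
# The voiced source is an impulse train with cycle-level period (jitter) and
# amplitude (shimmer) perturbation, spectrally shaped to a -12 dB/octave
# roll-off. Breathiness is modelled as additive aspiration noise whose
# spectrum falls off less steeply than the voiced source (default
# -3 dB/octave), so raising the noise gain preferentially raises
# high-frequency energy -- the mechanism that depresses low-to-high energy
# ratios (Energy Ratio, MFCC2) in breathy, disordered voices.

#' Glottal source parameters
#'
#' @param f0_hz fundamental frequency in Hz, in `[60, 400]`.
#' @param duration_s total synthesis length in seconds (>= 4 so the segmenter
#'   can discard 0.75 s and keep 2.5 s).
#' @param jitter_fraction SD of cycle-to-cycle period perturbation as a
#'   fraction of the mean period.
#' @param shimmer_db SD of cycle-to-cycle amplitude perturbation in dB.
#' @param source_tilt_db_per_octave spectral roll-off of the voiced source
#'   (negative; default -12 dB/octave).
#' @return object of class `glottal_source_params`.
#' @export
glottal_source_params <- function(f0_hz, duration_s = 4.5, jitter_fraction = 0,
                                  shimmer_db = 0,
                                  source_tilt_db_per_octave = -12) {
  if (f0_hz < 60 || f0_hz > 400) {
    phon_stop("invalidParams", "f0_hz must lie in [60, 400], got %g", f0_hz)
  }
  if (duration_s < 4) {
    phon_stop("invalidParams", "duration_s must be >= 4 s, got %g", duration_s)
  }
  if (jitter_fraction < 0 || shimmer_db < 0) {
    phon_stop("invalidParams", "jitter_fraction and shimmer_db must be >= 0")
  }
  structure(list(f0_hz = f0_hz, duration_s = duration_s,
                 jitter_fraction = jitter_fraction, shimmer_db = shimmer_db,
                 source_tilt_db_per_octave = source_tilt_db_per_octave),
            class = "glottal_source_params")
}

#' Aspiration noise parameters
#'
#' @param noise_gain RMS of the aspiration noise relative to the voiced
#'   component's RMS (>= 0; 0 disables noise).
#' @param noise_tilt_db_per_octave roll-off of the noise spectrum in
#'   dB/octave. Must be shallower (less negative) than the source tilt it is
#'   paired with; default -3.
#' @param cycle_modulation_depth fraction in `[0, 1]` of amplitude modulation
#'   of the noise by the glottal cycle (turbulence is strongest around the
#'   open phase).
#' @param noise_band_hz optional `c(low, high)` band limit in Hz; when given,
#'   noise energy is confined to this band. `NULL` (default) means broadband.
#' @return object of class `aspiration_params`.
#' @export
aspiration_params <- function(noise_gain = 0, noise_tilt_db_per_octave = -3,
                              cycle_modulation_depth = 0.5,
                              noise_band_hz = NULL) {
  if (noise_gain < 0) phon_stop("invalidParams", "noise_gain must be >= 0")
  if (cycle_modulation_depth < 0 || cycle_modulation_depth > 1) {
    phon_stop("invalidParams", "cycle_modulation_depth must lie in [0, 1]")
  }
  if (!is.null(noise_band_hz) &&
      (length(noise_band_hz) != 2 || noise_band_hz[1] >= noise_band_hz[2])) {
    phon_stop("invalidParams", "noise_band_hz must be c(low, high) with low < high")
  }
  structure(list(noise_gain = noise_gain,
                 noise_tilt_db_per_octave = noise_tilt_db_per_octave,
                 cycle_modulation_depth = cycle_modulation_depth,
                 noise_band_hz = noise_band_hz),
            class = "aspiration_params")
}

#' Vocal tract resonance parameters
#'
#' @param formant_frequencies_hz strictly increasing formant frequencies (Hz).
#' @param formant_bandwidths_hz matching -3 dB bandwidths (Hz), all > 0.
#' @return object of class `vocal_tract_params`.
#' @export
vocal_tract_params <- function(formant_frequencies_hz,
                               formant_bandwidths_hz) {
  f <- formant_frequencies_hz; bw <- formant_bandwidths_hz
  if (length(f) != length(bw)) {
    phon_stop("invalidParams", "formant frequency and bandwidth lists differ in length")
  }
  if (length(f) > 1 && any(diff(f) <= 0)) {
    phon_stop("invalidParams", "formant frequencies must be strictly increasing")
  }
  if (any(bw <= 0)) phon_stop("invalidParams", "formant bandwidths must be > 0")
  structure(list(formant_frequencies_hz = f, formant_bandwidths_hz = bw),
            class = "vocal_tract_params")
}

#' Speaker profile with sex-typical defaults
#'
#' Defaults follow standard /a/ values: male f0 115 Hz with formants
#' 700/1220/2600 Hz; female f0 215 Hz with formants scaled by 1.15.
#'
#' @param sex_label one of `"male"`, `"female"`, `"other"`.
#' @param f0_hz fundamental frequency override (Hz).
#' @param glottal optional [glottal_source_params()] override.
#' @param tract optional [vocal_tract_params()] override.
#' @param duration_s synthesis length passed to the default glottal source.
#' @return object of class `speaker_profile`.
#' @export
speaker_profile <- function(sex_label = c("male", "female", "other"),
                            f0_hz = NULL, glottal = NULL, tract = NULL,
                            duration_s = 4.5) {
  sex_label <- match.arg(sex_label)
  if (is.null(f0_hz)) f0_hz <- if (sex_label == "female") 215 else 115
  if (is.null(glottal)) {
    glottal <- glottal_source_params(f0_hz = f0_hz, duration_s = duration_s,
                                     jitter_fraction = 0.005, shimmer_db = 0.3)
  }
  if (is.null(tract)) {
    scale <- if (sex_label == "female") 1.15 else 1.0
    tract <- vocal_tract_params(c(700, 1220, 2600) * scale, c(80, 90, 120))
  }
  structure(list(sex_label = sex_label, glottal = glottal, tract = tract),
            class = "speaker_profile")
}

# Apply a constant-dB-per-octave spectral tilt by FFT filtering with a
# minimum-phase response of the desired magnitude. Minimum phase keeps each
# glottal pulse causal (no pre-ringing), so cycle peaks stay aligned with
# excitation instants. Unity gain at ref_hz; the gain is clamped below
# ref_hz so DC is not boosted.
apply_spectral_tilt <- function(x, tilt_db_per_octave, sample_rate_hz,
                                ref_hz) {
  n <- length(x)
  nf <- next_pow2(n)
  freqs <- (0:(nf - 1)) / nf * sample_rate_hz
  freqs <- pmin(freqs, sample_rate_hz - freqs)  # mirror for negative freqs
  gain_db <- tilt_db_per_octave * log2(pmax(freqs, ref_hz) / ref_hz)
  h <- min_phase_response(10^(gain_db / 20))
  y <- Re(fft(fft(c(x, rep(0, nf - n))) * h, inverse = TRUE)) / nf
  y[seq_len(n)]
}

# Minimum-phase frequency response with the given (full-length, symmetric)
# magnitude, via the real-cepstrum folding construction.
min_phase_response <- function(mag) {
  nf <- length(mag)
  cep <- Re(fft(log(pmax(mag, 1e-12)), inverse = TRUE)) / nf
  win <- numeric(nf)
  win[1] <- 1
  half <- nf %/% 2L
  win[2:half] <- 2
  win[half + 1L] <- 1
  exp(fft(cep * win))
}

#' Generate a quasi-periodic glottal source waveform
#'
#' An impulse train whose cycle onsets follow periods
#' `T0 * (1 + jitter_fraction * z_i)` and amplitudes `10^(shimmer_db * z'_i / 20)`
#' (`z`, `z'` standard normal), then shaped to the source spectral tilt.
#' The realized per-cycle periods and amplitudes (after sample quantization
#' of the onsets) are returned as ground truth.
#'
#' @param params [glottal_source_params()].
#' @param sample_rate_hz synthesis rate (Hz); must exceed `4 * f0_hz`.
#' @param seed RNG seed for the perturbations.
#' @return object of class `glottal_source`: `samples`, `sample_rate_hz`,
#'   `cycle_onsets_s`, `cycle_periods_s`, `cycle_amplitudes`, and
#'   `cycle_envelope` (a `[0, 1]` per-sample glottal-cycle envelope used to
#'   modulate aspiration noise).
#' @export
generate_glottal_source <- function(params, sample_rate_hz = 32000,
                                    seed = 1) {
  stopifnot(inherits(params, "glottal_source_params"))
  if (params$f0_hz >= sample_rate_hz / 4) {
    phon_stop("invalidParams", "f0 must be below sample_rate/4")
  }
  t0 <- 1 / params$f0_hz
  n_cycles_max <- ceiling(params$duration_s / t0) + 10L
  if (params$duration_s / t0 < 10) {
    phon_stop("invalidParams", "duration too short for >= 10 glottal cycles")
  }
  n <- round(params$duration_s * sample_rate_hz)
  with_seed(seed, {
    periods <- t0 * (1 + params$jitter_fraction * rnorm(n_cycles_max))
    periods <- pmax(periods, 0.25 * t0)
    amps <- 10^(params$shimmer_db * rnorm(n_cycles_max) / 20)
  })
  onsets_s <- cumsum(c(0, periods))
  keep <- onsets_s < params$duration_s
  onsets_s <- onsets_s[keep]
  amps <- amps[seq_along(onsets_s)]
  onset_idx <- round(onsets_s * sample_rate_hz) + 1L
  # de-duplicate onsets that quantize to the same sample (extreme jitter only)
  ok <- !duplicated(onset_idx) & onset_idx <= n
  onset_idx <- onset_idx[ok]; amps <- amps[ok]

  x <- numeric(n)
  x[onset_idx] <- amps
  x <- apply_spectral_tilt(x, params$source_tilt_db_per_octave,
                           sample_rate_hz, ref_hz = params$f0_hz)

  # per-sample envelope: raised cosine peaking at each excitation instant
  env <- numeric(n)
  bounds <- c(onset_idx, n + 1L)
  for (i in seq_along(onset_idx)) {
    span <- bounds[i]:(bounds[i + 1L] - 1L)
    len <- length(span)
    env[span] <- 0.5 + 0.5 * cos(2 * pi * (seq_len(len) - 1) / len)
  }

  realized_onsets <- (onset_idx - 1L) / sample_rate_hz
  structure(list(
    samples = x,
    sample_rate_hz = sample_rate_hz,
    cycle_onsets_s = realized_onsets,
    cycle_periods_s = diff(realized_onsets),
    cycle_amplitudes = amps,
    cycle_envelope = env
  ), class = "glottal_source")
}

#' Filter a waveform through a cascade of formant resonators
#'
#' Each formant is a two-pole resonator (pole radius `exp(-pi * BW / fs)`,
#' angle `2 * pi * F / fs`) normalized to unity gain at DC; resonators are
#' applied in cascade. An empty formant list is the identity.
#'
#' @param waveform numeric vector.
#' @param tract [vocal_tract_params()].
#' @param sample_rate_hz sampling rate (Hz).
#' @return filtered waveform, same length.
#' @export
apply_vocal_tract <- function(waveform, tract, sample_rate_hz) {
  stopifnot(inherits(tract, "vocal_tract_params"))
  if (length(tract$formant_frequencies_hz) == 0) return(waveform)
  if (any(tract$formant_frequencies_hz >= sample_rate_hz / 2)) {
    phon_stop("invalidParams", "formant frequency at or above Nyquist")
  }
  y <- waveform
  for (i in seq_along(tract$formant_frequencies_hz)) {
    f <- tract$formant_frequencies_hz[i]
    bw <- tract$formant_bandwidths_hz[i]
    r <- exp(-pi * bw / sample_rate_hz)
    b1 <- 2 * r * cos(2 * pi * f / sample_rate_hz)
    b2 <- -r^2
    a0 <- 1 - b1 - b2  # unity DC gain
    y <- as.numeric(signal::filter(a0, c(1, -b1, -b2), y))
  }
  y
}

# Shape white noise to a dB/octave tilt (ref 1 kHz, clamped below 100 Hz),
# optionally band-limit, modulate by the glottal cycle, and scale to the
# requested RMS ratio.
shape_aspiration_noise <- function(n, params, cycle_envelope, sample_rate_hz,
                                   target_rms, seed) {
  noise <- with_seed(seed, rnorm(n))
  noise <- apply_spectral_tilt(noise, params$noise_tilt_db_per_octave,
                               sample_rate_hz, ref_hz = 1000)
  if (!is.null(params$noise_band_hz)) {
    X <- fft(noise)
    freqs <- (0:(n - 1)) / n * sample_rate_hz
    freqs <- pmin(freqs, sample_rate_hz - freqs)
    X[freqs < params$noise_band_hz[1] | freqs > params$noise_band_hz[2]] <- 0
    noise <- Re(fft(X, inverse = TRUE)) / n
  }
  m <- params$cycle_modulation_depth
  if (m > 0 && !is.null(cycle_envelope)) {
    noise <- noise * ((1 - m) + m * cycle_envelope[seq_len(n)])
  }
  noise * target_rms / rms(noise)
}

#' Add shaped aspiration noise to a voiced waveform
#'
#' White noise is spectrally tilted to `noise_tilt_db_per_octave` (shallower
#' than the voiced source's tilt, so it dominates at high frequency),
#' optionally band-limited and amplitude-modulated by the glottal cycle, then
#' scaled so that `RMS(noise) / RMS(voiced)` equals `noise_gain` exactly.
#'
#' @param voiced voiced waveform (non-zero RMS).
#' @param params [aspiration_params()].
#' @param cycle_envelope per-sample `[0, 1]` glottal-cycle envelope (from
#'   [generate_glottal_source()]), or `NULL` for unmodulated noise.
#' @param sample_rate_hz sampling rate (Hz).
#' @param seed RNG seed for the noise.
#' @return `voiced + noise` waveform.
#' @export
add_aspiration_noise <- function(voiced, params, cycle_envelope = NULL,
                                 sample_rate_hz = 32000, seed = 1) {
  stopifnot(inherits(params, "aspiration_params"))
  v_rms <- rms(voiced)
  if (v_rms <= 0) phon_stop("invalidParams", "voiced waveform has zero RMS")
  if (params$noise_gain == 0) return(voiced)
  noise <- shape_aspiration_noise(length(voiced), params, cycle_envelope,
                                  sample_rate_hz,
                                  target_rms = params$noise_gain * v_rms,
                                  seed = seed)
  voiced + noise
}

#' Synthesize one labeled sustained-phonation recording
#'
#' Composes glottal source, vocal tract and aspiration noise, then
#' peak-normalizes to 0.9. The generating parameters and realized cycle data
#' are carried in `truth`.
#'
#' @param profile [speaker_profile()].
#' @param aspiration [aspiration_params()].
#' @param sample_rate_hz synthesis rate (Hz), >= 24000 for 12 kHz analysis.
#' @param seed RNG seed; source and noise use seeds derived from it.
#' @param metadata optional list (subject id, group, sex, age, ...) stored on
#'   the recording.
#' @return object of class `labeled_recording`: `samples`, `sample_rate_hz`,
#'   `metadata`, `truth`.
#' @export
simulate_phonation <- function(profile, aspiration = aspiration_params(),
                               sample_rate_hz = 32000, seed = 1,
                               metadata = list()) {
  stopifnot(inherits(profile, "speaker_profile"))
  src <- generate_glottal_source(profile$glottal, sample_rate_hz,
                                 seed = child_seed(seed, 1L))
  voiced <- apply_vocal_tract(src$samples, profile$tract, sample_rate_hz)
  x <- add_aspiration_noise(voiced, aspiration, src$cycle_envelope,
                            sample_rate_hz, seed = child_seed(seed, 2L))
  x <- x * 0.9 / max(abs(x))
  metadata$sex <- metadata$sex %||% profile$sex_label
  structure(list(
    samples = x,
    sample_rate_hz = sample_rate_hz,
    metadata = metadata,
    truth = list(
      f0_hz = profile$glottal$f0_hz,
      jitter_fraction = profile$glottal$jitter_fraction,
      shimmer_db = profile$glottal$shimmer_db,
      source_tilt_db_per_octave = profile$glottal$source_tilt_db_per_octave,
      noise_gain = aspiration$noise_gain,
      noise_tilt_db_per_octave = aspiration$noise_tilt_db_per_octave,
      noise_band_hz = aspiration$noise_band_hz,
      formant_frequencies_hz = profile$tract$formant_frequencies_hz,
      cycle_onsets_s = src$cycle_onsets_s,
      cycle_periods_s = src$cycle_periods_s,
      cycle_amplitudes = src$cycle_amplitudes,
      seed = seed
    )
  ), class = "labeled_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort specification for the phonation simulator
#'
#' Defines the group-by-sex design and per-group severity distributions. The
#' case group's aspiration-noise severity must stochastically dominate the
#' control group's, so cases gain high-frequency energy by construction.
#'
#' @param n_per_cell recordings per (group x sex) cell (>= 1).
#' @param groups character vector of group labels; first is the control.
#' @param sexes character vector of sex labels.
#' @param group_severity named list, one entry per group, each with
#'   `noise_gain_meanlog` and `noise_gain_sdlog` (log-normal severity), and
#'   optional `jitter_delta` / `shimmer_delta_db` added to the speaker
#'   baseline.
#' @param age_distribution named list per group with `mean` and `sd` (years).
#' @param sex_aspiration_factor named list of multipliers applied to the
#'   drawn `noise_gain` per sex. The default (female 2.5) encodes the
#'   well-documented breathier female glottal configuration (posterior
#'   glottal gap producing relatively stronger aspiration noise), which is
#'   what gives male voices their higher low-to-high energy ratio and MFCC2.
#' @param noise_gain_cap ceiling applied to the effective per-subject
#'   noise gain. Beyond roughly this level the recording is dominated by
#'   turbulence and no longer registers as voiced, so such a phonation
#'   would be excluded at segmentation anyway; the cap keeps severe cases
#'   inside the analyzable range of the instrument.
#' @param sample_rate_hz synthesis rate, >= 24000.
#' @param duration_s recording length (s).
#' @param noise_band_hz optional band limit for the aspiration noise,
#'   passed through to every recording.
#' @param seed cohort RNG seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_cell = 30,
                        groups = c("control", "case"),
                        sexes = c("male", "female"),
                        group_severity = list(
                          control = list(noise_gain_meanlog = log(0.05),
                                         noise_gain_sdlog = 0.4),
                          case = list(noise_gain_meanlog = log(0.25),
                                      noise_gain_sdlog = 0.4)
                        ),
                        age_distribution = list(
                          control = list(mean = 63, sd = 8),
                          case = list(mean = 66, sd = 8)
                        ),
                        sex_aspiration_factor = list(male = 1, female = 2.5,
                                                     other = 1.5),
                        noise_gain_cap = 0.7,
                        sample_rate_hz = 32000, duration_s = 4.5,
                        noise_band_hz = NULL, seed = 1) {
  if (n_per_cell < 1) phon_stop("invalidParams", "n_per_cell must be >= 1")
  if (sample_rate_hz < 24000) {
    phon_stop("invalidParams", "sample_rate_hz must be >= 24000")
  }
  if (!all(groups %in% names(group_severity))) {
    phon_stop("invalidParams", "every group needs a group_severity entry")
  }
  structure(list(n_per_cell = n_per_cell, groups = groups, sexes = sexes,
                 group_severity = group_severity,
                 age_distribution = age_distribution,
                 sex_aspiration_factor = sex_aspiration_factor,
                 noise_gain_cap = noise_gain_cap,
                 sample_rate_hz = sample_rate_hz, duration_s = duration_s,
                 noise_band_hz = noise_band_hz, seed = seed),
            class = "cohort_spec")
}

#' Simulate a labeled phonation cohort
#'
#' Draws per-subject fundamental frequency, age and aspiration severity, then
#' synthesizes one recording per subject. Reproducible: the manifest and all
#' waveforms are identical under the same spec and seed.
#'
#' @param spec [cohort_spec()].
#' @return list with `recordings` (list of `labeled_recording`) and
#'   `manifest` (data.frame: subject_id, group, sex, age, f0_hz,
#'   jitter_fraction, shimmer_db, noise_gain, seed).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  cells <- expand.grid(group = spec$groups, sex = spec$sexes,
                       stringsAsFactors = FALSE)
  rows <- list(); recs <- list(); idx <- 0L
  for (ci in seq_len(nrow(cells))) {
    grp <- cells$group[ci]; sx <- cells$sex[ci]
    sev <- spec$group_severity[[grp]]
    aged <- spec$age_distribution[[grp]]
    for (k in seq_len(spec$n_per_cell)) {
      idx <- idx + 1L
      sseed <- child_seed(spec$seed, idx)
      draws <- with_seed(sseed, {
        list(
          f0 = if (sx == "female") rnorm(1, 215, 12) else rnorm(1, 115, 8),
          age = rnorm(1, aged$mean, aged$sd),
          noise_gain = rlnorm(1, sev$noise_gain_meanlog, sev$noise_gain_sdlog)
        )
      })
      f0 <- min(max(draws$f0, 70), 330)
      draws$noise_gain <- min(
        draws$noise_gain * (spec$sex_aspiration_factor[[sx]] %||% 1),
        spec$noise_gain_cap %||% Inf)
      jit <- 0.005 + (sev$jitter_delta %||% 0)
      shim <- 0.3 + (sev$shimmer_delta_db %||% 0)
      glottal <- glottal_source_params(f0, duration_s = spec$duration_s,
                                       jitter_fraction = jit,
                                       shimmer_db = shim)
      prof <- speaker_profile(sx, glottal = glottal)
      asp <- aspiration_params(noise_gain = draws$noise_gain,
                               noise_band_hz = spec$noise_band_hz)
      id <- sprintf("S%03d", idx)
      rec <- simulate_phonation(prof, asp, spec$sample_rate_hz,
                                seed = child_seed(sseed, 7L),
                                metadata = list(subject_id = id, group = grp,
                                                sex = sx,
                                                age = round(draws$age, 1)))
      recs[[idx]] <- rec
      rows[[idx]] <- data.frame(
        subject_id = id, group = grp, sex = sx, age = round(draws$age, 1),
        f0_hz = f0, jitter_fraction = jit, shimmer_db = shim,
        noise_gain = draws$noise_gain, seed = sseed,
        stringsAsFactors = FALSE
      )
    }
  }
  list(recordings = recs, manifest = do.call(rbind, rows))
}
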