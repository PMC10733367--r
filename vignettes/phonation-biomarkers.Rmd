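---
title: "Methods: sustained-phonation biomarkers and the MFCC2 energy-ratio view"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sustained-phonation biomarkers and the MFCC2 energy-ratio view}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Sustained vowel phonation ("aaah") is a steady-state probe of the voice
source. Several neurological diseases — Parkinson's disease and
frontotemporal dementia among them — impair glottal closure, and incomplete
closure lets turbulent air leak through the glottis. That turbulence is
aspiration noise, and its spectrum falls off far less steeply with frequency
than the voiced source does. As aspiration increases it barely changes the
low-frequency part of the spectrum but dominates the high frequencies, so a
*low-to-high frequency energy ratio* drops with disease severity.

Two families of features capture this ratio:

* **Energy Ratio (ER)**, computed from a Welch power spectral density as

  $$ER\,\mathrm{[dB]} = 10\log_{10}
     \frac{\int_0^{4000} P_{xx}(f)\,df}{\int_{4000}^{f_{max}} P_{xx}(f)\,df},
     \qquad f_{max} = 12\,\mathrm{kHz}.$$

* **MFCC2**, the second mel-frequency cepstral coefficient. The cepstral
  transform multiplies the log mel spectrum by cosines; the MFCC2 cosine is
  a single half cycle — positive over the low mel filters, negative over the
  high ones. Because $\log a - \log b = \log(a/b)$, MFCC2 *is* a weighted
  low-to-high log-energy ratio, with the extreme frequencies weighted most.
  `mfcc2_weighting_curve()` returns this weighting remapped to Hz.

The package implements the full measurement chain — segmentation, spectral
and voice-quality features, cohort statistics — together with a synthetic
source-filter phonation generator that reproduces the aspiration mechanism,
so every claim the package makes about its own behaviour is testable against
known ground truth.

## The synthesis model

`simulate_phonation()` composes three stages:

1. **Glottal source** (`generate_glottal_source()`): an impulse train whose
   cycle periods are perturbed by `jitter_fraction` (SD as a fraction of the
   mean period) and whose cycle amplitudes are perturbed by `shimmer_db`
   (SD in dB), shaped by a spectral tilt of `source_tilt_db_per_octave`
   (default −12 dB/octave, unity gain at f0). The tilt filter is
   *minimum-phase*: each glottal pulse stays causal, with no pre-ringing,
   so cycle peaks remain aligned with excitation instants and the
   jitter/shimmer written into the truth log is recoverable from the
   waveform. Realized (sample-quantized) cycle onsets, periods and
   amplitudes are recorded as ground truth.
2. **Vocal tract** (`apply_vocal_tract()`): a cascade of two-pole
   resonators, one per formant, each normalized to unity DC gain. Defaults
   are the standard /a/ formants 700/1220/2600 Hz (bandwidths 80/90/120 Hz)
   for male profiles, scaled by 1.15 for female profiles.
3. **Aspiration noise** (`add_aspiration_noise()`): white noise shaped to
   `noise_tilt_db_per_octave` (default −3 dB/octave — much shallower than
   the source, encoding "falls off less rapidly with frequency"),
   optionally amplitude-modulated by the glottal cycle
   (`cycle_modulation_depth`, default 0.5) and optionally band-limited
   (`noise_band_hz`). The noise is scaled so RMS(noise)/RMS(voiced) equals
   `noise_gain` exactly; `noise_gain` is the severity knob.

Raising `noise_gain` with everything else fixed raises high-frequency power
almost exclusively, so ER, MFCC2 (at both frequency bounds), CPP and HNR
fall monotonically while jitter and shimmer estimates rise — the package's
acceptance tests assert exactly this over a six-point sweep.

### Cohort design

`simulate_cohort()` draws per-subject parameters for a (group × sex)
factorial design:

* f0 ~ N(115, 8) Hz for male profiles, N(215, 12) Hz for female profiles;
* baseline jitter 0.5% and shimmer 0.3 dB — ordinary healthy values;
* `noise_gain` log-normal per group. Defaults: controls
  `meanlog = log(0.05)`, cases `meanlog = log(0.25)`, both `sdlog = 0.4`.
  The source study reports no quantitative aspiration levels, so these are
  free design parameters: a clearly separated but overlapping contrast of
  the kind seen between healthy voices and mild dysphonia;
* `sex_aspiration_factor` (default female ×2.5): female voices are
  systematically breathier than male voices — the posterior glottal gap
  common in female phonation adds aspiration noise. This is the mechanism
  that makes MFCC2 *higher in men* here. Without it the model predicts the
  opposite sign, because female voiced energy concentrates in fewer
  harmonics and sits higher above the shared noise floor;
* `noise_gain_cap` (default 0.7): above roughly this level the recording is
  turbulence-dominated and no longer registers as voiced, so such a
  phonation would be excluded at segmentation. The cap keeps severe cases
  inside the analyzable range of the instrument, mirroring a study that
  excludes recordings with no detectable phonation;
* age N(63, 8) for controls, N(66, 8) for cases — typical of the cohorts
  this design emulates.

Recordings are 4.5 s at 32 kHz (Nyquist 16 kHz leaves margin above the
12 kHz analysis bound) and peak-normalized to 0.9.

### What the generator does *not* emulate

The simulator produces quasi-periodic /a/-like phonations with controllable
aspiration, not perceptually realistic speech. It has no breath groups, no
vibrato or intonation drift, no room acoustics, microphone coloration or
compression artifacts, no consonants or vowel variety, and its severity
dimension is one-dimensional (aspiration level, optionally linked
jitter/shimmer). Passing tests therefore demonstrate that the *measurement
chain* behaves correctly and that the *mechanism* (aspiration noise →
depressed low-to-high ratios) propagates through it — they do not
demonstrate clinical performance on real recordings, and the absolute AUCs
on synthetic cohorts are much higher than those achievable on real data.

## Segmentation

`voicing_track()` marks a 40 ms frame voiced when its normalized
autocorrelation peak within the 60–500 Hz lag range reaches 0.45 and its
RMS is above a silence floor (1% of the loudest frame).
`extract_phonation()` then takes the *longest* contiguous voiced run
(robust to pre-phonation throat clearing), bridges unvoiced gaps up to
0.1 s, discards the first 0.75 s (onset transient) and keeps the next
2.5 s. When less than 2.5 s remains, at least 0.5 s is retained with a
warning (`strict = TRUE` turns that into an error); shorter runs and fully
unvoiced recordings raise classed errors, and batch processing records them
per recording without aborting.

## Spectral features

* `welch_psd()`: averaged modified periodograms, 20 ms Hann windows, 50%
  overlap, one-sided density scaling (the integral of the PSD equals the
  mean squared signal; the tests assert Parseval to 5%).
* `energy_ratio_db()`: trapezoidal integration of the PSD over [0, 4 kHz)
  and [4 kHz, 12 kHz). A flat spectrum gives exactly
  $10\log_{10}(4000/8000) = -3.01$ dB.
* `build_mel_filterbank()`: 40 triangular filters, area-normalized, centers
  equally spaced in mel between 133 Hz and `fmax_hz` (8 or 12 kHz). The
  mel scale is the Slaney variant (linear below 1 kHz, logarithmic above),
  matching the implementation family the measurement convention comes from;
  the HTK formula is available via `variant = "htk"`.
* `mfcc_frames()`: 25 ms Hann frames, 10 ms hop, FFT length the next power
  of two, mel energies floored at 1e−10 before `10·log10`, then an
  orthonormal DCT-II over the filter index. Coefficients are 1-based —
  MFCC1 is the constant (energy) term — and the fast path is verified
  against a direct cosine-sum oracle to 1e−9. Raising `fmax_hz` from 8 to
  12 kHz moves the MFCC2 zero crossing up in frequency, which is why the
  12 kHz variant is more sensitive to noise that lives above 8 kHz.
* `spectral_contrast_octave()`: per frame and octave band (100–200 …
  3200–6400 Hz), the dB difference between the mean top and bottom 2%
  quantiles of within-band spectral magnitude, with dB taken as
  `10·log10` of the magnitude ratio — the convention of the widely used
  Python implementation this feature mirrors. Bands with fewer than two
  FFT bins are merged upward with a warning.
* `spectral_flatness()`: geometric over arithmetic mean of the framewise
  power spectrum (1 = noise-like, → 0 = tonal).

MFCC2's ratio interpretation is checked two ways: algebraically (the
weighting curve has one sign change), and empirically — on the default
synthetic cohort the Pearson correlation between `mfcc_mn_2` (12 kHz) and
`er_db` must be at least 0.6, the bottom of the range reported for real
cohorts of this kind.

## Voice quality

* `pitch_contour()`: framewise normalized autocorrelation with parabolic
  lag refinement and an octave guard that prefers, among near-maximal
  candidates, the one closest in octaves to the previous frame.
* `cycle_series()`: pitch-guided peak picking. Each mark is the maximum of
  |x| over its cycle; marks and peak values are refined to sub-sample
  precision by parabolic interpolation. The refinement matters: at 1%
  jitter the cycle-to-cycle period differences are a fraction of a
  millisecond, and integer-sample marks would add comparable quantization
  noise.
* `jitter_local_abs()`: mean |T\_i − T\_{i−1}| in seconds ('localabs').
* `shimmer_local_db()`: mean |20·log10(A\_{i+1}/A\_i)| in dB ('local dB').
* `harmonicity_hnr()`: HNR = 10·log10(r/(1−r)) from the autocorrelation
  value r at the pitch lag, per voiced frame.
* `cepstral_peak_prominence()`: real cepstrum of the dB magnitude
  spectrum per 40 ms frame; the peak within quefrencies 2–16.7 ms
  (f0 60–500 Hz) is measured above a least-squares trend line fitted over
  that same quefrency window. Frame length, quefrency range and trend
  domain are conventional choices; CPP values are only compared within the
  package's own scale.

All of these are invariant to global amplitude scaling by construction, and
the tests assert it numerically. The semitone range is
`12·log2(f0_max/f0_min)` after trimming 1% from each tail of the voiced
frames — an outlier guard, since a single octave error would otherwise
dominate the range.

## Cohort statistics

* `auc_scalar()`: the scalar-statistic ROC AUC, computed as the normalized
  Mann–Whitney pair count (ties contribute 0.5) — exactly the full
  threshold sweep. Verified against brute-force pair enumeration on 500
  random tie-heavy instances, and against an independent ROC
  implementation.
* `bootstrap_auc_ci()`: stratified percentile bootstrap (resampling within
  class), 2000 replicates by default, seeded. Percentile intervals were
  chosen for transparency; the source convention names a package but not a
  CI method.
* `correlation_screen()`: Spearman by default (Pearson available — the
  source material is internally inconsistent about which it used, so both
  are implemented), retaining features whose max |r| against any MFCC
  column exceeds 0.3.
* `ols_aic_select()`: least squares over all subsets of the candidate
  factors with $AIC = n\ln(RSS/n) + 2(p+1)$; AICc available via flag.
  Listwise deletion; rank-deficient designs are an error, not a silent
  drop.
* `one_way_anova()`: classical between/within decomposition via `lm`;
  the fully degenerate case (no variation at all) is reported as F = 0,
  p = 1 rather than NaN.
* `descriptive_table()`: mean/SD/n per (dataset × sex × group) cell.

## Problem sizes and runtime choices

The default verification cohort is 120 recordings (30 per group × sex
cell), which gives stable AUCs and correlations while keeping a full
simulate–extract–analyze cycle around two minutes on one core. The
fmax-sensitivity experiment uses a second 120-recording cohort with
aspiration noise confined to 8–12 kHz: there the 8 kHz MFCC2 is nearly
blind to the pathology while the 12 kHz variant sees it, reproducing the
qualitative benefit of raising the analysis bound. Statistical calibration
uses 200 null ANOVA replicates (Kolmogorov–Smirnov uniformity of p-values)
and 200 AIC-selection replicates (a pure-noise factor must be rejected in
at least 80% of them; the expected rejection rate under this AIC penalty is
about 84%).

## Known limitations

* The synthetic severity scale is not calibrated to any clinical scale;
  only directions and orderings transfer to real data.
* Jitter/shimmer/CPP values follow the stated formulas but are not
  bit-compatible with Praat's implementations (different windowing, cycle
  marking and smoothing choices).
* WAV ingestion resamples to the configured analysis rate and refuses
  files whose bandwidth cannot support the requested `fmax`; it does not
  attempt denoising or compression-artifact repair, which matters for
  browser-recorded material.
* Absolute MFCC magnitudes depend on framing and filterbank choices that
  published studies rarely report in full; comparisons across studies
  should always carry the frequency bounds and mel variant, which is why
  every MFCC column in the feature table is tagged with its `fmax`.
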