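# phonmark

Sustained-phonation acoustic biomarkers in R: mel-frequency cepstral
coefficients (MFCCs) with tunable frequency bounds, a Welch-spectrum band
Energy Ratio, interpretable voice-quality metrics, and the cohort
statistics used to evaluate scalar voice biomarkers — together with a
source-filter phonation simulator that generates labeled synthetic cohorts
with known ground truth.

## The scientific problem

Neurological diseases such as Parkinson's disease and frontotemporal
dementia often impair glottal closure. Incomplete closure produces
aspiration noise — turbulence whose spectrum falls off far less steeply
with frequency than the voiced source — so diseased voices gain energy
above roughly 4 kHz while their low-frequency spectrum barely changes. Any
*low-to-high frequency energy ratio* therefore drops with severity.

Two such ratios are implemented and connected:

* the **Energy Ratio** from a Welch PSD $P_{xx}(f)$ (20 ms Hann windows,
  50% overlap):

  $$ER\,\mathrm{[dB]} = 10\log_{10}
     \frac{\int_0^{4000} P_{xx}(f)\,df}{\int_{4000}^{f_{max}} P_{xx}(f)\,df},
     \qquad f_{max}=12\,\mathrm{kHz}$$

* **MFCC2**, the half-cycle-cosine cepstral coefficient of the log mel
  spectrum (133 Hz to 8 or 12 kHz). Its cosine weighting is positive over
  the low mel filters and negative over the high ones, and since
  $\log a - \log b = \log(a/b)$, MFCC2 is a *weighted* low-to-high
  log-energy ratio. Raising the upper bound from 8 to 12 kHz moves its
  zero crossing upward and makes it more sensitive to high-frequency
  aspiration noise.

The package is for speech-biomarker researchers and engineers who need a
tested, fully inspectable measurement chain: voiced-segment extraction,
spectral and voice-quality features (jitter 'localabs', shimmer 'local dB',
HNR, cepstral peak prominence, pitch statistics, octave-band spectral
contrast, spectral flatness), scalar-statistic ROC AUC with stratified
bootstrap CIs, correlation screening, AIC model selection and one-way
ANOVA. Because the real clinical corpora in this area are not publicly
redistributable, the package ships a synthetic cohort generator that
reproduces the aspiration mechanism with known ground truth, so every
stage is verifiable end to end.

## Worked example

```r
library(phonmark)

# one healthy-like and one breathy phonation, same speaker, same seed
control <- simulate_phonation(speaker_profile("male"),
                              aspiration_params(noise_gain = 0.05), seed = 1)
case    <- simulate_phonation(speaker_profile("male"),
                              aspiration_params(noise_gain = 0.30), seed = 1)

for (nm in c("control", "case")) {
  seg <- extract_phonation(get(nm))      # drop 0.75 s, keep 2.5 s of voicing
  f <- extract_features(seg)             # MFCCs at 8k & 12k, ER, voice quality
  cat(sprintf("%-8s MFCC2@12k %6.1f  MFCC2@8k %6.1f  ER %5.1f dB  HNR %5.1f dB\n",
              nm, f$mfcc_mn_2_12k, f$mfcc_mn_2_8k, f$er_db, f$hnr_mn_db))
}
#> control  MFCC2@12k   76.7  MFCC2@8k   77.9  ER  31.0 dB  HNR  21.7 dB
#> case     MFCC2@12k   39.7  MFCC2@8k   38.4  ER  15.7 dB  HNR   9.1 dB

# a small labeled cohort and the biomarker's discrimination
co <- simulate_cohort(cohort_spec(n_per_cell = 10, seed = 7))
fx <- cohort_features(co$recordings)
tab <- merge(co$manifest, fx$features, by = "subject_id")
males <- tab[tab$sex == "male", ]
roc <- bootstrap_auc_ci(males$mfcc_mn_2_12k, males$group,
                        n_boot = 2000, seed = 7)
cat(sprintf("male MFCC2@12k AUC %.2f (95%% CI %.2f-%.2f)\n",
            roc$auc, roc$ci_low, roc$ci_high))
#> male MFCC2@12k AUC 0.96 (95% CI 0.86-1.00)

cor(tab$mfcc_mn_2_12k, tab$er_db)   # MFCC2 behaves as an energy ratio
#> [1] 0.95
```

Raising the aspiration noise from 5% to 30% of the voiced RMS cuts MFCC2
roughly in half and costs ~15 dB of Energy Ratio and ~13 dB of HNR — the
high band fills with turbulence while the low band is nearly untouched.
On the cohort, MFCC2 separates cases from controls (AUC near 1 under these
clean synthetic conditions) and tracks the Energy Ratio almost linearly.

A full simulate → extract → analyze run, writing WAVs, feature CSVs and a
JSON report:

```sh
Rscript inst/cli/phonmark.R all --out runs/demo --n-per-cell 30 --seed 1
```

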