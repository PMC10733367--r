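Package: phonmark
Title: Sustained-Phonation Acoustic Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for sustained vowel phonation recordings used as
    digital voice biomarkers. Computes mel-frequency cepstral coefficients with
    tunable frequency bounds (interpreting MFCC2 as a weighted low-to-high
    frequency energy ratio), a Welch-spectrum band Energy Ratio, and
    interpretable voice-quality metrics (jitter, shimmer, harmonics-to-noise
    ratio, cepstral peak prominence, pitch statistics, spectral contrast and
    flatness). Includes a source-filter phonation simulator with controllable
    aspiration noise for generating labeled synthetic cohorts, voiced-segment
    extraction, and cohort statistics: scalar-statistic ROC AUC with stratified
    bootstrap confidence intervals, correlation screening, AIC-based linear
    model selection and one-way ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
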