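Package: ictalkit
Title: Seizure Detection, Classification and Structure-Function Analysis
    for Neonatal Continuous EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of continuous multichannel
    electroencephalography (cEEG) in neonatal hypoxic-ischemic injury
    models. Detects ictal-like events by a root-mean-square amplitude
    threshold against a pre-insult baseline, extracts per-epoch spectral
    biomarkers (six-band Welch power spectral density, band ratios,
    spectral entropy, magnitude-squared coherence, Hurst exponent),
    classifies events as focal or generalized by a five-criterion
    majority vote and by channel extent, and summarises seizure burden
    (binned counts, durations, area under the curve, onset latency). A
    companion image module quantifies immunofluorescent puncta (area,
    circularity, laminar coverage and density) and relates histology to
    seizure metrics by simple linear regression. A synthetic-data module
    generates ground-truth-labelled EEG recordings, fractional Gaussian
    noise, puncta images and per-animal cohorts for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    pracma,
    withr,
    stats,
    utils,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
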