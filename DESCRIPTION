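Package: hrvconcord
Title: Ultra-Short-Term Heart Rate Variability Concordance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing whether heart rate variability (HRV)
    metrics computed on 1-minute windows agree with the conventional
    5-minute short-term standard.  Screens beat-to-beat interval (BBI)
    series for artifact-free 5-minute segments using range-based outlier
    bounds and a Malik-style relative ectopic criterion, selects at most
    one segment per hour, computes time-domain (RMSSD, SDNN) and
    frequency-domain (LF and HF band power via Welch or Lomb-Scargle
    estimators) metrics on each segment and on its first minute, and
    quantifies per-metric agreement as Pearson correlation with
    categorical interpretation.  A seeded synthetic RR-interval generator
    with controllable respiratory-band and low-frequency modulation, slow
    nonstationary drift, and injectable ectopic beats and outliers
    supports end-to-end validation when recorded data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
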