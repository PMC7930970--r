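Package: capsig
Title: Analysis of Capacitive ECG and Cough-Associated EMG from Textile Electrodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing pipeline for non-contact biopotential recordings
    acquired through capacitive (insulator-coupled) cloth electrodes, such as
    in-pillow neck electrodes that pick up both the electrocardiogram (cECG)
    and cough-associated electromyogram (cEMG). Provides threshold-based
    R-wave detection with RR-interval beat matching and detection metrics
    (sensitivity, accuracy, positive predictive value), cough-segment
    selection with total-spectral-amplitude (TSA, 40-500 Hz) analysis and a
    normality-gated paired comparison, frequency-domain heart-rate-variability
    band power with error-rate comparison, an analytic model of the
    bootstrapped-varistor front-end input impedance and capacitive coupling,
    and a seeded generator of paired synthetic sessions for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
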