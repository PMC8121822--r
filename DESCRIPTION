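Package: pulsevar
Title: Pulse Rate Variability Versus Heart Rate Variability Across Blood
    Pressure States
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to compare pulse rate variability (PRV, from
    photoplethysmography) with heart rate variability (HRV, from the
    electrocardiogram) under hypotensive, normotensive and hypertensive
    conditions. Provides a synthetic generator of coupled ECG/PPG/arterial
    blood pressure (ABP) records with ground truth, a per-cycle ABP signal
    quality gate based on k-means clustering of cycle features, blood
    pressure state labelling from systolic/diastolic trends, R-peak and
    tangent-intersection pulse onset detection, 33 time-domain,
    frequency-domain and nonlinear variability indices, and an agreement
    statistics layer (Bland-Altman bias, limits of agreement, ratio of
    agreement, Spearman, Friedman, Kruskal-Wallis with Bonferroni-corrected
    post hoc Wilcoxon tests, Lilliefors screening).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    nortest,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
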