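Package: fetalhrv
Title: Fetal Heart Rate Variability Analysis and Acidosis Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing fetal heart rate (FHR) and heart rate
    variability (HRV) from beat-to-beat RR-interval series, aimed at the
    prediction of fetal acidosis (arterial pH < 7.10). Implements time-domain
    indices (RMSSD, SDNN, and the fetal short- and long-term variability STV
    and LTV), wavelet-based low- and high-frequency band powers and the
    normalised high-frequency index HFnu, the Fetal Stress Index (FSI, an
    envelope-based 0-100 score of high-frequency oscillations of the
    normalised RR series), and morphological analysis of FHR decelerations
    (duration, amplitude, slope, deceleration area). A synthetic
    umbilical-cord-occlusion session generator and a two-group cohort
    generator provide reproducible test beds. The multivariable analysis
    pipeline covers Pearson correlation screening, PCA with varimax rotation
    for variable reduction, univariable logistic regression, bootstrap
    stepwise backward selection, ROC analysis with DeLong confidence
    intervals, threshold classification metrics, and chi-square (CHAID-style)
    and Gini (CART-style) binary decision trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    rpart
Config/testthat/edition: 3
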