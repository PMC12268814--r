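Package: plexrank
Title: In-Silico Selection of Multiplex PCR Assays from Amplification Curve Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ranks candidate multiplex PCR primer mixes in silico from
    singleplex real-time amplification curves. Fits an asymmetric
    five-parameter sigmoid to each curve, extracts concentration-robust
    kinetic features from the fitted curve and its analytic first and
    second derivatives, screens features for inter-target separability
    (mean silhouette score), concentration robustness (Kruskal-Wallis with
    Dunn post-hoc) and singleplex-to-multiplex consistency (Pearson
    correlation on median-curve features), then scores every candidate
    primer mix by Average and Minimum Distance Scores under median-based
    or clustering-based (silhouette) inter-target distances and evaluates
    selected assays with single-channel amplification-curve-analysis
    classification under stratified k-fold and leave-one-concentration-out
    cross-validation. Includes a seeded synthetic-data generator emulating
    digital PCR panels.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    class,
    withr,
    optparse,
    jsonlite,
    knitr
Config/testthat/edition: 3
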