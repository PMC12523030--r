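Package: megastate
Title: Resting-State MEG Microstate Segmentation and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for resting-state magnetoencephalography (MEG) microstate
    analysis on sensor-space recordings: global field power and peak map
    extraction, polarity-invariant modified k-means topographic clustering
    with knee-point (kneedle) selection of the number of classes, two-level
    (subject then grand-mean) clustering, backfitting, and the four standard
    microstate parameters (duration, occurrence per second, coverage,
    transition probabilities). Includes a seeded semi-Markov simulator of
    helmet-array MEG cohorts with known ground truth, preprocessing
    (zero-phase band-pass and notch filtering, PSD-based bad-channel
    detection, nearest-neighbour spatial filtering), and a statistics layer
    with covariate-adjusted group comparisons, Benjamini-Hochberg false
    discovery rate control, E-value sensitivity analysis for unmeasured
    confounding, complementary logistic regression, and exploratory Pearson
    correlation screening against clinical scores.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
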