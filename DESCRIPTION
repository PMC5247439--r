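Package: wavefi
Title: Single-Trial EEG Classification of Fluid-Intelligence Groups with
    Haar Wavelet Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts whether a subject belongs to a low-ability (LA) or
    high-ability (HA) fluid-intelligence group from single-trial
    event-related EEG epochs recorded over the midline channels Fz, Pz
    and Cz during a visual oddball task. Implements the full pipeline:
    band-pass filtering (0.3-30 Hz), 600 ms epoch segmentation,
    +/-90 microvolt artifact rejection, RAPM-score based grouping with
    mean +/- 3 SD outlier screening, level-4 Haar discrete wavelet
    decomposition with dyadic band labelling, statistical wavelet
    features (relative energy, mean, standard deviation, kurtosis,
    skewness, entropy) and raw wavelet-coefficient features with
    optional magnitude thresholding, AUC-based feature ranking,
    band/channel/statistic combination search, soft-margin RBF-kernel
    support vector machine classification with nested grid-search
    tuning, stratified 10-fold and subject-holdout evaluation, and
    scatter-matrix (J1, J2), Kruskal-Wallis and two-sample t
    discrimination statistics. Includes a seeded synthetic oddball-EEG
    cohort generator whose group contrast is confined to the delta band
    (below 3.75 Hz) so every stage can be exercised and calibrated
    without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
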