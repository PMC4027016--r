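Package: wavefrac
Title: Wavelet Packet Fractal Dimension Analysis of Sustained-Vowel
    Recordings
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Objective voice analysis for three-class auscultation
    studies. Decomposes sustained-vowel recordings with a db4 wavelet
    packet filter bank into frequency-ordered subbands, estimates the
    box-counting (Minkowski) fractal dimension of every subband
    coefficient sequence by a least-squares log-log slope, assembles
    subject-by-subband feature tables as SummarizedExperiment objects,
    performs age-adjusted per-subband group comparisons, and classifies
    subjects with one-vs-one radial-basis support vector machines whose
    feature subsets and kernel parameters are tuned per binary problem
    by nested cross-validated grid search. Includes a source-filter
    vowel simulator so the full pipeline can be exercised on synthetic
    cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    withr
Config/testthat/edition: 3
biocViews: Classification, FeatureExtraction, Preprocessing
RoxygenNote: 7.3.3
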