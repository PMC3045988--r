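Package: pcgscreen
Title: Segmentation-Free Heart Sound Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of phonocardiogram (heart sound) recordings without
    segmentation into labelled fundamental heart sounds. The pipeline computes a
    Complex-Morlet scalogram envelope, estimates the cardiac-cycle length from
    the autocorrelation of the envelope, crops five-cycle segments, extracts a
    35-element feature vector (32 Daubechies-2 detail-coefficient window
    energies plus three envelope statistics), reduces it by principal component
    analysis, and classifies normal versus abnormal sounds with a bagged
    ensemble of single-hidden-layer neural networks under threshold voting.
    Includes an annotated synthetic phonocardiogram simulator with white- and
    impulse-noise injection, ten-fold cross-validated evaluation with minority
    oversampling, geometric-mean scoring, ROC threshold selection, and
    leave-one-type-out testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    signal,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
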