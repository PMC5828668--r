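Package: gliaquant
Title: Soma Counting, Colocalization and White-Matter Electrophysiology Pipelines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipelines for fluorescence microscopy and
    white-matter electrophysiology. Implements a morphological soma-counting
    algorithm for tiled fluorescence images (opening-based process
    suppression, thresholding, connected components, small-object removal and
    erosion splitting) with cell-density and object-based colocalization
    metrics; compound-action-potential peak detection with
    latency-versus-distance conduction-velocity regression; local field
    potential spectrogram band-power analysis; and cohort-level group
    statistics (percent-of-control, blocked two-factor ANOVA with Sidak
    contrasts, slope ANCOVA, Mann-Whitney with Benjamini-Hochberg
    correction). A synthetic-data module generates ground-truthed images,
    sweeps and recordings with the statistical structure the analyses assume,
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
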