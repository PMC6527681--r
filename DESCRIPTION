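Package: stomadet
Title: High-Throughput Stomatal Density Phenotyping with a Single-Shot
    Multibox Detector
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying stomatal density from leaf-surface
    replica micrographs. Implements a desk-scale single-shot multibox
    detector (prior boxes, ground-truth matching, offset encoding,
    multibox loss, non-maximum suppression) trained end-to-end on
    annotated micrographs, together with the model-selection procedure
    that sweeps training-set size and confidence threshold against
    manual counts (R-squared/RMSE grids, batch resampling with
    Tukey-Kramer comparison), fine-tuning of a basal model for new
    imaging domains, count-to-density conversion with within-leaflet
    positional aggregation, and accession-diversity statistics (two-way
    and one-way ANOVA, Pearson correlation, Tukey multiple comparison,
    origin-stacked histograms). A synthetic replica-micrograph
    generator with exact ground-truth boxes makes every stage trainable
    and testable without proprietary image data. Reads and writes
    Pascal-VOC-style XML annotations in the LabelImg dialect.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    car,
    graphics,
    grDevices,
    jsonlite,
    png,
    stats,
    tools,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    withr,
    yaml
Config/testthat/edition: 3
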