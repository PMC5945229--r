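Package: epimosaic
Title: Quantification of Notch Reporter Dynamics and Apical Remodelling in
    Neuroepithelial Mosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-analysis pipeline for mosaic electroporation experiments in
    the embryonic neural tube. Measures per-nucleus fluorescence of a nuclear
    Notch-activity reporter from labelled segmentations, applies the two-anchor
    normalization (neuron background mapped to 0, progenitor mean to 1) with
    cross-session re-anchoring, classifies cells into cycling progenitors,
    prospective neurons and neurons from cumulative EdU and HuC/D calls,
    computes differentiation and proliferation rates (including the
    neighbour-referenced rate), derives neighbour-referenced apical-area and
    junction-intensity ratios from en-face segmentations, analyses
    pulse-labelled cohort time courses, and provides the matching parametric
    and nonparametric group comparisons with exact small-sample behaviour.
    A synthetic-data generator with full ground truth emulates the imagery and
    cohort structure the analysis assumes, so every stage is verifiable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
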