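Package: cmcount
Title: Enumeration of Circulating Melanoma Cells from Immunofluorescence Cytospin Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Semi-automated enumeration of circulating melanoma cells (CMCs)
    from three-channel (DAPI / CD45 / melanoma-marker) immunofluorescence
    images of CD45-depleted blood fractions deposited on cytospin slides.
    Implements isodata (intermeans) thresholding, nuclear segmentation with
    aspect-ratio, circularity and margin-sharpness filters, per-cell intensity
    and staining-pattern measurement, and the four-class (green / red / yellow
    / null) classification that yields CMC counts; converts slide tallies to
    per-mL concentrations with Poisson counting error; analyses spike-in
    recovery experiments (regression, limit of detection); and provides
    small-cohort statistics (exact Mann-Whitney, univariate Cox proportional
    hazards, log-rank, Spearman) together with qPCR fold-enrichment. A
    synthetic-data module renders ground-truthed fields of view and simulates
    the immunomagnetic leukocyte-depletion split, spike-in series and survival
    cohorts so the whole pipeline is testable without patient material.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
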