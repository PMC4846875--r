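Package: phenoks
Title: Image-Based Phenotypic Compound Profiling with Signed
    Kolmogorov-Smirnov Z-Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mechanism-of-action profiling of small-molecule
    compounds from high-content fluorescence microscopy of EGFR signalling
    and vesicle trafficking. Implements nucleus/cell segmentation with
    seeded propagation, derived perinuclear and plasma-membrane ring
    regions, top-hat endosome detection and colocalization counting,
    per-cell descriptor extraction, signed two-sample Kolmogorov-Smirnov
    statistics standardized against a bootstrap control null,
    replicate-reliability filtering, and clustering of compound Z-score
    profiles by PCA and Ward linkage. A synthetic-data module generates
    plates of per-cell feature tables or rendered cell images with known
    ground truth so the full pipeline is testable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    graphics,
    stats,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
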