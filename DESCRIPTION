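Package: erquant
Title: Quantitative Image Analysis of ER Cisternae, Golgi Morphology and
    Secretory Traffic
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the substructure of endoplasmic reticulum (ER)
    cisternae and its functional consequences from fluorescence micrographs.
    Segments the cortical ER network by hysteresis thresholding, identifies
    cisternae with a morphological opening, profiles lumenal marker intensity
    in radial bins, and summarises per-cisterna grey-level co-occurrence
    matrix (GLCM) texture properties (contrast, correlation, energy,
    homogeneity) with pixel-weighted pooling. Also computes corrected 405/488
    excitation ratios for roGFP2 membrane-topology assays, Golgi cisterna
    curvature (B-spline) and width (integrated polyline distance) from
    electron-micrograph traces, ER-to-Golgi transport fractions and apoplast
    secretion indices from polygon regions of interest, and runs the
    MANOVA/ANOVA/Tukey and Kruskal-Wallis/Dunn group comparisons. A synthetic
    phantom generator renders two-channel confocal-like scenes with known
    ground truth (tubule networks, sac-like, nanohole-punctured and
    tubular-matrix cisternae, ratio pairs, whole-cell scenes) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
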