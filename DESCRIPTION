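Package: smfishq
Title: Per-Cell Quantification of Single-Molecule FISH in Islet Tissue Sections
Version: 0.1.0
Authors@R:
    person("Islet Imaging", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying single-molecule fluorescence
    in situ hybridization (smFISH) images of pancreatic islet sections: nucleus
    mask post-processing, radial cell-boundary prediction, beta/non-beta cell
    classification from the insulin-intensity histogram, Laplacian-of-Gaussian
    spot detection, intensity-based deconvolution of multi-mRNA foci, Tukey-fence
    outlier removal, nuclear versus cytoplasmic transcript localization, and
    Mann-Whitney group statistics. Includes a synthetic islet-tissue image
    simulator with complete ground truth so that every stage is testable without
    microscope data, plus minimal uncompressed multi-page TIFF input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    yaml,
    png
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
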