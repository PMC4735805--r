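Package: idnodes
Title: Cluster Colocalization, Placement Simulations and Surface Topology
    for Intercalated Disc Nanodomains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative tools for studying adhesion/excitability nodes at
    the cardiac intercalated disc from super-resolution and volume-EM data.
    Detects clusters in reconstructed two-channel localization images,
    restricts analysis to a membrane region, and computes morphology and
    nearest-neighbour distance statistics; registers fluorescence and EM
    frames from fiducial pairs by least-squares affine estimation; runs
    Monte Carlo simulations of ellipse placement under random and
    attraction models; simulates lattice random-walk ligand binding to
    immobilized channel clusters with dissociation-constant readout;
    aligns and averages boxed two-channel particles by cross-correlation;
    quantifies membrane surface topology (area amplification, peak
    spacing, Fourier periodicity) from height maps; and predicts ensemble
    sodium current from cluster geometry. A synthetic-data module
    generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
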