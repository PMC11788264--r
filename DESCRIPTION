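Package: MicroCalcSim
Title: Simulation of Microcalcification Cluster Models for Mammographic Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An automated toolbox for modeling clusters of breast
    microcalcifications and rendering them into mammographic images.
    Provides generation of 3D single-calcification voxel models from
    geometric primitives with noise-induced irregular boundaries,
    assembly of calcifications into 3D cluster volumes with random,
    grid or predefined placement (including BI-RADS style clinical
    presets), a texture-driven 2D cluster generator that tailors
    calcification candidates to the local textures of a given
    mammogram via radiomics cell voting and Frangi filtering, and a
    hybrid insertion engine based on multiplicative exp(-mu*T)
    projection templates with For-Presentation contrast calibration
    and a distance-transform intensity-scaling surrogate for 2D
    models. Sparse and RAW voxel storage, metadata tables, and a
    synthetic fixture generator for fully self-contained testing are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    jsonlite,
    yaml,
    png,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, Visualization, BiomedicalInformatics
RoxygenNote: 7.3.3
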