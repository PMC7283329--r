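Package: grainspec
Title: Vis/NIR Hyperspectral Phenotyping of Rice Grain and Mixed-Model
    Association Mapping of Spectral Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline linking visible/near-infrared (400-1004 nm)
    hyperspectral images of whole rice grain to genetic sub-population,
    production environment and grain-quality traits (chiefly percent chalk),
    and mapping spectral variation to genomic segments and candidate genes.
    Provides white/dark reflectance calibration, grain segmentation and
    per-sample spectrum extraction; eight chemometric pre-processing
    operators; NIPALS partial least squares discriminant analysis with
    VIP-based wavelength selection and linear discriminant classification;
    K-means wavelength grouping and per-group PC1 spectral traits; a
    per-marker REML mixed linear model association scan with principal
    component covariates and VanRaden kinship; Storey/Benjamini-Hochberg
    false discovery rate control; merging of significant markers into
    genomic segments and a candidate-gene search around peak SNPs. A
    synthetic-data module generates hyperspectral scenes, traits, structured
    genotypes and gene annotations with the statistical structure the
    analysis assumes, so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    signal,
    Rcpp,
    EBImage,
    vcfR,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
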