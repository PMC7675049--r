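Package: fvmech
Title: Depth-Segmented Nanomechanics and Adhesion Mapping for AFM Force-Volume Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis of atomic force microscopy (AFM) force-volume datasets
    from living cells: second-degree polynomial baseline correction, noise
    estimation, contact-point location, Hertz sphere-contact fits segmented by
    indentation depth to separate plasma-membrane from cortical elasticity
    (with a bottom-effect correction for thin layers), detection and
    worm-like-chain validation of single-molecule rupture events, specificity
    classification, binding-probability and domain-size statistics on
    multiparametric maps, and the group comparisons used in such studies
    (one-way ANOVA with Tukey HSD, exact Mann-Whitney U). Includes a synthetic
    force-volume generator with full ground truth so that every stage of the
    pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    EBImage
Config/testthat/edition: 3
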