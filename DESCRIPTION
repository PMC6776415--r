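Package: tractnet
Title: Structural Brain Connectome Construction and Multi-Threshold Network Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted structural brain networks from deterministic
    diffusion-tensor tractography and analyses them across network thresholds.
    Provides tensor-field phantoms and synthetic subject cohorts for validation,
    deterministic streamline tracking with fractional-anisotropy and curvature
    stopping rules, connectome construction under streamline-length-adjusted and
    end-node-volume-adjusted edge weightings, weighted and unweighted graph
    metrics with rewired-null small-worldness, density-matched multi-threshold
    metric curves with area-under-curve summaries, and group statistics:
    parametric and Freedman-Lane permutation ANCOVA, multi-threshold permutation
    correction (MTPC) with cluster criteria, and partial Spearman correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
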