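Package: superlobule
Title: Synthetic Liver Vasculature Generation and Lumped-Parameter Perfusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates fully connected three-dimensional models of the liver
    vasculature by a space colonization algorithm with target attractors,
    partitions the organ volume into lumped "super lobule" elements via
    k-means, assigns vessel radii by a downstream-weighted Murray's law,
    solves steady flow on the resulting Hagen-Poiseuille resistance network
    with an electrical analogy, calibrates the shared super-lobule resistance
    by bisection to meet bulk pressure/flow boundary conditions, and simulates
    cryoprotective-agent loading by explicit advective time stepping, with
    wall-shear-stress reporting and boundary-condition sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
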