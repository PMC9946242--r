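Package: omnicurrent
Title: Omnidirectional Circuit-Theory Connectivity Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating multi-species landscape connectivity with
    circuit theory. Builds ranked movement-cost rasters from category layers
    using a highest-cost-wins combination rule, solves Kirchhoff current flow
    on the raster's resistor network with sparse linear algebra, and runs the
    omnidirectional wall-to-wall protocol (strip-to-strip solves in the four
    cardinal directions, averaged into a single current-density map). Includes
    buffered tiling with mean-of-overlap stitching and seam repair,
    cost-scenario and tile-size sensitivity analyses, used-versus-available
    telemetry validation with linear mixed models, roadkill section
    correlation tests, and a synthetic-data module (patchy and split
    landscapes, preference-biased lattice tracks, Poisson roadkill counts,
    and a Monte-Carlo random-walk oracle for the solver).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    EBImage,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lme4,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
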