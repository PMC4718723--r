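Package: helixtrace
Title: Covariance-Constrained Helix Tracing in Medium-Resolution Cryo-EM Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building alpha-helical backbone models into
    medium-resolution (6-8 Angstrom) cryo-EM density maps under distance
    constraints from evolutionary covariance analysis. Provides ideal helix
    construction from backbone dihedrals, rod-like feature detection in
    density maps, exhaustive combinatorial assignment of helix segments to
    density rods scored by constraint satisfaction, real-space rigid map
    alignment and multi-state averaging with heterogeneity statistics,
    Fourier shell correlation, rigid-body rotation decomposition of
    conformational states, and a synthetic-data generator for helical
    bundles, simulated maps, and contact lists with controlled error rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    generics,
    jsonlite,
    igraph,
    bio3d,
    ggplot2,
    yaml,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
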