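Package: dcwater
Title: Polarizable Water Nanoclusters with a Many-Body Cutoff
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Rigid 4-site polarizable water potential of the Dang-Chang
    type (Lennard-Jones on oxygen, partial charges on the hydrogens and
    the M site, self-consistent induced dipoles on the M site) in which
    the many-body polarization term can be truncated at a configurable
    oxygen-oxygen cutoff radius.  Includes basin-hopping global
    optimization of clusters in rigid-body angle-axis coordinates with
    analytic gradients, permutation-minimized distance RMSD and
    coordination-shell metrics, a cutoff-scan analysis pipeline, random
    and idealized cluster generators, and XYZ input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
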