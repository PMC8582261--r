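Package: pathmetad
Title: Path Collective Variables, Essential Dynamics Sampling and
    Well-Tempered Metadynamics at Desk Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for modelling large conformational
    transitions with enhanced sampling. Generates transition paths by
    essential dynamics sampling (EDS) over a principal-component subspace,
    selects evenly spaced, topologically consecutive reference frames,
    evaluates progress-along-path and distance-from-path collective
    variables s(R)/z(R), runs well-tempered metadynamics biased on those
    variables with a one-sided harmonic wall on z, reconstructs the free
    energy surface from the deposited bias, extracts a binned minimum free
    energy path with per-step barriers, and estimates statistical errors by
    constant-final-bias reweighting with block averaging. Includes
    deterministic generators for two-state bead-chain systems and analytic
    free-energy landscapes so the whole pipeline is testable without
    external data, plus structural observables (element-wise RMSD traces,
    hydrogen-bond counts, Shrake-Rupley solvent accessible surface area,
    backbone dihedrals, pairwise RMSD maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
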