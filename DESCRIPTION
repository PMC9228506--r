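Package: memperm
Title: Membrane Permeation Analysis and Umbrella-Sampling Free Energy Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis for small-molecule permeation of lipid
    bilayers. Computes membrane structural observables (area per lipid,
    bilayer thickness, deuterium order parameters, tilt-angle and density
    profiles), solute configuration statistics (position along the membrane
    normal, ring and side-chain angles, two-dimensional free-energy
    surfaces, insertion and translocation events, aggregation analysis),
    solvation and dynamics (radial distribution functions, geometric
    hydrogen-bond counting, lateral diffusion from mean-squared
    displacement), and potentials of mean force from umbrella-sampling
    windows via a self-consistent weighted histogram analysis method with
    barrier decomposition. Includes a synthetic bilayer and overdamped
    Langevin umbrella-window generator with known ground truth for
    validating every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    igraph,
    bio3d,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
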