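Package: knotfold
Title: Coarse-Grained Monte Carlo Folding and Knot Detection for Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A C-alpha coarse-grained Go-model Monte Carlo folding engine
    with switchable potentials (purely native-centric, or native plus
    quasi-chemical non-native and screened electrostatic interactions),
    coupled to an open-chain knot detection and localization toolkit
    (KMT-style chain simplification, Alexander determinants, minimally
    interfering and stochastic chain closure with majority voting, knot
    core localization and chirality from the Gauss writhe). Includes
    generators for synthetic curves of known topology and toy native
    structures, trajectory observables (gyration radius, fraction of
    native contacts, segment interaction energies, windowed knotting
    probability), and campaign drivers for comparative knotting-propensity
    studies of natively knotted versus unknotted chains and their in
    silico mutants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
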