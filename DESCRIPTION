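Package: ringmelt
Title: Two-Temperature Langevin Dynamics and Threading Analysis of Active
    Ring-Polymer Melts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, simulates and analyses dense melts of unknotted,
    nonconcatenated ring polymers in which a consecutive segment of each ring
    is coupled to a hotter Langevin thermostat than the rest of the chain.
    Provides a Kremer-Grest bead-spring engine (WCA + FENE + cosine bending)
    with two independent per-monomer thermostats, a melt builder that
    guarantees zero pairwise Gauss linking numbers by construction, minimal
    disc-topology surfaces spanned on ring contours by triangulated area
    descent, detection of ring-ring threadings through those surfaces
    (separation length, threading ratio, threading clusters and kinetics),
    and the structural and dynamic observables used to diagnose the active
    topological glass: radius of gyration, centre-of-mass mean squared
    displacement, self-intermediate scattering function, non-ergodicity
    parameter, ergodicity-breaking parameter, displacement statistics,
    cold-hot directionality and internal distance scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
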