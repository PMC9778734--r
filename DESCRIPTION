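Package: glycopmf
Title: Free-Energy, Ring-Puckering and Conformational Analysis for Biased
    Molecular Simulations of Glycoside Hydrolases
Version: 0.1.0
Authors@R:
    person("glycopmf", "maintainers", email = "glycopmf@example.org",
           role = c("aut", "cre"))
Description: Analysis machinery for umbrella-sampling and conventional
    molecular-dynamics studies of glycosidase catalysis: weighted-histogram
    (WHAM) reconstruction of potentials of mean force with per-conformation
    reweighting onto arbitrary collective variables, direct Gibbs-energy
    projections from binned occupancies, Cremer-Pople puckering coordinates
    and canonical conformer classification for six-membered rings, active-site
    distance collective variables, Gromos and k-means trajectory clustering
    with occupancy-based seeding, transition-state-theory rate conversion, and
    a synthetic biased-Langevin data generator with analytically known free
    energies so the whole pipeline is testable without trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
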