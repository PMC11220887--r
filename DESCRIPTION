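Package: sadret
Title: SAD Substructure Determination by Modified RAAR Phase Retrieval
Version: 0.1.0
Authors@R:
    person("sadret", "developers", email = "sadret@example.org", role = c("aut", "cre"))
Description: Determines heavy-atom (anomalous scatterer) substructures from
    single-wavelength anomalous diffraction (SAD) data with a dual-space
    phase-retrieval algorithm built on the relaxed averaged alternating
    reflections (RAAR) iteration, augmented by pi-half phase perturbation of
    weak reflections and tangent-formula refinement of strong reflections in
    reciprocal space.  Includes preparation of normalized anomalous difference
    magnitudes from Bijvoet pairs (resolution cutoff at |dF|/sigma = 1.2,
    shell-wise E normalization), explicit space-group symmetry handling
    (expansion, Laue reduction, systematic absences, permissible origin
    shifts), peak search and symmetry/origin/enantiomorph-aware site matching,
    a synthetic SAD data simulator providing ground truth for every stage, and
    a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
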