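Package: grest
Title: Generalized Replica Exchange with Solute Tempering on Toy Molecular Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of generalized replica exchange with
    solute tempering (gREST), together with its REST2 and temperature
    replica-exchange (T-REMD) special cases.  Potential-energy terms of a toy
    force field (bonds, angles, cosine dihedrals, Lennard-Jones, Coulomb,
    harmonic restraints) are classified against a solute region and scaled by
    (beta_m/beta_0)^(k/l); replicas are propagated by Langevin (BAOAB) or
    Metropolis Monte Carlo dynamics and exchange their scaling parameters by
    the Metropolis criterion.  Includes a ladder optimizer targeting a fixed
    neighbour exchange acceptance, trajectory demultiplexing by parameter,
    Kabsch RMSD and distance-matrix PCA analysis, exactly enumerable discrete
    fixtures for detailed-balance proofs, and analytic harmonic-bath oracles
    for exchange-acceptance theory.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    bio3d,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
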