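Package: ffbalance
Title: Selective Protein-Water Scaling and Backbone Torsion Refinement for Molecular Force Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for rebalancing molecular-mechanics force fields for
    simulations of folded and intrinsically disordered proteins. Reads and
    writes GROMACS-dialect topologies and applies verifiable transformations:
    selective scaling of protein-water Lennard-Jones interactions (all-atom,
    backbone, side-chain, and side-chain-excluding-charged schemes), residue-
    specific psi-torsion force-constant presets for Ser/Thr/Gln, and hydrogen
    mass repartitioning. A cutoff-free single-point energy oracle verifies
    every transformation. Includes the validation observables used to assess
    such force fields: radius of gyration, Debye small-angle X-ray scattering
    with Guinier analysis, Kabsch RMSD/RMSF, DSSP secondary structure and
    helix fractions, secondary chemical-shift differences, and iRED S2 order
    parameters, together with synthetic generators (toy topologies, ideal
    helices, Gaussian chains, tumbling/wobble trajectories) that make the
    whole pipeline testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    bio3d,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
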