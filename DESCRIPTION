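Package: ringfree
Title: Detection and Repair of Ring-Penetration Artifacts in Molecular
    Simulation Systems
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects ring-piercing artifacts in biomolecular structures by
    their force-field symptom -- bonds stretched far beyond their CHARMM
    equilibrium lengths -- confirms them with an exact segment-through-ring
    geometric test, and repairs them through an iterative biased
    minimization loop.  The loop combines soft-core nonbonded potentials on
    atoms near the offending bond, a repulsive Gaussian density hill, a
    one-sided center-of-mass separation bias, perpendicular displacement
    targets with force-constant escalation, and improper-dihedral restraints
    that preserve the chirality of every potential stereocenter.  Reads and
    writes CHARMM PSF topology, PDB coordinates and PRM/RTF/STR parameter
    files, and ships deterministic pierced test-system generators.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
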