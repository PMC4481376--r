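Package: DockPBSA
Title: Restricted Rigid-Body Antibody Docking with Constraint Screening
    and Clustered MM-PBSA Free-Energy Decomposition
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling antibody-antigen complexes from
    deposited structures and conformational ensembles: PDB structure
    preparation with Kabat-aware residue bookkeeping, heuristic
    protonation and hydrogen placement; map-based rigid-body pose
    enumeration restricted to an epitope cone, grid-threading and
    all-atom Monte-Carlo refinement, and classifier-based pose ranking;
    screening of ranked poses against experimental epitope, stoichiometry
    and buried-surface constraints; ensemble interface statistics
    (occupancy-based interface residues, hydrogen bonds, van der Waals
    contacts); and a clustered, population-weighted MM-PBSA binding
    free-energy calculation with per-residue decomposition, built on an
    internal finite-difference linearized Poisson-Boltzmann solver with
    grid focusing and a Shrake-Rupley surface-area term. A synthetic-data
    generator produces parameterized toy complexes, multi-run
    perturbation ensembles and labelled docking decoys for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    e1071
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'docking.R'
    'energetics.R'
    'ensemble.R'
    'geometry.R'
    'mmpbsa.R'
    'pbsolver.R'
    'screening.R'
    'structio.R'
    'synthetic.R'
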