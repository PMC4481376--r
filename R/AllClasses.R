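#' @import methods
#' @importFrom stats sd rnorm runif setNames aggregate coef lm predict
#' @importFrom utils head read.table write.table
#' @useDynLib DockPBSA, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.atom_cols <- c("serial", "name", "altloc", "resname", "chain", "resnum",
                "icode", "x", "y", "z", "occupancy", "element", "record")

#' Protein structure container
#'
#' An ordered atom table parsed from PDB records.  Residues are keyed by
#' \code{(chain, resnum, icode)} and ordered by first appearance in the
#' file, never by arithmetic on residue numbers: antibody (Kabat) numbering
#' is discontinuous and uses insertion codes (27A, 100c, ...), so residue
#' numbers are labels, not indices.
#'
#' @slot atoms a \code{data.frame} with one row per atom, columns
#'   \code{serial, name, altloc, resname, chain, resnum, icode, x, y, z,
#'   occupancy, element, record}.
#' @exportClass PDBStructure
setClass("PDBStructure", representation(atoms = "data.frame"))

setValidity("PDBStructure", function(object) {
  a <- object@atoms
  miss <- setdiff(.atom_cols, names(a))
  if (length(miss)) return(paste("missing atom columns:", paste(miss, collapse = ", ")))
  if (nrow(a)) {
    if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
      return("non-finite coordinates")
    if (any(!nzchar(a$element))) return("empty element field")
  }
  TRUE
})

#' Rigid-body transform
#'
#' A proper rotation plus translation, applied as \code{x R^T + t} to row
#' vectors of coordinates.
#'
#' @slot rotation 3x3 proper orthogonal matrix (det = +1).
#' @slot translation length-3 numeric, Angstrom.
#' @exportClass RigidTransform
setClass("RigidTransform",
         representation(rotation = "matrix", translation = "numeric"),
         prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (length(object@translation) != 3L) return("translation must have length 3")
  if (abs(det(R) - 1) > 1e-9) return("rotation must be proper (det = +1)")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6) return("rotation not orthogonal")
  TRUE
})

#' Per-atom force-field parameter table
#'
#' Holds partial charges (e), Lennard-Jones well depth epsilon (kcal/mol)
#' and minimum-distance half radius Rmin/2 (Angstrom), and a
#' Poisson-Boltzmann cavity radius (Angstrom), keyed by
#' (residue name, atom name).  A row with \code{atomname == "*"} is a
#' residue-level fallback; a row with \code{resname == "*"} an atom-name
#' fallback.
#'
#' @slot table data.frame with columns \code{resname, atomname, charge,
#'   epsilon, rmin_half, pb_radius}.
#' @exportClass ParameterSet
setClass("ParameterSet", representation(table = "data.frame"))

setValidity("ParameterSet", function(object) {
  t <- object@table
  need <- c("resname", "atomname", "charge", "epsilon", "rmin_half", "pb_radius")
  if (!all(need %in% names(t))) return("parameter table lacks required columns")
  if (nrow(t)) {
    if (any(t$epsilon < 0)) return("epsilon must be >= 0")
    if (any(t$rmin_half <= 0) || any(t$pb_radius <= 0)) return("radii must be > 0")
    if (any(!is.finite(t$charge))) return("charges must be finite")
  }
  TRUE
})

#' Scalar field on a regular cubic grid
#'
#' Shared layout for occupancy maps and electrostatic potential grids:
#' node \code{[i,j,k]} sits at \code{origin + spacing * (i-1, j-1, k-1)}.
#'
#' @slot origin length-3 numeric, Angstrom.
#' @slot spacing grid spacing, Angstrom.
#' @slot values 3-D numeric array.
#' @exportClass ScalarGrid
setClass("ScalarGrid",
         representation(origin = "numeric", spacing = "numeric",
                        values = "array"))

setValidity("ScalarGrid", function(object) {
  if (length(object@origin) != 3L) return("origin must have length 3")
  if (object@spacing <= 0) return("spacing must be > 0")
  if (length(dim(object@values)) != 3L) return("values must be a 3-D array")
  TRUE
})

#' Docking occupancy map
#'
#' Gaussian-smeared heavy-atom occupancy used by the rigid-body search;
#' also records which atom subset contributed.
#' @slot subset character description of the contributing atom subset.
#' @exportClass GridMap
setClass("GridMap", contains = "ScalarGrid",
         representation(subset = "character"),
         prototype(subset = "all heavy atoms"))

#' Electrostatic potential grid (kcal/mol/e)
#' @exportClass PotentialGrid
setClass("PotentialGrid", contains = "ScalarGrid")

#' A docking pose
#'
#' A rigid placement of the ligand relative to the fixed receptor, with the
#' scores attached as the pipeline progresses: coarse map score, refined
#' interaction energy, energy-component feature vector, classifier rank.
#'
#' @slot transform \code{RigidTransform} applied to the ligand.
#' @slot mapScore coarse map-complementarity score (lower is better).
#' @slot energy refined interaction energy, kcal/mol.
#' @slot features numeric feature vector (named) once scored.
#' @slot rank integer rank after classifier scoring (NA until ranked).
#' @slot provenance list with start-point id, seed, etc.
#' @exportClass Pose
setClass("Pose",
         representation(transform = "RigidTransform", mapScore = "numeric",
                        energy = "numeric", features = "numeric",
                        rank = "integer", provenance = "list"),
         prototype(mapScore = NA_real_, energy = NA_real_,
                   features = numeric(0), rank = NA_integer_,
                   provenance = list()))

#' Poisson-Boltzmann solver configuration
#'
#' @slot epsIn solute dielectric (default 1).
#' @slot epsOut solvent dielectric (default 78.54).
#' @slot dime grid points per side (odd; production 321, tests use 33-97).
#' @slot spacings focusing ladder of grid spacings in Angstrom, strictly
#'   decreasing (default \code{c(1.5, 1.0, 0.5)}).
#' @slot ionicStrength molar ionic strength (default 0: plain Poisson).
#' @slot gamma nonpolar surface coefficient, cal/mol/A^2 (default 8).
#' @slot tol relative SOR convergence tolerance.
#' @slot maxit maximum SOR iterations per solve.
#' @slot smoothWindow half-width of the cubic-spline dielectric boundary
#'   transition, Angstrom.
#' @exportClass PbConfig
setClass("PbConfig",
         representation(epsIn = "numeric", epsOut = "numeric",
                        dime = "integer", spacings = "numeric",
                        ionicStrength = "numeric", gamma = "numeric",
                        tol = "numeric", maxit = "integer",
                        smoothWindow = "numeric"))

setValidity("PbConfig", function(object) {
  if (!(object@epsOut > object@epsIn && object@epsIn >= 1))
    return("need epsOut > epsIn >= 1")
  if (object@dime %% 2L != 1L) return("dime must be odd")
  if (is.unsorted(rev(object@spacings), strictly = TRUE))
    return("spacings must be strictly decreasing")
  TRUE
})

#' Multi-run conformational ensemble
#'
#' Frames grouped by independent run, all sharing one topology.  Each frame
#' is an n_atoms x 3 coordinate matrix.
#'
#' @slot topology \code{PDBStructure} shared by all frames.
#' @slot runs list of runs; each run a list of coordinate matrices.
#' @slot intervalPs time between saved frames, picoseconds.
#' @exportClass Ensemble
setClass("Ensemble",
         representation(topology = "PDBStructure", runs = "list",
                        intervalPs = "numeric"),
         prototype(intervalPs = 0.5))

setValidity("Ensemble", function(object) {
  if (!length(object@runs)) return("ensemble needs >= 1 run")
  nat <- nrow(object@topology@atoms)
  for (r in object@runs) for (f in r)
    if (!is.matrix(f) || nrow(f) != nat || ncol(f) != 3L)
      return("every frame must be an n_atoms x 3 matrix matching the topology")
  TRUE
})

#' MM-PBSA thermodynamic-cycle components
#'
#' Gas-phase van der Waals and electrostatic binding energies plus the
#' electrostatic and nonpolar solvation differences; the derived totals
#' satisfy dG_sln = dG_gas + dG_solv by construction.
#'
#' @slot vdw,elecGas,solvElec,solvNonel component energies, kcal/mol.
#' @exportClass EnergyComponents
setClass("EnergyComponents",
         representation(vdw = "numeric", elecGas = "numeric",
                        solvElec = "numeric", solvNonel = "numeric"))

#' Equal-width clustering of a gas-phase electrostatic energy series
#'
#' @slot edges bin edges (length k + 1), kcal/mol.
#' @slot assignment bin index per frame (NA never occurs).
#' @slot representatives frame index per non-empty bin (closest to bin mean).
#' @slot weights member count / total frames per non-empty bin.
#' @slot energies representative energies, kcal/mol.
#' @exportClass ElecClusterSet
setClass("ElecClusterSet",
         representation(edges = "numeric", assignment = "integer",
                        representatives = "integer", weights = "numeric",
                        energies = "numeric"))

setValidity("ElecClusterSet", function(object) {
  if (length(object@weights) &&
      abs(sum(object@weights) - 1) > 1e-9)
    return("weights must sum to 1")
  if (length(object@representatives) != length(object@weights))
    return("one representative per non-empty bin")
  TRUE
})

#' Protonation assignment
#'
#' Integer formal charge per residue plus a tautomer label for histidines.
#' Asp/Glu side chains carry -1, Lys/Arg +1; His is neutral by default with
#' the tautomer (ND1-H or NE2-H) chosen by local hydrogen-bond geometry.
#'
#' @slot charges named integer vector, one per residue key.
#' @slot hisTautomer named character vector over His residues, values
#'   \code{"ND1"}, \code{"NE2"} or \code{"both"} (+1 charged form).
#' @slot flagged residue keys with nonstandard names (assigned charge 0).
#' @exportClass ProtonationAssignment
setClass("ProtonationAssignment",
         representation(charges = "integer", hisTautomer = "character",
                        flagged = "character"))

#' Constraint set for pose screening
#'
#' @slot requiredContacts antigen-side residue keys that must appear in the
#'   interface contact list.
#' @slot contactCutoff heavy-atom contact cutoff, Angstrom (default 5).
#' @slot requiredPairs data.frame with columns \code{a}, \code{b} of residue
#'   keys that must be in contact (may have zero rows).
#' @slot stoichiometry if TRUE, require that a second ligand copy placed by
#'   the internal symmetry fits without steric clash.
#' @slot clashThreshold heavy-atom clash distance, Angstrom (default 2.5).
#' @slot buriedAreaWindow length-2 numeric: admissible interface buried
#'   area, A^2 (default \code{c(1144, 2500)}).
#' @exportClass ConstraintSet
setClass("ConstraintSet",
         representation(requiredContacts = "character",
                        contactCutoff = "numeric",
                        requiredPairs = "data.frame",
                        stoichiometry = "logical",
                        clashThreshold = "numeric",
                        buriedAreaWindow = "numeric"),
         prototype(requiredContacts = character(0), contactCutoff = 5,
                   requiredPairs = data.frame(a = character(0), b = character(0)),
                   stoichiometry = FALSE, clashThreshold = 2.5,
                   buriedAreaWindow = c(1144, 2500)))
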