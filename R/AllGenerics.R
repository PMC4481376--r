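#' @include AllClasses.R
NULL

#' Number of atoms
#' @param x a \code{PDBStructure}
#' @return integer atom count
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Coordinate matrix
#' @param x an object holding coordinates
#' @return n x 3 numeric matrix (Angstrom)
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Replace coordinates
#' @param x an object holding coordinates
#' @param value n x 3 numeric matrix
#' @export
setGeneric("coords<-", function(x, value) standardGeneric("coords<-"))

#' Atom table
#' @param x a \code{PDBStructure}
#' @return data.frame of atoms in file order
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Residue keys in file order
#'
#' Keys are \code{"chain:resnum:icode:resname"} strings; ordering follows
#' first appearance in the file, not residue-number arithmetic.
#' @param x a \code{PDBStructure}
#' @return character vector of unique residue keys
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))

#' Apply a rigid transform
#' @param x coordinates, a structure, or a transform to compose with
#' @param transform a \code{RigidTransform}
#' @return transformed object of the same class as \code{x}
#' @export
setGeneric("applyTransform",
           function(x, transform) standardGeneric("applyTransform"))

#' @rdname nAtoms
setMethod("nAtoms", "PDBStructure", function(x) nrow(x@atoms))

#' @rdname coords
setMethod("coords", "PDBStructure", function(x) {
  m <- as.matrix(x@atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
})

#' @rdname coords-set
#' @name coords<-
setReplaceMethod("coords", "PDBStructure", function(x, value) {
  stopifnot(is.matrix(value), nrow(value) == nrow(x@atoms), ncol(value) == 3L)
  x@atoms$x <- value[, 1]; x@atoms$y <- value[, 2]; x@atoms$z <- value[, 3]
  x
})

#' @rdname atoms
setMethod("atoms", "PDBStructure", function(x) x@atoms)

.reskey <- function(a) paste(a$chain, a$resnum, a$icode, a$resname, sep = ":")

#' @rdname residueKeys
setMethod("residueKeys", "PDBStructure", function(x) unique(.reskey(x@atoms)))

#' Per-atom residue index (order of first appearance)
#' @param x a \code{PDBStructure}
#' @return integer vector, one entry per atom
#' @export
residueIndex <- function(x) {
  k <- .reskey(x@atoms)
  match(k, unique(k))
}

#' Logical mask of heavy (non-hydrogen) atoms
#' @param x a \code{PDBStructure}
#' @return logical vector over atoms
#' @export
isHeavy <- function(x) x@atoms$element != "H"

setMethod("show", "PDBStructure", function(object) {
  a <- object@atoms
  cat(sprintf("PDBStructure: %d atoms (%d heavy), %d residues, chains: %s\n",
              nrow(a), sum(a$element != "H"),
              length(residueKeys(object)),
              paste(unique(a$chain), collapse = " ")))
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.1f deg, translation (%.2f, %.2f, %.2f) A\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "Pose", function(object) {
  cat(sprintf("Pose: mapScore=%.3f energy=%.2f rank=%s features=%d\n",
              object@mapScore, object@energy,
              ifelse(is.na(object@rank), "unranked", object@rank),
              length(object@features)))
})

setMethod("show", "Ensemble", function(object) {
  nf <- vapply(object@runs, length, 1L)
  cat(sprintf("Ensemble: %d runs x frames (%s), %d atoms, interval %.2f ps\n",
              length(object@runs), paste(nf, collapse = ", "),
              nrow(object@topology@atoms), object@intervalPs))
})

setMethod("show", "EnergyComponents", function(object) {
  cat(sprintf(paste0("EnergyComponents (kcal/mol): vdW %.3f  elec(gas) %.3f",
                     "  solv(elec) %.3f  solv(nonpolar) %.3f  total %.3f\n"),
              object@vdw, object@elecGas, object@solvElec, object@solvNonel,
              dGsln(object)))
})

setMethod("show", "ElecClusterSet", function(object) {
  cat(sprintf("ElecClusterSet: %d occupied / %d bins over [%.2f, %.2f] kcal/mol\n",
              length(object@weights), length(object@edges) - 1L,
              min(object@edges), max(object@edges)))
})

#' Gas-phase binding free energy dG_gas = dE_vdw + dE_elec
#' @param x an \code{EnergyComponents}
#' @return kcal/mol
#' @export
dGgas <- function(x) x@vdw + x@elecGas

#' Solvation free energy dG_solv = dG_solv^elec + dG_solv^nonpolar
#' @param x an \code{EnergyComponents}
#' @return kcal/mol
#' @export
dGsolv <- function(x) x@solvElec + x@solvNonel

#' Binding free energy in solution dG_sln = dG_gas + dG_solv
#' @param x an \code{EnergyComponents}
#' @return kcal/mol
#' @export
dGsln <- function(x) dGgas(x) + dGsolv(x)

#' Construct an EnergyComponents object
#' @param vdw,elecGas,solvElec,solvNonel component energies, kcal/mol
#' @return an \code{EnergyComponents}
#' @export
energyComponents <- function(vdw = 0, elecGas = 0, solvElec = 0,
                             solvNonel = 0) {
  new("EnergyComponents", vdw = vdw, elecGas = elecGas, solvElec = solvElec,
      solvNonel = solvNonel)
}

#' Construct a PB solver configuration
#'
#' Defaults mirror a standard protein implicit-solvent setup: solute
#' dielectric 1, solvent 78.54, a focusing ladder of 1.5, 1.0 and 0.5 A
#' spacings, zero ionic strength and a nonpolar coefficient of
#' 8 cal/mol/A^2.  The production grid is 321 points per side; tests and
#' small systems use far fewer.
#'
#' @param epsIn,epsOut solute / solvent dielectric constants
#' @param dime odd number of grid points per side
#' @param spacings strictly decreasing focusing spacings, Angstrom
#' @param ionicStrength molar ionic strength (0 = plain Poisson)
#' @param gamma nonpolar surface-tension coefficient, cal/mol/A^2
#' @param tol relative convergence tolerance of the relaxation solver
#' @param maxit iteration cap per solve
#' @param smoothWindow dielectric-boundary spline half-width, Angstrom
#' @return a \code{PbConfig}
#' @export
pbConfig <- function(epsIn = 1, epsOut = 78.54, dime = 321L,
                     spacings = c(1.5, 1.0, 0.5), ionicStrength = 0,
                     gamma = 8, tol = 1e-6, maxit = 2000L,
                     smoothWindow = 0.3) {
  new("PbConfig", epsIn = epsIn, epsOut = epsOut, dime = as.integer(dime),
      spacings = spacings, ionicStrength = ionicStrength, gamma = gamma,
      tol = tol, maxit = as.integer(maxit), smoothWindow = smoothWindow)
}

#' Coulomb constant in kcal A / (mol e^2)
#'
#' The CHARMM convention value used for all electrostatics in the package.
#' @export
KE_COULOMB <- 332.0636

#' Boltzmann constant in kcal/(mol K)
#' @export
KB_KCAL <- 0.0019872041
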