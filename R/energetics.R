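#' @include AllGenerics.R
NULL

#' Construct a ParameterSet from a data frame
#' @param table data.frame with columns \code{resname, atomname, charge,
#'   epsilon, rmin_half, pb_radius}
#' @return a \code{ParameterSet}
#' @export
parameterSet <- function(table) new("ParameterSet", table = table)

#' Read / write a parameter table as TSV
#' @param path file path
#' @return a \code{ParameterSet}
#' @export
readParameterSet <- function(path)
  parameterSet(read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE))

#' @rdname readParameterSet
#' @param params a \code{ParameterSet}
#' @export
writeParameterSet <- function(params, path)
  write.table(params@table, path, sep = "\t", row.names = FALSE,
              quote = FALSE)

#' Simplified per-atom parameters for the twenty amino acids
#'
#' A compact additive-force-field-style table: CHARMM-like backbone partial
#' charges, unit side-chain charges localised on the charged-group termini
#' of Asp/Glu/Lys/Arg, and element-based Lennard-Jones and PB cavity radii.
#' It is deliberately simplified (no CMAP, no per-atom charge refinement)
#' and is the default when no user table is supplied; all tests of the
#' energy machinery use explicit toy tables so correctness is
#' table-independent.
#'
#' @return a \code{ParameterSet}
#' @export
defaultParameterSet <- function() {
  # element-level LJ (epsilon kcal/mol, Rmin/2 A) and PB radii
  lj <- data.frame(
    el = c("C", "N", "O", "S", "H"),
    epsilon = c(0.07, 0.20, 0.12, 0.45, 0.046),
    rmin_half = c(2.00, 1.85, 1.70, 2.00, 0.80),
    pb_radius = c(1.70, 1.55, 1.52, 1.80, 1.00))
  bb <- data.frame(atomname = c("N", "CA", "C", "O", "H", "HA", "OXT"),
                   charge = c(-0.47, 0.07, 0.51, -0.51, 0.31, 0.09, -0.51))
  side <- rbind(
    data.frame(resname = "ASP", atomname = c("OD1", "OD2"), charge = -0.5),
    data.frame(resname = "GLU", atomname = c("OE1", "OE2"), charge = -0.5),
    data.frame(resname = "LYS", atomname = "NZ", charge = 0.4),
    data.frame(resname = "LYS", atomname = c("HZ1", "HZ2", "HZ3"), charge = 0.2),
    data.frame(resname = "ARG", atomname = c("NH1", "NH2"), charge = 0.2),
    data.frame(resname = "ARG", atomname = c("HH11", "HH12", "HH21", "HH22",
                                             "HE"), charge = 0.12),
    data.frame(resname = "SER", atomname = c("OG", "HG"), charge = c(-0.66, 0.43)),
    data.frame(resname = "THR", atomname = c("OG1", "HG1"), charge = c(-0.66, 0.43)),
    data.frame(resname = "TYR", atomname = c("OH", "HH"), charge = c(-0.54, 0.43)),
    data.frame(resname = "ASN", atomname = c("OD1", "ND2", "HD21", "HD22"),
               charge = c(-0.55, -0.62, 0.32, 0.30)),
    data.frame(resname = "GLN", atomname = c("OE1", "NE2", "HE21", "HE22"),
               charge = c(-0.55, -0.62, 0.32, 0.30)),
    data.frame(resname = "HIS", atomname = c("ND1", "NE2", "HD1", "HE2"),
               charge = c(-0.36, -0.36, 0.32, 0.32)),
    data.frame(resname = "TRP", atomname = c("NE1", "HE1"), charge = c(-0.51, 0.37)))
  rows <- list()
  for (i in seq_len(nrow(bb)))
    rows[[length(rows) + 1L]] <- data.frame(resname = "*",
                                            atomname = bb$atomname[i],
                                            charge = bb$charge[i])
  side$resname <- as.character(side$resname)
  rows[[length(rows) + 1L]] <- side[, c("resname", "atomname", "charge")]
  rows[[length(rows) + 1L]] <- data.frame(resname = "*", atomname = "*",
                                          charge = 0)
  tab <- do.call(rbind, rows)
  el <- .guess_element(tab$atomname)
  el[tab$atomname == "*"] <- "C"
  m <- match(el, lj$el); m[is.na(m)] <- 1L
  tab$epsilon <- lj$epsilon[m]
  tab$rmin_half <- lj$rmin_half[m]
  tab$pb_radius <- lj$pb_radius[m]
  parameterSet(tab)
}

#' Attach per-atom parameters to a structure
#'
#' Looks up each atom by (residue name, atom name), falling back to
#' residue-wildcard then full-wildcard rows.
#'
#' @param x a \code{PDBStructure}
#' @param params a \code{ParameterSet}
#' @return data.frame with per-atom \code{charge, epsilon, rmin_half,
#'   pb_radius}
#' @export
attachParameters <- function(x, params) {
  t <- params@table
  a <- x@atoms
  key <- paste(t$resname, t$atomname)
  i1 <- match(paste(a$resname, a$name), key)
  i2 <- match(paste("*", a$name), key)
  i3 <- match(paste(a$resname, "*"), key)
  i4 <- match("* *", key)
  idx <- ifelse(!is.na(i1), i1, ifelse(!is.na(i2), i2,
                ifelse(!is.na(i3), i3, i4)))
  if (anyNA(idx))
    stop("unparameterized atom: ",
         paste(a$resname[is.na(idx)][1], a$name[is.na(idx)][1]))
  data.frame(charge = t$charge[idx], epsilon = t$epsilon[idx],
             rmin_half = t$rmin_half[idx], pb_radius = t$pb_radius[idx])
}

.cross_dist <- function(xa, xb) {
  # n_a x n_b distance matrix
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * tcrossprod(xa, xb)
  sqrt(pmax(d2, 0))
}

#' Gas-phase Coulomb interaction energy between two atom sets
#'
#' \eqn{\sum k_e q_i q_j / r_{ij}} over cross pairs with
#' \eqn{r_{ij} \le} \code{cutoff}, with \eqn{k_e = 332.0636}
#' kcal A/(mol e^2) (CHARMM convention).  The cutoff is applied
#' atom-pairwise.
#'
#' @param xa,xb n x 3 coordinate matrices of the two parts
#' @param qa,qb partial charges (e)
#' @param cutoff pair cutoff, Angstrom (999 is effectively infinite)
#' @return energy in kcal/mol
#' @export
coulombEnergy <- function(xa, qa, xb, qb, cutoff = 999) {
  stopifnot(cutoff > 0)
  if (!nrow(xa) || !nrow(xb)) return(0)
  d <- .cross_dist(xa, xb)
  if (any(d < 1e-9)) {
    ij <- which(d < 1e-9, arr.ind = TRUE)[1, ]
    stop(sprintf("singularity: atoms %d/%d at zero distance", ij[1], ij[2]))
  }
  e <- KE_COULOMB * outer(qa, qb) / d
  e[d > cutoff] <- 0
  sum(e)
}

# standard CHARMM cubic switching function on [ron, roff]
.switch_fn <- function(r, ron, roff) {
  s <- rep(1, length(r))
  s[r >= roff] <- 0
  w <- r > ron & r < roff
  if (any(w)) {
    r2 <- r[w]^2; ron2 <- ron^2; roff2 <- roff^2
    s[w] <- (roff2 - r2)^2 * (roff2 + 2 * r2 - 3 * ron2) / (roff2 - ron2)^3
  }
  s
}

#' Lennard-Jones interaction energy with switching
#'
#' 12-6 LJ with Lorentz-Berthelot combining
#' (\eqn{\epsilon_{ij} = \sqrt{\epsilon_i\epsilon_j}},
#' \eqn{R_{min,ij} = R_{min,i}/2 + R_{min,j}/2}), multiplied by the
#' standard cubic switching function on [\code{switchOn}, \code{switchOff}]
#' and zero beyond \code{switchOff}.
#'
#' @param xa,xb coordinate matrices
#' @param epsa,epsb well depths (kcal/mol)
#' @param rmina,rminb Rmin/2 radii (A)
#' @param switchOn,switchOff switching window, A (default 10-12)
#' @return energy in kcal/mol
#' @export
ljEnergy <- function(xa, epsa, rmina, xb, epsb, rminb,
                     switchOn = 10, switchOff = 12) {
  stopifnot(switchOn < switchOff)
  if (!nrow(xa) || !nrow(xb)) return(0)
  d <- .cross_dist(xa, xb)
  if (any(d < 1e-9)) stop("singularity: zero interatomic distance")
  eps <- sqrt(outer(epsa, epsb))
  rmin <- outer(rmina, rminb, `+`)
  sr6 <- (rmin / d)^6
  e <- eps * (sr6^2 - 2 * sr6) * .switch_fn(d, switchOn, switchOff)
  e[d >= switchOff] <- 0
  sum(e)
}

#' Total gas-phase cross energy between two structures
#'
#' Convenience wrapper returning Coulomb and switched LJ cross terms with
#' parameters attached from a \code{ParameterSet}.
#' @param a,b \code{PDBStructure}s (disjoint parts)
#' @param params a \code{ParameterSet}
#' @param cutoff Coulomb pair cutoff, A
#' @param switchOn,switchOff LJ switching window, A
#' @return list with \code{elec}, \code{vdw} (kcal/mol)
#' @export
gasEnergy <- function(a, b, params, cutoff = 999, switchOn = 10,
                      switchOff = 12) {
  pa <- attachParameters(a, params); pb <- attachParameters(b, params)
  xa <- coords(a); xb <- coords(b)
  list(elec = coulombEnergy(xa, pa$charge, xb, pb$charge, cutoff),
       vdw = ljEnergy(xa, pa$epsilon, pa$rmin_half, xb, pb$epsilon,
                      pb$rmin_half, switchOn, switchOff))
}

#' Per-residue gas-phase interaction energies
#'
#' For each residue of \code{a}, the summed Coulomb plus switched LJ
#' interaction of its atoms with all atoms of \code{b}.  The per-residue
#' values sum exactly to the totals at the same cutoffs.
#'
#' @inheritParams gasEnergy
#' @return data.frame with \code{key, elec, vdw} per residue of \code{a}
#' @export
residuePairwiseEnergy <- function(a, b, params, cutoff = 999,
                                  switchOn = 10, switchOff = 12) {
  pa <- attachParameters(a, params); pb <- attachParameters(b, params)
  ridx <- residueIndex(a)
  keys <- residueKeys(a)
  xa <- coords(a); xb <- coords(b)
  elec <- vdw <- numeric(length(keys))
  for (r in seq_along(keys)) {
    m <- ridx == r
    elec[r] <- coulombEnergy(xa[m, , drop = FALSE], pa$charge[m],
                             xb, pb$charge, cutoff)
    vdw[r] <- ljEnergy(xa[m, , drop = FALSE], pa$epsilon[m], pa$rmin_half[m],
                       xb, pb$epsilon, pb$rmin_half, switchOn, switchOff)
  }
  data.frame(key = keys, elec = elec, vdw = vdw, stringsAsFactors = FALSE)
}
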