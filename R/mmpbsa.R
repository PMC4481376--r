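#' @include AllGenerics.R
NULL

.frame_structure <- function(ens, run, frame) {
  s <- ens@topology
  coords(s) <- ens@runs[[run]][[frame]]
  s
}

.split_parts <- function(x, chainsA, chainsB) {
  list(a = selectAtoms(x, chains = chainsA),
       b = selectAtoms(x, chains = chainsB))
}

#' Per-frame gas-phase electrostatic interaction energy series
#'
#' The cross-part Coulomb energy (14 A atom-pairwise cutoff by default)
#' for every frame of every run; this is the series used to bin frames
#' into electrostatic clusters.
#'
#' @param ens a stripped \code{Ensemble} (protein only)
#' @param chainsA,chainsB the two parts
#' @param params a \code{ParameterSet}
#' @param cutoff pair cutoff, A (default 14)
#' @return list of per-run numeric vectors (kcal/mol)
#' @export
gasElecSeries <- function(ens, chainsA, chainsB, params, cutoff = 14) {
  topo <- ens@topology
  p <- attachParameters(topo, params)
  ia <- which(topo@atoms$chain %in% chainsA)
  ib <- which(topo@atoms$chain %in% chainsB)
  lapply(ens@runs, function(run)
    vapply(run, function(f)
      coulombEnergy(f[ia, , drop = FALSE], p$charge[ia],
                    f[ib, , drop = FALSE], p$charge[ib], cutoff), 1))
}

#' Equal-width clustering of an energy series
#'
#' Sorts frame energies into \code{k} equal-width bins spanning
#' [min, max].  Empty bins carry zero weight and are dropped from the
#' representative set; each occupied bin's representative is the frame
#' whose energy is closest to the bin's member mean (ties to the lowest
#' frame index), and its weight is the member count over the total frame
#' count.
#'
#' @param series numeric vector of per-frame energies
#' @param k number of bins (default 25)
#' @return an \code{ElecClusterSet}
#' @export
clusterFrames <- function(series, k = 25L) {
  if (k < 1L) stop("k must be >= 1")
  if (!length(series)) stop("empty energy series")
  lo <- min(series); hi <- max(series)
  if (hi == lo) {
    return(new("ElecClusterSet", edges = c(lo, hi),
               assignment = rep(1L, length(series)),
               representatives = 1L, weights = 1,
               energies = series[1]))
  }
  edges <- seq(lo, hi, length.out = k + 1L)
  bin <- pmin(findInterval(series, edges, rightmost.closed = TRUE), k)
  occupied <- sort(unique(bin))
  reps <- vapply(occupied, function(b) {
    members <- which(bin == b)
    mu <- mean(series[members])
    members[which.min(abs(series[members] - mu))]
  }, 1L)
  w <- vapply(occupied, function(b) sum(bin == b), 1L) / length(series)
  new("ElecClusterSet", edges = edges, assignment = as.integer(bin),
      representatives = as.integer(reps), weights = w,
      energies = series[reps])
}

#' MM-PBSA energy components of one complex conformation
#'
#' Single-trajectory end-state energetics: the two parts are cut from the
#' complex frame in place.  Gas terms use an effectively infinite (999 A)
#' cutoff; electrostatic solvation is the complex-minus-parts difference of
#' LPBE solves on a common grid centre; the nonpolar term is gamma times
#' the (negative) surface area buried on binding.  The thermodynamic-cycle
#' identity dG_sln = dG_gas + dG_solv holds exactly by construction.
#'
#' @param x complex \code{PDBStructure} (one frame)
#' @param chainsA,chainsB the two parts
#' @param params a \code{ParameterSet}
#' @param config a \code{\link{pbConfig}}
#' @param nPoints SASA sampling density
#' @return an \code{EnergyComponents}
#' @export
frameEnergy <- function(x, chainsA, chainsB, params, config = pbConfig(),
                        nPoints = 480L) {
  pp <- .split_parts(x, chainsA, chainsB)
  pa <- attachParameters(pp$a, params); pb <- attachParameters(pp$b, params)
  xa <- coords(pp$a); xb <- coords(pp$b)
  elec <- coulombEnergy(xa, pa$charge, xb, pb$charge, cutoff = 999)
  vdw <- ljEnergy(xa, pa$epsilon, pa$rmin_half, xb, pb$epsilon,
                  pb$rmin_half, switchOn = 998, switchOff = 999)
  cen <- colMeans(rbind(xa, xb))
  gC <- solveLPBE(x, config = config, params = params, center = cen)$Gsolv
  gA <- solveLPBE(pp$a, config = config, params = params, center = cen)$Gsolv
  gB <- solveLPBE(pp$b, config = config, params = params, center = cen)$Gsolv
  buried <- shrakeRupley(pp$a, nPoints = nPoints)$total +
    shrakeRupley(pp$b, nPoints = nPoints)$total -
    shrakeRupley(x, nPoints = nPoints)$total
  energyComponents(vdw = vdw, elecGas = elec, solvElec = gC - gA - gB,
                   solvNonel = -nonpolarSolvation(buried, config@gamma))
}

#' Cluster-weighted binding energy from representative components
#'
#' Within a run, the representative free energies are weighted by cluster
#' population; across runs the per-run values are averaged without weights
#' and the sample standard deviation reported.
#'
#' @param weights list of per-run weight vectors (each summing to 1)
#' @param values list of per-run numeric vectors of representative dG_sln
#' @return list with \code{perRun}, \code{mean}, \code{sd}
#' @export
weightedBindingEnergy <- function(weights, values) {
  stopifnot(length(weights) == length(values))
  perRun <- vapply(seq_along(weights), function(r) {
    w <- weights[[r]]
    if (sum(w) <= 0) stop("zero total cluster weight")
    sum(w * values[[r]]) / sum(w)
  }, 1)
  list(perRun = perRun, mean = mean(perRun),
       sd = if (length(perRun) > 1) sd(perRun) else 0)
}

#' Clustered, population-weighted MM-PBSA binding free energy
#'
#' For each run: bin the 14-A gas-phase electrostatic series into \code{k}
#' equal-width clusters, evaluate full MM-PBSA components on each cluster
#' representative, and population-weight them.  Across runs: unweighted
#' mean and standard deviation.
#'
#' @param ens an \code{Ensemble}
#' @param chainsA,chainsB the two parts
#' @param params a \code{ParameterSet}
#' @param config a \code{\link{pbConfig}}
#' @param k clusters per run (default 25)
#' @param nPoints SASA sampling density
#' @return list with \code{mean}, \code{sd}, \code{perRun},
#'   \code{clusters} (per run), \code{components} (per run, list of
#'   \code{EnergyComponents} per representative)
#' @export
mmpbsaBindingEnergy <- function(ens, chainsA, chainsB, params,
                                config = pbConfig(), k = 25L,
                                nPoints = 480L) {
  series <- gasElecSeries(ens, chainsA, chainsB, params)
  clusters <- lapply(series, clusterFrames, k = k)
  comps <- lapply(seq_along(ens@runs), function(r) {
    lapply(clusters[[r]]@representatives, function(f)
      frameEnergy(.frame_structure(ens, r, f), chainsA, chainsB, params,
                  config, nPoints = nPoints))
  })
  wbe <- weightedBindingEnergy(
    lapply(clusters, function(cl) cl@weights),
    lapply(comps, function(cc) vapply(cc, dGsln, 1)))
  c(wbe, list(clusters = clusters, components = comps, series = series))
}

# per-residue components for one frame: returns data.frame over ALL
# residues of the complex with columns vdw, elec, pb, np (kcal/mol).
# Gas terms carry a symmetric 1/2 so that the sum over the residues of
# both parts equals the cross-part total exactly (see vignette).
.residue_frame_decomposition <- function(x, chainsA, chainsB, params,
                                         config, nPoints = 480L) {
  pp <- .split_parts(x, chainsA, chainsB)
  keys <- c(residueKeys(pp$a), residueKeys(pp$b))
  gA <- residuePairwiseEnergy(pp$a, pp$b, params, cutoff = 999,
                              switchOn = 998, switchOff = 999)
  gB <- residuePairwiseEnergy(pp$b, pp$a, params, cutoff = 999,
                              switchOn = 998, switchOff = 999)
  gas <- rbind(gA, gB)
  gas$elec <- gas$elec / 2; gas$vdw <- gas$vdw / 2
  # nonpolar: gamma * (SASA_bound - SASA_free) per residue
  sb <- shrakeRupley(x, nPoints = nPoints)$residue
  sfA <- shrakeRupley(pp$a, nPoints = nPoints)$residue
  sfB <- shrakeRupley(pp$b, nPoints = nPoints)$residue
  sfree <- rbind(sfA, sfB)
  np <- config@gamma / 1000 *
    (sb$area[match(keys, sb$key)] - sfree$area[match(keys, sfree$key)])
  # electrostatic solvation: bound-minus-free per-residue contributions
  cen <- colMeans(coords(x))
  rsB <- residueSolvation(x, params, config, center = cen)
  rsFA <- residueSolvation(pp$a, params, config, center = cen)
  rsFB <- residueSolvation(pp$b, params, config, center = cen)
  rsF <- c(rsFA, rsFB)
  pb <- rsB[keys] - rsF[keys]
  data.frame(key = keys, vdw = gas$vdw[match(keys, gas$key)],
             elec = gas$elec[match(keys, gas$key)],
             pb = unname(pb), np = np, stringsAsFactors = FALSE)
}

#' Per-residue MM-PBSA free-energy decomposition
#'
#' For every residue \eqn{i} of both parts: (a) half the cross-part
#' pairwise van der Waals and electrostatic interactions of residue
#' \eqn{i}; (b) \eqn{\gamma\,[SASA_{bound}(i) - SASA_{free}(i)]}; (c) the
#' bound-minus-free difference of residue \eqn{i}'s electrostatic
#' solvation contribution.  Components are cluster-weighted within each
#' run and averaged across runs, with the across-run standard deviation
#' reported; the residue values sum to the total binding free energy
#' within solver tolerance.
#'
#' @inheritParams mmpbsaBindingEnergy
#' @return data.frame with one row per residue: \code{key, dG, sd, vdw,
#'   elec, pb, np} (means over runs, kcal/mol)
#' @export
perResidueDecomposition <- function(ens, chainsA, chainsB, params,
                                    config = pbConfig(), k = 25L,
                                    nPoints = 480L) {
  series <- gasElecSeries(ens, chainsA, chainsB, params)
  clusters <- lapply(series, clusterFrames, k = k)
  runTables <- lapply(seq_along(ens@runs), function(r) {
    cl <- clusters[[r]]
    tabs <- lapply(seq_along(cl@representatives), function(j) {
      d <- .residue_frame_decomposition(
        .frame_structure(ens, r, cl@representatives[j]),
        chainsA, chainsB, params, config, nPoints = nPoints)
      d[, c("vdw", "elec", "pb", "np")] * cl@weights[j]
    })
    Reduce(`+`, tabs)
  })
  # residue keys from the topology partition (stable across frames)
  pp <- .split_parts(ens@topology, chainsA, chainsB)
  keys <- c(residueKeys(pp$a), residueKeys(pp$b))
  dGr <- vapply(runTables, function(t) rowSums(t), numeric(length(keys)))
  out <- data.frame(key = keys,
                    dG = rowMeans(dGr),
                    sd = apply(dGr, 1, function(v)
                      if (length(v) > 1) sd(v) else 0),
                    vdw = rowMeans(vapply(runTables, `[[`, numeric(length(keys)), "vdw")),
                    elec = rowMeans(vapply(runTables, `[[`, numeric(length(keys)), "elec")),
                    pb = rowMeans(vapply(runTables, `[[`, numeric(length(keys)), "pb")),
                    np = rowMeans(vapply(runTables, `[[`, numeric(length(keys)), "np")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Sum per-residue free energies over an epitope region
#'
#' Region total with the across-run standard deviations propagated in
#' quadrature.
#'
#' @param perResidue output of \code{\link{perResidueDecomposition}}
#' @param region character vector of residue keys
#' @return list with \code{dG} and \code{sd} (kcal/mol)
#' @export
epitopeRegionSum <- function(perResidue, region) {
  if (!length(region)) return(list(dG = 0, sd = 0))
  m <- match(region, perResidue$key)
  if (anyNA(m))
    stop("unknown residue(s): ", paste(region[is.na(m)], collapse = ", "))
  list(dG = sum(perResidue$dG[m]), sd = sqrt(sum(perResidue$sd[m]^2)))
}
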