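#' @include AllGenerics.R
NULL

#' Build a Gaussian occupancy map from heavy atoms
#'
#' Each contributing heavy atom is smeared onto the grid with an isotropic
#' Gaussian of width \code{sigma} (default: the grid spacing), truncated at
#' three sigma.  A subset restricts which atoms contribute (e.g. only atoms
#' within 8 A of the CDR loops for an antibody map).
#'
#' @param x a \code{PDBStructure}
#' @param spacing grid spacing, Angstrom (default 2)
#' @param subset optional logical/integer atom selection of contributing
#'   atoms (default: all heavy atoms)
#' @param padding box padding beyond the contributing atoms, A
#'   (default: the 3-sigma Gaussian reach)
#' @param sigma Gaussian width, A
#' @return a \code{GridMap}
#' @export
buildMap <- function(x, spacing = 2, subset = NULL, sigma = spacing,
                     padding = 3 * sigma) {
  heavy <- isHeavy(x)
  keep <- if (is.null(subset)) heavy else {
    sel <- rep(FALSE, nAtoms(x)); sel[subset] <- TRUE; sel & heavy
  }
  if (!any(keep)) stop("empty atom subset for map construction")
  xyz <- coords(x)[keep, , drop = FALSE]
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  dims <- pmax(ceiling((hi - lo) / spacing) + 1L, 4L)
  vals <- array(0, dims)
  cut <- 3 * sigma
  nc <- ceiling(cut / spacing)
  for (a in seq_len(nrow(xyz))) {
    c0 <- round((xyz[a, ] - lo) / spacing)
    ix <- max(0, c0[1] - nc):min(dims[1] - 1, c0[1] + nc)
    iy <- max(0, c0[2] - nc):min(dims[2] - 1, c0[2] + nc)
    iz <- max(0, c0[3] - nc):min(dims[3] - 1, c0[3] + nc)
    gx <- lo[1] + spacing * ix; gy <- lo[2] + spacing * iy
    gz <- lo[3] + spacing * iz
    d2 <- outer(outer((gx - xyz[a, 1])^2, (gy - xyz[a, 2])^2, `+`),
                (gz - xyz[a, 3])^2, `+`)
    g <- exp(-d2 / (2 * sigma^2))
    g[d2 > cut^2] <- 0
    vals[ix + 1L, iy + 1L, iz + 1L] <- vals[ix + 1L, iy + 1L, iz + 1L] + g
  }
  new("GridMap", origin = lo, spacing = spacing, values = vals,
      subset = if (is.null(subset)) "all heavy atoms" else "user subset")
}

#' Build the core/surface receptor map pair for pose scoring
#'
#' The map-based score uses two Gaussian occupancy maps of the same
#' receptor: a narrow \emph{core} map (penetration detector) and a wide
#' \emph{surface} map (contact attractor).
#'
#' @inheritParams buildMap
#' @param coreSigma,surfaceSigma Gaussian widths of the two maps, A
#' @return list with \code{core} and \code{surface} \code{GridMap}s
#' @export
receptorMaps <- function(x, spacing = 2, subset = NULL, coreSigma = 1.2,
                         surfaceSigma = 3.0) {
  list(core = buildMap(x, spacing, subset, sigma = coreSigma),
       surface = buildMap(x, spacing, subset, sigma = surfaceSigma))
}

.map_sum <- function(map, xyz) {
  dims <- dim(map@values)
  hi <- map@origin + map@spacing * (dims - 1)
  inside <- xyz[, 1] > map@origin[1] & xyz[, 1] < hi[1] &
            xyz[, 2] > map@origin[2] & xyz[, 2] < hi[2] &
            xyz[, 3] > map@origin[3] & xyz[, 3] < hi[3]
  if (!any(inside)) return(0)
  sum(.interp_trilinear(map@values, map@origin, map@spacing, dims,
                        xyz[inside, , drop = FALSE]))
}

#' Map-complementarity score of ligand atoms against receptor maps
#'
#' Surrogate surface-complementarity score: the wide surface map rewards
#' ligand atoms near the receptor surface, the narrow core map penalises
#' penetration into the receptor interior.  Lower is better; atoms outside
#' the map box contribute zero.
#'
#' @param maps list with \code{core} and \code{surface} \code{GridMap}s
#'   (from \code{\link{receptorMaps}})
#' @param xyz ligand heavy-atom coordinates
#' @param penalty core-penetration penalty weight
#' @return scalar score (lower = better surface contact without clash)
#' @export
mapScore <- function(maps, xyz, penalty = 20) {
  penalty * .map_sum(maps$core, xyz) - .map_sum(maps$surface, xyz)
}

# six deterministic starting rotations: orientations mapping +z onto the
# six axis directions
.six_rotations <- function(k = 6L) {
  rots <- list(diag(3),
               rotationAbout(c(1, 0, 0), 90),
               rotationAbout(c(1, 0, 0), -90),
               rotationAbout(c(0, 1, 0), 90),
               rotationAbout(c(0, 1, 0), -90),
               rotationAbout(c(1, 0, 0), 180))
  if (k <= 6L) return(rots[seq_len(k)])
  extra <- lapply(seq_len(k - 6L), function(i)
    rotationAbout(c(0, 0, 1), 360 * i / (k - 5L)))
  c(rots, extra)
}

#' Search specification for restricted pose enumeration
#'
#' @param stride start a search every \code{stride} grid points per side
#' @param rotationsPerPoint starting rotations per admissible grid point
#' @param coneHalfAngle degrees; start points must lie within this angle of
#'   the receptor-to-constraint-region axis
#' @param receptorCenter,constraintCenter 3-vectors defining the cone axis
#'   (e.g. the centroid of the receptor domain C-alphas and the centroid of
#'   the epitope-residue C-alphas)
#' @return a list with class checks applied downstream
#' @export
searchSpec <- function(stride = 6L, rotationsPerPoint = 6L,
                       coneHalfAngle = 60, receptorCenter,
                       constraintCenter) {
  stopifnot(stride >= 1L, coneHalfAngle > 0, coneHalfAngle <= 180)
  list(stride = as.integer(stride),
       rotationsPerPoint = as.integer(rotationsPerPoint),
       coneHalfAngle = coneHalfAngle,
       receptorCenter = receptorCenter,
       constraintCenter = constraintCenter)
}

#' Enumerate restricted rigid-body start poses
#'
#' One pose per (admissible grid point x starting rotation).  A grid point
#' is admissible when the direction of its displacement from the receptor
#' centre is within the cone half-angle of the receptor-to-constraint axis;
#' zero displacement counts as on-axis.  Deterministic.
#'
#' @param receptorMap a \code{GridMap} of the receptor (defines the start
#'   grid; the core map of \code{\link{receptorMaps}} is the usual choice)
#' @param ligand the ligand \code{PDBStructure} (placed by centroid)
#' @param spec a \code{\link{searchSpec}}
#' @return list of \code{Pose} objects
#' @export
enumerateStartPoses <- function(receptorMap, ligand, spec) {
  if (is.list(receptorMap) && !is(receptorMap, "GridMap"))
    receptorMap <- receptorMap$core
  dims <- dim(receptorMap@values)
  axis <- .unit(spec$constraintCenter - spec$receptorCenter)
  idx <- lapply(dims, function(n) seq(1L, n, by = spec$stride))
  pts <- as.matrix(expand.grid(idx[[1]], idx[[2]], idx[[3]]))
  xyz <- sweep((pts - 1) * receptorMap@spacing, 2, receptorMap@origin, `+`)
  disp <- sweep(xyz, 2, spec$receptorCenter)
  nrm <- sqrt(rowSums(disp^2))
  cosang <- ifelse(nrm < 1e-9, 1, (disp %*% axis) / pmax(nrm, 1e-9))
  adm <- which(cosang >= cos(spec$coneHalfAngle * pi / 180) - 1e-12)
  if (!length(adm)) stop("search error: no admissible start points in cone")
  rots <- .six_rotations(spec$rotationsPerPoint)
  cen <- colMeans(coords(ligand)[isHeavy(ligand), , drop = FALSE])
  poses <- list()
  for (p in adm) for (r in seq_along(rots)) {
    R <- rots[[r]]
    tr <- rigidTransform(R, xyz[p, ] - as.numeric(R %*% cen))
    poses[[length(poses) + 1L]] <-
      new("Pose", transform = tr,
          provenance = list(point = unname(p), rotation = r))
  }
  poses
}

.random_rotation <- function(maxAngle) {
  ax <- rnorm(3)
  rotationAbout(ax, runif(1, -maxAngle, maxAngle))
}

#' Grid-threading Monte-Carlo minimisation of a pose on occupancy maps
#'
#' Runs \code{cycles} threading cycles of \code{stepsPerCycle} Metropolis
#' steps each; every cycle restarts from the best pose found so far
#' (threading), and the best-scoring pose encountered anywhere is returned,
#' so the reported score is non-increasing in the number of steps.
#' Proposals are rigid translations up to one grid cell and rotations up to
#' \code{maxRot} degrees about the ligand centroid.  Bit-identical under a
#' fixed seed.
#'
#' @param pose starting \code{Pose}
#' @param receptorMaps core/surface map pair from \code{\link{receptorMaps}}
#' @param ligand ligand \code{PDBStructure}
#' @param cycles,stepsPerCycle search schedule (defaults 50 x 20)
#' @param kT Metropolis temperature in score units
#' @param maxRot maximal proposal rotation, degrees
#' @param maxTrans maximal proposal translation, A (at most one grid cell;
#'   sub-cell moves keep the minimisation local, so each start descends
#'   into its own basin instead of drifting across the receptor)
#' @param seed RNG seed
#' @return the best \code{Pose} with \code{mapScore} set
#' @export
gridThreadingMC <- function(pose, receptorMaps, ligand, cycles = 50L,
                            stepsPerCycle = 20L, kT = 0.05, maxRot = 10,
                            maxTrans = 0.8, seed = 1L) {
  set.seed(seed)
  lig0 <- coords(ligand)[isHeavy(ligand), , drop = FALSE]
  sc <- function(tr) mapScore(receptorMaps, applyTransform(lig0, tr))
  best <- pose@transform
  bestScore <- sc(best)
  for (cy in seq_len(cycles)) {
    cur <- best; curScore <- bestScore
    for (st in seq_len(stepsPerCycle)) {
      cen <- colMeans(applyTransform(lig0, cur))
      R <- .random_rotation(maxRot)
      dt <- runif(3, -maxTrans, maxTrans)
      prop <- rigidTransform(
        R %*% cur@rotation,
        as.numeric(R %*% (cur@translation - cen)) + cen + dt)
      propScore <- sc(prop)
      if (propScore <= curScore ||
          runif(1) < exp(-(propScore - curScore) / kT)) {
        cur <- prop; curScore <- propScore
        if (curScore < bestScore) { best <- cur; bestScore <- curScore }
      }
    }
  }
  out <- pose
  out@transform <- best
  out@mapScore <- bestScore
  out@provenance$seed <- seed
  out
}

.backbone_names <- c("N", "CA", "C", "O", "H", "HA", "OXT")

# rotate the side chain (atoms beyond CB) of residue rows `mine` about the
# CA->CB axis by `angle` degrees
.rotate_chi <- function(a, mine, angle) {
  ca <- mine[a$name[mine] == "CA"]; cb <- mine[a$name[mine] == "CB"]
  if (!length(ca) || !length(cb)) return(a)
  A <- c(a$x[ca], a$y[ca], a$z[ca]); B <- c(a$x[cb], a$y[cb], a$z[cb])
  R <- rotationAbout(B - A, angle)
  move <- mine[!a$name[mine] %in% c(.backbone_names, "CB")]
  if (!length(move)) return(a)
  xyz <- cbind(a$x[move], a$y[move], a$z[move])
  xyz <- t(R %*% (t(xyz) - B)) + matrix(B, length(move), 3, byrow = TRUE)
  a$x[move] <- xyz[, 1]; a$y[move] <- xyz[, 2]; a$z[move] <- xyz[, 3]
  a
}

.dd_coulomb <- function(xa, qa, xb, qb) {
  # distance-dependent dielectric eps = r: E = ke q q / r^2
  if (!nrow(xa) || !nrow(xb)) return(0)
  d <- .cross_dist(xa, xb)
  sum(KE_COULOMB * outer(qa, qb) / pmax(d, 1e-6)^2)
}

#' All-atom Monte-Carlo refinement of a docked pose
#'
#' Metropolis minimisation of the cross interaction energy (switched
#' Lennard-Jones plus distance-dependent-dielectric Coulomb) at temperature
#' \code{temperature}, proposing whole-ligand translations up to
#' \code{maxTrans} A or side-chain torsion rotations (chi about CA-CB) of
#' interface residues up to \code{maxTorsion} degrees, torsions attempted
#' \code{moveRatio} times as often as translations.  Interface residues are
#' those with cross heavy-atom contacts within 5 A in the starting pose.
#' A short rigid-body local minimisation follows: up to 200 pattern-search
#' steps on the Lennard-Jones term alone, then up to 300 including the
#' distance-dependent-dielectric electrostatic term.
#'
#' @param pose starting \code{Pose}
#' @param receptor,ligand \code{PDBStructure}s (ligand in its reference
#'   frame; the pose transform places it)
#' @param params \code{ParameterSet}
#' @param nSteps Monte-Carlo steps (default 4000)
#' @param temperature Kelvin (default 300)
#' @param maxTrans maximal translation per move, A (default 0.3)
#' @param maxTorsion maximal torsion rotation, degrees (default 30)
#' @param moveRatio torsion:translation attempt ratio (default 2)
#' @param seed RNG seed
#' @param minimize run the post-MC local minimisation
#' @return a \code{Pose} with \code{energy} set; the refined all-atom
#'   complex is in \code{provenance$refined} (receptor chains first), and
#'   \code{provenance$moveCounts} records attempted move types
#' @export
mcRefine <- function(pose, receptor, ligand, params, nSteps = 4000L,
                     temperature = 300, maxTrans = 0.3, maxTorsion = 30,
                     moveRatio = 2, seed = 1L, minimize = TRUE) {
  set.seed(seed)
  lig <- applyTransform(ligand, pose@transform)
  ra <- receptor@atoms; la <- lig@atoms
  pr <- attachParameters(receptor, params); pl <- attachParameters(lig, params)
  heavR <- ra$element != "H"; heavL <- la$element != "H"
  dmat <- .res_min_dist(as.matrix(ra[heavR, c("x", "y", "z")]),
                        residueIndex(receptor)[heavR],
                        length(residueKeys(receptor)),
                        as.matrix(la[heavL, c("x", "y", "z")]),
                        residueIndex(lig)[heavL],
                        length(residueKeys(lig)))
  ifaceR <- which(apply(dmat, 1, min) <= 5)
  ifaceL <- which(apply(dmat, 2, min) <= 5)
  if (!length(ifaceR) && !length(ifaceL))
    stop("refinement error: no interface residues within 5 A")
  ridxR <- residueIndex(receptor); ridxL <- residueIndex(lig)

  energy <- function(ra, la, elec = TRUE) {
    xa <- as.matrix(ra[, c("x", "y", "z")]); xb <- as.matrix(la[, c("x", "y", "z")])
    e <- ljEnergy(xa, pr$epsilon, pr$rmin_half, xb, pl$epsilon, pl$rmin_half)
    if (elec) e <- e + .dd_coulomb(xa, pr$charge, xb, pl$charge)
    e
  }
  curE <- energy(ra, la)
  bestE <- curE; bestRa <- ra; bestLa <- la
  kT <- KB_KCAL * temperature
  nTor <- 0L; nTra <- 0L
  pTor <- moveRatio / (moveRatio + 1)
  ifaceAll <- c(paste0("R", ifaceR), paste0("L", ifaceL))
  for (s in seq_len(nSteps)) {
    if (runif(1) < pTor && length(ifaceAll)) {
      nTor <- nTor + 1L
      pick <- sample(ifaceAll, 1L)
      ang <- runif(1, -maxTorsion, maxTorsion)
      if (substr(pick, 1, 1) == "R") {
        ra2 <- .rotate_chi(ra, which(ridxR == as.integer(substring(pick, 2))), ang)
        la2 <- la
      } else {
        ra2 <- ra
        la2 <- .rotate_chi(la, which(ridxL == as.integer(substring(pick, 2))), ang)
      }
    } else {
      nTra <- nTra + 1L
      dt <- runif(3, -1, 1)
      dt <- dt / max(sqrt(sum(dt^2)), 1e-9) * runif(1, 0, maxTrans)
      la2 <- la; la2$x <- la$x + dt[1]; la2$y <- la$y + dt[2]; la2$z <- la$z + dt[3]
      ra2 <- ra
    }
    newE <- energy(ra2, la2)
    if (newE <= curE || runif(1) < exp(-(newE - curE) / kT)) {
      ra <- ra2; la <- la2; curE <- newE
      if (curE < bestE) { bestE <- curE; bestRa <- ra; bestLa <- la }
    }
  }
  ra <- bestRa; la <- bestLa; curE <- bestE
  if (minimize) {
    # rigid-ligand pattern search: LJ only, then with electrostatics
    for (phase in 1:2) {
      elec <- phase == 2
      budget <- if (elec) 300L else 200L
      step <- 0.2
      e0 <- energy(ra, la, elec)
      used <- 0L
      while (used < budget && step > 0.01) {
        improved <- FALSE
        for (dim in 1:3) for (sgn in c(1, -1)) {
          if (used >= budget) break
          la2 <- la
          la2[[c("x", "y", "z")[dim]]] <- la[[c("x", "y", "z")[dim]]] + sgn * step
          e1 <- energy(ra, la2, elec)
          used <- used + 1L
          if (e1 < e0) { la <- la2; e0 <- e1; improved <- TRUE }
        }
        if (!improved) step <- step / 2
      }
      curE <- energy(ra, la)
    }
  }
  # recover the net rigid transform of the ligand centroid shift (torsions
  # excluded); the full refined coordinates are what downstream stages use
  lig0 <- applyTransform(ligand, pose@transform)
  shift <- colMeans(cbind(la$x, la$y, la$z)) -
    colMeans(coords(lig0))
  out <- pose
  out@transform <- rigidTransform(pose@transform@rotation,
                                  pose@transform@translation + shift)
  out@energy <- curE
  la$serial <- max(ra$serial) + seq_len(nrow(la))
  refined <- new("PDBStructure", atoms = rbind(ra, la))
  out@provenance$refined <- refined
  out@provenance$moveCounts <- c(torsion = nTor, translation = nTra)
  out@provenance$seed <- seed
  out
}

#' Energy-component features of a pose
#'
#' Feature vector used by the pose ranker:
#' \code{(dE_vdw, dE_elec_gas, dG_solv_elec, dG_solv_nonpolar,
#' buried_SASA)}.  When \code{pbConfig} is \code{NULL} the electrostatic
#' solvation feature is omitted from computation (set to 0) for fast
#' map-stage triage.
#'
#' @param pose a \code{Pose}
#' @param receptor,ligand \code{PDBStructure}s
#' @param params \code{ParameterSet}
#' @param pbConfig optional \code{PbConfig} for the solvation feature
#' @param nPoints SASA sampling density
#' @return the pose with \code{features} set
#' @export
scoreFeatures <- function(pose, receptor, ligand, params, pbConfig = NULL,
                          nPoints = 240L) {
  lig <- applyTransform(ligand, pose@transform)
  g <- gasEnergy(receptor, lig, params, cutoff = 999)
  buried <- shrakeRupley(receptor, nPoints = nPoints)$total +
    shrakeRupley(lig, nPoints = nPoints)$total -
    shrakeRupley(mergeStructures(receptor, lig), nPoints = nPoints)$total
  solvNonel <- -nonpolarSolvation(max(buried, 0))
  solvElec <- 0
  if (!is.null(pbConfig)) {
    cen <- colMeans(rbind(coords(receptor), coords(lig)))
    cplx <- mergeStructures(receptor, lig)
    solvElec <- solveLPBE(cplx, config = pbConfig, params = params,
                          center = cen)$Gsolv -
      solveLPBE(receptor, config = pbConfig, params = params, center = cen)$Gsolv -
      solveLPBE(lig, config = pbConfig, params = params, center = cen)$Gsolv
  }
  out <- pose
  out@features <- c(vdw = g$vdw, elec = g$elec, solvElec = solvElec,
                    solvNonel = solvNonel, buriedSASA = buried)
  out
}

#' Run the restricted rigid-body docking pipeline end to end
#'
#' Enumerates cone-restricted start poses on the receptor occupancy grid,
#' locally minimises each by grid-threading Monte Carlo on the map pair,
#' refines the best map-scored candidates with all-atom Monte Carlo plus
#' local minimisation, computes energy-component features, and ranks them
#' with the supplied classifier.
#'
#' @param receptor,ligand \code{PDBStructure}s
#' @param params \code{ParameterSet} for refinement and features
#' @param epitopeResidues receptor-side residue keys defining the
#'   constraint region whose centroid anchors the search cone
#' @param model ranker from \code{\link{trainRanker}}
#' @param stride,rotationsPerPoint,coneHalfAngle search-cone settings
#' @param threadCycles,threadSteps grid-threading schedule per start
#' @param nRefine number of top map-scored candidates refined all-atom
#' @param refineSteps Monte-Carlo steps per refinement
#' @param pbConfig optional \code{PbConfig} for the solvation feature
#' @param k number of ranked poses returned
#' @param seed RNG seed
#' @return list of ranked \code{Pose}s, best first
#' @export
dockComplex <- function(receptor, ligand, params, epitopeResidues, model,
                        stride = 3L, rotationsPerPoint = 6L,
                        coneHalfAngle = 60, threadCycles = 15L,
                        threadSteps = 10L, nRefine = 20L,
                        refineSteps = 400L, pbConfig = NULL, k = 25L,
                        seed = 1L) {
  maps <- receptorMaps(receptor)
  keys <- residueKeys(receptor)
  ridx <- residueIndex(receptor)
  onEpi <- keys[ridx] %in% epitopeResidues
  epiCA <- which(onEpi & receptor@atoms$name == "CA")
  epiSide <- which(onEpi & !receptor@atoms$name %in% c("N", "CA", "C", "O") &
                     isHeavy(receptor))
  if (!length(epiCA)) stop("no epitope residues found in receptor")
  if (!length(epiSide)) epiSide <- which(onEpi & isHeavy(receptor))
  # cone axis: from the epitope backbone centroid outward through the
  # epitope side-chain centroid (the local surface normal of the epitope
  # face; robust also for elongated receptors)
  spec <- searchSpec(stride, rotationsPerPoint, coneHalfAngle,
                     receptorCenter = colMeans(coords(receptor)[epiCA, ,
                                                                drop = FALSE]),
                     constraintCenter = colMeans(coords(receptor)[epiSide, ,
                                                                  drop = FALSE]))
  starts <- enumerateStartPoses(maps$core, ligand, spec)
  threaded <- lapply(seq_along(starts), function(i)
    gridThreadingMC(starts[[i]], maps, ligand, cycles = threadCycles,
                    stepsPerCycle = threadSteps,
                    seed = seed * 10000L + i))
  # cluster-diverse candidate selection: best map score per 4-A cluster
  lx <- coords(ligand)[isHeavy(ligand), , drop = FALSE]
  sets <- lapply(threaded, function(p) applyTransform(lx, p@transform))
  sc <- vapply(threaded, function(p) p@mapScore, 1)
  cl <- clusterByRMSD(sets[order(sc)], cutoff = 4)
  cand <- threaded[order(sc)][vapply(cl, function(c) c$members[1], 1L)]
  cand <- head(cand, nRefine)
  refined <- lapply(seq_along(cand), function(i)
    mcRefine(cand[[i]], receptor, ligand, params, nSteps = refineSteps,
             seed = seed * 100L + i))
  feats <- lapply(refined, scoreFeatures, receptor = receptor,
                  ligand = ligand, params = params, pbConfig = pbConfig)
  rankPoses(feats, model, k = k)
}

#' Train the default pose ranker
#'
#' A linear-kernel support-vector classifier over pose feature vectors,
#' trained on labelled synthetic decoys (near-native vs displaced).  The
#' ranker is pluggable: any object usable by \code{\link{rankPoses}} via a
#' \code{decision} function can replace it.
#'
#' @param features numeric matrix (poses x features)
#' @param labels logical or 0/1 vector: TRUE = near-native
#' @return ranker object with a \code{decision(features)} function
#' @export
trainRanker <- function(features, labels) {
  y <- factor(ifelse(as.logical(labels), "pos", "neg"),
              levels = c("neg", "pos"))
  keep <- apply(features, 2, function(col) stats::var(col) > 0)
  fit <- e1071::svm(features[, keep, drop = FALSE], y, kernel = "linear",
                    scale = TRUE)
  flip <- 1
  dv <- attr(predict(fit, features[, keep, drop = FALSE],
                     decision.values = TRUE), "decision.values")[, 1]
  if (mean(dv[as.logical(labels)]) < mean(dv[!as.logical(labels)])) flip <- -1
  structure(list(fit = fit, keep = keep, flip = flip,
                 decision = function(f) {
                   d <- attr(predict(fit, f[, keep, drop = FALSE],
                                     decision.values = TRUE),
                             "decision.values")[, 1]
                   flip * d
                 }),
            class = "dockRanker")
}

#' Rank featurized poses with a classifier
#'
#' Orders poses by descending classifier decision value with a stable
#' tie-break on input index, assigns ranks, and returns the top \code{k}.
#'
#' @param poses list of featurized \code{Pose}s
#' @param model a ranker from \code{\link{trainRanker}} (or any list with a
#'   \code{decision} function)
#' @param k how many top poses to return (default 25; larger than the pose
#'   count returns all)
#' @return list of ranked \code{Pose}s, best first, with \code{rank} set
#' @export
rankPoses <- function(poses, model, k = 25L) {
  if (is.null(model) || is.null(model$decision))
    stop("ranking error: untrained or invalid model")
  if (!length(poses)) return(poses)
  f <- do.call(rbind, lapply(poses, function(p) p@features))
  if (any(!is.finite(f))) stop("non-finite pose features")
  dv <- model$decision(f)
  ord <- order(-dv, seq_along(poses))
  out <- poses[ord]
  for (i in seq_along(out)) out[[i]]@rank <- i
  head(out, k)
}
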