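#' @include AllClasses.R
NULL

#' Construct an Ensemble
#' @param topology shared \code{PDBStructure}
#' @param runs list of runs, each a list of n_atoms x 3 coordinate matrices
#' @param intervalPs frame interval, picoseconds
#' @return an \code{Ensemble}
#' @export
ensemble <- function(topology, runs, intervalPs = 0.5)
  new("Ensemble", topology = topology, runs = runs, intervalPs = intervalPs)

#' Read a whitespace XYZ-per-frame trajectory
#'
#' A plain-text dialect: one coordinate triple per atom per line, frames
#' concatenated, atom count and order fixed by the topology.
#' @param path file path
#' @param topology \code{PDBStructure} defining atom count/order
#' @return list of coordinate matrices
#' @export
readTrajectory <- function(path, topology) {
  v <- scan(path, quiet = TRUE)
  nat <- nAtoms(topology)
  if (length(v) %% (3 * nat) != 0)
    stop("trajectory length is not a multiple of 3 x atom count")
  nf <- length(v) / (3 * nat)
  lapply(seq_len(nf), function(f) {
    matrix(v[((f - 1) * 3 * nat + 1):(f * 3 * nat)], ncol = 3, byrow = TRUE)
  })
}

#' Read a multi-run ensemble from a manifest
#'
#' The manifest (YAML) declares the topology PDB, the frame interval and
#' one trajectory file per run (multi-model PDB or plain XYZ-per-frame).
#' @param path manifest path; file paths inside are resolved relative to it
#' @return an \code{Ensemble}
#' @export
readEnsembleManifest <- function(path) {
  m <- yaml::read_yaml(path)
  dir <- dirname(path)
  topo <- readPDB(file.path(dir, m$topology))
  runs <- lapply(m$runs, function(f) {
    fp <- file.path(dir, f)
    if (grepl("\\.pdb$", f)) {
      frames <- readPDB(fp)
      if (is(frames, "PDBStructure")) frames <- list(frames)
      lapply(frames, coords)
    } else readTrajectory(fp, topo)
  })
  ensemble(topo, runs, intervalPs = if (is.null(m$interval_ps)) 0.5
                                    else m$interval_ps)
}

.ens_parts <- function(ens, chainsA, chainsB) {
  a <- ens@topology@atoms
  ia <- which(a$chain %in% chainsA & a$element != "H")
  ib <- which(a$chain %in% chainsB & a$element != "H")
  if (!length(ia) || !length(ib)) stop("empty part selection")
  ridx <- residueIndex(ens@topology)
  keys <- residueKeys(ens@topology)
  ka <- unique(ridx[ia]); kb <- unique(ridx[ib])
  list(ia = ia, ib = ib, ra = match(ridx[ia], ka), rb = match(ridx[ib], kb),
       keysA = keys[ka], keysB = keys[kb])
}

# mean over all frames of the per-frame minimum cross heavy-atom distance
# per residue pair; returns list(mean matrix, per-run occupancy array)
.pair_dist_stats <- function(ens, chainsA, chainsB, dMax = NULL) {
  p <- .ens_parts(ens, chainsA, chainsB)
  nra <- length(p$keysA); nrb <- length(p$keysB)
  total <- array(0, c(nra, nrb))
  nfr <- 0L
  occ <- if (!is.null(dMax)) array(0, c(nra, nrb, length(ens@runs))) else NULL
  for (r in seq_along(ens@runs)) {
    frames <- ens@runs[[r]]
    for (f in frames) {
      D <- .res_min_dist(f[p$ia, , drop = FALSE], p$ra, nra,
                         f[p$ib, , drop = FALSE], p$rb, nrb)
      total <- total + D
      if (!is.null(dMax)) occ[, , r] <- occ[, , r] + (D <= dMax)
      nfr <- nfr + 1L
    }
    if (!is.null(dMax)) occ[, , r] <- occ[, , r] / length(frames)
  }
  list(mean = total / nfr, occ = occ, keysA = p$keysA, keysB = p$keysB)
}

#' Occupancy-based interface residues of an ensemble
#'
#' A residue is at the interface when its minimum cross-part heavy-atom
#' distance, averaged over all frames of all runs, is at or below
#' \code{cutoff} (default 5 A).  The mean is taken over per-frame minimum
#' distances per residue pair, which is what yields residue-level
#' interfaces.
#'
#' @param ens an \code{Ensemble}
#' @param chainsA,chainsB chain sets defining the two parts
#' @param cutoff Angstrom (default 5)
#' @return list with \code{pairs} (data.frame resA, resB, meanMinDist for
#'   pairs within cutoff) and \code{residues} (data.frame key, side,
#'   meanMinDist of each interface residue)
#' @export
interfaceResidues <- function(ens, chainsA, chainsB, cutoff = 5) {
  s <- .pair_dist_stats(ens, chainsA, chainsB)
  hit <- which(s$mean <= cutoff, arr.ind = TRUE)
  pairs <- data.frame(resA = s$keysA[hit[, 1]], resB = s$keysB[hit[, 2]],
                      meanMinDist = s$mean[hit], stringsAsFactors = FALSE)
  ra <- apply(s$mean, 1, min); rb <- apply(s$mean, 2, min)
  res <- rbind(
    data.frame(key = s$keysA[ra <= cutoff],
               side = rep("A", sum(ra <= cutoff)),
               meanMinDist = ra[ra <= cutoff]),
    data.frame(key = s$keysB[rb <= cutoff],
               side = rep("B", sum(rb <= cutoff)),
               meanMinDist = rb[rb <= cutoff]))
  rownames(res) <- NULL
  list(pairs = pairs[order(pairs$meanMinDist), , drop = FALSE],
       residues = res)
}

#' Ensemble hydrogen bonds with per-run occupancy
#'
#' Donor-hydrogen...acceptor triples across the interface whose mean
#' hydrogen-acceptor distance is at or below \code{dMax} (default 2.4 A)
#' and mean donor-hydrogen-acceptor angle exceeds \code{angleMin} (default
#' 130 degrees), means taken over all frames of all runs.  Per-run
#' occupancy is the fraction of frames satisfying both criteria
#' per-frame.  Donors are hydrogens covalently bonded (< 1.25 A) to N/O/S;
#' acceptors are N/O/S heavy atoms of the other part.
#'
#' @param ens an \code{Ensemble} whose topology carries hydrogens
#' @param chainsA,chainsB the two parts
#' @param dMax mean H-acceptor distance cutoff, A
#' @param angleMin mean D-H-A angle cutoff, degrees
#' @param candidateCutoff topology H-A distance prefilter, A
#' @return data.frame: donor/hydrogen/acceptor keys and atom names, mean
#'   distance, mean angle, per-run occupancy columns \code{occ.run1}, ...
#' @export
hydrogenBonds <- function(ens, chainsA, chainsB, dMax = 2.4,
                          angleMin = 130, candidateCutoff = 6) {
  a <- ens@topology@atoms
  keys <- residueKeys(ens@topology)
  ridx <- residueIndex(ens@topology)
  xyz0 <- coords(ens@topology)
  hyd <- which(a$element == "H")
  if (!length(hyd))
    stop("no hydrogens in topology; run addHydrogens() first")
  polar <- which(a$element %in% c("N", "O", "S"))
  # bond H to nearest polar heavy atom within 1.25 A
  cand <- list()
  for (side in 1:2) {
    cha <- if (side == 1) chainsA else chainsB
    chb <- if (side == 1) chainsB else chainsA
    hs <- hyd[a$chain[hyd] %in% cha]
    acc <- polar[a$chain[polar] %in% chb]
    if (!length(hs) || !length(acc)) next
    don <- polar[a$chain[polar] %in% cha]
    for (h in hs) {
      if (!length(don)) next
      dd <- sqrt(rowSums(sweep(xyz0[don, , drop = FALSE], 2, xyz0[h, ])^2))
      if (min(dd) > 1.25) next
      d0 <- don[which.min(dd)]
      da <- sqrt(rowSums(sweep(xyz0[acc, , drop = FALSE], 2, xyz0[h, ])^2))
      for (ac in acc[da <= candidateCutoff])
        cand[[length(cand) + 1L]] <- c(d0, h, ac)
    }
  }
  if (!length(cand))
    return(data.frame(donor = character(0), hydrogen = character(0),
                      acceptor = character(0), meanDist = numeric(0),
                      meanAngle = numeric(0)))
  cand <- do.call(rbind, cand)
  nr <- length(ens@runs)
  nc <- nrow(cand)
  sumd <- suma <- numeric(nc)
  occ <- matrix(0, nc, nr)
  nfr <- 0L
  for (r in seq_len(nr)) {
    for (f in ens@runs[[r]]) {
      hv <- f[cand[, 2], , drop = FALSE]
      dv <- f[cand[, 1], , drop = FALSE]
      av <- f[cand[, 3], , drop = FALSE]
      dHA <- sqrt(rowSums((hv - av)^2))
      u1 <- dv - hv; u2 <- av - hv
      cosang <- rowSums(u1 * u2) /
        pmax(sqrt(rowSums(u1^2)) * sqrt(rowSums(u2^2)), 1e-9)
      ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
      sumd <- sumd + dHA; suma <- suma + ang
      occ[, r] <- occ[, r] + (dHA <= dMax & ang > angleMin)
      nfr <- nfr + 1L
    }
    occ[, r] <- occ[, r] / length(ens@runs[[r]])
  }
  meanDist <- sumd / nfr; meanAngle <- suma / nfr
  keep <- meanDist <= dMax & meanAngle > angleMin
  out <- data.frame(
    donor = keys[ridx[cand[keep, 1]]],
    donorAtom = a$name[cand[keep, 1]],
    hydrogen = a$name[cand[keep, 2]],
    acceptor = keys[ridx[cand[keep, 3]]],
    acceptorAtom = a$name[cand[keep, 3]],
    meanDist = meanDist[keep], meanAngle = meanAngle[keep],
    stringsAsFactors = FALSE)
  occk <- occ[keep, , drop = FALSE]
  colnames(occk) <- paste0("occ.run", seq_len(nr))
  cbind(out, as.data.frame(occk))
}

#' Ensemble van der Waals contacts with run-replication requirement
#'
#' Residue pairs whose minimum cross heavy-atom distance is at or below
#' \code{dMax} (default 4 A) in at least \code{minFraction} of the frames
#' (default 50\%) of at least \code{minRuns} independent runs (default 2).
#'
#' @param ens an \code{Ensemble}
#' @param chainsA,chainsB the two parts
#' @param dMax Angstrom
#' @param minFraction per-run occupancy threshold
#' @param minRuns independent-run replication requirement
#' @return data.frame resA, resB, meanMinDist, per-run occupancy columns,
#'   and \code{nRunsSatisfied}
#' @export
vdwContacts <- function(ens, chainsA, chainsB, dMax = 4.0,
                        minFraction = 0.5, minRuns = 2L) {
  if (length(ens@runs) < minRuns)
    stop("ensemble has fewer runs than minRuns")
  s <- .pair_dist_stats(ens, chainsA, chainsB, dMax = dMax)
  nOk <- apply(s$occ >= minFraction, c(1, 2), sum)
  hit <- which(nOk >= minRuns, arr.ind = TRUE)
  out <- data.frame(resA = s$keysA[hit[, 1]], resB = s$keysB[hit[, 2]],
                    meanMinDist = s$mean[hit],
                    nRunsSatisfied = nOk[hit], stringsAsFactors = FALSE)
  occ <- t(vapply(seq_len(nrow(hit)),
                  function(i) s$occ[hit[i, 1], hit[i, 2], ],
                  numeric(length(ens@runs))))
  if (nrow(out)) {
    colnames(occ) <- paste0("occ.run", seq_along(ens@runs))
    out <- cbind(out, as.data.frame(occ))
  }
  out[order(out$meanMinDist), , drop = FALSE]
}

#' Equilibration check on interface-zone backbone RMSD
#'
#' Backbone-atom (N, CA, C, O) RMSD versus a reference structure, per
#' frame and per run, restricted to residues of either part within
#' \code{zone} A of the other part in the reference.  A run is flagged as
#' plateaued when the least-squares slope over its final third is below
#' \code{slopeThreshold} (A/ns) in magnitude.
#'
#' @param ens an \code{Ensemble}
#' @param reference \code{PDBStructure} matching the topology atom order
#' @param chainsA,chainsB the two parts
#' @param zone interface-zone distance, A (default 10)
#' @param slopeThreshold plateau slope bound, A/ns (default 0.05)
#' @return list with \code{series} (list of per-run RMSD vectors),
#'   \code{slopes} (A/ns) and \code{plateau} (logical per run)
#' @export
equilibrationCheck <- function(ens, reference, chainsA, chainsB, zone = 10,
                               slopeThreshold = 0.05) {
  if (nAtoms(reference) != nAtoms(ens@topology))
    stop("reference does not match topology")
  a <- ens@topology@atoms
  p <- .ens_parts(ens, chainsA, chainsB)
  refxyz <- coords(reference)
  D <- .res_min_dist(refxyz[p$ia, , drop = FALSE], p$ra, length(p$keysA),
                     refxyz[p$ib, , drop = FALSE], p$rb, length(p$keysB))
  keys <- residueKeys(ens@topology)
  zoneKeys <- c(p$keysA[apply(D, 1, min) <= zone],
                p$keysB[apply(D, 2, min) <= zone])
  if (!length(zoneKeys)) stop("empty interface zone")
  ridx <- residueIndex(ens@topology)
  sel <- which(keys[ridx] %in% zoneKeys & a$name %in% c("N", "CA", "C", "O"))
  series <- lapply(ens@runs, function(run)
    vapply(run, function(f)
      sqrt(mean(rowSums((f[sel, , drop = FALSE] -
                         refxyz[sel, , drop = FALSE])^2))), 1))
  dtNs <- ens@intervalPs / 1000
  slopes <- vapply(series, function(sr) {
    n <- length(sr)
    i0 <- max(1L, ceiling(2 * n / 3))
    w <- i0:n
    if (length(w) < 2) return(0)
    unname(coef(lm(sr[w] ~ I(w * dtNs)))[2])
  }, 1)
  list(series = series, slopes = slopes,
       plateau = abs(slopes) < slopeThreshold)
}
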