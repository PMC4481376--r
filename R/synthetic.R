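#' @include AllGenerics.R
NULL

#' Generator configuration for synthetic complexes, ensembles and decoys
#'
#' All randomness flows from \code{seed}; per-run sub-seeds are derived
#' deterministically.  The defaults emulate the structure of the study
#' conditions the package targets: four independent runs of frames saved
#' at 0.5 ps, toy two-chain complexes with planted interface interactions,
#' and decoy sets with planted near-native poses.
#'
#' @param seed integer master seed
#' @param nResidues residues per chain (default 6)
#' @param planted data.frame with columns \code{pos} (aligned residue
#'   position, pairing chain A residue pos with chain B residue pos) and
#'   \code{type} in \code{"salt-bridge"}, \code{"hbond"}, \code{"vdw"}
#' @param runs independent ensemble runs (default 4)
#' @param framesPerRun frames per run (default 50; the emulated production
#'   regime is 2000 frames x 4 runs)
#' @param noiseSigma per-atom Gaussian coordinate noise, A (default 0.15)
#' @param occupancy target fraction of frames in which planted contacts
#'   are enforced (default 0.9)
#' @param intervalPs frame interval, ps (default 0.5)
#' @param nNative near-native decoys (default 8)
#' @param nDecoys displaced decoys (default 32)
#' @param decoyTrans displaced-decoy translation range, A
#' @param nativePerturb near-native translation bound, A
#' @return a plain list of settings
#' @export
generatorConfig <- function(seed = 1L, nResidues = 6L,
                            planted = data.frame(
                              pos = c(2L, 4L),
                              type = c("salt-bridge", "hbond")),
                            runs = 4L, framesPerRun = 50L,
                            noiseSigma = 0.15, occupancy = 0.9,
                            intervalPs = 0.5, nNative = 8L, nDecoys = 32L,
                            decoyTrans = c(8, 20), nativePerturb = 1.0) {
  stopifnot(noiseSigma >= 0, runs >= 1L, occupancy >= 0, occupancy <= 1)
  list(seed = as.integer(seed), nResidues = as.integer(nResidues),
       planted = planted, runs = as.integer(runs),
       framesPerRun = as.integer(framesPerRun), noiseSigma = noiseSigma,
       occupancy = occupancy, intervalPs = intervalPs,
       nNative = as.integer(nNative), nDecoys = as.integer(nDecoys),
       decoyTrans = decoyTrans, nativePerturb = nativePerturb)
}

# residue names used by the toy complexes; each maps to a tip chemistry
.toy_resnames <- c("salt-bridge" = "SBP", "hbond" = "HBD", "vdw" = "VWA",
                   none = "NEU")
.toy_partner <- c(SBP = "SBN", HBD = "HBA", VWA = "VWB", NEU = "NEU")

#' Parameter table for the toy residues
#'
#' A tiny explicit table covering the synthetic residue types: neutral
#' backbone, unit charges on salt-bridge tips, partial charges on
#' hydrogen-bond donor/acceptor tips, zero elsewhere.  Tests of the energy
#' machinery use this table so correctness is independent of the shipped
#' amino-acid table.
#' @return a \code{ParameterSet}
#' @export
toyParameterSet <- function() {
  t <- rbind(
    data.frame(resname = "SBP", atomname = "CG", charge = 1),
    data.frame(resname = "SBN", atomname = "CG", charge = -1),
    data.frame(resname = "HBD", atomname = c("CG", "HG"),
               charge = c(-0.40, 0.40)),
    data.frame(resname = "HBA", atomname = c("CG", "CB"),
               charge = c(-0.40, 0.40)),
    data.frame(resname = "*", atomname = "*", charge = 0))
  t$epsilon <- ifelse(grepl("^H", t$atomname), 0.046, 0.10)
  t$rmin_half <- ifelse(grepl("^H", t$atomname), 0.45, 1.90)
  t$pb_radius <- ifelse(grepl("^H", t$atomname), 1.00, 1.70)
  # wildcard row: heavy-atom defaults
  t$epsilon[t$atomname == "*"] <- 0.10
  t$rmin_half[t$atomname == "*"] <- 1.90
  t$pb_radius[t$atomname == "*"] <- 1.70
  parameterSet(t)
}

# chain geometry: the receptor (chain A, backbone at y = 0) presents a
# groove: floor atoms plus two rows of wall atoms at z = +/- 3.4 rising to
# y ~ 4.6, with interaction tips on the groove floor.  The ligand (chain
# B, backbone at y = 8, offset +3 A in x) lowers its tips into the groove,
# interdigitating between the receptor tips (knobs into holes, ~3.6 A
# contacts) - so the native arrangement is also the shape-complementarity
# optimum of the occupancy maps.  Planted pairs bend the chain-B tip into
# x alignment with its partner so the interaction distance is exact.
.toy_residue <- function(chain, pos, resname, serial0, side, tipReach,
                         tipX = NULL, withH = FALSE, jitter = c(0, 0)) {
  xb <- 6 * (pos - 1) + (if (side > 0) 0 else 3) + jitter[1]
  y0 <- if (side > 0) 0 else 8
  z <- jitter[2]
  tx <- if (is.null(tipX)) xb else tipX + jitter[1]
  rows <- data.frame(
    serial = serial0 + 1:3,
    name = c("N", "CA", "CB"),
    altloc = "", resname = resname, chain = chain, resnum = pos, icode = "",
    x = c(xb - 0.8, xb, xb),
    y = c(y0 + side * 0.3, y0, y0 + side * 1.5),
    z = c(z, z, z),
    occupancy = 1, element = c("N", "C", "C"),
    record = "ATOM", stringsAsFactors = FALSE)
  if (side > 0) {
    # groove walls on the receptor
    wall <- rows[rep(2, 4), ]
    wall$serial <- serial0 + 3L + 1:4
    wall$name <- c("CD1", "CD2", "CE1", "CE2")
    wall$y <- c(2.2, 2.2, 4.6, 4.6)
    wall$z <- z + c(-3.4, 3.4, -3.4, 3.4)
    rows <- rbind(rows, wall)
  }
  tip <- rows[2, ]
  tip$serial <- max(rows$serial) + 1L
  tip$name <- "CG"; tip$element <- "C"
  tip$x <- tx; tip$y <- y0 + side * tipReach; tip$z <- z + 0.4
  rows <- rbind(rows, tip)
  if (withH) {
    h <- tip
    h$serial <- max(rows$serial) + 1L
    h$name <- "HG"; h$element <- "H"
    h$y <- y0 + side * (tipReach + 1.0)
    rows <- rbind(rows, h)
  }
  rows
}

#' Generate a toy two-chain complex with planted interactions
#'
#' Two facing chains (A fixed "receptor", B the "ligand") of simplified
#' 4-5-atom residues on a backbone 11 A apart.  Planted residue pairs
#' extend their tip atoms toward each other to realise the interaction
#' geometry: salt bridges place +1e/-1e tips 2.8 A apart, hydrogen bonds a
#' donor H 1.9 A from the acceptor tip, van der Waals pairs tips at 3.5 A;
#' unplanted residues keep their tips retracted (> 7 A cross separation).
#' Output is bit-identical for a fixed seed.
#'
#' @param cfg a \code{\link{generatorConfig}}
#' @return list with \code{complex} (a \code{PDBStructure}),
#'   \code{params} (the toy \code{ParameterSet}) and \code{truth}
#'   (data.frame of planted pairs with their isolated-pair gas energies)
#' @export
makeToyComplex <- function(cfg = generatorConfig()) {
  set.seed(cfg$seed)
  planted <- cfg$planted
  if (nrow(planted) && any(planted$pos > cfg$nResidues))
    stop("generator error: planted position beyond chain length")
  rowsA <- list(); rowsB <- list()
  serial <- 0L
  for (pos in seq_len(cfg$nResidues)) {
    hit <- if (nrow(planted)) match(pos, planted$pos) else NA
    type <- if (!is.na(hit)) planted$type[hit] else "none"
    rnA <- .toy_resnames[[type]]
    rnB <- .toy_partner[[rnA]]
    # tip reaches chosen so the cross-tip distance hits the target:
    # planted tips are x-aligned (gap 8 => distance = 8 - reachA - reachB);
    # asymmetric reaches keep the chain-B tips clear of the groove walls.
    # Unplanted reaches follow an aperiodic height wave, with the ligand
    # heights complementary to the receptor's, so the native registration
    # is the unique shape-complementarity optimum (no lattice-shift
    # degeneracy along the chain).
    # ligand tips track the taller of their two receptor neighbours so the
    # native contact distance is uniform while any registration shift
    # clashes or loses contact
    wave <- function(p) 1.0 * cos(1.9 * p)
    reach <- switch(type,
                    "salt-bridge" = c(3.6, 1.6),  # tips 2.8 A apart
                    "hbond" = c(3.6, 1.5),        # H..acceptor 1.9 A
                    "vdw" = c(3.3, 1.2),          # tips 3.5 A apart
                    c(3.0 + wave(pos),
                      3.0 - max(wave(pos), wave(pos + 1))))
    x0 <- 6 * (pos - 1)
    tipX <- if (type == "none") NULL else x0
    jit <- rnorm(2, 0, 0.05)
    ra <- .toy_residue("A", pos, rnA, serial, +1, reach[1],
                       withH = (type == "hbond"), jitter = jit)
    serial <- max(ra$serial)
    rb <- .toy_residue("B", pos, rnB, serial, -1, reach[2], tipX = tipX,
                       jitter = rnorm(2, 0, 0.05))
    serial <- max(rb$serial)
    rowsA[[pos]] <- ra; rowsB[[pos]] <- rb
  }
  atoms <- rbind(do.call(rbind, rowsA), do.call(rbind, rowsB))
  atoms <- atoms[order(atoms$chain, atoms$serial), ]
  rownames(atoms) <- NULL
  # tip chemistry: polar/charged tips carry N/O elements so donor and
  # acceptor detection works on the toys
  tipel <- c(SBP = "N", SBN = "O", HBD = "N", HBA = "O")
  tips <- atoms$name == "CG" & atoms$resname %in% names(tipel)
  atoms$element[tips] <- tipel[atoms$resname[tips]]
  cplx <- new("PDBStructure", atoms = atoms)
  params <- toyParameterSet()
  truth <- NULL
  if (nrow(planted)) {
    truth <- planted
    truth$resA <- .toy_resnames[planted$type]
    truth$resB <- .toy_partner[truth$resA]
    truth$pairEnergy <- vapply(seq_len(nrow(planted)), function(i) {
      a <- selectAtoms(cplx, chains = "A",
                       resnumRange = rep(planted$pos[i], 2))
      b <- selectAtoms(cplx, chains = "B",
                       resnumRange = rep(planted$pos[i], 2))
      g <- gasEnergy(a, b, params)
      g$elec + g$vdw
    }, 1)
  }
  list(complex = cplx, params = params, truth = truth)
}

#' Generate a multi-run perturbation ensemble around a complex
#'
#' \code{runs} independent runs of \code{framesPerRun} frames of iid
#' per-atom Gaussian coordinate noise (sd \code{noiseSigma}) around the
#' input coordinates, each run seeded from the master seed.  Each planted
#' contact is explicitly controlled: in a fraction \code{occupancy} of
#' frames (decided per frame) the contact's atoms receive attenuated noise
#' so the interaction geometry holds; in the remainder the chain-B tip is
#' displaced outward so the contact is broken.  This keeps the realised
#' contact occupancy at the configured level up to binomial noise.
#'
#' @param toy output of \code{\link{makeToyComplex}} (or any list with
#'   \code{complex}); planted control uses \code{truth}
#' @param cfg a \code{\link{generatorConfig}}
#' @return an \code{Ensemble}
#' @export
makeEnsemble <- function(toy, cfg = generatorConfig()) {
  cplx <- toy$complex
  atoms <- cplx@atoms
  xyz0 <- coords(cplx)
  planted <- if (!is.null(toy$truth)) toy$truth else data.frame()
  runs <- vector("list", cfg$runs)
  for (r in seq_len(cfg$runs)) {
    set.seed(cfg$seed * 1000L + r)
    frames <- vector("list", cfg$framesPerRun)
    for (f in seq_len(cfg$framesPerRun)) {
      xyz <- xyz0 + matrix(rnorm(length(xyz0), 0, cfg$noiseSigma),
                           ncol = 3)
      if (nrow(planted)) for (i in seq_len(nrow(planted))) {
        pos <- planted$pos[i]
        sel <- which((atoms$chain %in% c("A", "B")) & atoms$resnum == pos &
                       atoms$name %in% c("CG", "HG"))
        if (runif(1) < cfg$occupancy) {
          # keep: attenuate noise on the interacting tips
          xyz[sel, ] <- xyz0[sel, ] +
            matrix(rnorm(3 * length(sel), 0, 0.02 * cfg$noiseSigma),
                   ncol = 3)
        } else {
          # break: push the B-side tip outward along +y, just past the
          # contact criteria so kept frames still dominate the means
          selB <- sel[atoms$chain[sel] == "B"]
          xyz[selB, 2] <- xyz[selB, 2] + 3.0
        }
      }
      frames[[f]] <- xyz
    }
    runs[[r]] <- frames
  }
  new("Ensemble", topology = cplx, runs = runs, intervalPs = cfg$intervalPs)
}

#' Generate labelled docking decoys with planted near-native poses
#'
#' Near-native poses perturb the native ligand placement by small random
#' rotations (<= 5 deg) and translations (<= \code{nativePerturb} A);
#' displaced decoys combine large translations (range \code{decoyTrans})
#' with arbitrary rotations.  Labels record whether the transformed-ligand
#' heavy-atom RMSD from native is below 4 A, together with the true RMSD.
#'
#' @param toy output of \code{\link{makeToyComplex}}
#' @param cfg a \code{\link{generatorConfig}}
#' @return list of \code{Pose}s with \code{provenance$label} (logical
#'   near-native) and \code{provenance$rmsd}
#' @export
makeDecoys <- function(toy, cfg = generatorConfig()) {
  set.seed(cfg$seed + 7L)
  lig <- selectAtoms(toy$complex, chains = "B")
  lxyz <- coords(lig)[isHeavy(lig), , drop = FALSE]
  cen <- colMeans(lxyz)
  mk <- function(R, t) {
    tr <- rigidTransform(R, cen - as.numeric(R %*% cen) + t)
    r <- rmsd(applyTransform(lxyz, tr), lxyz)
    new("Pose", transform = tr,
        provenance = list(label = r < 4, rmsd = r))
  }
  natives <- lapply(seq_len(cfg$nNative), function(i) {
    u <- .unit(rnorm(3))
    mk(rotationAbout(rnorm(3), runif(1, -5, 5)),
       u * runif(1, 0, cfg$nativePerturb))
  })
  decoys <- lapply(seq_len(cfg$nDecoys), function(i) {
    u <- .unit(rnorm(3))
    mk(rotationAbout(rnorm(3), runif(1, -180, 180)),
       u * runif(1, cfg$decoyTrans[1], cfg$decoyTrans[2]))
  })
  c(natives, decoys)
}
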