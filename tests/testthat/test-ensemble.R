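static_ens <- function(xyzA, xyzB, nFrames = 2L, nRuns = 2L,
                       frames = NULL) {
  topo <- point_structure(rbind(xyzA, xyzB),
                          chain = c(rep("A", nrow(xyzA)), rep("B", nrow(xyzB))),
                          resnum = c(seq_len(nrow(xyzA)), seq_len(nrow(xyzB))))
  if (is.null(frames))
    frames <- replicate(nFrames, coords(topo), simplify = FALSE)
  ensemble(topo, replicate(nRuns, frames, simplify = FALSE))
}

test_that("interface residues use the mean of per-frame minimum distances", {
  # static pair at 4.0 A -> included
  e1 <- static_ens(matrix(c(0, 0, 0), 1, 3), matrix(c(4, 0, 0), 1, 3))
  ir <- interfaceResidues(e1, "A", "B")
  expect_equal(nrow(ir$pairs), 1L)
  expect_equal(ir$pairs$meanMinDist, 4)
  # frames at 4.0 and 6.2 A -> mean 5.1 -> excluded
  topo <- point_structure(rbind(c(0, 0, 0), c(4, 0, 0)),
                          chain = c("A", "B"), resnum = c(1, 1))
  f1 <- coords(topo); f2 <- f1; f2[2, 1] <- 6.2
  e2 <- ensemble(topo, list(list(f1, f2)))
  ir2 <- interfaceResidues(e2, "A", "B")
  expect_equal(nrow(ir2$pairs), 0L)
  # with an infinite cutoff every cross-part residue appears
  ir3 <- interfaceResidues(e2, "A", "B", cutoff = Inf)
  expect_equal(nrow(ir3$pairs), 1L)
})

test_that("ensemble statistics match the brute-force per-frame oracle", {
  cfg <- generatorConfig(seed = 6, framesPerRun = 12)
  toy <- makeToyComplex(cfg)
  ens <- makeEnsemble(toy, cfg)
  at <- atoms(toy$complex)
  selA <- which(at$chain == "A" & at$element != "H")
  selB <- which(at$chain == "B" & at$element != "H")
  acc <- NULL; n <- 0
  for (run in ens@runs) for (f in run) {
    D <- oracle_pair_min_dist(f, at, selA, selB)
    acc <- if (is.null(acc)) D else acc + D
    n <- n + 1
  }
  meanD <- acc / n
  ir <- interfaceResidues(ens, "A", "B")
  expect_equal(nrow(ir$pairs), sum(meanD <= 5))
  expect_equal(sort(ir$pairs$meanMinDist), sort(meanD[meanD <= 5]),
               tolerance = 1e-9)
  # vdW contacts against the counting oracle
  occ <- array(0, c(nrow(meanD), ncol(meanD), length(ens@runs)))
  for (r in seq_along(ens@runs)) {
    for (f in ens@runs[[r]])
      occ[, , r] <- occ[, , r] + (oracle_pair_min_dist(f, at, selA, selB) <= 4)
    occ[, , r] <- occ[, , r] / length(ens@runs[[r]])
  }
  nOK <- apply(occ >= 0.5, c(1, 2), sum)
  vc <- vdwContacts(ens, "A", "B")
  expect_equal(nrow(vc), sum(nOK >= 2))
})

test_that("planted contacts are detected near their configured occupancy", {
  cfg <- generatorConfig(seed = 9, framesPerRun = 40, occupancy = 0.85)
  toy <- makeToyComplex(cfg)
  ens <- makeEnsemble(toy, cfg)
  vc <- vdwContacts(ens, "A", "B", minFraction = 0.5, minRuns = 2)
  # the planted pairs appear with per-run occupancy near 0.85
  for (pos in toy$truth$pos) {
    row <- vc[grepl(paste0("^A:", pos, ":"), vc$resA) &
                grepl(paste0("^B:", pos, ":"), vc$resB), ]
    expect_equal(nrow(row), 1L)
    occ <- as.numeric(row[grep("occ.run", names(row))])
    expect_lt(abs(mean(occ) - 0.85), 0.10)
  }
})

test_that("hydrogen bonds follow the mean 2.4-A / 130-degree definition", {
  # ideal linear bond: D at 0, H at 1.0, A at 2.9 -> H..A 1.9, angle 180
  topo <- readPDB(c(pdb_line(1, "N", "XXD", "A", 1, 0, 0, 0, "N"),
                    pdb_line(2, "H", "XXD", "A", 1, 1.0, 0, 0, "H"),
                    pdb_line(3, "O", "XXA", "B", 1, 2.9, 0, 0, "O")))
  e <- ensemble(topo, list(list(coords(topo)), list(coords(topo))))
  hb <- hydrogenBonds(e, "A", "B")
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$meanDist, 1.9, tolerance = 1e-9)
  expect_equal(hb$meanAngle, 180, tolerance = 1e-6)
  expect_true(all(hb[grep("occ", names(hb))] == 1))
  # bent geometry with mean angle 129 -> excluded
  bend <- coords(topo)
  th <- 129 * pi / 180
  bend[3, ] <- c(1.0 + 1.9 * cos(pi - th), 1.9 * sin(pi - th), 0)
  eb <- ensemble(topo, list(list(bend)))
  expect_equal(nrow(hydrogenBonds(eb, "A", "B")), 0L)
  # no hydrogens -> advisory error
  noH <- point_structure(rbind(c(0, 0, 0), c(3, 0, 0)), chain = c("A", "B"),
                         resnum = c(1, 1))
  expect_error(hydrogenBonds(ensemble(noH, list(list(coords(noH)))), "A", "B"),
               "addHydrogens")
  # ten-frame constructed ensemble matches per-frame brute force averaging
  set.seed(13)
  frames <- lapply(1:10, function(i)
    coords(topo) + matrix(rnorm(9, 0, 0.08), 3, 3))
  e10 <- ensemble(topo, list(frames))
  hb10 <- hydrogenBonds(e10, "A", "B")
  dists <- vapply(frames, function(f) sqrt(sum((f[2, ] - f[3, ])^2)), 1)
  expect_equal(hb10$meanDist, mean(dists), tolerance = 1e-9)
})

test_that("every hydrogen-bond pair lies inside the 5-A interface set", {
  cfg <- generatorConfig(seed = 12, framesPerRun = 15)
  toy <- makeToyComplex(cfg)
  ens <- makeEnsemble(toy, cfg)
  hb <- hydrogenBonds(ens, "A", "B")
  ir <- interfaceResidues(ens, "A", "B")
  expect_gt(nrow(hb), 0L)
  expect_true(all(hb$donor %in% ir$residues$key))
  expect_true(all(hb$acceptor %in% ir$residues$key))
})

test_that("vdW contacts require replication across independent runs", {
  topo <- point_structure(rbind(c(0, 0, 0), c(3.5, 0, 0)),
                          chain = c("A", "B"), resnum = c(1, 1))
  near <- coords(topo)
  far <- near; far[2, 1] <- 9
  mixed <- c(replicate(6, near, simplify = FALSE),
             replicate(4, far, simplify = FALSE))  # 60% occupancy
  alloff <- replicate(10, far, simplify = FALSE)
  # within 4 A in 60% of frames of runs 1 and 2 only -> reported
  e <- ensemble(topo, list(mixed, mixed, alloff, alloff))
  vc <- vdwContacts(e, "A", "B")
  expect_equal(nrow(vc), 1L)
  expect_equal(vc$nRunsSatisfied, 2L)
  # in run 1 only -> excluded
  e1 <- ensemble(topo, list(mixed, alloff, alloff, alloff))
  expect_equal(nrow(vdwContacts(e1, "A", "B")), 0L)
  expect_error(vdwContacts(ensemble(topo, list(mixed)), "A", "B"),
               "fewer runs")
})

test_that("occupancy statistics are invariant to run and frame order", {
  cfg <- generatorConfig(seed = 17, framesPerRun = 10)
  toy <- makeToyComplex(cfg)
  ens <- makeEnsemble(toy, cfg)
  perm <- ens
  perm@runs <- rev(lapply(ens@runs, rev))
  ir1 <- interfaceResidues(ens, "A", "B")
  ir2 <- interfaceResidues(perm, "A", "B")
  expect_equal(ir1$pairs$meanMinDist, ir2$pairs$meanMinDist, tolerance = 1e-12)
  v1 <- vdwContacts(ens, "A", "B"); v2 <- vdwContacts(perm, "A", "B")
  expect_setequal(paste(v1$resA, v1$resB), paste(v2$resA, v2$resB))
})

test_that("equilibration is flagged by the final-window slope", {
  cfg <- generatorConfig(seed = 3, framesPerRun = 30)
  toy <- makeToyComplex(cfg)
  ref <- toy$complex
  nat <- nAtoms(ref)
  # identical frames: zero series, plateau
  still <- ensemble(ref, list(replicate(30, coords(ref), simplify = FALSE)))
  eq <- equilibrationCheck(still, ref, "A", "B")
  expect_true(all(abs(eq$series[[1]]) < 1e-12))
  expect_true(all(eq$plateau))
  # linear drift: no plateau
  drift <- ensemble(ref, list(lapply(1:30, function(i)
    coords(ref) + i * 0.05)))
  eqd <- equilibrationCheck(drift, ref, "A", "B")
  expect_false(any(eqd$plateau))
  # plateaued noisy series (frames 50 ps apart so the window spans ~0.5 ns)
  set.seed(2)
  noisy <- ensemble(ref, list(lapply(1:30, function(i)
    coords(ref) + matrix(rnorm(3 * nat, 0, 0.02), nat, 3))),
    intervalPs = 50)
  eqn <- equilibrationCheck(noisy, ref, "A", "B")
  expect_true(all(eqn$plateau))
})

test_that("plain-text trajectories and manifests round-trip", {
  cfg <- generatorConfig(seed = 2, framesPerRun = 3, runs = 2)
  toy <- makeToyComplex(cfg)
  ens <- makeEnsemble(toy, cfg)
  dir <- tempfile(); dir.create(dir)
  writePDB(toy$complex, file.path(dir, "topo.pdb"))
  for (r in 1:2) {
    con <- file(file.path(dir, sprintf("run%d.xyz", r)), "w")
    for (f in ens@runs[[r]])
      write(t(f), con, ncolumns = 3)
    close(con)
  }
  writeLines(c("topology: topo.pdb", "interval_ps: 0.5",
               "runs:", "  - run1.xyz", "  - run2.xyz"),
             file.path(dir, "manifest.yaml"))
  ens2 <- readEnsembleManifest(file.path(dir, "manifest.yaml"))
  expect_length(ens2@runs, 2L)
  expect_equal(ens2@runs[[1]][[2]], ens@runs[[1]][[2]], tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
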