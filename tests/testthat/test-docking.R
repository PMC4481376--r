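test_that("occupancy maps peak at atoms and scale with atom count", {
  one <- point_structure(matrix(c(0, 0, 0), 1, 3))
  m <- buildMap(one, spacing = 1, sigma = 1)
  peak <- which(m@values == max(m@values), arr.ind = TRUE)[1, ]
  node <- m@origin + (peak - 1) * m@spacing
  expect_lt(sqrt(sum(node^2)), 1)   # peak at the atom within one node
  # subset = NULL vs explicit full selection: identical maps
  toy <- makeToyComplex(generatorConfig(seed = 2))
  rec <- selectAtoms(toy$complex, "A")
  m1 <- buildMap(rec, spacing = 2)
  m2 <- buildMap(rec, spacing = 2, subset = seq_len(nAtoms(rec)))
  expect_equal(m1@values, m2@values, tolerance = 1e-12)
  # integrated mass proportional to contributing atom count
  two <- point_structure(rbind(c(0, 0, 0), c(40, 0, 0)), resnum = c(1, 2))
  mm <- buildMap(two, spacing = 1, sigma = 1)
  expect_equal(sum(mm@values) / sum(m@values), 2, tolerance = 0.01)
  expect_error(buildMap(rec, subset = integer(0)), "empty")
})

test_that("start-pose enumeration counts match the brute-force cone test", {
  lig <- point_structure(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
                         resnum = 1:3)
  grid13 <- new("GridMap", origin = c(0, 0, 0), spacing = 2,
                values = array(1, c(13, 13, 13)), subset = "synthetic")
  # 180-degree cone: every stride-6 point admissible -> 3^3 x 6 = 162
  spec <- searchSpec(stride = 6, rotationsPerPoint = 6, coneHalfAngle = 180,
                     receptorCenter = c(12, 12, 12),
                     constraintCenter = c(12, 12, 24))
  expect_length(enumerateStartPoses(grid13, lig, spec), 162L)
  # restricted cones equal an exhaustive membership count
  for (ang in c(30, 60, 90)) {
    sp <- searchSpec(6, 6, ang, c(12, 12, 12), c(12, 12, 24))
    got <- length(enumerateStartPoses(grid13, lig, sp))
    pts <- as.matrix(expand.grid(c(0, 12, 24), c(0, 12, 24), c(0, 12, 24)))
    n_adm <- 0
    for (i in seq_len(nrow(pts))) {
      d <- pts[i, ] - c(12, 12, 12)
      nrmv <- sqrt(sum(d^2))
      a <- if (nrmv < 1e-9) 0 else acos(min(1, d[3] / nrmv)) * 180 / pi
      if (a <= ang + 1e-9) n_adm <- n_adm + 1
    }
    expect_equal(got, n_adm * 6L)
  }
  # degenerate zero-width cone pointing between grid points -> error
  sp0 <- searchSpec(6, 6, 1e-6, c(11, 11, 11), c(11, 11, 24))
  expect_error(enumerateStartPoses(grid13, lig, sp0), "search error")
})

test_that("grid threading is deterministic, monotone, and recovers displaced poses", {
  toy <- makeToyComplex(generatorConfig(seed = 1))
  rec <- selectAtoms(toy$complex, "A"); lig <- selectAtoms(toy$complex, "B")
  maps <- receptorMaps(rec)
  p0 <- new("Pose", transform = rigidTransform(diag(3), c(0, 5, 0)))
  a1 <- gridThreadingMC(p0, maps, lig, cycles = 5, stepsPerCycle = 5, seed = 7)
  a2 <- gridThreadingMC(p0, maps, lig, cycles = 5, stepsPerCycle = 5, seed = 7)
  expect_identical(a1@transform@rotation, a2@transform@rotation)
  expect_identical(a1@transform@translation, a2@transform@translation)
  expect_identical(a1@mapScore, a2@mapScore)
  # best-so-far contract: returned score never worse than the start score
  lx <- coords(lig)[isHeavy(lig), ]
  expect_lte(a1@mapScore, mapScore(maps, applyTransform(lx, p0@transform)))
  # longer schedules never yield a worse best score (same seed)
  a3 <- gridThreadingMC(p0, maps, lig, cycles = 20, stepsPerCycle = 5, seed = 7)
  expect_lte(a3@mapScore, a1@mapScore)
})

test_that("threading pulls a 5-A displaced pose back toward the native basin", {
  ok <- 0L
  for (s in 1:20) {
    toy <- makeToyComplex(generatorConfig(seed = s))
    rec <- selectAtoms(toy$complex, "A"); lig <- selectAtoms(toy$complex, "B")
    maps <- receptorMaps(rec)
    lx <- coords(lig)[isHeavy(lig), ]
    p0 <- new("Pose", transform = rigidTransform(diag(3), c(0, 5, 0)))
    pt <- gridThreadingMC(p0, maps, lig, cycles = 30, stepsPerCycle = 15,
                          seed = s)
    if (rmsd(applyTransform(lx, pt@transform), lx) < 5) ok <- ok + 1L
  }
  expect_gte(ok, 18L)  # >= 90% of 20 seeds
})

test_that("all-atom MC refinement honours its move contract", {
  toy <- makeToyComplex(generatorConfig(seed = 3))
  rec <- selectAtoms(toy$complex, "A"); lig <- selectAtoms(toy$complex, "B")
  p0 <- new("Pose", transform = rigidTransform(diag(3), c(0, 0.5, 0)))
  # zero proposal magnitudes leave the pose unchanged
  frozen <- mcRefine(p0, rec, lig, toy$params, nSteps = 50, maxTrans = 0,
                     maxTorsion = 0, seed = 1, minimize = FALSE)
  expect_equal(frozen@transform@translation, p0@transform@translation,
               tolerance = 1e-12)
  # 2:1 torsion:translation attempt ratio within a binomial interval
  r <- mcRefine(p0, rec, lig, toy$params, nSteps = 1200, seed = 2,
                minimize = FALSE)
  frac <- r@provenance$moveCounts["torsion"] / 1200
  expect_lt(abs(frac - 2 / 3), 4 * sqrt(2 / 9 / 1200))
  # refinement energy is never worse than the starting energy
  e0 <- mcRefine(p0, rec, lig, toy$params, nSteps = 1, maxTrans = 0,
                 maxTorsion = 0, seed = 1, minimize = FALSE)@energy
  expect_lte(r@energy, e0 + 1e-9)
  # no interface -> refinement error
  pfar <- new("Pose", transform = rigidTransform(diag(3), c(0, 50, 0)))
  expect_error(mcRefine(pfar, rec, lig, toy$params, nSteps = 10, seed = 1),
               "refinement error")
})

test_that("pose features are reproducible and respond to contact geometry", {
  toy <- makeToyComplex(generatorConfig(seed = 4))
  rec <- selectAtoms(toy$complex, "A"); lig <- selectAtoms(toy$complex, "B")
  native <- new("Pose", transform = rigidTransform())
  f1 <- scoreFeatures(native, rec, lig, toy$params)
  f2 <- scoreFeatures(native, rec, lig, toy$params)
  expect_identical(f1@features, f2@features)
  expect_true(all(is.finite(f1@features)))
  # non-contacting pose: near-zero vdW and buried area
  far <- new("Pose", transform = rigidTransform(diag(3), c(0, 60, 0)))
  ff <- scoreFeatures(far, rec, lig, toy$params)@features
  expect_lt(abs(ff["vdw"]), 0.01)
  expect_lt(abs(ff["buriedSASA"]), 1)
  # clashed pose: large positive vdW
  clash <- new("Pose", transform = rigidTransform(diag(3), c(0, -7.2, 0)))
  expect_gt(scoreFeatures(clash, rec, lig, toy$params)@features["vdw"], 100)
})

test_that("the ranker separates planted near-natives and breaks ties stably", {
  set.seed(5)
  # separable synthetic features: near-natives have low vdW + elec
  n <- 40
  lab <- rep(c(TRUE, FALSE), c(10, 30))
  f <- cbind(vdw = ifelse(lab, rnorm(n, -20, 2), rnorm(n, 0, 2)),
             elec = ifelse(lab, rnorm(n, -100, 10), rnorm(n, -5, 10)),
             solvElec = rnorm(n), solvNonel = rnorm(n),
             buriedSASA = ifelse(lab, rnorm(n, 800, 50), rnorm(n, 50, 50)))
  rk <- trainRanker(f, lab)
  poses <- lapply(seq_len(n), function(i) {
    p <- new("Pose", transform = rigidTransform())
    p@features <- f[i, ]
    p
  })
  ranked <- rankPoses(poses, rk, k = 10)
  # planted positives dominate the top ten
  top_idx <- vapply(ranked, function(p) which(vapply(poses, function(q)
    identical(q@features, p@features), TRUE))[1], 1L)
  expect_gte(sum(lab[top_idx]), 8)
  # identical features preserve input order; k > n returns everything
  same <- lapply(1:4, function(i) {
    p <- new("Pose", transform = rigidTransform())
    p@features <- c(vdw = -1, elec = -1, solvElec = 0, solvNonel = 0,
                    buriedSASA = 100)
    p@provenance <- list(id = i)
    p
  })
  rs <- rankPoses(same, rk, k = 10)
  expect_length(rs, 4L)
  expect_equal(vapply(rs, function(p) p@provenance$id, 1L), 1:4)
  expect_error(rankPoses(poses, NULL), "ranking error")
})

test_that("the full docking pipeline recovers planted natives in the top ten", {
  hits <- 0L
  for (s in 1:10) {
    toy <- makeToyComplex(generatorConfig(seed = s))
    rec <- selectAtoms(toy$complex, "A"); lig <- selectAtoms(toy$complex, "B")
    dec <- makeDecoys(toy, generatorConfig(seed = s))
    dec <- lapply(dec, scoreFeatures, receptor = rec, ligand = lig,
                  params = toy$params)
    f <- do.call(rbind, lapply(dec, function(p) p@features))
    lab <- vapply(dec, function(p) p@provenance$label, TRUE)
    rk <- trainRanker(f, lab)
    epi <- residueKeys(rec)[toy$truth$pos]
    top <- dockComplex(rec, lig, toy$params, epi, rk, seed = s)
    lx <- coords(lig)[isHeavy(lig), ]
    rms <- vapply(top[seq_len(min(10, length(top)))], function(p)
      rmsd(applyTransform(lx, p@transform), lx), 1)
    if (min(rms) < 4) hits <- hits + 1L
  }
  expect_gte(hits, 8L)
})
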