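test_that("the gas-phase electrostatic series matches a per-frame oracle", {
  cfg <- small_toy_cfg(seed = 4, frames = 5L)
  toy <- makeToyComplex(cfg)
  ens <- makeEnsemble(toy, cfg)
  series <- gasElecSeries(ens, "A", "B", toy$params)
  expect_length(series, 4L)
  # frame-by-frame oracle via coulombEnergy on cut parts
  p <- attachParameters(ens@topology, toy$params)
  at <- atoms(ens@topology)
  ia <- which(at$chain == "A"); ib <- which(at$chain == "B")
  for (r in 1:2) for (f in 1:3) {
    fr <- ens@runs[[r]][[f]]
    e <- coulombEnergy(fr[ia, ], p$charge[ia], fr[ib, ], p$charge[ib],
                       cutoff = 14)
    expect_equal(series[[r]][f], e, tolerance = 1e-9)
  }
  # uncharged toy: all zeros
  cfg0 <- generatorConfig(seed = 4, nResidues = 3,
                          planted = data.frame(pos = integer(0),
                                               type = character(0)),
                          framesPerRun = 3L)
  toy0 <- makeToyComplex(cfg0)
  ens0 <- makeEnsemble(toy0, cfg0)
  expect_true(all(unlist(gasElecSeries(ens0, "A", "B", toy0$params)) == 0))
  # static ensemble: constant series
  st <- ensemble(toy$complex, list(replicate(4, coords(toy$complex),
                                             simplify = FALSE)))
  expect_equal(diff(range(gasElecSeries(st, "A", "B", toy$params)[[1]])), 0)
})

test_that("equal-width clustering reproduces the brute-force binning", {
  # all-equal series: one occupied bin with weight 1
  cl0 <- clusterFrames(rep(-3.2, 7), k = 25)
  expect_equal(cl0@weights, 1)
  expect_equal(cl0@representatives, 1L)
  # integers 0..24, k = 25: one frame per bin, each its own representative
  cl1 <- clusterFrames(0:24, k = 25)
  expect_equal(length(cl1@weights), 25L)
  expect_equal(cl1@representatives, 1:25)
  expect_equal(cl1@weights, rep(1 / 25, 25))
  # random series against a brute-force oracle
  set.seed(8)
  x <- rnorm(200, -50, 12)
  k <- 25
  cl <- clusterFrames(x, k)
  edges <- seq(min(x), max(x), length.out = k + 1)
  bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), k)
  for (bi in seq_along(cl@representatives)) {
    b <- sort(unique(bin))[bi]
    members <- which(bin == b)
    mu <- mean(x[members])
    expect_equal(cl@representatives[bi],
                 members[which.min(abs(x[members] - mu))])
    expect_equal(cl@weights[bi], length(members) / 200)
  }
  expect_equal(sum(cl@weights), 1, tolerance = 1e-12)
  expect_error(clusterFrames(x, 0), "k must be")
})

test_that("frame energies satisfy the thermodynamic-cycle identity exactly", {
  cfg <- small_toy_cfg(seed = 2)
  toy <- makeToyComplex(cfg)
  fe <- frameEnergy(toy$complex, "A", "B", toy$params, test_pb())
  expect_identical(dGsln(fe), dGgas(fe) + dGsolv(fe))
  expect_identical(dGgas(fe), fe@vdw + fe@elecGas)
  expect_identical(dGsolv(fe), fe@solvElec + fe@solvNonel)
  # hand-assembled components give the same total
  a <- selectAtoms(toy$complex, "A"); b <- selectAtoms(toy$complex, "B")
  g <- gasEnergy(a, b, toy$params, cutoff = 999, switchOn = 998,
                 switchOff = 999)
  expect_equal(fe@elecGas, g$elec, tolerance = 1e-9)
  expect_equal(fe@vdw, g$vdw, tolerance = 1e-9)
  # far-separated uncharged parts: every difference term near zero
  cfg0 <- generatorConfig(seed = 2, nResidues = 3,
                          planted = data.frame(pos = integer(0),
                                               type = character(0)))
  sep <- makeToyComplex(cfg0)$complex
  xyz <- coords(sep)
  bidx <- atoms(sep)$chain == "B"
  xyz[bidx, 2] <- xyz[bidx, 2] + 40
  coords(sep) <- xyz
  cfgb <- pbConfig(dime = 65L, spacings = c(2.0, 1.0))
  feSep <- frameEnergy(sep, "A", "B", toy$params, cfgb)
  expect_lt(abs(feSep@vdw), 0.01)
  expect_identical(feSep@elecGas, 0)
  expect_identical(feSep@solvElec, 0)
  expect_lt(abs(feSep@solvNonel), 0.05)
})

test_that("cluster-weighted averaging follows the population arithmetic", {
  # two clusters sized {3,1} with dG {-10,-2} -> run value -8
  w <- list(c(3, 1) / 4)
  v <- list(c(-10, -2))
  expect_equal(weightedBindingEnergy(w, v)$perRun, -8)
  # four identical runs -> sd 0
  r4 <- weightedBindingEnergy(rep(w, 4), rep(v, 4))
  expect_equal(r4$mean, -8)
  expect_equal(r4$sd, 0)
  # random fixture equals the direct sum
  set.seed(10)
  ww <- lapply(1:3, function(i) { x <- runif(5); x / sum(x) })
  vv <- lapply(1:3, function(i) rnorm(5, -10, 3))
  got <- weightedBindingEnergy(ww, vv)
  direct <- vapply(1:3, function(i) sum(ww[[i]] * vv[[i]]), 1)
  expect_equal(got$perRun, direct, tolerance = 1e-12)
  expect_equal(got$mean, mean(direct))
  expect_equal(got$sd, sd(direct))
  expect_error(weightedBindingEnergy(list(c(0, 0)), list(c(1, 2))),
               "zero total")
})

test_that("per-residue decomposition sums to the weighted binding energy", {
  cfg <- small_toy_cfg(seed = 1, frames = 6L)
  toy <- makeToyComplex(cfg)
  ens <- makeEnsemble(toy, cfg)
  pb <- test_pb()
  be <- mmpbsaBindingEnergy(ens, "A", "B", toy$params, pb, k = 3)
  pr <- perResidueDecomposition(ens, "A", "B", toy$params, pb, k = 3)
  expect_equal(sum(pr$dG), be$mean, tolerance = 0.5)
  expect_true(all(pr$sd >= 0))
  # component columns sum to the residue total
  expect_equal(pr$dG, pr$vdw + pr$elec + pr$pb + pr$np, tolerance = 1e-9)
  # residues far from the interface contribute little
  far <- pr[grepl("NEU", pr$key), ]
  expect_true(all(abs(far$dG) < 2))
  # the planted salt-bridge partner is the strongest contributor
  expect_match(pr$key[which.min(pr$dG)], "SB")
})

test_that("epitope region sums are additive with quadrature errors", {
  pr <- data.frame(key = c("A:1", "A:2", "A:3"),
                   dG = c(-1, -2, -0.5), sd = c(0.3, 0.4, 0))
  expect_equal(epitopeRegionSum(pr, character(0)), list(dG = 0, sd = 0))
  all3 <- epitopeRegionSum(pr, pr$key)
  expect_equal(all3$dG, -3.5)
  expect_equal(all3$sd, sqrt(0.09 + 0.16))
  # split regions sum to the full region value
  s1 <- epitopeRegionSum(pr, "A:1")
  s2 <- epitopeRegionSum(pr, c("A:2", "A:3"))
  expect_equal(s1$dG + s2$dG, all3$dG)
  expect_error(epitopeRegionSum(pr, "A:9"), "unknown residue")
})
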