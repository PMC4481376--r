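test_that("contact lists apply the 5-A boundary exactly and are symmetric", {
  a <- point_structure(matrix(c(0, 0, 0), 1, 3))
  near <- point_structure(matrix(c(4.9, 0, 0), 1, 3), chain = "B")
  far <- point_structure(matrix(c(5.1, 0, 0), 1, 3), chain = "B")
  expect_equal(nrow(contactList(a, near)), 1L)
  expect_equal(nrow(contactList(a, far)), 0L)
  # separated parts
  expect_equal(nrow(contactList(a, point_structure(matrix(c(25, 0, 0), 1, 3),
                                                   chain = "B"))), 0L)
  # symmetry and cutoff monotonicity on a toy complex
  toy <- makeToyComplex(generatorConfig(seed = 5))
  pa <- selectAtoms(toy$complex, "A"); pb <- selectAtoms(toy$complex, "B")
  ab <- contactList(pa, pb)
  ba <- contactList(pb, pa)
  expect_setequal(paste(ab$resA, ab$resB), paste(ba$resB, ba$resA))
  small <- contactList(pa, pb, cutoff = 4)
  expect_true(all(paste(small$resA, small$resB) %in%
                    paste(ab$resA, ab$resB)))
  # matches a brute-force O(N^2) scan
  atomsAll <- atoms(toy$complex)
  D <- oracle_pair_min_dist(coords(toy$complex), atomsAll,
                            which(atomsAll$chain == "A" & atomsAll$element != "H"),
                            which(atomsAll$chain == "B" & atomsAll$element != "H"))
  expect_equal(nrow(ab), sum(D <= 5))
})

test_that("second-copy construction reproduces exact symmetry", {
  # a C2-symmetric receptor: two identical domains related by 180 deg about z
  d1 <- cbind(c(2, 4, 3, 5), c(1, 1.5, 3, 2.5), c(0, 0.5, 1, -0.5))
  R <- rotationAbout(c(0, 0, 1), 180)
  d2 <- t(R %*% t(d1))
  lig <- cbind(c(2.5, 4.5, 3.5), c(4, 4.5, 6), c(0, 0.3, 0.6))
  x <- point_structure(rbind(d1, d2, lig),
                       chain = c(rep("A", 4), rep("B", 4), rep("L", 3)),
                       resnum = c(1:4, 1:4, 1:3))
  out <- buildSecondCopy(x, ligandChains = "L",
                         domainA = list(chains = "A"),
                         domainB = list(chains = "B"))
  # the transform equals the C2 operation
  expect_equal(out$transform@rotation, R, tolerance = 1e-6)
  expect_equal(coords(out$copy), t(R %*% t(lig)), tolerance = 1e-6)
  expect_equal(nAtoms(out$assembly), nAtoms(x) + 3L)
  # degenerate case: domain B = domain A puts the copy on top of the original
  same <- buildSecondCopy(x, "L", list(chains = "A"), list(chains = "A"))
  expect_equal(coords(same$copy), lig, tolerance = 1e-9)
  expect_gt(nrow(clashAtoms(same$copy, selectAtoms(x, chains = "L"), 0.1)), 0L)
  # transform equals a direct superpose() of the matched domains
  sup <- superpose(d1, d2)
  expect_equal(out$transform@rotation, sup$transform@rotation,
               tolerance = 1e-9)
})

test_that("pose checking evaluates each constraint and accepts iff none violated", {
  toy <- makeToyComplex(generatorConfig(seed = 1))
  antigen <- selectAtoms(toy$complex, "A")
  lig <- selectAtoms(toy$complex, "B")
  keys <- residueKeys(antigen)
  # constraints the native pose satisfies (buried-area window from the toy)
  buried <- sasaChangeOnBinding(toy$complex, antigen, lig)
  cs <- constraintSet(requiredContacts = keys[toy$truth$pos],
                      buriedAreaWindow = c(buried - 100, buried + 100))
  rep1 <- checkPose(antigen, lig, cs)
  expect_true(rep1$accepted)
  expect_length(rep1$violated, 0L)
  # a shifted ligand violates the contact requirement
  ligFar <- lig; coords(ligFar) <- coords(lig) + matrix(rep(c(0, 30, 0),
    each = nAtoms(lig)), ncol = 3)
  rep2 <- checkPose(antigen, ligFar, cs)
  expect_false(rep2$accepted)
  expect_true("required-contacts" %in% rep2$violated)
  # stoichiometry: overlapping second copy violates only that constraint
  cs3 <- constraintSet(requiredContacts = keys[toy$truth$pos],
                       stoichiometry = TRUE,
                       buriedAreaWindow = c(buried - 100, buried + 100))
  rep3 <- checkPose(antigen, lig, cs3, secondCopy = lig)
  expect_false(rep3$accepted)
  expect_identical(rep3$violated, "stoichiometry")
  # vacuous constraint set accepts anything
  rep4 <- checkPose(antigen, ligFar,
                    constraintSet(buriedAreaWindow = c(-Inf, Inf)))
  expect_true(rep4$accepted)
  expect_true(rep1$accepted == (length(rep1$violated) == 0L))
})

test_that("screening returns the satisfying cluster or an explicit no-model result", {
  toy <- makeToyComplex(generatorConfig(seed = 2))
  antigen <- selectAtoms(toy$complex, "A")
  lig <- selectAtoms(toy$complex, "B")
  keys <- residueKeys(antigen)
  buried <- sasaChangeOnBinding(toy$complex, antigen, lig)
  cs <- constraintSet(requiredContacts = keys[toy$truth$pos],
                      buriedAreaWindow = c(buried - 150, buried + 150))
  # nine poses: eight displaced clusters, one near-native planted pose
  mkpose <- function(t, rank) {
    p <- new("Pose", transform = rigidTransform(diag(3), t))
    p@rank <- rank
    p
  }
  displaced <- lapply(1:8, function(i)
    mkpose(c(10 * i, 18 + 2 * i, 0), rank = i))
  planted <- mkpose(c(0, 0.2, 0), rank = 9L)
  res <- screenRanked(c(displaced, list(planted)), antigen, lig, cs)
  expect_false(res$noModel)
  expect_equal(res$best@rank, 9L)
  # every pose violating -> explicit no-model, not an error
  res2 <- screenRanked(displaced, antigen, lig, cs)
  expect_true(res2$noModel)
  expect_null(res2$best)
  # a single satisfying pose is returned directly
  res3 <- screenRanked(list(planted), antigen, lig, cs)
  expect_equal(res3$best@rank, 9L)
  # determinism
  resR <- screenRanked(c(displaced, list(planted)), antigen, lig, cs)
  expect_equal(resR$report, res$report)
})

test_that("superposition clash testing equals manual transform-then-scan", {
  set.seed(21)
  base <- matrix(rnorm(18, sd = 4), 6, 3)
  probe <- sweep(matrix(rnorm(9, sd = 1), 3, 3), 2, c(8, 0, 0), `+`)
  model <- point_structure(rbind(base, probe),
                           chain = c(rep("A", 6), rep("P", 3)),
                           resnum = c(1:6, 1:3))
  tr <- rigidTransform(rotationAbout(c(0, 1, 0), 40), c(3, -2, 1))
  refBase <- applyTransform(base, tr)
  refProbe <- sweep(matrix(rnorm(9, sd = 1), 3, 3), 2, c(8, 0, 0) + 1, `+`)
  refProbe <- applyTransform(refProbe, tr)
  reference <- point_structure(rbind(refBase, refProbe),
                               chain = c(rep("A", 6), rep("Q", 3)),
                               resnum = c(1:6, 1:3))
  got <- superpositionClashTest(model, reference,
                                alignModel = list(chains = "A"),
                                alignReference = list(chains = "A"),
                                probeModel = list(chains = "P"),
                                probeReference = list(chains = "Q"),
                                threshold = 2.5)
  # manual: transform the model by the alignment, then scan
  sup <- superpose(base, refBase)
  moved <- applyTransform(probe, sup$transform)
  manual <- 0L
  for (i in 1:3) for (j in 1:3)
    if (sqrt(sum((moved[i, ] - refProbe[j, ])^2)) <= 2.5)
      manual <- manual + 1L
  expect_equal(nrow(got), manual)
  # compatible parts under self-superposition: no clashes
  self <- superpositionClashTest(model, model, list(chains = "A"),
                                 list(chains = "A"), list(chains = "P"),
                                 list(chains = "A"), threshold = 0.5)
  expect_equal(nrow(self), 0L)
})
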