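test_that("PDB parsing preserves Kabat-style gaps and insertion codes", {
  # numbering gap: residues 408 and 410 with no 409
  s <- readPDB(c(pdb_line(1, "CA", "SER", "A", 408, 0, 0, 0, "C"),
                 pdb_line(2, "CA", "ALA", "A", 410, 3.8, 0, 0, "C")))
  expect_equal(length(residueKeys(s)), 2L)
  expect_equal(atoms(s)$resnum, c(408L, 410L))

  # insertion codes 27A, 27C, 27D are three distinct residues
  s2 <- readPDB(c(pdb_line(1, "CA", "ASP", "L", 27, 0, 0, 0, "C", icode = "A"),
                  pdb_line(2, "CA", "ASP", "L", 27, 3.8, 0, 0, "C", icode = "C"),
                  pdb_line(3, "CA", "TYR", "L", 27, 7.6, 0, 0, "C", icode = "D")))
  expect_equal(length(residueKeys(s2)), 3L)

  # single atom
  s3 <- readPDB(pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0, "N"))
  expect_equal(nAtoms(s3), 1L)
  expect_equal(length(residueKeys(s3)), 1L)

  expect_error(readPDB("REMARK nothing here"), "empty structure")
})

test_that("multi-model files yield a frame list and altlocs keep top occupancy", {
  lines <- c("MODEL     1",
             pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C"),
             "ENDMDL", "MODEL     2",
             pdb_line(1, "CA", "GLY", "A", 1, 1, 0, 0, "C"),
             "ENDMDL")
  frames <- readPDB(lines)
  expect_length(frames, 2L)
  expect_equal(coords(frames[[2]])[1, 1], 1)

  alt <- readPDB(c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C",
                            altloc = "A", occ = 0.4),
                   pdb_line(2, "CA", "GLY", "A", 1, 9, 0, 0, "C",
                            altloc = "B", occ = 0.6)))
  expect_equal(nAtoms(alt), 1L)
  expect_equal(coords(alt)[1, 1], 9)
})

test_that("write/read round-trip preserves atoms, order, keys and coordinates", {
  toy <- makeToyComplex(generatorConfig(seed = 4))
  s <- toy$complex
  s2 <- readPDB(writePDB(s))
  expect_equal(nAtoms(s2), nAtoms(s))
  expect_identical(residueKeys(s2), residueKeys(s))
  expect_identical(atoms(s2)$name, atoms(s)$name)
  expect_lt(max(abs(coords(s2) - coords(s))), 5e-4)
})

test_that("selection by chain subsets atoms and flags unknown chains", {
  toy <- makeToyComplex(generatorConfig(seed = 1))
  s <- toy$complex
  expect_equal(nAtoms(selectAtoms(s, chains = c("A", "B"))), nAtoms(s))
  a <- selectAtoms(s, chains = "A")
  expect_setequal(unique(atoms(a)$chain), "A")
  expect_true(all(atoms(a)$serial %in% atoms(s)$serial))
  expect_error(selectAtoms(s, chains = "Z"), "unknown chain")
  expect_warning(selectAtoms(s, chains = "A", resnumRange = c(900, 901)),
                 "empty")
})

test_that("protonation: acidic -1, basic +1, His neutral by default", {
  s <- ala_arg()
  pa <- assignProtonation(s)
  expect_equal(unname(pa@charges[grep("ARG", names(pa@charges))]), 1L)
  expect_equal(formalCharge(s, pa), 1L)

  # 2 Arg + 1 Asp + neutral His -> net +1 (keys only; geometry irrelevant)
  pep <- readPDB(c(
    pdb_line(1, "CA", "ARG", "A", 1, 0, 0, 0, "C"),
    pdb_line(2, "CA", "ARG", "A", 2, 4, 0, 0, "C"),
    pdb_line(3, "CA", "ASP", "A", 3, 8, 0, 0, "C"),
    pdb_line(4, "CA", "HIS", "A", 4, 12, 0, 0, "C"),
    pdb_line(5, "CA", "GLU", "A", 5, 16, 0, 0, "C")))
  pa2 <- assignProtonation(pep)
  expect_equal(formalCharge(pep, pa2), 0L)  # +2 -1 +0 -1
  # a buried histidine stays neutral regardless of reported SASA
  pa3 <- assignProtonation(pep, hisSasa = c("A:4::HIS" = 3))
  expect_equal(unname(pa3@charges["A:4::HIS"]), 0L)
  # explicit override makes it +1
  pa4 <- assignProtonation(pep, hisOverride = "A:4::HIS")
  expect_equal(unname(pa4@charges["A:4::HIS"]), 1L)
  expect_equal(unname(pa4@hisTautomer["A:4::HIS"]), "both")
})

test_that("formal charge is additive over chains", {
  one <- readPDB(c(pdb_line(1, "CA", "LYS", "A", 1, 0, 0, 0, "C"),
                   pdb_line(2, "CA", "GLU", "A", 2, 4, 0, 0, "C")))
  two <- readPDB(c(pdb_line(1, "CA", "LYS", "A", 1, 0, 0, 0, "C"),
                   pdb_line(2, "CA", "GLU", "A", 2, 4, 0, 0, "C"),
                   pdb_line(3, "CA", "ARG", "B", 1, 0, 4, 0, "C")))
  fc <- function(s) formalCharge(s, assignProtonation(s))
  expect_equal(fc(two), fc(one) + 1L)
})

test_that("hydrogen placement: counts, 1.0 A bonds, heavy atoms unmoved", {
  s <- ala_arg()
  xyz0 <- coords(s)
  sh <- addHydrogens(s)
  a <- atoms(sh)
  # heavy atoms unmoved and in original order
  expect_equal(coords(sh)[a$element != "H", ], xyz0)
  # backbone N of residue 2 gains exactly one H
  h2 <- a$element == "H" & a$resnum == 2 & a$name == "H"
  expect_equal(sum(h2), 1L)
  # every placed hydrogen 1.0 +/- 0.05 A from its nearest heavy atom
  hv <- which(a$element != "H")
  for (h in which(a$element == "H")) {
    d <- sqrt((a$x[hv] - a$x[h])^2 + (a$y[hv] - a$y[h])^2 +
              (a$z[hv] - a$z[h])^2)
    expect_lt(abs(min(d) - 1.0), 0.05)
  }
  # idempotent: existing hydrogens are preserved, not duplicated
  sh2 <- addHydrogens(sh)
  expect_equal(nAtoms(sh2), nAtoms(sh))
})

test_that("neutral His gains exactly one ring N-H on the assigned tautomer", {
  his <- readPDB(c(
    pdb_line(1, "N", "HIS", "A", 1, -10, 0, 0, "N"),
    pdb_line(2, "CA", "HIS", "A", 1, 0, 0, 0, "C"),
    pdb_line(3, "CB", "HIS", "A", 1, 0.6, 1.4, 0, "C"),
    pdb_line(4, "CG", "HIS", "A", 1, 2.1, 1.4, 0, "C"),
    pdb_line(5, "ND1", "HIS", "A", 1, 2.9, 0.6, 0.8, "N"),
    pdb_line(6, "CD2", "HIS", "A", 1, 2.9, 2.2, -0.6, "C"),
    pdb_line(7, "CE1", "HIS", "A", 1, 4.2, 0.9, 0.6, "C"),
    pdb_line(8, "NE2", "HIS", "A", 1, 4.3, 2.0, -0.3, "N")))
  for (taut in c("ND1", "NE2")) {
    pa <- assignProtonation(his)
    pa@hisTautomer[] <- taut
    sh <- addHydrogens(his, pa)
    a <- atoms(sh)
    ring_h <- a$element == "H" & a$name %in% c("HD1", "HE2")
    expect_equal(sum(ring_h), 1L)
    expect_equal(a$name[ring_h], paste0("H", substring(taut, 2)))
  }
})

test_that("counterion placement respects surface and pairwise constraints", {
  s <- ala_arg()
  q <- attachParameters(s, defaultParameterSet())$charge
  expect_equal(nrow(placeCounterions(s, 0, q)), 0L)
  ions <- placeCounterions(s, 3, q)
  expect_equal(nrow(ions), 3L)
  # >= 10 A apart
  expect_gte(min(dist(ions)), 10)
  # >= 6 A from every heavy-atom surface (element van der Waals radii)
  xyz <- coords(s)
  rad <- c(C = 1.70, N = 1.55, O = 1.52)[atoms(s)$element]
  for (i in seq_len(nrow(ions))) {
    d <- sqrt(rowSums(sweep(xyz, 2, ions[i, ])^2)) - rad
    expect_gte(min(d), 6 - 1e-9)
  }
})

test_that("counterion sites rank by Coulomb potential", {
  # single +1 charge: a negative ion site must sit on the charge side
  s <- point_structure(matrix(c(0, 0, 0), 1, 3))
  ion <- placeCounterions(s, 1, charges = 1, minSurface = 6,
                          minPairwise = 10, padding = 10)
  # brute-force: every admissible candidate potential is <= the chosen one
  d <- sqrt(sum(ion[1, ]^2))
  expect_gte(332.0636 / d, 332.0636 / (10 * sqrt(3)))
})
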