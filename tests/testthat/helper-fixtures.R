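# shared fixture builders: everything is generated in code at test time

pdb_line <- function(serial, name, resname, chain, resnum, x, y, z, el,
                     icode = " ", altloc = " ", occ = 1) {
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f  0.00          %2s",
          serial, name, altloc, resname, chain, resnum, icode, x, y, z, occ, el)
}

# a small two-chain structure of single-atom "residues" at given coords
point_structure <- function(xyz, chain = "A", resnum = seq_len(nrow(xyz)),
                            name = "CA", resname = "GLY", element = "C") {
  lines <- vapply(seq_len(nrow(xyz)), function(i)
    pdb_line(i, name, resname, chain[min(i, length(chain))],
             resnum[i], xyz[i, 1], xyz[i, 2], xyz[i, 3], element), "")
  readPDB(lines)
}

# dipeptide with an arginine side chain (all heavy atoms present)
ala_arg <- function() {
  readPDB(c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0, "N"),
    pdb_line(2, "CA", "ALA", "A", 1, 1.46, 0, 0, "C"),
    pdb_line(3, "C", "ALA", "A", 1, 2.0, 1.4, 0, "C"),
    pdb_line(4, "O", "ALA", "A", 1, 1.4, 2.4, 0, "O"),
    pdb_line(5, "CB", "ALA", "A", 1, 2.0, -0.8, 1.2, "C"),
    pdb_line(6, "N", "ARG", "A", 2, 3.3, 1.5, 0, "N"),
    pdb_line(7, "CA", "ARG", "A", 2, 4.0, 2.75, 0, "C"),
    pdb_line(8, "C", "ARG", "A", 2, 5.5, 2.5, 0, "C"),
    pdb_line(9, "O", "ARG", "A", 2, 6.0, 1.4, 0, "O"),
    pdb_line(10, "CB", "ARG", "A", 2, 3.6, 3.6, 1.2, "C"),
    pdb_line(11, "CG", "ARG", "A", 2, 3.9, 5.1, 1.1, "C"),
    pdb_line(12, "CD", "ARG", "A", 2, 3.5, 5.8, 2.4, "C"),
    pdb_line(13, "NE", "ARG", "A", 2, 3.8, 7.2, 2.4, "N"),
    pdb_line(14, "CZ", "ARG", "A", 2, 3.5, 8.1, 3.3, "C"),
    pdb_line(15, "NH1", "ARG", "A", 2, 2.8, 7.7, 4.4, "N"),
    pdb_line(16, "NH2", "ARG", "A", 2, 3.8, 9.4, 3.2, "N")))
}

# brute-force per-frame minimum heavy-atom distance between residue pairs
oracle_pair_min_dist <- function(frame, atoms, selA, selB) {
  keysA <- unique(paste(atoms$chain, atoms$resnum)[selA])
  keysB <- unique(paste(atoms$chain, atoms$resnum)[selB])
  D <- matrix(Inf, length(keysA), length(keysB))
  for (i in selA) for (j in selB) {
    ki <- match(paste(atoms$chain[i], atoms$resnum[i]), keysA)
    kj <- match(paste(atoms$chain[j], atoms$resnum[j]), keysB)
    d <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    if (d < D[ki, kj]) D[ki, kj] <- d
  }
  D
}

# small PB config for fast tests (final focus 0.75 A unless stated)
test_pb <- function(dime = 49L, spacings = c(1.5, 0.75))
  pbConfig(dime = dime, spacings = spacings)

# 4-residue toy that fits the test PB grids
small_toy_cfg <- function(seed = 1, frames = 8L, ...)
  generatorConfig(seed = seed, nResidues = 4L,
                  planted = data.frame(pos = 2L, type = "salt-bridge"),
                  framesPerRun = frames, ...)
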