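#' @include AllGenerics.R
NULL

.vdw_element_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                        H = 1.20, CL = 1.75, NA. = 2.27, X = 1.70)

.element_radius <- function(element) {
  r <- .vdw_element_radii[toupper(element)]
  r[is.na(r)] <- .vdw_element_radii[["X"]]
  unname(r)
}

.guess_element <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  two <- toupper(substr(nm, 1, 2))
  el <- ifelse(two %in% c("CL", "BR", "FE", "ZN", "MG"), two,
               toupper(substr(nm, 1, 1)))
  el[el == ""] <- "X"
  el
}

#' Read a PDB structure from text or file
#'
#' Parses ATOM/HETATM records with fixed-column semantics, preserving
#' insertion codes, discontinuous residue numbering and file order.  When
#' alternate locations are present only the highest-occupancy conformer of
#' each atom is kept.  Multi-model files (MODEL/ENDMDL) return a list of
#' \code{PDBStructure} frames.
#'
#' @param x PDB text (single string or character vector of lines) or the
#'   path of a PDB file.
#' @return a \code{PDBStructure}, or a list of them for multi-model input.
#' @examples
#' pdb <- readPDB(c(
#'   "ATOM      1  N   ALA A   1      0.000   0.000   0.000  1.00  0.00           N"))
#' nAtoms(pdb)
#' @export
readPDB <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x))
    x <- readLines(x, warn = FALSE)
  if (length(x) == 1L && grepl("\n", x))
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  lines <- x
  rec <- substr(lines, 1, 6)
  is_atom <- grepl("^(ATOM|HETATM)", rec)
  is_model <- grepl("^MODEL", rec)
  is_endmdl <- grepl("^ENDMDL", rec)
  if (!any(is_atom))
    stop("empty structure: no ATOM/HETATM records in input")

  parse_block <- function(bl) {
    ln <- lines[bl]
    pad <- formatC(ln, width = 80, flag = "-")
    f <- function(a, b) substr(pad, a, b)
    xyz <- suppressWarnings(cbind(as.numeric(f(31, 38)),
                                  as.numeric(f(39, 46)),
                                  as.numeric(f(47, 54))))
    bad <- which(!stats::complete.cases(xyz))
    if (length(bad))
      stop(sprintf("malformed ATOM record at line %d: %s",
                   which(bl)[bad[1]], trimws(ln[bad[1]])))
    serial <- suppressWarnings(as.integer(trimws(f(7, 11))))
    serial[is.na(serial)] <- seq_along(serial)[is.na(serial)]
    resnum <- suppressWarnings(as.integer(trimws(f(23, 26))))
    if (anyNA(resnum))
      stop(sprintf("malformed residue number at line %d",
                   which(bl)[which(is.na(resnum))[1]]))
    occ <- suppressWarnings(as.numeric(trimws(f(55, 60))))
    occ[is.na(occ)] <- 1
    element <- trimws(f(77, 78))
    name <- trimws(f(13, 16))
    element <- ifelse(nzchar(element), toupper(element), .guess_element(name))
    a <- data.frame(serial = serial, name = name,
                    altloc = trimws(f(17, 17)),
                    resname = trimws(f(18, 20)),
                    chain = trimws(f(22, 22)),
                    resnum = resnum, icode = trimws(f(27, 27)),
                    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    occupancy = occ, element = element,
                    record = trimws(substr(ln, 1, 6)),
                    stringsAsFactors = FALSE)
    # alternate locations: keep the highest-occupancy conformer
    if (any(nzchar(a$altloc))) {
      key <- paste(.reskey(a), a$name)
      keep <- unlist(lapply(split(seq_len(nrow(a)), factor(key, unique(key))),
                            function(i) i[which.max(a$occupancy[i])]),
                     use.names = FALSE)
      a <- a[sort(keep), , drop = FALSE]
      rownames(a) <- NULL
    }
    new("PDBStructure", atoms = a)
  }

  if (any(is_model)) {
    starts <- which(is_model); ends <- which(is_endmdl)
    if (length(ends) < length(starts)) ends <- c(ends, length(lines))
    frames <- lapply(seq_along(starts), function(m) {
      bl <- logical(length(lines))
      bl[starts[m]:ends[m]] <- TRUE
      parse_block(bl & is_atom)
    })
    if (length(frames) == 1L) frames[[1]] else frames
  } else parse_block(is_atom)
}

#' Write a structure as PDB text
#'
#' Coordinates are written to three decimals; residue keys, atom order and
#' serials are preserved so that \code{readPDB(writePDB(x))} round-trips.
#'
#' @param x a \code{PDBStructure}
#' @param file optional path; if \code{NULL} the text is returned invisibly.
#' @return character vector of PDB lines (invisibly when writing to file)
#' @export
writePDB <- function(x, file = NULL) {
  a <- x@atoms
  name4 <- ifelse(nchar(a$name) >= 4, substr(a$name, 1, 4),
                  paste0(" ", formatC(a$name, width = -3)))
  ln <- sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                a$record, a$serial %% 100000L, name4, a$altloc, a$resname,
                a$chain, a$resnum, a$icode, a$x, a$y, a$z, a$occupancy, 0,
                a$element)
  out <- c(ln, "END")
  if (!is.null(file)) { writeLines(out, file); return(invisible(out)) }
  out
}

#' Subset a structure by chain and residue range
#'
#' Atoms retain their original serial numbers and order.  Residue ranges are
#' applied by position in the chain's residue list (file order), so Kabat
#' gaps and insertion codes are handled naturally when \code{from}/\code{to}
#' are given as residue keys; plain integers select by residue number.
#'
#' @param x a \code{PDBStructure}
#' @param chains character vector of chain identifiers (NULL = all)
#' @param resnumRange optional length-2 integer range of residue numbers
#'   (applied within the selected chains, inclusive)
#' @param residues optional character vector of residue keys
#'   (\code{"chain:num:icode:resname"}) to keep
#' @return a \code{PDBStructure} subset
#' @export
selectAtoms <- function(x, chains = NULL, resnumRange = NULL, residues = NULL) {
  a <- x@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chains)) {
    unknown <- setdiff(chains, unique(a$chain))
    if (length(unknown))
      stop("unknown chain(s): ", paste(unknown, collapse = ", "))
    keep <- keep & a$chain %in% chains
  }
  if (!is.null(resnumRange))
    keep <- keep & a$resnum >= resnumRange[1] & a$resnum <= resnumRange[2]
  if (!is.null(residues))
    keep <- keep & .reskey(a) %in% residues
  if (!any(keep))
    warning("selection is empty")
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  new("PDBStructure", atoms = out)
}

#' Merge two structures into one atom list
#'
#' Atom order is first structure then second; duplicate chain identifiers in
#' \code{y} can be relabelled via \code{relabel}.
#' @param x,y \code{PDBStructure} objects
#' @param relabel named character vector mapping old to new chain ids for y
#' @return combined \code{PDBStructure}
#' @export
mergeStructures <- function(x, y, relabel = NULL) {
  b <- y@atoms
  if (!is.null(relabel)) {
    hit <- b$chain %in% names(relabel)
    b$chain[hit] <- relabel[b$chain[hit]]
  }
  b$serial <- max(x@atoms$serial, 0L) + seq_len(nrow(b))
  new("PDBStructure", atoms = rbind(x@atoms, b))
}

.acidic <- c("ASP", "GLU")
.basic <- c("LYS", "ARG")
.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

#' Assign protonation states and formal charges
#'
#' Side-chain formal charges at neutral pH: Asp/Glu carry -1, Lys/Arg +1.
#' Histidines are neutral by default (charged only through
#' \code{hisOverride}); the neutral tautomer (ND1-H vs NE2-H) is picked to
#' maximise hydrogen-bond geometry with polar neighbours within 3.5 A of
#' the candidate donor nitrogen.  Nonstandard residues are flagged and
#' assigned charge 0.
#'
#' @param x a \code{PDBStructure}
#' @param hisSasa optional named numeric of relative SASA (\%) per His
#'   residue key, recorded for reporting (low-SASA buried histidines are
#'   consistent with the neutral default).
#' @param hisOverride character vector of His residue keys to protonate
#'   (+1, both ring nitrogens).
#' @return a \code{ProtonationAssignment}
#' @export
assignProtonation <- function(x, hisSasa = NULL, hisOverride = character(0)) {
  a <- x@atoms
  keys <- residueKeys(x)
  resname <- vapply(strsplit(keys, ":", fixed = TRUE), `[`, "", 4L)
  chg <- integer(length(keys))
  chg[resname %in% .acidic] <- -1L
  chg[resname %in% .basic] <- 1L
  flagged <- keys[!resname %in% .standard_aa]
  names(chg) <- keys

  his_keys <- keys[resname == "HIS"]
  taut <- character(0)
  if (length(his_keys)) {
    ridx <- residueIndex(x)
    heavy <- a$element != "H"
    taut <- vapply(his_keys, function(k) {
      if (k %in% hisOverride) return("both")
      ri <- match(k, keys)
      mine <- which(ridx == ri)
      nd1 <- mine[a$name[mine] == "ND1"]
      ne2 <- mine[a$name[mine] == "NE2"]
      if (!length(nd1) || !length(ne2)) return("NE2")
      other <- which(ridx != ri & heavy & a$element %in% c("N", "O", "S"))
      score <- function(i) {
        if (!length(other)) return(0)
        d <- sqrt((a$x[other] - a$x[i])^2 + (a$y[other] - a$y[i])^2 +
                  (a$z[other] - a$z[i])^2)
        m <- d[d <= 3.5]
        if (!length(m)) 0 else max(3.5 - m)
      }
      if (score(nd1[1]) > score(ne2[1])) "ND1" else "NE2"
    }, "")
    names(taut) <- his_keys
    chg[names(taut)[taut == "both"]] <- 1L
  }
  new("ProtonationAssignment", charges = chg, hisTautomer = taut,
      flagged = flagged)
}

#' Net formal charge of a structure
#'
#' Sum of per-residue side-chain formal charges plus terminal charges
#' (+1 amino, -1 carboxy per chain), which cancel for intact chains.
#' Additive over chains.
#'
#' @param x a \code{PDBStructure}
#' @param assignment a \code{ProtonationAssignment} covering all residues
#' @return integer net charge (e)
#' @export
formalCharge <- function(x, assignment) {
  keys <- residueKeys(x)
  miss <- setdiff(keys, names(assignment@charges))
  if (length(miss))
    stop("assignment does not cover residues: ", paste(head(miss, 3), collapse = ", "))
  # terminal +1 and -1 cancel per intact chain, so only side chains remain
  sum(assignment@charges[keys])
}

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-9) c(1, 0, 0) else v / n
}

.any_perp <- function(u) {
  p <- c(-u[2], u[1], 0)
  if (sum(p^2) < 1e-6) p <- c(0, -u[3], u[2])
  .unit(p)
}

# place n hydrogens of bond length len on anchor A completing the valence
# suggested by the bonded reference positions (rows of refs)
.place_h <- function(A, refs, n, len = 1.0) {
  dirs <- -apply(refs, 1, function(r) .unit(r - A))
  u <- .unit(rowSums(matrix(dirs, nrow = 3)))
  if (n == 1L) return(matrix(A + len * u, 1, 3, byrow = TRUE))
  e2 <- .any_perp(u); e3 <- .unit(pracma_cross(u, e2))
  if (n == 2L) {
    ang <- 60 * pi / 180  # sp2: H-N-H 120 deg, symmetric about u
    rbind(A + len * (cos(ang) * u + sin(ang) * e2),
          A + len * (cos(ang) * u - sin(ang) * e2))
  } else {
    tilt <- 70.53 * pi / 180  # tetrahedral
    t(vapply(0:2, function(k) {
      phi <- 2 * pi * k / 3
      A + len * (cos(tilt) * u +
                 sin(tilt) * (cos(phi) * e2 + sin(phi) * e3))
    }, numeric(3)))
  }
}

pracma_cross <- function(a, b)
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])

.polar_h_sites <- function(resname, tautomer = "NE2") {
  sites <- switch(resname,
    SER = list(list(anchor = "OG", refs = "CB", n = 1L)),
    THR = list(list(anchor = "OG1", refs = "CB", n = 1L)),
    TYR = list(list(anchor = "OH", refs = "CZ", n = 1L)),
    LYS = list(list(anchor = "NZ", refs = "CE", n = 3L)),
    ARG = list(list(anchor = "NE", refs = c("CD", "CZ"), n = 1L),
               list(anchor = "NH1", refs = "CZ", n = 2L),
               list(anchor = "NH2", refs = "CZ", n = 2L)),
    ASN = list(list(anchor = "ND2", refs = "CG", n = 2L)),
    GLN = list(list(anchor = "NE2", refs = "CD", n = 2L)),
    TRP = list(list(anchor = "NE1", refs = c("CD1", "CE2"), n = 1L)),
    HIS = {
      nd1 <- list(anchor = "ND1", refs = c("CG", "CE1"), n = 1L)
      ne2 <- list(anchor = "NE2", refs = c("CD2", "CE1"), n = 1L)
      switch(tautomer, ND1 = list(nd1), NE2 = list(ne2),
             both = list(nd1, ne2))
    },
    list())
  sites
}

#' Add polar hydrogens at ideal geometry
#'
#' Places backbone amide hydrogens and side-chain polar hydrogens (Ser/Thr/
#' Tyr hydroxyls, Lys/Arg/Asn/Gln/Trp amines, His ring nitrogens per the
#' assigned tautomer) at 1.0 A bond length along idealised valence
#' directions.  Heavy atoms are never moved; hydrogens already present are
#' preserved and their anchors skipped.  Residues with missing heavy-atom
#' anchors are skipped with a warning; residue names outside the standard
#' twenty are left untouched.
#'
#' @param x a \code{PDBStructure} with complete heavy atoms
#' @param assignment a \code{ProtonationAssignment} (for His tautomers)
#' @return a \code{PDBStructure} with hydrogens inserted after their anchors
#' @export
addHydrogens <- function(x, assignment = assignProtonation(x)) {
  a <- x@atoms
  ridx <- residueIndex(x)
  keys <- residueKeys(x)
  newrows <- list()
  skipped <- character(0)
  for (ri in seq_along(keys)) {
    mine <- which(ridx == ri)
    rn <- a$resname[mine[1]]
    if (!rn %in% .standard_aa) next
    sites <- list()
    # backbone amide NH (not proline)
    if (rn != "PRO") {
      prev <- which(ridx == ri - 1L & a$chain == a$chain[mine[1]])
      prevC <- prev[a$name[prev] == "C"]
      refs <- if (length(prevC)) c("CA", ".prevC") else "CA"
      sites <- c(sites, list(list(anchor = "N", refs = refs, n = 1L,
                                  prevC = if (length(prevC)) prevC[1] else NA)))
    }
    taut <- assignment@hisTautomer[keys[ri]]
    if (is.na(taut)) taut <- "NE2"
    sites <- c(sites, .polar_h_sites(rn, taut))
    for (s in sites) {
      anc <- mine[a$name[mine] == s$anchor]
      if (!length(anc)) { skipped <- c(skipped, keys[ri]); next }
      anc <- anc[1]
      A <- c(a$x[anc], a$y[anc], a$z[anc])
      # existing hydrogen bonded to this anchor?
      hs <- mine[a$element[mine] == "H"]
      if (length(hs)) {
        d <- sqrt((a$x[hs] - A[1])^2 + (a$y[hs] - A[2])^2 + (a$z[hs] - A[3])^2)
        if (any(d < 1.25)) next
      }
      refnames <- s$refs
      refrows <- integer(0)
      for (rf in refnames) {
        if (rf == ".prevC") refrows <- c(refrows, s$prevC)
        else {
          hit <- mine[a$name[mine] == rf]
          if (length(hit)) refrows <- c(refrows, hit[1])
        }
      }
      if (!length(refrows)) { skipped <- c(skipped, keys[ri]); next }
      refs <- cbind(a$x[refrows], a$y[refrows], a$z[refrows])
      H <- .place_h(A, refs, s$n)
      hname <- if (s$anchor == "N") "H" else
        paste0("H", substring(s$anchor, 2))
      for (hh in seq_len(nrow(H))) {
        row <- a[anc, , drop = FALSE]
        row$name <- if (s$n == 1L) hname else paste0(hname, hh)
        row$element <- "H"
        row$x <- H[hh, 1]; row$y <- H[hh, 2]; row$z <- H[hh, 3]
        newrows[[length(newrows) + 1L]] <- list(after = anc, row = row)
      }
    }
  }
  if (length(skipped))
    warning("missing heavy-atom anchor; skipped site(s) in: ",
            paste(unique(skipped), collapse = ", "))
  if (!length(newrows)) return(x)
  ord <- order(vapply(newrows, function(r) r$after, 1L))
  add <- do.call(rbind, lapply(newrows[ord], `[[`, "row"))
  att <- vapply(newrows[ord], function(r) r$after, 1L)
  pieces <- list()
  prev <- 0L
  for (i in seq_along(att)) {
    pieces[[length(pieces) + 1L]] <- a[seq_len(att[i])[seq_len(att[i]) > prev], , drop = FALSE]
    pieces[[length(pieces) + 1L]] <- add[i, , drop = FALSE]
    prev <- att[i]
  }
  if (prev < nrow(a))
    pieces[[length(pieces) + 1L]] <- a[(prev + 1L):nrow(a), , drop = FALSE]
  out <- do.call(rbind, pieces)
  out$serial <- ifelse(out$element == "H" & !out$serial %in% a$serial,
                       out$serial, out$serial)
  hnew <- which(duplicated(out$serial))
  out$serial[hnew] <- max(a$serial) + seq_along(hnew)
  rownames(out) <- NULL
  new("PDBStructure", atoms = out)
}

#' Place neutralizing counterions at electropositive surface sites
#'
#' Candidate positions on a regular grid around the protein are ranked by
#' descending Coulomb potential; positions are accepted greedily subject to
#' being at least \code{minSurface} A from every protein heavy-atom surface
#' (atom centre plus van der Waals radius) and at least \code{minPairwise}
#' A from each other.  For chloride counterions around a net-positive
#' protein the top-ranked (most electropositive) sites are used.
#'
#' @param x a \code{PDBStructure}
#' @param n number of ions to place
#' @param charges per-atom partial charges (e), same order as atoms
#' @param minSurface minimum distance from any heavy-atom surface, A
#' @param minPairwise minimum ion-ion distance, A
#' @param padding box padding beyond the structure extent, A
#' @param gridSpacing candidate-grid spacing, A
#' @return n x 3 matrix of ion positions (0 x 3 for n = 0)
#' @export
placeCounterions <- function(x, n, charges, minSurface = 6, minPairwise = 10,
                             padding = 14, gridSpacing = 2) {
  stopifnot(n >= 0)
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  xyz <- coords(x)
  heavy <- isHeavy(x)
  rad <- .element_radius(x@atoms$element[heavy])
  lo <- apply(xyz, 2, min) - padding
  hi <- apply(xyz, 2, max) + padding
  gx <- seq(lo[1], hi[1], by = gridSpacing)
  gy <- seq(lo[2], hi[2], by = gridSpacing)
  gz <- seq(lo[3], hi[3], by = gridSpacing)
  cand <- as.matrix(expand.grid(gx, gy, gz))
  hxyz <- xyz[heavy, , drop = FALSE]
  # distance from candidate to nearest atom *surface*
  dmin <- rep(Inf, nrow(cand))
  for (i in seq_len(nrow(hxyz))) {
    d <- sqrt((cand[, 1] - hxyz[i, 1])^2 + (cand[, 2] - hxyz[i, 2])^2 +
              (cand[, 3] - hxyz[i, 3])^2) - rad[i]
    dmin <- pmin(dmin, d)
  }
  ok <- dmin >= minSurface
  if (!any(ok)) stop("box too small: no candidate satisfies the surface constraint")
  cand <- cand[ok, , drop = FALSE]
  pot <- numeric(nrow(cand))
  for (i in seq_len(nrow(xyz))) {
    if (charges[i] == 0) next
    d <- sqrt((cand[, 1] - xyz[i, 1])^2 + (cand[, 2] - xyz[i, 2])^2 +
              (cand[, 3] - xyz[i, 3])^2)
    pot <- pot + KE_COULOMB * charges[i] / pmax(d, 1e-6)
  }
  ord <- order(pot, decreasing = TRUE)
  placed <- matrix(numeric(0), 0, 3)
  for (i in ord) {
    p <- cand[i, ]
    if (nrow(placed) &&
        min(sqrt(rowSums((placed - matrix(p, nrow(placed), 3, byrow = TRUE))^2))) < minPairwise)
      next
    placed <- rbind(placed, p)
    if (nrow(placed) == n) break
  }
  if (nrow(placed) < n)
    stop("placement error: could not satisfy pairwise constraint for all ions")
  dimnames(placed) <- NULL
  placed
}
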