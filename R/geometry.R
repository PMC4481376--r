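#' @include AllGenerics.R
NULL

#' @rdname applyTransform
setMethod("applyTransform", signature("matrix", "RigidTransform"),
          function(x, transform) {
            t(transform@rotation %*% t(x)) +
              matrix(transform@translation, nrow(x), 3, byrow = TRUE)
          })

#' @rdname applyTransform
setMethod("applyTransform", signature("PDBStructure", "RigidTransform"),
          function(x, transform) {
            coords(x) <- applyTransform(coords(x), transform)
            x
          })

#' @rdname applyTransform
setMethod("applyTransform", signature("RigidTransform", "RigidTransform"),
          function(x, transform) {
            # composition: (transform o x)
            new("RigidTransform",
                rotation = transform@rotation %*% x@rotation,
                translation = as.numeric(transform@rotation %*% x@translation) +
                  transform@translation)
          })

#' Construct a rigid transform
#' @param rotation 3x3 proper rotation matrix
#' @param translation length-3 translation, Angstrom
#' @return a \code{RigidTransform}
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0))
  new("RigidTransform", rotation = rotation, translation = translation)

#' Rotation matrix about an axis
#' @param axis length-3 axis (normalised internally)
#' @param angle rotation angle in degrees
#' @return 3x3 rotation matrix
#' @export
rotationAbout <- function(axis, angle) {
  u <- .unit(axis); th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' matched point sets.  Reflections are excluded by the standard sign
#' correction on the smallest singular value.
#'
#' @param mobile n x 3 matrix of points to move
#' @param reference n x 3 matrix of target points (same n)
#' @return list with \code{transform} (a \code{RigidTransform}) and
#'   \code{rmsd} (Angstrom, after transformation)
#' @export
superpose <- function(mobile, reference) {
  if (!is.matrix(mobile)) mobile <- as.matrix(mobile)
  if (!is.matrix(reference)) reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference))
    stop("superposition error: point counts differ")
  if (n < 3L)
    stop("superposition error: need >= 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- t(A) %*% B
  s <- svd(H)
  if (min(s$d) < 1e-12 && sum(s$d > 1e-12) < 2)
    stop("superposition error: degenerate (collinear) geometry")
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t0 <- cr - as.numeric(R %*% cm)
  tr <- rigidTransform(R, t0)
  moved <- applyTransform(mobile, tr)
  list(transform = tr, rmsd = sqrt(mean(rowSums((moved - reference)^2))))
}

#' Root-mean-square deviation between matched coordinate sets
#' @param a,b n x 3 matrices in correspondence
#' @param fit superpose first (default FALSE: no re-fitting)
#' @return RMSD in Angstrom
#' @export
rmsd <- function(a, b, fit = FALSE) {
  if (nrow(a) != nrow(b)) stop("pairing error: point counts differ")
  if (fit) return(superpose(a, b)$rmsd)
  sqrt(mean(rowSums((a - b)^2)))
}

#' C-alpha RMSD between two structures
#'
#' Pairs C-alpha atoms by residue order over an optional chain selection;
#' no re-fitting unless requested.
#' @param a,b \code{PDBStructure} objects with matched C-alpha counts
#' @param chains optional chain selection applied to both
#' @param fit superpose before measuring
#' @return RMSD in Angstrom
#' @export
rmsdCA <- function(a, b, chains = NULL, fit = FALSE) {
  pick <- function(s) {
    if (!is.null(chains)) s <- selectAtoms(s, chains = chains)
    m <- s@atoms$name == "CA"
    coords(s)[m, , drop = FALSE]
  }
  ca <- pick(a); cb <- pick(b)
  if (nrow(ca) != nrow(cb))
    stop("pairing error: C-alpha counts differ (", nrow(ca), " vs ", nrow(cb), ")")
  rmsd(ca, cb, fit = fit)
}

#' Greedy centroid clustering by pairwise RMSD
#'
#' Repeatedly selects the unassigned member with the most unassigned
#' neighbours within \code{cutoff} as a cluster centroid and assigns those
#' neighbours to it; ties break to the earliest input index, so the result
#' is deterministic given input order.  Every member ends within
#' \code{cutoff} of its centroid and clusters partition the input.
#'
#' @param x either a list of n x 3 coordinate matrices in correspondence,
#'   or a precomputed symmetric distance matrix (class \code{"matrix"} with
#'   equal dims and zero diagonal)
#' @param cutoff RMSD cutoff in Angstrom (default 4)
#' @return list of clusters, each a list with \code{centroid} (index) and
#'   \code{members} (integer indices, centroid first)
#' @export
clusterByRMSD <- function(x, cutoff = 4) {
  if (is.matrix(x) && nrow(x) == ncol(x)) D <- x
  else {
    n <- length(x)
    if (n < 1L) stop("need >= 1 pose")
    D <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (j > i)
      D[i, j] <- D[j, i] <- rmsd(x[[i]], x[[j]])
  }
  n <- nrow(D)
  unassigned <- rep(TRUE, n)
  clusters <- list()
  while (any(unassigned)) {
    idx <- which(unassigned)
    counts <- vapply(idx, function(i) sum(D[i, idx] <= cutoff), 1L)
    centroid <- idx[which.max(counts)]
    members <- idx[D[centroid, idx] <= cutoff]
    members <- c(centroid, setdiff(members, centroid))
    clusters[[length(clusters) + 1L]] <- list(centroid = centroid,
                                              members = members)
    unassigned[members] <- FALSE
  }
  clusters
}

# deterministic golden-spiral unit sphere points
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Theoretical maximum residue SASA (Gly-X-Gly), A^2
#'
#' Published tripeptide maxima used to normalise per-residue areas to
#' relative (percent) accessibility (Tien et al. 2013, theoretical set).
#' @export
MAX_SASA_GXG <- c(ALA = 129, ARG = 274, ASN = 195, ASP = 193, CYS = 167,
                  GLN = 225, GLU = 223, GLY = 104, HIS = 224, ILE = 197,
                  LEU = 201, LYS = 236, MET = 224, PHE = 240, PRO = 159,
                  SER = 155, THR = 172, TRP = 285, TYR = 263, VAL = 174)

#' Shrake-Rupley solvent-accessible surface area
#'
#' Sphere-point sampling with a deterministic golden-spiral point set on
#' each heavy atom's solvent-expanded sphere (radius + probe); hydrogens
#' are ignored.  Relative per-residue areas are the residue area divided by
#' the tabulated Gly-X-Gly maximum (standard residues only, NA otherwise).
#'
#' @param x a \code{PDBStructure}
#' @param probe probe radius, Angstrom (default 1.4)
#' @param nPoints sample points per atom (default 960)
#' @param radii optional per-atom radii; default element van der Waals radii
#' @return list with \code{atomArea} (per heavy atom, A^2; 0 rows for H),
#'   \code{residue} data.frame (key, resname, area, relative) and
#'   \code{total} (A^2)
#' @export
shrakeRupley <- function(x, probe = 1.4, nPoints = 960L, radii = NULL) {
  a <- x@atoms
  heavy <- which(a$element != "H")
  if (!length(heavy)) stop("no heavy atoms")
  if (is.null(radii)) radii <- .element_radius(a$element[heavy])
  else {
    radii <- radii[heavy]
    if (anyNA(radii))
      stop("missing radius for atom ", a$name[heavy[which(is.na(radii))[1]]])
  }
  xyz <- coords(x)[heavy, , drop = FALSE]
  pts <- .sphere_points(nPoints)
  R <- radii + probe
  n <- length(heavy)
  area <- numeric(nrow(a))
  # neighbour lists once
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (R[i] + R)^2 & seq_len(n) != i)
    p <- sweep(pts * R[i], 2, xyz[i, ], `+`)
    acc <- rep(TRUE, nPoints)
    for (j in nb) {
      if (!any(acc)) break
      dd <- rowSums(sweep(p[acc, , drop = FALSE], 2, xyz[j, ])^2)
      acc[acc] <- dd >= R[j]^2
    }
    area[heavy[i]] <- 4 * pi * R[i]^2 * sum(acc) / nPoints
  }
  ridx <- residueIndex(x)
  keys <- residueKeys(x)
  resarea <- vapply(seq_along(keys), function(r) sum(area[ridx == r]), 1)
  resname <- vapply(strsplit(keys, ":", fixed = TRUE), `[`, "", 4L)
  rel <- 100 * resarea / unname(MAX_SASA_GXG[resname])
  list(atomArea = area,
       residue = data.frame(key = keys, resname = resname, area = resarea,
                            relative = rel, stringsAsFactors = FALSE),
       total = sum(area))
}

#' Steric clashes between two structures
#'
#' All heavy-heavy atom pairs at or below \code{threshold} Angstrom.
#' @param a,b \code{PDBStructure} objects
#' @param threshold distance threshold, Angstrom (default 2.5)
#' @return data.frame with columns \code{i} (atom row in a), \code{j}
#'   (atom row in b), \code{dist}, plus residue keys \code{resA}, \code{resB}
#' @export
clashAtoms <- function(a, b, threshold = 2.5) {
  if (!nrow(a@atoms) || !nrow(b@atoms)) stop("both structures must be non-empty")
  ha <- which(isHeavy(a)); hb <- which(isHeavy(b))
  xa <- coords(a)[ha, , drop = FALSE]; xb <- coords(b)[hb, , drop = FALSE]
  ka <- .reskey(a@atoms); kb <- .reskey(b@atoms)
  out <- list()
  for (i in seq_along(ha)) {
    d <- sqrt(rowSums(sweep(xb, 2, xa[i, ])^2))
    hit <- which(d <= threshold)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(i = ha[i], j = hb[hit],
                                            dist = d[hit],
                                            resA = ka[ha[i]], resB = kb[hb[hit]],
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(i = integer(0), j = integer(0), dist = numeric(0),
                      resA = character(0), resB = character(0)))
  do.call(rbind, out)
}

#' SASA buried on binding
#'
#' \code{SASA(a) + SASA(b) - SASA(complex)}; non-negative for contacting
#' parts.  The parts must partition the complex atom list exactly (checked
#' via serials).
#' @param complex,partA,partB \code{PDBStructure}s
#' @param ... passed to \code{\link{shrakeRupley}}
#' @return buried area, A^2
#' @export
sasaChangeOnBinding <- function(complex, partA, partB, ...) {
  sa <- sort(c(partA@atoms$serial, partB@atoms$serial))
  if (length(intersect(partA@atoms$serial, partB@atoms$serial)))
    stop("partition error: parts share atoms")
  if (!identical(sa, sort(complex@atoms$serial)))
    stop("partition error: parts do not partition the complex")
  shrakeRupley(partA, ...)$total + shrakeRupley(partB, ...)$total -
    shrakeRupley(complex, ...)$total
}
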