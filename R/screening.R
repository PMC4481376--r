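#' @include AllGenerics.R
NULL

#' Construct a screening constraint set
#'
#' Experimental constraints a candidate complex must satisfy: required
#' antigen-side contact residues (mutagenesis/epitope-mapping evidence),
#' required residue-residue contacts, 1:2 stoichiometry feasibility via a
#' symmetry-built second ligand copy, and a buried-surface-area window
#' (default 1144-2500 A^2, the benchmark range for antibody-antigen
#' complexes).
#'
#' @param requiredContacts antigen residue keys that must be in contact
#' @param contactCutoff heavy-atom contact cutoff, A
#' @param requiredPairs data.frame(a =, b =) of residue-key pairs
#' @param stoichiometry logical: check second-copy clash freedom
#' @param clashThreshold heavy-atom clash distance, A
#' @param buriedAreaWindow length-2 numeric, A^2
#' @return a \code{ConstraintSet}
#' @export
constraintSet <- function(requiredContacts = character(0),
                          contactCutoff = 5,
                          requiredPairs = data.frame(a = character(0),
                                                     b = character(0)),
                          stoichiometry = FALSE, clashThreshold = 2.5,
                          buriedAreaWindow = c(1144, 2500)) {
  new("ConstraintSet", requiredContacts = requiredContacts,
      contactCutoff = contactCutoff, requiredPairs = requiredPairs,
      stoichiometry = stoichiometry, clashThreshold = clashThreshold,
      buriedAreaWindow = buriedAreaWindow)
}

#' Residue-residue contact list between two parts
#'
#' All residue pairs with any heavy-heavy atom distance at or below
#' \code{cutoff}.  Symmetric in the parts and monotone in the cutoff.
#'
#' @param partA,partB disjoint \code{PDBStructure}s
#' @param cutoff Angstrom (default 5)
#' @return data.frame with \code{resA, resB, minDist}
#' @export
contactList <- function(partA, partB, cutoff = 5) {
  ha <- isHeavy(partA); hb <- isHeavy(partB)
  ka <- residueKeys(partA); kb <- residueKeys(partB)
  D <- .res_min_dist(coords(partA)[ha, , drop = FALSE],
                     residueIndex(partA)[ha], length(ka),
                     coords(partB)[hb, , drop = FALSE],
                     residueIndex(partB)[hb], length(kb))
  hit <- which(D <= cutoff, arr.ind = TRUE)
  out <- data.frame(resA = ka[hit[, 1]], resB = kb[hit[, 2]],
                    minDist = D[hit], stringsAsFactors = FALSE)
  out[order(match(out$resA, ka), match(out$resB, kb)), , drop = FALSE]
}

#' Build a 1:2 assembly by domain superposition
#'
#' Places a second copy of the ligand by the transform that superposes one
#' receptor domain onto its symmetry mate (e.g. one C-epsilon-3 domain onto
#' the other), the standard construction for testing whether two antibody
#' fragments can bind one antigen simultaneously.
#'
#' @param x the 1:1 complex \code{PDBStructure}
#' @param ligandChains chains of the ligand copy to duplicate
#' @param domainA,domainB named lists of \code{\link{selectAtoms}} arguments
#'   selecting the two sequence-matched receptor domains; the transform
#'   superposes domain A onto domain B (C-alpha atoms)
#' @param relabel chain relabelling for the new copy (default: lowercase)
#' @return list with \code{assembly} (1:2 \code{PDBStructure}),
#'   \code{copy} (the placed second ligand) and \code{transform}
#' @export
buildSecondCopy <- function(x, ligandChains, domainA, domainB,
                            relabel = NULL) {
  selA <- do.call(selectAtoms, c(list(x), domainA))
  selB <- do.call(selectAtoms, c(list(x), domainB))
  caA <- coords(selA)[selA@atoms$name == "CA", , drop = FALSE]
  caB <- coords(selB)[selB@atoms$name == "CA", , drop = FALSE]
  if (nrow(caA) != nrow(caB))
    stop("pairing error: domain selections are not sequence-matched")
  sup <- superpose(caA, caB)
  lig <- selectAtoms(x, chains = ligandChains)
  copy <- applyTransform(lig, sup$transform)
  if (is.null(relabel))
    relabel <- setNames(tolower(ligandChains), ligandChains)
  list(assembly = mergeStructures(x, copy, relabel = relabel),
       copy = {
         b <- copy@atoms
         hitc <- b$chain %in% names(relabel)
         b$chain[hitc] <- relabel[b$chain[hitc]]
         new("PDBStructure", atoms = b)
       },
       transform = sup$transform)
}

#' Evaluate one pose complex against a constraint set
#'
#' Checks, in order: every required antigen contact residue appears in the
#' 5-A contact list; every required residue pair is in contact;
#' stoichiometry (a symmetry-placed second ligand copy has no heavy-atom
#' pair within the clash threshold of the antigen or the first copy);
#' buried area inside the window.  The pose is accepted iff all requested
#' constraints pass.
#'
#' @param antigen,ligand the two parts of the pose complex
#' @param constraints a \code{ConstraintSet}
#' @param secondCopy optional pre-built second ligand copy
#'   (\code{PDBStructure}) for the stoichiometry check
#' @param nPoints SASA sampling density for the buried-area constraint
#' @return list: \code{satisfied}, \code{violated} (character vectors),
#'   \code{contacts} (contact list), \code{buriedArea}, \code{accepted}
#' @export
checkPose <- function(antigen, ligand, constraints, secondCopy = NULL,
                      nPoints = 240L) {
  cl <- contactList(antigen, ligand, constraints@contactCutoff)
  satisfied <- character(0); violated <- character(0)
  mark <- function(name, ok) {
    if (ok) satisfied <<- c(satisfied, name) else violated <<- c(violated, name)
  }
  if (length(constraints@requiredContacts))
    mark("required-contacts",
         all(constraints@requiredContacts %in% cl$resA |
             constraints@requiredContacts %in% cl$resB))
  if (nrow(constraints@requiredPairs)) {
    pk <- paste(cl$resA, cl$resB)
    pk2 <- paste(cl$resB, cl$resA)
    want <- paste(constraints@requiredPairs$a, constraints@requiredPairs$b)
    mark("required-pairs", all(want %in% c(pk, pk2)))
  }
  if (constraints@stoichiometry) {
    if (is.null(secondCopy))
      mark("stoichiometry", FALSE)
    else {
      cs <- nrow(clashAtoms(secondCopy, antigen, constraints@clashThreshold)) +
        nrow(clashAtoms(secondCopy, ligand, constraints@clashThreshold))
      mark("stoichiometry", cs == 0L)
    }
  }
  buried <- NA_real_
  if (all(is.finite(constraints@buriedAreaWindow))) {
    cplx <- mergeStructures(antigen, ligand)
    buried <- shrakeRupley(antigen, nPoints = nPoints)$total +
      shrakeRupley(ligand, nPoints = nPoints)$total -
      shrakeRupley(cplx, nPoints = nPoints)$total
    mark("buried-area", buried >= constraints@buriedAreaWindow[1] &&
           buried <= constraints@buriedAreaWindow[2])
  }
  list(satisfied = satisfied, violated = violated, contacts = cl,
       buriedArea = buried, accepted = length(violated) == 0L)
}

#' Screen ranked, clustered poses against experimental constraints
#'
#' Walks clusters in order of their best member rank; within a cluster,
#' members are evaluated in rank order and the first accepted pose of the
#' best-ranked accepted cluster is returned.  If no pose is accepted the
#' result is an explicit no-model outcome, not an error.  Ties among
#' accepted poses break by most constraints satisfied, then by rank.
#'
#' @param poses ranked list of \code{Pose}s (from \code{\link{rankPoses}})
#' @param receptor,ligand \code{PDBStructure}s; each pose transform places
#'   the ligand
#' @param constraints a \code{ConstraintSet}
#' @param clusters optional cluster list from \code{\link{clusterByRMSD}}
#'   (computed from transformed-ligand coordinates at 4 A if missing)
#' @param secondCopyBuilder optional \code{function(antigen, ligand)}
#'   returning the second ligand copy for the stoichiometry check
#' @param nPoints SASA sampling density
#' @return list with \code{best} (a \code{Pose} or \code{NULL}),
#'   \code{noModel} flag and \code{report} (one row per evaluated pose)
#' @export
screenRanked <- function(poses, receptor, ligand, constraints,
                         clusters = NULL, secondCopyBuilder = NULL,
                         nPoints = 240L) {
  if (!length(poses))
    return(list(best = NULL, noModel = TRUE, report = data.frame()))
  lxyz <- coords(ligand)[isHeavy(ligand), , drop = FALSE]
  if (is.null(clusters)) {
    sets <- lapply(poses, function(p) applyTransform(lxyz, p@transform))
    clusters <- clusterByRMSD(sets, cutoff = 4)
  }
  ranks <- vapply(poses, function(p)
    if (is.na(p@rank)) .Machine$integer.max else p@rank, 1L)
  ord <- order(vapply(clusters, function(cl) min(ranks[cl$members]), 1L))
  rows <- list()
  best <- NULL; bestKey <- NULL
  for (ci in ord) {
    cl <- clusters[[ci]]
    for (m in cl$members[order(ranks[cl$members])]) {
      lig <- applyTransform(ligand, poses[[m]]@transform)
      sc <- if (!is.null(secondCopyBuilder)) secondCopyBuilder(receptor, lig)
            else NULL
      rep1 <- checkPose(receptor, lig, constraints, secondCopy = sc,
                        nPoints = nPoints)
      rows[[length(rows) + 1L]] <-
        data.frame(pose = m, cluster = ci, rank = ranks[m],
                   nSatisfied = length(rep1$satisfied),
                   nViolated = length(rep1$violated),
                   buriedArea = rep1$buriedArea,
                   accepted = rep1$accepted)
      if (rep1$accepted) {
        key <- c(-length(rep1$satisfied), ranks[m])
        if (is.null(best) || key[1] < bestKey[1] ||
            (key[1] == bestKey[1] && key[2] < bestKey[2])) {
          best <- poses[[m]]; bestKey <- key
        }
      }
    }
    if (!is.null(best)) break  # highest-ranked accepted cluster wins
  }
  list(best = best, noModel = is.null(best),
       report = do.call(rbind, rows))
}

#' Superposition-and-clash compatibility test
#'
#' Superposes the model complex onto a reference via matched alignment
#' selections (C-alpha), then reports heavy-atom clashes between a probe
#' part of the transformed model and a probe part of the reference.  This
#' is the standard test of whether a modelled binder is sterically
#' compatible with another ligand bound to the same antigen.
#'
#' @param model,reference \code{PDBStructure}s
#' @param alignModel,alignReference \code{\link{selectAtoms}} argument lists
#'   choosing matched alignment atoms in each structure
#' @param probeModel,probeReference argument lists choosing the parts to
#'   test for clashes
#' @param threshold heavy-atom clash distance, A (default 2.5)
#' @return data.frame of clash pairs (see \code{\link{clashAtoms}})
#' @export
superpositionClashTest <- function(model, reference, alignModel,
                                   alignReference, probeModel,
                                   probeReference, threshold = 2.5) {
  sm <- do.call(selectAtoms, c(list(model), alignModel))
  sr <- do.call(selectAtoms, c(list(reference), alignReference))
  caM <- coords(sm)[sm@atoms$name == "CA", , drop = FALSE]
  caR <- coords(sr)[sr@atoms$name == "CA", , drop = FALSE]
  sup <- superpose(caM, caR)
  moved <- applyTransform(model, sup$transform)
  pm <- do.call(selectAtoms, c(list(moved), probeModel))
  prb <- do.call(selectAtoms, c(list(reference), probeReference))
  clashAtoms(pm, prb, threshold)
}
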