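#' Construct alpha-carbon algorithm parameters
#'
#' @param burialRadius burial neighbourhood radius in Angstrom (default 7).
#' @param burialCount minimum neighbour count for burial (default 9).
#' @param m,s dendrogram cut parameters in Angstrom (defaults 22 and 5).
#' @param constraintDistance clamped distance for constrained pairs
#'   (default 4 Angstrom, roughly the backbone C-alpha spacing).
#' @param useSSEConstraint clamp pairs within one secondary-structure
#'   element (default TRUE).
#' @param useSheetConstraint clamp pairs within one beta-sheet (default
#'   FALSE).
#' @param minClusterFraction small-cluster deletion threshold as a fraction
#'   of the largest cluster (default 0.10).
#' @param minSegmentLen segment-absorption length threshold in residues
#'   (default 20).
#' @return a validated [CAParams-class] object.
#' @export
caParams <- function(burialRadius = 7, burialCount = 9L, m = 22, s = 5,
                     constraintDistance = 4, useSSEConstraint = TRUE,
                     useSheetConstraint = FALSE, minClusterFraction = 0.10,
                     minSegmentLen = 20L) {
  new("CAParams", burialRadius = burialRadius,
      burialCount = as.integer(burialCount), m = m, s = s,
      constraintDistance = constraintDistance,
      useSSEConstraint = useSSEConstraint,
      useSheetConstraint = useSheetConstraint,
      minClusterFraction = minClusterFraction,
      minSegmentLen = as.integer(minSegmentLen))
}

#' Classify residues as buried or exposed
#'
#' A residue is buried when at least \code{burialCount} (default 9) other
#' C-alphas lie within \code{burialRadius} (default 7 Angstrom) of its own
#' C-alpha; the residue itself is not counted. Neighbours are counted
#' across all chains of the set.
#'
#' @param calphas a [CalphaSet].
#' @param params a [CAParams-class] object.
#' @return logical vector, TRUE for buried residues.
#' @export
classifyBurial <- function(calphas, params = caParams()) {
  stopifnot(is(calphas, "CalphaSet"), is(params, "CAParams"))
  dm <- as.matrix(stats::dist(calphas@coords))
  unname(rowSums(dm <= params@burialRadius) - 1L >= params@burialCount)
}

#' Pairwise distance matrix over buried alpha-carbons
#'
#' Euclidean C-alpha distances restricted to the buried residues, with
#' optional geometric constraints: pairs of buried residues inside the same
#' secondary-structure element (and, when enabled, inside the same
#' beta-sheet) are clamped to \code{constraintDistance}, discouraging
#' domain boundaries that slice through an element or sheet.
#'
#' @param calphas a [CalphaSet].
#' @param buried logical mask from [classifyBurial()].
#' @param elements optional [SSElementSet] for the intra-element constraint.
#' @param sheets optional per-residue sheet labels (character, NA outside
#'   sheets), e.g. the \code{"sheet"} attribute of [parseDSSP()].
#' @param params a [CAParams-class] object.
#' @return symmetric distance matrix over the buried residues, in the order
#'   they appear in \code{calphas}.
#' @export
buildCaDistanceMatrix <- function(calphas, buried, elements = NULL,
                                  sheets = NULL, params = caParams()) {
  stopifnot(is(calphas, "CalphaSet"), length(buried) == nResidues(calphas))
  idx <- which(buried)
  if (length(idx) < 2L)
    stop("fewer than 2 buried residues; cannot build a distance matrix")
  dm <- as.matrix(stats::dist(calphas@coords[idx, , drop = FALSE]))
  dimnames(dm) <- NULL
  if (params@useSSEConstraint && !is.null(elements) &&
      nElements(elements) > 0L) {
    elemOf <- rep(NA_integer_, nResidues(calphas))
    for (e in seq_len(nElements(elements)))
      elemOf[elements@firstIndex[e]:elements@lastIndex[e]] <- e
    eb <- elemOf[idx]
    same <- outer(eb, eb, function(a, b) !is.na(a) & !is.na(b) & a == b)
    diag(same) <- FALSE
    dm[same] <- params@constraintDistance
  }
  if (params@useSheetConstraint && !is.null(sheets)) {
    sb <- sheets[idx]
    same <- outer(sb, sb, function(a, b) !is.na(a) & !is.na(b) & a == b)
    diag(same) <- FALSE
    dm[same] <- params@constraintDistance
  }
  dm
}

#' Clean up a raw domain assignment
#'
#' Two-stage cleanup applied after clustering:
#' \enumerate{
#'   \item small-cluster deletion: every domain with fewer residues than
#'     \code{minClusterFraction} times the largest domain's count is
#'     deleted, and each orphaned residue joins the domain of the nearest
#'     retained residue's C-alpha (ties to the lower residue index);
#'   \item segment absorption: per chain, a left-to-right scan absorbs any
#'     maximal same-domain segment shorter than \code{minSegmentLen}
#'     residues that is flanked on both sides by one same other domain, or
#'     that touches a chain end (absorbed into its single neighbour). The
#'     scan repeats until a full pass changes nothing.
#' }
#' Domains are renumbered 1..k in order of first appearance.
#'
#' @param assignment a [DomainAssignment].
#' @param params a [CAParams-class] object.
#' @return the cleaned [DomainAssignment].
#' @export
cleanupAssignment <- function(assignment, params = caParams()) {
  stopifnot(is(assignment, "DomainAssignment"))
  dom <- assignment@domain
  coords <- assignment@calphas@coords
  # (1) delete domains below the size threshold
  sizes <- table(dom)
  keepDoms <- as.integer(names(sizes)[
    sizes >= params@minClusterFraction * max(sizes)])
  orphan <- !(dom %in% keepDoms)
  if (any(orphan) && length(keepDoms) > 0L) {
    keepIdx <- which(!orphan)
    for (i in which(orphan)) {
      d2 <- colSums((t(coords[keepIdx, , drop = FALSE]) - coords[i, ])^2)
      dom[i] <- dom[keepIdx[which.min(d2)]]
    }
  }
  # (2) absorb short segments, per chain, to a fixed point
  chain <- assignment@calphas@chainId
  repeat {
    changed <- FALSE
    for (ch in unique(chain)) {
      cidx <- which(chain == ch)
      r <- rle(dom[cidx])
      if (length(r$lengths) < 2L) next
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (sgm in seq_along(r$lengths)) {
        if (r$lengths[sgm] >= params@minSegmentLen) next
        cur <- r$values[sgm]
        absorber <- NA_integer_
        if (sgm == 1L) absorber <- r$values[2L]
        else if (sgm == length(r$lengths))
          absorber <- r$values[length(r$lengths) - 1L]
        else if (r$values[sgm - 1L] == r$values[sgm + 1L])
          absorber <- r$values[sgm - 1L]
        if (!is.na(absorber) && absorber != cur) {
          dom[cidx[starts[sgm]:ends[sgm]]] <- absorber
          changed <- TRUE
          break                       # segments shifted; rescan this chain
        }
      }
      if (changed) break
    }
    if (!changed) break
  }
  dom <- as.integer(match(dom, unique(dom)))
  initialize(assignment, domain = dom)
}

#' Assign structural domains by clustering buried alpha-carbons
#'
#' The alpha-carbon pipeline: classify burial, build the (optionally
#' constrained) distance matrix over buried C-alphas, cluster with average
#' linkage, cut the dendrogram by the m/s gap rule, attach every exposed
#' residue to the cluster of its nearest buried C-alpha, then run
#' [cleanupAssignment()]. Domains may span chains: neighbour counting,
#' clustering and attachment all ignore chain boundaries, so the algorithm
#' works identically on single chains and whole complexes.
#'
#' With fewer than two buried residues (small peptides) a single-domain
#' assignment is returned with a warning.
#'
#' @param calphas a [CalphaSet].
#' @param ann optional per-residue secondary-structure annotation (from
#'   [parseDSSP()] or [readSSTable()]); used only for the intra-element /
#'   intra-sheet distance constraints.
#' @param params a [CAParams-class] object.
#' @return a [DomainAssignment].
#' @examples
#' g <- makeGlobuleStructure(globuleSpec(nDomains = 2, seed = 7))
#' assignDomainsCA(g$calphas)
#' @export
assignDomainsCA <- function(calphas, ann = NULL, params = caParams()) {
  stopifnot(is(calphas, "CalphaSet"), is(params, "CAParams"))
  n <- nResidues(calphas)
  buried <- classifyBurial(calphas, params)
  if (sum(buried) < 2L) {
    warning("fewer than 2 buried residues; returning a single domain")
    return(new("DomainAssignment", domain = rep(1L, n), calphas = calphas,
               algorithm = "ca", cutHeight = NA_real_))
  }
  elements <- NULL
  sheets <- NULL
  if (!is.null(ann)) {
    if (params@useSSEConstraint)
      elements <- extractElements(ann, calphas)
    if (params@useSheetConstraint)
      sheets <- attr(ann, "sheet")
  }
  dm <- buildCaDistanceMatrix(calphas, buried, elements, sheets, params)
  tree <- agglomerate(dm, "average")
  cut <- cutMergeTree(tree, m = params@m, s = params@s)
  idx <- which(buried)
  dom <- integer(n)
  dom[idx] <- cut@membership
  exposed <- which(!buried)
  if (length(exposed)) {
    for (i in exposed) {
      d2 <- colSums((t(calphas@coords[idx, , drop = FALSE]) -
                     calphas@coords[i, ])^2)
      dom[i] <- dom[idx[which.min(d2)]]  # which.min: first = lower index
    }
  }
  dom <- as.integer(match(dom, unique(dom)))
  raw <- new("DomainAssignment", domain = dom, calphas = calphas,
             algorithm = "ca", cutHeight = cut@cutHeight)
  cleanupAssignment(raw, params)
}
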