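#' Construct secondary-structure algorithm parameters
#'
#' @param metric element distance metric, \code{"midpoint"} (default) or
#'   \code{"closest"}.
#' @param linkage \code{"average"} (default) or \code{"complete"}.
#' @param m,s dendrogram cut parameters in Angstrom (defaults 22 and 5).
#' @param constraintDistance clamped distance for sequence-adjacent element
#'   pairs (default 4 Angstrom).
#' @param useAdjacencyConstraint clamp consecutive same-chain element pairs
#'   (default TRUE).
#' @param minClusterElements clusters with fewer elements are dissolved
#'   (default 3: one- and two-element clusters are discarded).
#' @param minElementsRequired minimum number of elements for the algorithm
#'   to run at all (default 3).
#' @return a validated [SSParams-class] object.
#' @export
ssParams <- function(metric = c("midpoint", "closest"),
                     linkage = c("average", "complete"),
                     m = 22, s = 5, constraintDistance = 4,
                     useAdjacencyConstraint = TRUE,
                     minClusterElements = 3L, minElementsRequired = 3L) {
  new("SSParams", metric = match.arg(metric), linkage = match.arg(linkage),
      m = m, s = s, constraintDistance = constraintDistance,
      useAdjacencyConstraint = useAdjacencyConstraint,
      minClusterElements = as.integer(minClusterElements),
      minElementsRequired = as.integer(minElementsRequired))
}

#' Assign structural domains by clustering secondary-structure elements
#'
#' The secondary-structure pipeline: extract element vectors, build their
#' pairwise distance matrix (midpoint or closest-approach metric, with
#' sequence-consecutive same-chain pairs optionally clamped to 4 Angstrom),
#' cluster, cut the dendrogram by the m/s gap rule, dissolve clusters of
#' fewer than \code{minClusterElements} elements (each dissolved element
#' joins the retained cluster with the smallest average distance to it),
#' then translate element clusters into residue domains: within each chain
#' a cut point is placed midway along the sequence between consecutive
#' elements that belong to different clusters, and every residue joins the
#' domain of its side of the nearest cut. Residues before the first or
#' after the last element of a chain follow that element; a chain with no
#' element at all follows the element nearest to its centroid.
#'
#' @param calphas a [CalphaSet].
#' @param ann per-residue secondary-structure annotation aligned to
#'   \code{calphas}.
#' @param params an [SSParams-class] object.
#' @return a [DomainAssignment].
#' @export
assignDomainsSS <- function(calphas, ann, params = ssParams()) {
  stopifnot(is(calphas, "CalphaSet"), is(params, "SSParams"))
  n <- nResidues(calphas)
  elements <- extractElements(ann, calphas)
  nE <- nElements(elements)
  if (nE < params@minElementsRequired)
    stop("insufficient secondary structure (", nE, " element(s), need ",
         params@minElementsRequired,
         "); use the alpha-carbon algorithm instead",
         call. = FALSE)
  dm <- elementDistance(elements, metric = params@metric)
  if (params@useAdjacencyConstraint && nE > 1L) {
    adj <- which(elements@chainId[-nE] == elements@chainId[-1])
    for (a in adj) dm[a, a + 1L] <- dm[a + 1L, a] <- params@constraintDistance
  }
  tree <- agglomerate(dm, params@linkage)
  cut <- cutMergeTree(tree, m = params@m, s = params@s)
  cl <- cut@membership
  # dissolve small clusters; orphans join the retained cluster with the
  # smallest average distance
  sizes <- table(cl)
  keep <- as.integer(names(sizes)[sizes >= params@minClusterElements])
  if (length(keep) == 0L) {
    warning("every cluster holds fewer than ", params@minClusterElements,
            " elements; returning a single domain")
    cl <- rep(1L, nE)
  } else if (length(keep) < length(sizes)) {
    for (e in which(!(cl %in% keep))) {
      avg <- vapply(keep, function(k)
        mean(dm[e, cl == k & seq_len(nE) != e]), numeric(1))
      cl[e] <- keep[which.min(avg)]
    }
  }
  cl <- as.integer(match(cl, unique(cl)))
  # element clusters -> residue domains, chain by chain
  dom <- integer(n)
  starts <- chainStarts(calphas)
  ends <- c(starts[-1] - 1L, n)
  for (ci in seq_along(starts)) {
    lo <- starts[ci]; hi <- ends[ci]
    ch <- calphas@chainId[lo]
    eIdx <- which(elements@chainId == ch)
    if (length(eIdx) == 0L) next                   # handled below
    eIdx <- eIdx[order(elements@firstIndex[eIdx])]
    bounds <- lo - 1L                              # cut after these indices
    for (k in seq_len(length(eIdx) - 1L)) {
      if (cl[eIdx[k]] != cl[eIdx[k + 1L]]) {
        p <- (elements@lastIndex[eIdx[k]] +
              elements@firstIndex[eIdx[k + 1L]]) %/% 2L
        bounds <- c(bounds, p)
      }
    }
    bounds <- c(bounds, hi)
    for (b in seq_len(length(bounds) - 1L)) {
      blockRange <- (bounds[b] + 1L):bounds[b + 1L]
      inBlock <- eIdx[elements@firstIndex[eIdx] > bounds[b] &
                      elements@firstIndex[eIdx] <= bounds[b + 1L]]
      dom[blockRange] <- cl[inBlock[1L]]
    }
  }
  # chains without any element: follow the element nearest the chain centroid
  if (any(dom == 0L)) {
    mids <- (elements@start + elements@end) / 2
    for (ci in seq_along(starts)) {
      lo <- starts[ci]; hi <- ends[ci]
      if (any(dom[lo:hi] != 0L)) next
      ctr <- colMeans(calphas@coords[lo:hi, , drop = FALSE])
      d2 <- colSums((t(mids) - ctr)^2)
      dom[lo:hi] <- cl[which.min(d2)]
    }
  }
  dom <- as.integer(match(dom, unique(dom)))
  new("DomainAssignment", domain = dom, calphas = calphas,
      algorithm = "ss", cutHeight = cut@cutHeight)
}
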