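#' @import methods
NULL

#' ProteinStructure: a parsed protein coordinate file
#'
#' Thin container for the protein atoms of one model of a PDB/mmCIF file,
#' after dropping waters, non-amino-acid heteroatoms and alternate locations
#' other than the primary one. Rows are atoms in file order; residues are
#' identified by chain id plus author residue number and insertion code.
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno} (integer,
#'   author numbering), \code{insert} (character, \code{""} when absent),
#'   \code{resid} (3-letter residue name), \code{elety} (atom name) and
#'   \code{x}, \code{y}, \code{z} (Angstrom).
#' @slot source path of the file the structure was read from.
#' @seealso [readStructure()], [extractCalphas()]
#' @export
setClass("ProteinStructure",
  representation(atoms = "data.frame", source = "character"))

setValidity("ProteinStructure", function(object) {
  need <- c("chain", "resno", "insert", "resid", "elety", "x", "y", "z")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss))
    return(paste("atoms lacks column(s):", paste(miss, collapse = ", ")))
  if (nrow(object@atoms) == 0L)
    return("structure contains no protein atoms")
  TRUE
})

#' CalphaSet: ordered alpha-carbon positions
#'
#' The substrate of the alpha-carbon domain-assignment algorithm: one point
#' per residue (the C-alpha), ordered chain-major then by position in the
#' chain. Residues without a C-alpha never appear. Residue identity is the
#' author numbering of the source file (chain, residue number, insertion
#' code), the public coordinate system of all outputs.
#'
#' @slot coords numeric N x 3 matrix of C-alpha coordinates (Angstrom).
#' @slot chainId character vector, chain id per residue.
#' @slot resno integer vector, author residue number per residue.
#' @slot insert character vector, insertion code per residue (\code{""} if
#'   none).
#' @seealso [extractCalphas()], [chainStarts()], [writeCalphaPDB()]
#' @export
setClass("CalphaSet",
  representation(coords = "matrix", chainId = "character",
                 resno = "integer", insert = "character"))

setValidity("CalphaSet", function(object) {
  n <- nrow(object@coords)
  if (n < 1L) return("CalphaSet must contain at least one residue")
  if (ncol(object@coords) != 3L) return("coords must be an N x 3 matrix")
  if (!all(is.finite(object@coords)))
    return("coords must be finite")
  if (length(object@chainId) != n || length(object@resno) != n ||
      length(object@insert) != n)
    return("chainId, resno and insert must each have one entry per residue")
  # chain-major ordering: each chain id forms one contiguous block
  r <- rle(object@chainId)
  if (anyDuplicated(r$values))
    return("residues of one chain must be contiguous (chain-major order)")
  key <- paste(object@chainId, object@resno, object@insert)
  if (anyDuplicated(key))
    return("duplicate (chain, resno, insert) residue identity")
  TRUE
})

#' SSElementSet: secondary-structure elements as 3D vectors
#'
#' Each helix or strand is reduced to a straight vector: the principal axis
#' of its C-alpha coordinates (largest eigenvector of their covariance
#' matrix), oriented N- to C-terminus, with start/end points obtained by
#' projecting the first and last C-alpha onto the axis through the element's
#' center of mass.
#'
#' @slot kind character, \code{"helix"} or \code{"strand"} per element.
#' @slot chainId character, chain each element lies in.
#' @slot firstIndex,lastIndex integer indices (1-based, into the parent
#'   [CalphaSet]) of the first and last member residue; members are the
#'   contiguous run between them.
#' @slot center numeric nE x 3: center of mass of member C-alphas.
#' @slot direction numeric nE x 3: unit axis vector, N-to-C.
#' @slot start,end numeric nE x 3: projected endpoints (Angstrom).
#' @seealso [extractElements()], [elementVector()], [elementDistance()]
#' @export
setClass("SSElementSet",
  representation(kind = "character", chainId = "character",
                 firstIndex = "integer", lastIndex = "integer",
                 center = "matrix", direction = "matrix",
                 start = "matrix", end = "matrix"))

setValidity("SSElementSet", function(object) {
  nE <- length(object@kind)
  if (!all(object@kind %in% c("helix", "strand")))
    return("kind must be 'helix' or 'strand'")
  for (s in c("center", "direction", "start", "end")) {
    m <- slot(object, s)
    if (!is.matrix(m) || nrow(m) != nE || (nE > 0L && ncol(m) != 3L))
      return(sprintf("slot '%s' must be an nE x 3 matrix", s))
  }
  if (length(object@chainId) != nE || length(object@firstIndex) != nE ||
      length(object@lastIndex) != nE)
    return("per-element slots must have equal length")
  if (nE > 0L) {
    if (any(object@lastIndex - object@firstIndex < 2L))
      return("each element must span at least 3 residues")
    nrm <- sqrt(rowSums(object@direction^2))
    if (any(abs(nrm - 1) > 1e-9))
      return("direction vectors must be unit length")
  }
  TRUE
})

#' MergeTree: an agglomerative-clustering dendrogram
#'
#' Result of [agglomerate()]: N leaves and N-1 merges, each carrying the
#' inter-cluster distance (merge height, Angstrom) at which it occurred.
#' The \code{merge} matrix uses the \code{\link[stats]{hclust}} encoding:
#' negative entries are leaves, positive entries refer to earlier merge rows.
#'
#' @slot merge integer (N-1) x 2 matrix in hclust encoding.
#' @slot height numeric merge heights, non-decreasing for average and
#'   complete linkage.
#' @slot size integer member count of the cluster formed at each merge.
#' @slot n integer, number of leaves.
#' @slot linkage \code{"average"} or \code{"complete"}.
#' @seealso [agglomerate()], [cutMergeTree()], [linkageTable()]
#' @export
setClass("MergeTree",
  representation(merge = "matrix", height = "numeric", size = "integer",
                 n = "integer", linkage = "character"))

setValidity("MergeTree", function(object) {
  n <- object@n
  if (n < 1L) return("need at least one leaf")
  if (nrow(object@merge) != n - 1L || length(object@height) != n - 1L ||
      length(object@size) != n - 1L)
    return("a tree over n leaves must have n - 1 merges")
  if (n > 1L) {
    kids <- as.vector(object@merge)
    leaves <- -kids[kids < 0]
    nodes <- kids[kids > 0]
    if (!setequal(leaves, seq_len(n)) || anyDuplicated(leaves))
      return("every leaf must appear exactly once as a child")
    if (anyDuplicated(nodes))
      return("every merge node may be used at most once as a child")
    if (object@size[n - 1L] != n)
      return("root member count must equal the number of leaves")
    if (any(diff(object@height) < -1e-9))
      return("merge heights must be non-decreasing")
  }
  TRUE
})

#' ClusterCut: a partition obtained by cutting a MergeTree
#'
#' @slot membership integer cluster label (1..k, by first appearance) per
#'   leaf.
#' @slot cutHeight numeric cut level in Angstrom; \code{NA_real_} when no cut
#'   was made (single cluster).
#' @seealso [cutMergeTree()]
#' @export
setClass("ClusterCut",
  representation(membership = "integer", cutHeight = "numeric"))

setValidity("ClusterCut", function(object) {
  k <- length(unique(object@membership))
  if (length(object@membership) < 1L) return("empty partition")
  if (!identical(sort(unique(object@membership)), seq_len(k)))
    return("membership labels must be 1..k")
  if ((k == 1L) != is.na(object@cutHeight))
    return("cutHeight must be NA exactly when a single cluster is returned")
  TRUE
})

#' DomainAssignment: per-residue structural-domain labels
#'
#' Output of both assignment algorithms: every residue of the underlying
#' [CalphaSet] carries exactly one domain index in 1..k (numbered by first
#' appearance along the sequence). [domainSegments()] derives the contiguous
#' segment representation in author numbering.
#'
#' @slot domain integer domain index per residue.
#' @slot calphas the [CalphaSet] the assignment covers.
#' @slot algorithm character tag (\code{"ca"}, \code{"ss"}, or other
#'   provenance such as \code{"reference"}/\code{"random"}).
#' @slot cutHeight numeric dendrogram cut level used (NA when none).
#' @seealso [assignDomainsCA()], [assignDomainsSS()], [domainSegments()]
#' @export
setClass("DomainAssignment",
  representation(domain = "integer", calphas = "CalphaSet",
                 algorithm = "character", cutHeight = "numeric"))

setValidity("DomainAssignment", function(object) {
  n <- nrow(object@calphas@coords)
  if (length(object@domain) != n)
    return("one domain label per residue is required")
  if (anyNA(object@domain)) return("domain labels must not be NA")
  k <- max(object@domain)
  if (!identical(sort(unique(object@domain)), seq_len(k)))
    return("domain labels must be 1..k")
  TRUE
})

#' ReferenceAssignment: a coordinate-free per-residue domain map
#'
#' Reference ("gold standard") domain assignments parsed from residue-range
#' files, and the output of the random baseline. Unlike [DomainAssignment]
#' it carries no coordinates, only residue identities.
#'
#' @slot chainId,resno,insert residue identity, as in [CalphaSet].
#' @slot domain integer domain index per residue (1..k).
#' @seealso [readReferenceTSV()], [randomAssign()], [overlapScore()]
#' @export
setClass("ReferenceAssignment",
  representation(chainId = "character", resno = "integer",
                 insert = "character", domain = "integer"))

setValidity("ReferenceAssignment", function(object) {
  n <- length(object@domain)
  if (n < 1L) return("empty assignment")
  if (length(object@chainId) != n || length(object@resno) != n ||
      length(object@insert) != n)
    return("residue identity vectors must match domain length")
  if (anyDuplicated(paste(object@chainId, object@resno, object@insert)))
    return("duplicate residue identity")
  TRUE
})

#' EvalResult: comparison of a predicted and a reference assignment
#'
#' @slot nPred,nRef integer domain counts over the shared residues.
#' @slot overlap numeric best-permutation overlap fraction in [0, 1];
#'   \code{NA_real_} when the domain counts differ (the comparison is then
#'   incorrect regardless of boundaries).
#' @slot mapping integer permutation: predicted domain i maps to reference
#'   domain \code{mapping[i]}; empty when counts differ.
#' @slot nResidues integer number of shared residues scored.
#' @seealso [overlapScore()], [isCorrect()]
#' @export
setClass("EvalResult",
  representation(nPred = "integer", nRef = "integer", overlap = "numeric",
                 mapping = "integer", nResidues = "integer"))

#' Parameters of the alpha-carbon assignment algorithm
#'
#' Defaults are the operating point of the method: burial = at least 9 other
#' C-alphas within 7 Angstrom; dendrogram cut with m = 22, s = 5; intra-element
#' pairs clamped to 4 Angstrom (on by default), same-sheet clamping off;
#' clusters under 10% of the largest deleted; segments under 20 residues
#' absorbed.
#'
#' @slot burialRadius,burialCount burial rule: buried iff at least
#'   \code{burialCount} other C-alphas lie within \code{burialRadius}.
#' @slot m,s dendrogram cut parameters (Angstrom): minimum cut height and
#'   gap step size.
#' @slot constraintDistance distance (Angstrom) substituted for constrained
#'   pairs.
#' @slot useSSEConstraint clamp intra-element C-alpha pairs to
#'   \code{constraintDistance}.
#' @slot useSheetConstraint clamp same-beta-sheet pairs likewise (off by
#'   default).
#' @slot minClusterFraction clusters smaller than this fraction of the
#'   largest are deleted during cleanup.
#' @slot minSegmentLen sequence segments shorter than this are absorbed
#'   during cleanup.
#' @seealso [caParams()], [assignDomainsCA()]
#' @export
setClass("CAParams",
  representation(burialRadius = "numeric", burialCount = "integer",
                 m = "numeric", s = "numeric",
                 constraintDistance = "numeric",
                 useSSEConstraint = "logical",
                 useSheetConstraint = "logical",
                 minClusterFraction = "numeric",
                 minSegmentLen = "integer"))

setValidity("CAParams", function(object) {
  pos <- c(burialRadius = object@burialRadius,
           burialCount = object@burialCount, m = object@m, s = object@s,
           constraintDistance = object@constraintDistance,
           minSegmentLen = object@minSegmentLen)
  if (any(pos <= 0)) return("all numeric parameters must be positive")
  if (object@minClusterFraction <= 0 || object@minClusterFraction >= 1)
    return("minClusterFraction must lie in (0, 1)")
  TRUE
})

#' Parameters of the secondary-structure assignment algorithm
#'
#' Defaults are the operating point of the method: midpoint distance metric,
#' average linkage, m = 22, s = 5, sequence-adjacent elements clamped to 4
#' Angstrom, clusters of one or two elements dissolved, at least 3 elements
#' required to run.
#'
#' @slot metric \code{"midpoint"} (distance between vector midpoints) or
#'   \code{"closest"} (closest approach of the two segments).
#' @slot linkage \code{"average"} or \code{"complete"}.
#' @slot m,s dendrogram cut parameters (Angstrom).
#' @slot constraintDistance distance substituted for adjacent element pairs.
#' @slot useAdjacencyConstraint clamp sequence-consecutive same-chain
#'   element pairs to \code{constraintDistance}.
#' @slot minClusterElements clusters with fewer elements than this are
#'   dissolved (default 3, i.e. one- and two-element clusters go).
#' @slot minElementsRequired minimum element count for the algorithm to run.
#' @seealso [ssParams()], [assignDomainsSS()]
#' @export
setClass("SSParams",
  representation(metric = "character", linkage = "character",
                 m = "numeric", s = "numeric",
                 constraintDistance = "numeric",
                 useAdjacencyConstraint = "logical",
                 minClusterElements = "integer",
                 minElementsRequired = "integer"))

setValidity("SSParams", function(object) {
  if (!object@metric %in% c("midpoint", "closest"))
    return("metric must be 'midpoint' or 'closest'")
  if (!object@linkage %in% c("average", "complete"))
    return("linkage must be 'average' or 'complete'")
  if (object@m <= 0 || object@s <= 0 || object@constraintDistance <= 0)
    return("m, s and constraintDistance must be positive")
  if (object@minClusterElements < 1L || object@minElementsRequired < 1L)
    return("element count thresholds must be at least 1")
  TRUE
})
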