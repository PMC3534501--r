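#' Number of residues in an object
#' @param x a [CalphaSet], [DomainAssignment] or [ReferenceAssignment].
#' @return integer residue count.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' C-alpha coordinates
#' @param x a [CalphaSet] or an object carrying one.
#' @return numeric N x 3 matrix (Angstrom).
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))

#' Per-residue chain identifiers
#' @param x an object with residue identities.
#' @return character vector.
#' @export
setGeneric("chainIds", function(x) standardGeneric("chainIds"))

#' Per-residue author residue numbers
#' @param x an object with residue identities.
#' @return integer vector.
#' @export
setGeneric("resNumbers", function(x) standardGeneric("resNumbers"))

#' Indices at which a new chain begins
#' @param x a [CalphaSet].
#' @return integer vector of 1-based start indices, first element always 1.
#' @export
setGeneric("chainStarts", function(x) standardGeneric("chainStarts"))

#' Number of assigned domains
#' @param x a [DomainAssignment], [ReferenceAssignment] or [EvalResult].
#' @return integer domain count.
#' @export
setGeneric("nDomains", function(x) standardGeneric("nDomains"))

#' Per-residue domain labels
#' @param x a [DomainAssignment] or [ReferenceAssignment].
#' @return integer vector of domain indices (1..k).
#' @export
setGeneric("domainLabels", function(x) standardGeneric("domainLabels"))

#' Contiguous-segment representation of an assignment
#'
#' Collapses the per-residue domain map into maximal same-domain segments in
#' author numbering, the interchange representation (\code{domain chain
#' start end}) used by the TSV output and reference files.
#'
#' @param x a [DomainAssignment] or [ReferenceAssignment].
#' @return data.frame with columns \code{domain}, \code{chain},
#'   \code{startRes}, \code{endRes}.
#' @export
setGeneric("domainSegments", function(x) standardGeneric("domainSegments"))

#' Number of elements in a set of secondary-structure elements
#' @param x an [SSElementSet].
#' @return integer element count.
#' @export
setGeneric("nElements", function(x) standardGeneric("nElements"))
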