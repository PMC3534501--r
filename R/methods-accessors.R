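#' @describeIn nResidues residues in a CalphaSet
#' @export
setMethod("nResidues", "CalphaSet", function(x) nrow(x@coords))

#' @describeIn nResidues residues covered by an assignment
#' @export
setMethod("nResidues", "DomainAssignment", function(x) length(x@domain))

#' @describeIn nResidues residues covered by a reference assignment
#' @export
setMethod("nResidues", "ReferenceAssignment", function(x) length(x@domain))

#' @describeIn caCoords coordinates of a CalphaSet
#' @export
setMethod("caCoords", "CalphaSet", function(x) x@coords)

#' @describeIn caCoords coordinates underlying an assignment
#' @export
setMethod("caCoords", "DomainAssignment", function(x) x@calphas@coords)

#' @describeIn chainIds chain ids of a CalphaSet
#' @export
setMethod("chainIds", "CalphaSet", function(x) x@chainId)

#' @describeIn chainIds chain ids of a reference assignment
#' @export
setMethod("chainIds", "ReferenceAssignment", function(x) x@chainId)

#' @describeIn resNumbers residue numbers of a CalphaSet
#' @export
setMethod("resNumbers", "CalphaSet", function(x) x@resno)

#' @describeIn resNumbers residue numbers of a reference assignment
#' @export
setMethod("resNumbers", "ReferenceAssignment", function(x) x@resno)

#' @describeIn chainStarts chain start indices of a CalphaSet
#' @export
setMethod("chainStarts", "CalphaSet", function(x) {
  r <- rle(x@chainId)
  as.integer(cumsum(c(1L, r$lengths[-length(r$lengths)])))
})

#' @describeIn nDomains domains of an assignment
#' @export
setMethod("nDomains", "DomainAssignment", function(x) max(x@domain))

#' @describeIn nDomains domains of a reference assignment
#' @export
setMethod("nDomains", "ReferenceAssignment", function(x) max(x@domain))

#' @describeIn domainLabels labels of an assignment
#' @export
setMethod("domainLabels", "DomainAssignment", function(x) x@domain)

#' @describeIn domainLabels labels of a reference assignment
#' @export
setMethod("domainLabels", "ReferenceAssignment", function(x) x@domain)

#' @describeIn nElements element count
#' @export
setMethod("nElements", "SSElementSet", function(x) length(x@kind))

# shared segment builder over (chain, resno, domain) in sequence order
.segmentsFromResidues <- function(chain, resno, domain) {
  n <- length(domain)
  brk <- which(domain[-1] != domain[-n] | chain[-1] != chain[-n])
  starts <- c(1L, brk + 1L)
  ends <- c(brk, n)
  data.frame(domain = domain[starts], chain = chain[starts],
             startRes = resno[starts], endRes = resno[ends],
             stringsAsFactors = FALSE)
}

#' @describeIn domainSegments segments of a DomainAssignment
#' @export
setMethod("domainSegments", "DomainAssignment", function(x) {
  .segmentsFromResidues(x@calphas@chainId, x@calphas@resno, x@domain)
})

#' @describeIn domainSegments segments of a ReferenceAssignment
#' @export
setMethod("domainSegments", "ReferenceAssignment", function(x) {
  .segmentsFromResidues(x@chainId, x@resno, x@domain)
})

# internal: uniform residue table for evaluation
.residueTable <- function(x) {
  if (is(x, "DomainAssignment"))
    data.frame(chain = x@calphas@chainId, resno = x@calphas@resno,
               insert = x@calphas@insert, domain = x@domain,
               stringsAsFactors = FALSE)
  else if (is(x, "ReferenceAssignment"))
    data.frame(chain = x@chainId, resno = x@resno, insert = x@insert,
               domain = x@domain, stringsAsFactors = FALSE)
  else stop("expected a DomainAssignment or ReferenceAssignment")
}

setMethod("show", "ProteinStructure", function(object) {
  a <- object@atoms
  cat("ProteinStructure:", length(unique(a$chain)), "chain(s),",
      length(unique(paste(a$chain, a$resno, a$insert))), "residues,",
      nrow(a), "atoms\n")
})

setMethod("show", "CalphaSet", function(object) {
  cs <- rle(object@chainId)
  cat("CalphaSet:", nResidues(object), "C-alpha(s) in",
      length(cs$values), "chain(s) [",
      paste(sprintf("%s:%d", cs$values, cs$lengths), collapse = ", "), "]\n")
})

setMethod("show", "SSElementSet", function(object) {
  cat("SSElementSet:", nElements(object), "element(s) (",
      sum(object@kind == "helix"), "helix,",
      sum(object@kind == "strand"), "strand )\n")
})

setMethod("show", "MergeTree", function(object) {
  cat("MergeTree:", object@n, "leaves,", object@linkage, "linkage",
      if (object@n > 1L)
        sprintf("; root height %.2f A", object@height[object@n - 1L])
      else "", "\n")
})

setMethod("show", "ClusterCut", function(object) {
  k <- length(unique(object@membership))
  cat("ClusterCut:", k, "cluster(s)",
      if (is.na(object@cutHeight)) "(no cut made)"
      else sprintf("at cut height %.2f A", object@cutHeight), "\n")
})

setMethod("show", "DomainAssignment", function(object) {
  cat("DomainAssignment (", object@algorithm, "): ",
      nDomains(object), " domain(s) over ", nResidues(object),
      " residues", sep = "")
  if (!is.na(object@cutHeight))
    cat(sprintf(", cut at %.2f A", object@cutHeight))
  cat("\n")
  seg <- domainSegments(object)
  str <- vapply(split(seg, seg$domain), function(s)
    paste(sprintf("%s:%d-%d", s$chain, s$startRes, s$endRes),
          collapse = ","), character(1))
  for (d in names(str)) cat("  domain ", d, ": ", str[[d]], "\n", sep = "")
})

setMethod("show", "ReferenceAssignment", function(object) {
  cat("ReferenceAssignment:", nDomains(object), "domain(s) over",
      nResidues(object), "residues\n")
})

setMethod("show", "EvalResult", function(object) {
  cat("EvalResult: predicted", object@nPred, "vs reference", object@nRef,
      "domains over", object@nResidues, "residues")
  if (!is.na(object@overlap))
    cat(sprintf("; best-permutation overlap %.3f", object@overlap))
  cat("\n")
})
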