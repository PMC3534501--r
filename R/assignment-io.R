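#' Write a domain assignment as a segment TSV
#'
#' Four tab-separated columns, no header: \code{domain}, \code{chain},
#' \code{start_res}, \code{end_res} (inclusive author numbering), one row
#' per contiguous segment, preceded by a comment-free summary line
#' \code{k=<count>}. The same format is accepted by [readReferenceTSV()],
#' so assignments round-trip into references for evaluation.
#'
#' @param assignment a [DomainAssignment] or [ReferenceAssignment].
#' @param path output file.
#' @param perResidue also append a per-residue two-column dump
#'   (\code{chain:resno<TAB>domain}) after the segments (default FALSE).
#' @return \code{path}, invisibly.
#' @export
writeAssignmentTSV <- function(assignment, path, perResidue = FALSE) {
  seg <- domainSegments(assignment)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("k=", max(seg$domain)), con)
  utils::write.table(seg, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (perResidue) {
    rt <- .residueTable(assignment)
    writeLines(paste0(rt$chain, ":", rt$resno, rt$insert, "\t", rt$domain),
               con)
  }
  invisible(path)
}

#' Read a reference domain assignment from a residue-range TSV
#'
#' Accepts the segment format written by [writeAssignmentTSV()]: rows of
#' \code{domain<TAB>chain<TAB>start<TAB>end} with inclusive author-numbered
#' ranges (1-based, as printed in PDB files). A leading \code{k=...}
#' summary line and blank or \code{#}-comment lines are ignored.
#'
#' @param path TSV file.
#' @return a [ReferenceAssignment].
#' @export
readReferenceTSV <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|k=|$)", lines)]
  lines <- lines[!grepl("^[^\t]+:[0-9]", lines)]   # per-residue dump rows
  if (length(lines) == 0L) stop("no segment rows in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 4L)
  if (length(bad))
    stop("malformed segment row ", bad[1], " in ", path)
  seg <- data.frame(
    domain = as.integer(vapply(parts, `[`, "", 1L)),
    chain = vapply(parts, `[`, "", 2L),
    startRes = as.integer(vapply(parts, `[`, "", 3L)),
    endRes = as.integer(vapply(parts, `[`, "", 4L)),
    stringsAsFactors = FALSE)
  if (anyNA(seg$domain) || anyNA(seg$startRes) || anyNA(seg$endRes))
    stop("non-numeric domain or residue bounds in ", path)
  chain <- character(0); resno <- integer(0); domain <- integer(0)
  for (r in seq_len(nrow(seg))) {
    rng <- seg$startRes[r]:seg$endRes[r]
    chain <- c(chain, rep(seg$chain[r], length(rng)))
    resno <- c(resno, rng)
    domain <- c(domain, rep(seg$domain[r], length(rng)))
  }
  dom <- as.integer(match(domain, unique(domain)))
  new("ReferenceAssignment", chainId = chain, resno = resno,
      insert = rep("", length(resno)), domain = dom)
}

#' Parse or format compact domain strings
#'
#' Compact interchange form \code{"A:1-120,A:200-250"} for one domain:
#' comma-separated \code{chain:start-end} ranges.
#'
#' @param x for \code{parseDomainString}, a character vector of domain
#'   strings (one per domain); for \code{formatDomainStrings}, a
#'   [DomainAssignment] or [ReferenceAssignment].
#' @return \code{parseDomainString}: a [ReferenceAssignment];
#'   \code{formatDomainStrings}: character vector, one string per domain.
#' @export
parseDomainString <- function(x) {
  chain <- character(0); resno <- integer(0); domain <- integer(0)
  for (d in seq_along(x)) {
    for (piece in strsplit(x[d], ",", fixed = TRUE)[[1]]) {
      mm <- regmatches(piece,
        regexec("^\\s*([^:]+):(-?[0-9]+)-(-?[0-9]+)\\s*$", piece))[[1]]
      if (length(mm) != 4L)
        stop("malformed range '", piece, "' (expected chain:start-end)")
      rng <- as.integer(mm[3]):as.integer(mm[4])
      chain <- c(chain, rep(mm[2], length(rng)))
      resno <- c(resno, rng)
      domain <- c(domain, rep(d, length(rng)))
    }
  }
  new("ReferenceAssignment", chainId = chain, resno = resno,
      insert = rep("", length(resno)), domain = as.integer(domain))
}

#' @rdname parseDomainString
#' @export
formatDomainStrings <- function(x) {
  seg <- domainSegments(x)
  vapply(split(seg, seg$domain), function(s)
    paste(sprintf("%s:%d-%d", s$chain, s$startRes, s$endRes),
          collapse = ","), character(1))
}
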