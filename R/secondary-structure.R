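#' Parse a classic DSSP output file into a per-residue annotation
#'
#' Reads the fixed-column residue block of a classic DSSP file and aligns it
#' to a [CalphaSet] by (chain, author residue number, insertion code).
#' DSSP structure codes H, G and I map to \code{"H"} (helix), E to
#' \code{"E"} (strand), everything else to \code{"C"} (coil). Residues of
#' the CalphaSet absent from the DSSP file become coil; a chain wholly
#' absent triggers a warning.
#'
#' The returned vector carries the DSSP beta-sheet label (column 34) of each
#' residue as attribute \code{"sheet"} (\code{NA} outside strands), used by
#' the optional same-sheet constraint of the alpha-carbon algorithm.
#'
#' @param path DSSP output file.
#' @param calphas the [CalphaSet] the annotation is for.
#' @return character vector in \code{c("H","E","C")}, one per residue, with
#'   attribute \code{"sheet"}.
#' @seealso [readSSTable()] for the plain-TSV alternative.
#' @export
parseDSSP <- function(path, calphas) {
  stopifnot(is(calphas, "CalphaSet"))
  if (!file.exists(path)) stop("DSSP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L)
    stop("not a classic DSSP file (no '  #  RESIDUE' header): ", path)
  body <- lines[seq(hdr[1] + 1L, length(lines))]
  body <- body[nchar(body) >= 17]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]                      # chain-break separator rows
  if (length(body) == 0L) stop("DSSP file has no residue records: ", path)
  resno <- suppressWarnings(as.integer(substr(body, 6, 10)))
  insert <- trimws(substr(body, 11, 11))
  chain <- substr(body, 12, 12)
  chain[chain == " "] <- " "
  ssCode <- substr(body, 17, 17)
  sheet <- trimws(substr(body, 34, 34))
  ok <- !is.na(resno)
  dkey <- paste(chain, resno, insert, sep = "\r")[ok]
  ss <- ssCode[ok]
  sheet <- sheet[ok]
  ckey <- paste(calphas@chainId, calphas@resno, calphas@insert, sep = "\r")
  hit <- match(ckey, dkey)
  if (all(is.na(hit)))
    stop("no residue of the structure was found in the DSSP file ",
         "(chain ids / numbering mismatch?)")
  missingChains <- setdiff(unique(calphas@chainId),
                           unique(calphas@chainId[!is.na(hit)]))
  if (length(missingChains))
    warning("chain(s) absent from DSSP file, treated as all-coil: ",
            paste(missingChains, collapse = ", "))
  lab <- rep("C", length(ckey))
  code <- ss[hit[!is.na(hit)]]
  lab[!is.na(hit)] <- ifelse(code %in% c("H", "G", "I"), "H",
                             ifelse(code == "E", "E", "C"))
  sh <- rep(NA_character_, length(ckey))
  shHit <- sheet[hit[!is.na(hit)]]
  shHit[shHit == ""] <- NA_character_
  sh[!is.na(hit)] <- shHit
  sh[lab != "E"] <- NA_character_
  attr(lab, "sheet") <- sh
  lab
}

#' Read a per-residue secondary-structure table (TSV)
#'
#' Three tab-separated columns without header: chain id, author residue
#' number, label. Labels H/G/I map to helix, E to strand, anything else to
#' coil. Residues not listed default to coil. This is the format-agnostic
#' route for annotations from any assignment program.
#'
#' @param path TSV file.
#' @param calphas the [CalphaSet] the annotation is for.
#' @return character vector in \code{c("H","E","C")}, one per residue.
#' @export
readSSTable <- function(path, calphas) {
  stopifnot(is(calphas, "CalphaSet"))
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = c("character", "integer",
                                          "character"),
                           col.names = c("chain", "resno", "label"))
  dkey <- paste(tab$chain, tab$resno, sep = "\r")
  ckey <- paste(calphas@chainId, calphas@resno, sep = "\r")
  hit <- match(ckey, dkey)
  if (all(is.na(hit)))
    stop("no residue of the structure was found in the annotation table")
  lab <- rep("C", length(ckey))
  code <- toupper(tab$label[hit[!is.na(hit)]])
  lab[!is.na(hit)] <- ifelse(code %in% c("H", "G", "I"), "H",
                             ifelse(code == "E", "E", "C"))
  lab
}

#' Principal-axis vector of a secondary-structure element
#'
#' The element's direction is the unit eigenvector of the 3x3 covariance
#' matrix of its C-alpha coordinates with the largest eigenvalue, oriented
#' N- to C-terminus (flipped if necessary so that it points from the first
#' member residue r1 towards the last, r2). The vector's endpoints are the
#' projections of r1 and r2 onto the axis through the center of mass c:
#' start = c + ((r1 - c) . v) v and end = c + ((r2 - c) . v) v.
#'
#' @param coords numeric n x 3 matrix of member C-alpha coordinates
#'   (n >= 3).
#' @param r1,r2 coordinates of the first and last member residue.
#' @return list with components \code{center}, \code{direction},
#'   \code{start}, \code{end}.
#' @examples
#' p <- cbind(0, 0, 0:3)
#' elementVector(p, p[1, ], p[4, ])$direction   # (0, 0, 1)
#' @export
elementVector <- function(coords, r1, r2) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3L) stop("an element needs at least 3 points")
  ctr <- colMeans(coords)
  cen <- sweep(coords, 2, ctr)
  if (max(abs(cen)) < 1e-12)
    stop("degenerate element geometry: all points coincide")
  cv <- crossprod(cen) / nrow(coords)
  eg <- eigen(cv, symmetric = TRUE)
  v <- eg$vectors[, 1]
  # near-equal top eigenvalues: no unique principal axis; pick
  # deterministically the candidate with the largest |x|, then |y|
  if (eg$values[1] - eg$values[2] < 1e-9 * max(eg$values[1], 1)) {
    warning("principal-axis tie in element covariance; ",
            "choosing axis deterministically")
    cand <- eg$vectors[, eg$values[1] - eg$values < 1e-9 *
                         max(eg$values[1], 1), drop = FALSE]
    pick <- order(-round(abs(cand[1, ]), 9), -abs(cand[2, ]))[1]
    v <- cand[, pick]
  }
  if (sum(v * (r2 - r1)) < 0) v <- -v
  list(center = ctr, direction = v,
       start = ctr + sum((r1 - ctr) * v) * v,
       end = ctr + sum((r2 - ctr) * v) * v)
}

# chain-break positions inside a CalphaSet: TRUE at i means a break between
# residue i and i+1 (new chain, numbering gap, or CA-CA distance > 4.5 A)
.breakAfter <- function(calphas, maxGap = 4.5) {
  n <- nResidues(calphas)
  if (n < 2L) return(logical(0))
  d <- sqrt(rowSums((calphas@coords[-1, , drop = FALSE] -
                     calphas@coords[-n, , drop = FALSE])^2))
  newChain <- calphas@chainId[-1] != calphas@chainId[-n]
  numGap <- (calphas@resno[-1] - calphas@resno[-n] > 1L) &
    calphas@insert[-1] == "" & calphas@insert[-n] == ""
  newChain | numGap | d > maxGap
}

#' Extract secondary-structure elements as vectors
#'
#' Finds maximal runs of identical helix/strand labels, splits them at chain
#' boundaries and chain breaks (consecutive C-alpha distance above 4.5
#' Angstrom or a gap in author numbering), demotes runs shorter than
#' \code{minLen} to coil, and converts each surviving run into a vector
#' via [elementVector()].
#'
#' @param ann per-residue annotation from [parseDSSP()] or [readSSTable()].
#' @param calphas the [CalphaSet] the annotation is aligned to.
#' @param minLen minimum member count of an element (default 3).
#' @return an [SSElementSet] (possibly empty).
#' @export
extractElements <- function(ann, calphas, minLen = 3L) {
  stopifnot(is(calphas, "CalphaSet"))
  n <- nResidues(calphas)
  if (length(ann) != n)
    stop("annotation length (", length(ann),
         ") does not match residue count (", n, ")")
  brk <- .breakAfter(calphas)
  # run id increments on label change or chain break
  chg <- c(TRUE, ann[-1] != ann[-n] | brk)
  runId <- cumsum(chg)
  keepKind <- c(H = "helix", E = "strand")
  firsts <- integer(0); lasts <- integer(0); kinds <- character(0)
  for (rid in unique(runId)) {
    idx <- which(runId == rid)
    lab <- ann[idx[1]]
    if (lab %in% names(keepKind) && length(idx) >= minLen) {
      firsts <- c(firsts, idx[1]); lasts <- c(lasts, idx[length(idx)])
      kinds <- c(kinds, keepKind[[lab]])
    }
  }
  nE <- length(firsts)
  ctr <- dir <- st <- en <- matrix(numeric(0), 0, 3)
  if (nE > 0L) {
    ctr <- dir <- st <- en <- matrix(0, nE, 3)
    for (e in seq_len(nE)) {
      idx <- firsts[e]:lasts[e]
      ev <- elementVector(calphas@coords[idx, , drop = FALSE],
                          calphas@coords[firsts[e], ],
                          calphas@coords[lasts[e], ])
      ctr[e, ] <- ev$center; dir[e, ] <- ev$direction
      st[e, ] <- ev$start; en[e, ] <- ev$end
    }
  }
  new("SSElementSet", kind = kinds,
      chainId = calphas@chainId[firsts],
      firstIndex = as.integer(firsts), lastIndex = as.integer(lasts),
      center = ctr, direction = dir, start = st, end = en)
}

# minimum distance between 3D segments [p1,q1] and [p2,q2]
# (clamped closest-point computation; Ericson, Real-Time Collision
# Detection, 5.1.9)
.segmentDistance <- function(p1, q1, p2, q2) {
  d1 <- q1 - p1; d2 <- q2 - p2; r <- p1 - p2
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  tiny <- 1e-12
  if (a <= tiny && e <= tiny) return(sqrt(sum(r * r)))
  if (a <= tiny) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    cc <- sum(d1 * r)
    if (e <= tiny) {
      t <- 0; s <- min(max(-cc / a, 0), 1)
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > tiny) min(max((b * f - cc * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-cc / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - cc) / a, 0), 1) }
    }
  }
  v <- (p1 + s * d1) - (p2 + t * d2)
  sqrt(sum(v * v))
}

#' Distance between two secondary-structure elements
#'
#' Either the Euclidean distance between the midpoints of the two element
#' vectors (\code{"midpoint"}), or the distance of closest approach of the
#' two 3D segments spanned by their start/end points (\code{"closest"}).
#'
#' @param elements an [SSElementSet].
#' @param i,j element indices (1-based). When omitted, the full pairwise
#'   matrix over all elements is returned.
#' @param metric \code{"midpoint"} or \code{"closest"}.
#' @return a single distance in Angstrom, or the symmetric matrix.
#' @export
elementDistance <- function(elements, i = NULL, j = NULL,
                            metric = c("midpoint", "closest")) {
  metric <- match.arg(metric)
  stopifnot(is(elements, "SSElementSet"))
  nE <- nElements(elements)
  if (is.null(i) != is.null(j))
    stop("give both i and j, or neither")
  one <- function(a, b) {
    if (metric == "midpoint") {
      ma <- (elements@start[a, ] + elements@end[a, ]) / 2
      mb <- (elements@start[b, ] + elements@end[b, ]) / 2
      sqrt(sum((ma - mb)^2))
    } else {
      .segmentDistance(elements@start[a, ], elements@end[a, ],
                       elements@start[b, ], elements@end[b, ])
    }
  }
  if (!is.null(i)) return(one(i, j))
  dm <- matrix(0, nE, nE)
  if (nE > 1L)
    for (a in seq_len(nE - 1L)) for (b in (a + 1L):nE)
      dm[a, b] <- dm[b, a] <- one(a, b)
  dm
}
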