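#' Read a protein structure from a PDB or mmCIF file
#'
#' Parses the coordinate file (via \pkg{bio3d}), keeps the first model only,
#' drops waters and heteroatoms that are not amino acids (modified residues
#' with a recognised amino-acid parent, such as MSE, are retained), and keeps
#' only the primary alternate location (\code{''} or \code{'A'}). Author
#' residue numbering and insertion codes are preserved.
#'
#' @param path path to the structure file.
#' @param format \code{"pdb"}, \code{"mmcif"}, or \code{"auto"} (decide from
#'   the file extension; \code{.cif}/\code{.mmcif} are mmCIF, anything else
#'   PDB).
#' @return a [ProteinStructure].
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeCalphaPDB(makeGlobuleStructure(globuleSpec(seed = 1))$calphas, pdb)
#' readStructure(pdb)
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  raw <- tryCatch(
    if (format == "pdb")
      suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE,
                                       verbose = FALSE))
    else
      suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = TRUE,
                                       verbose = FALSE)),
    error = function(e)
      stop("failed to parse ", format, " file '", path, "': ",
           conditionMessage(e), call. = FALSE))
  at <- raw$atom
  # amino-acid residues only: standard ATOM records, or heteroatoms whose
  # residue name maps to an amino-acid one-letter code (MSE etc.)
  aa1 <- suppressWarnings(bio3d::aa321(at$resid))
  keep <- at$type == "ATOM" | (at$type == "HETATM" & aa1 != "X")
  keep <- keep & !(at$resid %in% c("HOH", "WAT", "DOD"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("no protein residues found in '", path, "'")
  atoms <- data.frame(
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid),
    elety = as.character(at$elety),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE)
  atoms$chain[is.na(atoms$chain)] <- " "
  new("ProteinStructure", atoms = atoms, source = path)
}

#' Extract the ordered alpha-carbon set of a structure
#'
#' Selects the requested chains (all by default) and keeps one C-alpha per
#' residue, in chain-major order. Residues lacking a C-alpha are omitted
#' with a warning.
#'
#' @param structure a [ProteinStructure] from [readStructure()].
#' @param chains optional character vector of chain ids to keep, in the
#'   order they appear in the file.
#' @return a [CalphaSet].
#' @export
extractCalphas <- function(structure, chains = NULL) {
  stopifnot(is(structure, "ProteinStructure"))
  at <- structure@atoms
  avail <- unique(at$chain)
  if (!is.null(chains)) {
    bad <- setdiff(chains, avail)
    if (length(bad))
      stop("unknown chain id(s): ", paste(bad, collapse = ", "),
           "; available: ", paste(avail, collapse = ", "))
    at <- at[at$chain %in% chains, , drop = FALSE]
  }
  key <- paste(at$chain, at$resno, at$insert, sep = "\r")
  resKeys <- unique(key)                      # file order = chain-major
  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno, ca$insert, sep = "\r")), ,
           drop = FALSE]
  caKeys <- paste(ca$chain, ca$resno, ca$insert, sep = "\r")
  nMissing <- length(setdiff(resKeys, caKeys))
  if (nMissing > 0L)
    warning(nMissing, " residue(s) lack a C-alpha and were omitted")
  if (nrow(ca) == 0L)
    stop("no C-alpha atoms in the selected chains")
  ord <- order(match(caKeys, resKeys))
  ca <- ca[ord, , drop = FALSE]
  new("CalphaSet",
      coords = unname(as.matrix(ca[, c("x", "y", "z")])),
      chainId = ca$chain, resno = ca$resno, insert = ca$insert)
}

#' Write a CalphaSet as a minimal PDB file
#'
#' Emits one CA ATOM record per residue (residue name ALA throughout, since
#' the set carries no sequence), suitable as a round-trip fixture or for
#' visualisation.
#'
#' @param calphas a [CalphaSet].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeCalphaPDB <- function(calphas, path) {
  stopifnot(is(calphas, "CalphaSet"))
  n <- nResidues(calphas)
  suppressWarnings(bio3d::write.pdb(
    file = path,
    xyz = as.vector(t(calphas@coords)),
    resno = calphas@resno,
    chain = calphas@chainId,
    insert = calphas@insert,
    resid = rep("ALA", n),
    elety = rep("CA", n)))
  invisible(path)
}
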