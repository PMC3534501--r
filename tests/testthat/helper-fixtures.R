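# ---- text-fixture builders (all fixtures are generated in code) ----------

# one PDB ATOM/HETATM record (fixed-column format)
pdbAtomLine <- function(serial, elety, resid, chain, resno, x, y, z,
                        type = "ATOM", altloc = " ", icode = " ",
                        element = "C") {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f%10s%2s",
          type, serial, paste0(" ", elety), altloc, resid, chain, resno,
          icode, x, y, z, 1, 0, "", element)
}

# minimal CA-trace PDB text for given coordinate matrix / chains / resnos
pdbText <- function(coords, chain, resno, resid = NULL, icode = NULL) {
  n <- nrow(coords)
  if (is.null(resid)) resid <- rep("ALA", n)
  if (is.null(icode)) icode <- rep(" ", n)
  lines <- vapply(seq_len(n), function(i)
    pdbAtomLine(i, "CA", resid[i], chain[i], resno[i],
                coords[i, 1], coords[i, 2], coords[i, 3],
                icode = icode[i]), character(1))
  c(lines, "END")
}

writeTempPDB <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# the same content as an mmCIF atom_site loop (standard PDB field order)
mmcifText <- function(coords, chain, resno, resid = NULL) {
  n <- nrow(coords)
  if (is.null(resid)) resid <- rep("ALA", n)
  flds <- c("group_PDB", "id", "type_symbol", "label_atom_id",
            "label_alt_id", "label_comp_id", "label_asym_id",
            "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
            "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
            "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
            "auth_comp_id", "auth_asym_id", "auth_atom_id",
            "pdbx_PDB_model_num")
  rows <- sprintf(
    "ATOM %d C CA . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s CA 1",
    seq_len(n), resid, chain, seq_len(n),
    coords[, 1], coords[, 2], coords[, 3], resno, resid, chain)
  c("data_fixture", "#", "loop_", paste0("_atom_site.", flds), rows, "#")
}

# classic DSSP residue block; ss/sheet are per-residue character vectors
dsspText <- function(chain, resno, ss, sheet = NULL, icode = NULL) {
  n <- length(resno)
  if (is.null(sheet)) sheet <- rep(" ", n)
  if (is.null(icode)) icode <- rep(" ", n)
  rows <- vapply(seq_len(n), function(i) {
    head17 <- sprintf("%5d%5d%1s%1s %1s  %1s", i, resno[i], icode[i],
                      chain[i], "A", ss[i])
    paste0(head17, strrep(" ", 16), sheet[i])
  }, character(1))
  c("==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
    rows)
}

writeTempFile <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# quick CalphaSet constructor for in-code fixtures
makeCalphaSet <- function(coords, chain = NULL, resno = NULL) {
  n <- nrow(coords)
  if (is.null(chain)) chain <- rep("A", n)
  if (is.null(resno)) resno <- ave(seq_len(n), chain, FUN = seq_along)
  new("CalphaSet", coords = as.matrix(coords), chainId = chain,
      resno = as.integer(resno), insert = rep("", n))
}

# random rigid-body transform applied to an N x 3 matrix
rigidTransform <- function(coords, seed = 1) {
  set.seed(seed)
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)), 3, 3, byrow = TRUE)
  tr <- stats::runif(3, -30, 30)
  sweep(coords %*% t(R), 2, tr, `+`)
}

# ---- independent oracles ---------------------------------------------------

# naive O(N^3) agglomeration: inter-cluster distances recomputed from the
# original matrix at every step (no Lance-Williams recurrence); clusters
# are kept in creation order, scan order gives the lexicographic tie-break
naiveAgglomerate <- function(dm, linkage = "average") {
  n <- nrow(dm)
  clusters <- as.list(seq_len(n))      # member leaf sets, creation order
  active <- seq_along(clusters)
  heights <- numeric(0)
  partitions <- list()                 # membership after each merge
  while (length(active) > 1L) {
    best <- NULL; bestD <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (b <= a) next
        A <- clusters[[active[a]]]; B <- clusters[[active[b]]]
        cross <- dm[A, B, drop = FALSE]
        dd <- if (linkage == "average") mean(cross) else max(cross)
        if (dd < bestD) { bestD <- dd; best <- c(a, b) }
      }
    }
    merged <- c(clusters[[active[best[1]]]], clusters[[active[best[2]]]])
    clusters[[length(clusters) + 1L]] <- merged
    active <- c(active[-best], length(clusters))
    heights <- c(heights, bestD)
    mem <- integer(n)
    for (ci in seq_along(active)) mem[clusters[[active[ci]]]] <- ci
    partitions[[length(partitions) + 1L]] <- normalizeLabels(mem)
  }
  list(heights = heights, partitions = partitions)
}

normalizeLabels <- function(x) as.integer(match(x, unique(x)))

# exact assignment-problem maximum by subset dynamic programming
# (independent of both the exhaustive-permutation and the augmenting-path
# code in the package)
assignmentMaxOracle <- function(score) {
  k <- nrow(score)
  best <- rep(-Inf, bitwShiftL(1L, k))
  best[1] <- 0
  for (mask in 0:(bitwShiftL(1L, k) - 1L)) {
    if (!is.finite(best[mask + 1L])) next
    i <- sum(bitwAnd(bitwShiftR(mask, 0:(k - 1L)), 1L)) + 1L  # next row
    if (i > k) next
    for (j in seq_len(k)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) > 0L) next
      nxt <- bitwOr(mask, bit) + 1L
      cand <- best[mask + 1L] + score[i, j]
      if (cand > best[nxt]) best[nxt] <- cand
    }
  }
  best[bitwShiftL(1L, k)]
}

# dense-sampling lower bound for segment-segment closest approach
sampledSegmentDistance <- function(p1, q1, p2, q2, grid = 1000L) {
  s <- seq(0, 1, length.out = grid)
  A <- outer(s, q1 - p1) + rep(p1, each = grid)
  B <- outer(s, q2 - p2) + rep(p2, each = grid)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  sqrt(max(min(d2), 0))
}

# reference assignment from a plain per-residue domain vector on chain A
refFromLabels <- function(domain, chain = NULL, resno = NULL) {
  n <- length(domain)
  if (is.null(chain)) chain <- rep("A", n)
  if (is.null(resno)) resno <- ave(seq_len(n), chain, FUN = seq_along)
  new("ReferenceAssignment", chainId = chain, resno = as.integer(resno),
      insert = rep("", n), domain = normalizeLabels(as.integer(domain)))
}

# prediction carried by a DomainAssignment over dummy collinear coordinates
predFromLabels <- function(domain, chain = NULL, resno = NULL) {
  n <- length(domain)
  cs <- makeCalphaSet(cbind(seq_len(n) * 3.8, 0, 0), chain, resno)
  new("DomainAssignment", domain = normalizeLabels(as.integer(domain)),
      calphas = cs, algorithm = "test", cutHeight = NA_real_)
}
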