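#' Validate a pairwise distance matrix
#'
#' @param dm numeric N x N matrix: symmetric, non-negative, zero diagonal.
#' @return the matrix, invisibly, after validation.
#' @export
validateDistanceMatrix <- function(dm) {
  if (!is.matrix(dm) || !is.numeric(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be a square numeric matrix")
  if (any(!is.finite(dm))) stop("distance matrix must be finite")
  if (any(dm < 0)) stop("distance matrix must be non-negative")
  if (any(abs(dm - t(dm)) > 1e-9))
    stop("distance matrix must be symmetric (tolerance 1e-9)")
  if (any(diag(dm) != 0)) stop("distance matrix diagonal must be zero")
  invisible(dm)
}

#' Agglomerative clustering of a distance matrix
#'
#' Classic hierarchical agglomeration: starting from singleton clusters, the
#' globally closest pair of clusters is merged at each of the N-1 steps, and
#' distances to the new cluster follow the linkage recurrence — average
#' linkage \eqn{d(A \cup B, C) = (|A| d(A,C) + |B| d(B,C)) / (|A|+|B|)}
#' (the mean over all cross pairs), complete linkage the maximum. Ties on
#' the minimum distance are broken deterministically by the lexicographically
#' smallest (older cluster id, younger cluster id) pair, where leaves are
#' ids 1..N in input order and merged clusters receive ids N+1, N+2, ... in
#' creation order; the whole pipeline is therefore bit-for-bit reproducible.
#'
#' @param dm distance matrix (see [validateDistanceMatrix()]), entries in
#'   Angstrom.
#' @param linkage \code{"average"} or \code{"complete"}.
#' @return a [MergeTree].
#' @examples
#' dm <- matrix(c(0, 1, 4, 1, 0, 6, 4, 6, 0), 3, 3)
#' agglomerate(dm, "average")   # merges at heights 1 and 5
#' @export
agglomerate <- function(dm, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  validateDistanceMatrix(dm)
  n <- nrow(dm)
  if (n == 1L)
    return(new("MergeTree", merge = matrix(integer(0), 0, 2),
               height = numeric(0), size = integer(0), n = 1L,
               linkage = linkage))
  # active clusters keyed by creation id; id <= n are leaves
  id <- seq_len(n)            # ids of active clusters, always increasing
  sz <- rep(1L, n)            # sizes, parallel to id
  node <- -seq_len(n)         # hclust encoding of each active cluster
  D <- dm
  diag(D) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  size <- integer(n - 1L)
  for (step in seq_len(n - 1L)) {
    # first minimum in column-major upper triangle of D (rows/cols follow
    # ascending creation id) == lexicographic (older, younger) tie-break
    nAct <- length(id)
    Dut <- D
    Dut[lower.tri(Dut, diag = TRUE)] <- Inf
    flat <- which.min(t(Dut))          # row-major scan: (1,2),(1,3),...,(2,3)
    i <- (flat - 1L) %/% nAct + 1L
    j <- (flat - 1L) %% nAct + 1L
    h <- D[i, j]
    merge[step, ] <- c(node[i], node[j])
    height[step] <- h
    size[step] <- sz[i] + sz[j]
    others <- setdiff(seq_len(nAct), c(i, j))
    dNew <- if (linkage == "average")
      (sz[i] * D[i, others] + sz[j] * D[j, others]) / (sz[i] + sz[j])
    else
      pmax(D[i, others], D[j, others])
    # drop i and j, append the new cluster (largest id so far)
    D <- D[others, others, drop = FALSE]
    D <- rbind(cbind(D, dNew), c(dNew, Inf))
    id <- c(id[others], n + step)
    sz <- c(sz[others], size[step])
    node <- c(node[others], step)
  }
  new("MergeTree", merge = merge, height = height, size = size,
      n = as.integer(n), linkage = linkage)
}

#' Cut a dendrogram at the first sufficiently wide merge gap
#'
#' Implements the gap-based cut rule with two parameters: \code{m}, the
#' minimum cut height, and \code{s}, the step size. Starting at the root
#' height D, the procedure descends:
#' \enumerate{
#'   \item if D < m, stop without cutting (single cluster);
#'   \item if no merge node lies in the half-open interval [D - s, D), cut
#'     at c = D - s/2;
#'   \item otherwise move D down to the greatest merge height in
#'     [D - s, D) and repeat.
#' }
#' Because the interval (D - s, D) contains no merge when a cut is made, the
#' partition is identical for any cut level in that gap; c = D - s/2 is a
#' canonical representative. Clusters are the maximal groups of leaves
#' joined only by merges below c.
#'
#' @param tree a [MergeTree].
#' @param m minimum cut height in Angstrom (default 22).
#' @param s step size in Angstrom (default 5).
#' @return a [ClusterCut]; its \code{cutHeight} is \code{NA} when no cut was
#'   made.
#' @export
cutMergeTree <- function(tree, m = 22, s = 5) {
  stopifnot(is(tree, "MergeTree"), m > 0, s > 0)
  n <- tree@n
  if (n == 1L)
    return(new("ClusterCut", membership = 1L, cutHeight = NA_real_))
  h <- tree@height
  D <- h[n - 1L]                     # root height
  repeat {
    if (D < m)
      return(new("ClusterCut", membership = rep(1L, n),
                 cutHeight = NA_real_))
    inGap <- h[h >= D - s & h < D]
    if (length(inGap) == 0L) {
      cc <- D - s / 2
      return(new("ClusterCut", membership = .cutAtHeight(tree, cc),
                 cutHeight = cc))
    }
    D <- max(inGap)
  }
}

# membership labels (1..k, by first leaf appearance) for a cut strictly
# below height cc: union leaves over merges with height < cc
.cutAtHeight <- function(tree, cc) {
  n <- tree@n
  grp <- seq_len(n)
  repLeaf <- integer(max(n - 1L, 0L))  # one leaf inside each merge's subtree
  for (k in seq_len(n - 1L)) {
    ch <- tree@merge[k, ]
    a <- if (ch[1] < 0) -ch[1] else repLeaf[ch[1]]
    b <- if (ch[2] < 0) -ch[2] else repLeaf[ch[2]]
    if (tree@height[k] < cc) grp[grp == grp[b]] <- grp[a]
    repLeaf[k] <- a
  }
  as.integer(match(grp, unique(grp)))
}

#' Export a MergeTree as a linkage table
#'
#' Generic (left, right, height, count) text representation for debugging
#' and plotting; left/right use the hclust child encoding (negative =
#' leaf index, positive = earlier row).
#'
#' @param tree a [MergeTree].
#' @param path optional file path; when given, a TSV is written there.
#' @return the table as a data.frame (invisibly when \code{path} is given).
#' @export
linkageTable <- function(tree, path = NULL) {
  stopifnot(is(tree, "MergeTree"))
  tab <- data.frame(left = tree@merge[, 1], right = tree@merge[, 2],
                    height = tree@height, count = tree@size)
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' @title Convert a MergeTree to an hclust object
#' @description Enables plotting and interoperation with \pkg{stats}
#'   dendrogram tooling. The merge order is preserved; the leaf order is
#'   computed by \code{stats} conventions.
#' @param x a [MergeTree].
#' @param ... ignored.
#' @return an object of class \code{hclust}.
#' @export
as.hclust.MergeTree <- function(x, ...) {
  if (x@n < 2L) stop("cannot convert a single-leaf tree to hclust")
  ord <- .leafOrder(x)
  structure(list(merge = x@merge, height = x@height, order = ord,
                 labels = as.character(seq_len(x@n)),
                 method = x@linkage, call = match.call(),
                 dist.method = "euclidean"),
            class = "hclust")
}

.leafOrder <- function(tree) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(tree@merge[node, 1]), rec(tree@merge[node, 2]))
  }
  rec(tree@n - 1L)
}
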