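# shortest-augmenting-path solver for the linear assignment problem
# (maximisation, square cost matrix); used when the domain count exceeds
# the exhaustive-permutation limit
.assignmentMax <- function(score) {
  n <- nrow(score)
  cost <- max(score) - score               # minimise
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n) + 1L) {
        if (used[j]) next
        cur <- cost[i0, j - 1L] - u[i0] - v[j]
        if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
        if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
      }
      for (j in seq_len(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == 1L) break
    }
  }
  perm <- integer(n)
  for (j in seq_len(n) + 1L) if (p[j] > 0L) perm[p[j]] <- j - 1L
  perm
}

# all permutations of 1..k in lexicographic order (k! rows)
.permutations <- function(k) {
  if (k == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1L)
  out <- matrix(0L, 0, k)
  for (first in seq_len(k)) {
    rest <- setdiff(seq_len(k), first)
    out <- rbind(out, cbind(first, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

#' Score a predicted assignment against a reference
#'
#' Residues are matched by (chain, residue number, insertion code);
#' residues present in only one of the two assignments are dropped with a
#' warning. When the two domain counts differ the comparison is over
#' (\code{overlap} is NA): a prediction with the wrong number of domains is
#' incorrect regardless of boundaries. When counts agree, the overlap is
#' the maximum, over all bijections between predicted and reference domain
#' labels, of the fraction of residues whose mapped labels agree; the
#' search is exhaustive for up to 8 domains (lexicographically first
#' permutation on ties) and an optimal-assignment solver beyond.
#'
#' @param pred a [DomainAssignment] (or [ReferenceAssignment]).
#' @param ref a [ReferenceAssignment] (or [DomainAssignment]).
#' @return an [EvalResult].
#' @examples
#' # 100 residues, predicted split 50/50 vs reference split 60/40
#' pred <- randomAssign(100, c(0, 1), seed = 1)     # k = 2, equal split
#' ref <- new("ReferenceAssignment", chainId = rep("A", 100),
#'            resno = 1:100, insert = rep("", 100),
#'            domain = rep(1:2, c(60, 40)))
#' overlapScore(pred, ref)    # overlap 0.90
#' @export
overlapScore <- function(pred, ref) {
  pt <- .residueTable(pred)
  rt <- .residueTable(ref)
  pk <- paste(pt$chain, pt$resno, pt$insert, sep = "\r")
  rk <- paste(rt$chain, rt$resno, rt$insert, sep = "\r")
  shared <- intersect(pk, rk)
  if (length(shared) == 0L)
    stop("the two assignments share no residues")
  nDropped <- (length(pk) - length(shared)) + (length(rk) - length(shared))
  if (nDropped > 0L)
    warning(nDropped, " residue(s) present in only one assignment ",
            "were dropped")
  a <- pt$domain[match(shared, pk)]
  b <- rt$domain[match(shared, rk)]
  a <- as.integer(match(a, sort(unique(a))))
  b <- as.integer(match(b, sort(unique(b))))
  kp <- max(a); kr <- max(b)
  nShared <- length(shared)
  if (kp != kr)
    return(new("EvalResult", nPred = kp, nRef = kr, overlap = NA_real_,
               mapping = integer(0), nResidues = as.integer(nShared)))
  agree <- table(factor(a, levels = seq_len(kp)),
                 factor(b, levels = seq_len(kp)))
  agree <- matrix(as.numeric(agree), kp, kp)
  if (kp <= 8L) {
    perms <- .permutations(kp)
    scores <- apply(perms, 1, function(pm)
      sum(agree[cbind(seq_len(kp), pm)]))
    best <- which.max(scores)           # first maximum = lexicographic tie
    mapping <- perms[best, ]
    ov <- scores[best] / nShared
  } else {
    mapping <- .assignmentMax(agree)
    ov <- sum(agree[cbind(seq_len(kp), mapping)]) / nShared
  }
  new("EvalResult", nPred = kp, nRef = kr, overlap = ov,
      mapping = as.integer(mapping), nResidues = as.integer(nShared))
}

#' Is an assignment correct at a given overlap threshold?
#'
#' Correct means: same number of domains as the reference, and a
#' best-permutation overlap at or above the threshold (0.75 by default; the
#' stricter boundary benchmark uses 0.90).
#'
#' @param result an [EvalResult] from [overlapScore()].
#' @param threshold overlap fraction required (default 0.75).
#' @return logical flag.
#' @export
isCorrect <- function(result, threshold = 0.75) {
  stopifnot(is(result, "EvalResult"))
  result@nPred == result@nRef && !is.na(result@overlap) &&
    result@overlap >= threshold
}

#' Matthews correlation coefficient per domain-count class
#'
#' Treats "predicted k domains" vs "reference has k domains" as a binary
#' classification over a set of chains and computes
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' with the convention that a zero factor in the denominator yields 0.
#'
#' @param records two-column matrix or data.frame of (n_pred, n_ref) domain
#'   counts, one row per chain.
#' @param k the domain-count class to score.
#' @return MCC value in [-1, 1].
#' @examples
#' mccPerClass(cbind(c(2, 2, 1), c(2, 2, 1)), k = 2)  # perfect -> 1
#' @export
mccPerClass <- function(records, k) {
  records <- as.matrix(records)
  stopifnot(ncol(records) == 2L, nrow(records) >= 1L)
  predPos <- records[, 1] == k
  refPos <- records[, 2] == k
  tp <- sum(predPos & refPos); tn <- sum(!predPos & !refPos)
  fp <- sum(predPos & !refPos); fn <- sum(!predPos & refPos)
  den <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Random baseline domain assigner
#'
#' Draws a domain count k from a supplied domains-per-chain distribution
#' and splits the sequence into k contiguous, equal-as-possible blocks
#' (earlier blocks take the extra residue). The default distribution puts
#' 75% of the mass on single-domain chains — the single-domain fraction of
#' the non-redundant SCOP-derived set this baseline accompanies — spread as
#' 0.75/0.17/0.06/0.02 over 1..4 domains. The true domains-per-chain
#' distribution of the full SCOP hierarchy is not published; supply your
#' own when you have one.
#'
#' @param chainLength number of residues (single chain "A", numbered 1..n).
#' @param dist probability vector over domain counts 1..K; normalised
#'   internally.
#' @param seed integer seed making the draw reproducible.
#' @return a [ReferenceAssignment] carrying the random domains.
#' @export
randomAssign <- function(chainLength, dist = c(0.75, 0.17, 0.06, 0.02),
                         seed = NULL) {
  stopifnot(chainLength >= 1L, all(dist >= 0), sum(dist) > 0)
  dist <- dist / sum(dist)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  k <- sample.int(length(dist), 1L, prob = dist)
  if (k > chainLength) {
    warning("drawn domain count ", k, " exceeds chain length; clamped")
    k <- chainLength
  }
  base <- chainLength %/% k
  extra <- chainLength %% k
  sizes <- rep(base, k) + as.integer(seq_len(k) <= extra)
  new("ReferenceAssignment",
      chainId = rep("A", chainLength),
      resno = seq_len(chainLength),
      insert = rep("", chainLength),
      domain = rep(seq_len(k), sizes))
}
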