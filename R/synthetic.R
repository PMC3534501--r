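#' Specification of a synthetic multi-domain globule
#'
#' Describes a pseudo-protein built from compact globular point clouds of
#' C-alpha positions: one self-avoiding 3.8-Angstrom-step random walk per
#' domain, each confined to a sphere, with sphere centers placed on a line.
#' Defaults model the canonical two-domain test condition: 60 residues per
#' domain packed into 10-Angstrom spheres 40 Angstrom apart, one chain.
#'
#' @param nDomains number of domains (default 2).
#' @param residuesPerDomain residues in each domain (default 60).
#' @param centerSeparation distance between consecutive sphere centers in
#'   Angstrom (default 40).
#' @param packingRadius confinement sphere radius in Angstrom (default 10).
#' @param minContactSpacing minimum non-bonded point separation in Angstrom
#'   (default 3.0; the bond step itself is fixed at 3.8, the canonical
#'   consecutive C-alpha distance).
#' @param nChains number of chains the concatenated walk is split into
#'   (default 1).
#' @param seed integer seed; the generated structure is a deterministic
#'   function of the spec including the seed.
#' @return a validated list of class \code{"GlobuleSpec"}.
#' @export
globuleSpec <- function(nDomains = 2L, residuesPerDomain = 60L,
                        centerSeparation = 40, packingRadius = 10,
                        minContactSpacing = 3.0, nChains = 1L,
                        seed = 1L) {
  stopifnot(nDomains >= 1L, residuesPerDomain >= 1L,
            centerSeparation >= 0, packingRadius > 0,
            minContactSpacing > 0, nChains >= 1L)
  structure(list(nDomains = as.integer(nDomains),
                 residuesPerDomain = as.integer(residuesPerDomain),
                 centerSeparation = centerSeparation,
                 packingRadius = packingRadius,
                 minContactSpacing = minContactSpacing,
                 nChains = as.integer(nChains),
                 seed = as.integer(seed)),
            class = "GlobuleSpec")
}

# one self-avoiding random walk of n steps of length `step`, confined to a
# sphere (center, radius), keeping >= minSep from all points in `avoid` and
# from its own non-bonded points; bounded retries, NULL on failure
.selfAvoidingWalk <- function(n, center, radius, step, minSep, avoid,
                              maxStepTries = 200L) {
  pts <- matrix(NA_real_, n, 3)
  # random start inside the sphere (rejection from the bounding cube)
  repeat {
    p <- center + stats::runif(3, -radius, radius)
    if (sum((p - center)^2) <= radius^2) break
  }
  pts[1, ] <- p
  for (i in seq_len(n - 1L)) {
    placed <- FALSE
    for (try in seq_len(maxStepTries)) {
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      q <- pts[i, ] + step * u
      if (sum((q - center)^2) > radius^2) next
      prev <- pts[seq_len(max(i - 1L, 0L)), , drop = FALSE]
      if (nrow(prev) && min(colSums((t(prev) - q)^2)) < minSep^2) next
      if (nrow(avoid) && min(colSums((t(avoid) - q)^2)) < minSep^2) next
      pts[i + 1L, ] <- q
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  pts
}

#' Generate a synthetic globular structure with known domains
#'
#' Builds one confined self-avoiding random walk per domain (3.8-Angstrom
#' bond steps, non-bonded points at least \code{minContactSpacing} apart,
#' enforced across domains as well so overlapping spheres stay physical),
#' places the sphere centers on the x-axis \code{centerSeparation} apart,
#' concatenates the walks, and splits the result into \code{nChains}
#' contiguous chains labelled A, B, ... with sequential author numbering
#' from 1 within each chain.
#'
#' @param spec a [globuleSpec()].
#' @param maxWalkRestarts restart budget per domain walk before giving up
#'   (default 100).
#' @return list with components \code{calphas} (a [CalphaSet]) and
#'   \code{reference} (a [ReferenceAssignment] holding the ground-truth
#'   per-residue domain labels).
#' @examples
#' g <- makeGlobuleStructure(globuleSpec(nDomains = 2, seed = 42))
#' nResidues(g$calphas)      # 120
#' nDomains(g$reference)     # 2
#' @export
makeGlobuleStructure <- function(spec, maxWalkRestarts = 100L) {
  stopifnot(inherits(spec, "GlobuleSpec"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  coords <- matrix(numeric(0), 0, 3)
  for (d in seq_len(spec$nDomains)) {
    center <- c((d - 1L) * spec$centerSeparation, 0, 0)
    walk <- NULL
    for (attempt in seq_len(maxWalkRestarts)) {
      # when spheres overlap heavily (small separations) the fixed radius
      # can be geometrically unpackable; let it swell slowly, as fused
      # domains do, rather than fail: +10% every 20 exhausted restarts
      radius <- spec$packingRadius * 1.1^((attempt - 1L) %/% 20L)
      walk <- .selfAvoidingWalk(spec$residuesPerDomain, center,
                                radius, 3.8,
                                spec$minContactSpacing, coords)
      if (!is.null(walk)) break
    }
    if (is.null(walk))
      stop("could not pack ", spec$residuesPerDomain, " residues into a ",
           spec$packingRadius, " Angstrom sphere after ", maxWalkRestarts,
           " restarts; the spec is infeasible")
    coords <- rbind(coords, walk)
  }
  n <- nrow(coords)
  domain <- rep(seq_len(spec$nDomains), each = spec$residuesPerDomain)
  chainLen <- rep(n %/% spec$nChains, spec$nChains) +
    as.integer(seq_len(spec$nChains) <= n %% spec$nChains)
  chainId <- rep(LETTERS[seq_len(spec$nChains)], chainLen)
  resno <- unlist(lapply(chainLen, seq_len), use.names = FALSE)
  calphas <- new("CalphaSet", coords = coords, chainId = chainId,
                 resno = as.integer(resno), insert = rep("", n))
  reference <- new("ReferenceAssignment", chainId = chainId,
                   resno = as.integer(resno), insert = rep("", n),
                   domain = as.integer(domain))
  list(calphas = calphas, reference = reference)
}

#' Ideal alpha-helix C-alpha coordinates
#'
#' Canonical helical spiral: 1.5 Angstrom rise and 100 degrees of turn per
#' residue at 2.3 Angstrom radius, about an arbitrary axis; residue 1 sits
#' at the origin end of the axis.
#'
#' @param nRes number of residues (at least 3).
#' @param axis direction of the helix axis (any non-zero 3-vector;
#'   normalised internally).
#' @param rise rise per residue in Angstrom (default 1.5).
#' @param radius helix radius in Angstrom (default 2.3).
#' @param turnDeg rotation per residue in degrees (default 100).
#' @param origin coordinates of the axis start (default the origin).
#' @return numeric nRes x 3 matrix.
#' @examples
#' h <- makeIdealHelix(12, axis = c(1, 0, 0))
#' diff(range(h[, 1]))       # 16.5 = 11 * 1.5
#' @export
makeIdealHelix <- function(nRes, axis = c(0, 0, 1), rise = 1.5,
                           radius = 2.3, turnDeg = 100,
                           origin = c(0, 0, 0)) {
  stopifnot(nRes >= 3L)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("axis must be a non-zero vector")
  a <- axis / nrm
  # orthonormal frame perpendicular to the axis
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * a) * a
  u <- u / sqrt(sum(u^2))
  w <- c(a[2] * u[3] - a[3] * u[2],
         a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  t <- seq_len(nRes) - 1
  ang <- t * turnDeg * pi / 180
  pts <- outer(t * rise, a) + radius * (outer(cos(ang), u) +
                                        outer(sin(ang), w))
  sweep(pts, 2, origin, `+`)
}
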