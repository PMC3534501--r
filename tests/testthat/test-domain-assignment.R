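test_that("burial classification follows the 9-within-7-Angstrom rule", {
  # single isolated point -> exposed
  expect_false(classifyBurial(makeCalphaSet(matrix(0, 1, 3))))
  # a point surrounded by exactly 9 others on a 6 A sphere -> buried
  set.seed(3)
  th <- acos(runif(9, -1, 1)); ph <- runif(9, 0, 2 * pi)
  shell <- 6 * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  cs <- makeCalphaSet(rbind(c(0, 0, 0), shell))
  expect_true(classifyBurial(cs)[1])
  # with only 8 neighbours it stays exposed (count excludes self)
  cs8 <- makeCalphaSet(rbind(c(0, 0, 0), shell[1:8, ]))
  expect_false(classifyBurial(cs8)[1])
  # neighbours beyond 7 A do not count
  far <- 7.5 * cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  expect_false(classifyBurial(makeCalphaSet(rbind(c(0, 0, 0), far)))[1])
})

test_that("burial flags equal a brute-force all-pairs count on a globule", {
  g <- makeGlobuleStructure(globuleSpec(nDomains = 2,
                                        residuesPerDomain = 100,
                                        seed = 12))
  cs <- g$calphas
  got <- classifyBurial(cs)
  n <- nResidues(cs)
  brute <- logical(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_len(n)) {
      if (j == i) next
      if (sqrt(sum((cs@coords[i, ] - cs@coords[j, ])^2)) <= 7) cnt <- cnt + 1L
    }
    brute[i] <- cnt >= 9L
  }
  expect_identical(got, brute)
  expect_gt(sum(got), 0)
})

test_that("constrained distance matrix clamps intra-element and sheet pairs", {
  # two residues 17 A apart, in different elements
  coords <- rbind(cbind(0:5 * 3.4, 0, 0), cbind(0:5 * 3.4, 17, 0))
  cs <- makeCalphaSet(coords)
  buried <- rep(TRUE, 12)
  els <- new("SSElementSet", kind = c("helix", "helix"),
             chainId = c("A", "A"), firstIndex = c(1L, 7L),
             lastIndex = c(6L, 12L),
             center = matrix(0, 2, 3), direction = matrix(c(1, 0, 0,
                                                            1, 0, 0),
                                                          2, 3, TRUE),
             start = matrix(0, 2, 3), end = matrix(0, 2, 3))
  dm <- buildCaDistanceMatrix(cs, buried, els, params = caParams())
  expect_equal(dm[1, 7], 17)                 # across elements: Euclidean
  expect_equal(dm[1, 6], 4)                  # same element: clamped
  expect_equal(dm[7, 12], 4)
  # constraint off: pure Euclidean everywhere
  dmOff <- buildCaDistanceMatrix(cs, buried, els,
                                 params = caParams(useSSEConstraint = FALSE))
  expect_equal(dmOff[1, 6], 3.4 * 5)
  diffs <- which(dm != dmOff, arr.ind = TRUE)
  elemOf <- rep(1:2, each = 6)
  expect_true(all(elemOf[diffs[, 1]] == elemOf[diffs[, 2]]))
  # sheet constraint clamps same-sheet pairs when enabled
  sheets <- c(rep("S", 6), rep(NA, 6))
  dmSheet <- buildCaDistanceMatrix(cs, buried, NULL, sheets,
    caParams(useSheetConstraint = TRUE, useSSEConstraint = FALSE))
  expect_equal(dmSheet[1, 6], 4)
  expect_equal(dmSheet[7, 12], 3.4 * 5)
  # fewer than two buried residues is an error
  expect_error(buildCaDistanceMatrix(cs, c(TRUE, rep(FALSE, 11))),
               "buried")
})

test_that("cleanup deletes small clusters and absorbs short segments", {
  # domains of sizes 100 and 5: the 5-residue domain is deleted
  g <- makeGlobuleStructure(globuleSpec(nDomains = 1,
                                        residuesPerDomain = 105, seed = 2))
  asn <- new("DomainAssignment",
             domain = rep(c(1L, 2L), c(100L, 5L)), calphas = g$calphas,
             algorithm = "test", cutHeight = NA_real_)
  cleaned <- cleanupAssignment(asn, caParams())
  expect_equal(nDomains(cleaned), 1L)
  # A x30, B x10, A x30 -> B absorbed
  g2 <- makeGlobuleStructure(globuleSpec(nDomains = 1,
                                         residuesPerDomain = 70, seed = 4))
  asn2 <- new("DomainAssignment",
              domain = rep(c(1L, 2L, 1L), c(30L, 10L, 30L)),
              calphas = g2$calphas, algorithm = "test",
              cutHeight = NA_real_)
  # sizes 60 vs 10: survives the 10% rule (10 >= 6), absorbed by the scan
  expect_equal(nDomains(cleanupAssignment(asn2, caParams())), 1L)
  # A x30, B x25, A x30 -> unchanged (25 >= 20)
  g3 <- makeGlobuleStructure(globuleSpec(nDomains = 1,
                                         residuesPerDomain = 85, seed = 6))
  dom3 <- rep(c(1L, 2L, 1L), c(30L, 25L, 30L))
  asn3 <- new("DomainAssignment", domain = dom3, calphas = g3$calphas,
              algorithm = "test", cutHeight = NA_real_)
  expect_equal(domainLabels(cleanupAssignment(asn3, caParams())), dom3)
  # a short segment at a chain end is consumed by its single neighbour
  asn4 <- new("DomainAssignment",
              domain = rep(c(2L, 1L), c(10L, 75L)), calphas = g3$calphas,
              algorithm = "test", cutHeight = NA_real_)
  out4 <- cleanupAssignment(asn4, caParams())
  expect_equal(nDomains(out4), 1L)
  # a short segment flanked by two DIFFERENT domains is left untouched
  dom5 <- rep(c(1L, 3L, 2L), c(35L, 15L, 35L))
  asn5 <- new("DomainAssignment", domain = dom5, calphas = g3$calphas,
              algorithm = "test", cutHeight = NA_real_)
  out5 <- cleanupAssignment(asn5, caParams(minClusterFraction = 0.10))
  expect_equal(nDomains(out5), 3L)
})

test_that("two separated globules split into two exact domains", {
  okBoth <- 0L
  for (seed in 1:12) {
    g <- makeGlobuleStructure(globuleSpec(nDomains = 2, seed = seed))
    a <- assignDomainsCA(g$calphas)
    r <- overlapScore(a, g$reference)
    if (nDomains(a) == 2L && !is.na(r@overlap) && r@overlap == 1)
      okBoth <- okBoth + 1L
  }
  expect_gte(okBoth, 11L)
  # one globule stays one domain
  g1 <- makeGlobuleStructure(globuleSpec(nDomains = 1, seed = 31))
  expect_equal(nDomains(assignDomainsCA(g1$calphas)), 1L)
})

test_that("assignments are complete, deterministic and rigid-body invariant", {
  g <- makeGlobuleStructure(globuleSpec(nDomains = 2, seed = 77))
  a1 <- assignDomainsCA(g$calphas)
  a2 <- assignDomainsCA(g$calphas)
  expect_identical(domainLabels(a1), domainLabels(a2))
  expect_equal(length(domainLabels(a1)), nResidues(g$calphas))
  expect_true(all(domainLabels(a1) >= 1L))
  # rotated + translated copy gives the identical assignment
  csR <- new("CalphaSet", coords = rigidTransform(g$calphas@coords, 5),
             chainId = g$calphas@chainId, resno = g$calphas@resno,
             insert = g$calphas@insert)
  aR <- assignDomainsCA(csR)
  expect_identical(domainLabels(aR), domainLabels(a1))
  # segments reconstruct the per-residue map exactly
  seg <- domainSegments(a1)
  rebuilt <- integer(0)
  for (r in seq_len(nrow(seg)))
    rebuilt <- c(rebuilt, rep(seg$domain[r],
                              seg$endRes[r] - seg$startRes[r] + 1L))
  expect_equal(rebuilt, domainLabels(a1))
})

test_that("the CA pipeline partitions residues across chains jointly", {
  g <- makeGlobuleStructure(globuleSpec(nDomains = 2, nChains = 2,
                                        seed = 19))
  a <- assignDomainsCA(g$calphas)
  expect_equal(length(domainLabels(a)), 120L)
  expect_equal(sort(unique(chainIds(a@calphas))), c("A", "B"))
  # domains follow the globules, not the chains
  r <- overlapScore(a, g$reference)
  expect_equal(r@nPred, 2L)
  expect_equal(r@overlap, 1.0)
})

test_that("tiny all-exposed peptides fall back to a single domain", {
  cs <- makeCalphaSet(cbind(seq_len(5) * 3.8, 0, 0))
  expect_warning(a <- assignDomainsCA(cs), "single domain")
  expect_equal(nDomains(a), 1L)
})

test_that("the SS pipeline separates two helix bundles at the midpoint", {
  mkBundle <- function(cx) {
    offs <- rbind(c(0, 0, 0), c(0, 6, 0), c(0, 0, 6), c(0, 6, 6))
    do.call(rbind, lapply(1:4, function(i)
      makeIdealHelix(10, axis = c(0, 0, 1), origin = c(cx, 0, 0) + offs[i, ])))
  }
  coords <- rbind(mkBundle(0), mkBundle(40))
  cs <- makeCalphaSet(coords)
  ann <- rep("H", 80)
  a <- assignDomainsSS(cs, ann)
  expect_equal(nDomains(a), 2L)
  expect_equal(domainLabels(a), rep(1:2, each = 40))
  # both metrics and linkages produce a two-domain split here
  for (metric in c("midpoint", "closest"))
    expect_equal(nDomains(assignDomainsSS(cs, ann,
      ssParams(metric = metric))), 2L)
  expect_equal(nDomains(assignDomainsSS(cs, ann,
    ssParams(linkage = "complete", m = 40, s = 7))), 2L)
})

test_that("too few elements is an error pointing at the CA algorithm", {
  h <- rbind(makeIdealHelix(10), makeIdealHelix(10, origin = c(12, 0, 0)))
  cs <- makeCalphaSet(h)
  expect_error(assignDomainsSS(cs, rep("H", 20)),
               "insufficient secondary structure")
})

test_that("clusters of one or two elements are dissolved into neighbours", {
  # two 4-helix bundles 40 A apart plus an isolated helix pair placed so
  # the gap cut yields three clusters; the 2-element cluster must dissolve
  mkBundle <- function(cx) {
    offs <- rbind(c(0, 0, 0), c(0, 6, 0), c(0, 0, 6), c(0, 6, 6))
    do.call(rbind, lapply(1:4, function(i)
      makeIdealHelix(10, axis = c(0, 0, 1), origin = c(cx, 0, 0) + offs[i, ])))
  }
  coords <- rbind(mkBundle(0), mkBundle(40),
                  makeIdealHelix(10, axis = c(0, 0, 1),
                                 origin = c(20, 38, 0)),
                  makeIdealHelix(10, axis = c(0, 0, 1),
                                 origin = c(20, 44, 0)))
  cs <- makeCalphaSet(coords)
  a <- assignDomainsSS(cs, rep("H", 100))
  expect_equal(nDomains(a), 2L)
  # the dissolved pair joined one of the bundle domains wholesale
  expect_length(unique(domainLabels(a)[81:100]), 1L)
})

test_that("SS assignment is rigid-body invariant and covers every residue", {
  mkBundle <- function(cx) {
    offs <- rbind(c(0, 0, 0), c(0, 6, 0), c(0, 0, 6), c(0, 6, 6))
    do.call(rbind, lapply(1:4, function(i)
      makeIdealHelix(10, axis = c(0, 0, 1), origin = c(cx, 0, 0) + offs[i, ])))
  }
  coords <- rbind(mkBundle(0), mkBundle(40))
  ann <- rep("H", 80)
  a0 <- assignDomainsSS(makeCalphaSet(coords), ann)
  aR <- assignDomainsSS(makeCalphaSet(rigidTransform(coords, 23)), ann)
  expect_identical(domainLabels(aR), domainLabels(a0))
  expect_equal(length(domainLabels(a0)), 80L)
})

test_that("increasing separation never decreases the assigned domain count", {
  for (seed in 1:3) {
    ks <- vapply(c(0, 15, 25, 40, 60), function(sep) {
      g <- makeGlobuleStructure(globuleSpec(nDomains = 2,
                                            centerSeparation = sep,
                                            seed = seed))
      nDomains(assignDomainsCA(g$calphas))
    }, numeric(1))
    expect_false(is.unsorted(ks))
    expect_equal(ks[1], 1)
    expect_equal(ks[5], 2)
  }
})
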