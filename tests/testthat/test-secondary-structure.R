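test_that("DSSP codes map H/G/I to helix, E to strand, rest to coil", {
  cs <- makeCalphaSet(cbind(seq_len(6) * 3.8, 0, 0), resno = 1:6)
  f <- writeTempFile(dsspText(rep("A", 6), 1:6,
                              c("H", "H", "H", "H", "H", "H")))
  expect_equal(unname(parseDSSP(f, cs))[1:5], rep("H", 5))
  f2 <- writeTempFile(dsspText(rep("A", 6), 1:6,
                               c(" ", " ", "E", "E", " ", "T")))
  expect_equal(as.vector(parseDSSP(f2, cs)),
               c("C", "C", "E", "E", "C", "C"))
  f3 <- writeTempFile(dsspText(rep("A", 6), 1:6,
                               c("G", "I", "H", "S", "B", "E")))
  expect_equal(as.vector(parseDSSP(f3, cs)),
               c("H", "H", "H", "C", "C", "E"))
})

test_that("DSSP alignment is by chain + author numbering; absent chains coil", {
  coords <- rbind(cbind(1:4 * 3.8, 0, 0), cbind(1:3 * 3.8, 10, 0))
  cs <- makeCalphaSet(coords, chain = rep(c("A", "B"), c(4, 3)),
                      resno = c(11:14, 1:3))
  f <- writeTempFile(dsspText(rep("A", 4), 11:14, rep("H", 4)))
  expect_warning(ann <- parseDSSP(f, cs), "all-coil")
  expect_equal(as.vector(ann), c(rep("H", 4), rep("C", 3)))
  # complete mismatch errors
  f2 <- writeTempFile(dsspText(rep("Q", 2), 900:901, c("H", "H")))
  expect_error(parseDSSP(f2, cs), "mismatch|no residue")
})

test_that("DSSP sheet labels ride along for strand residues only", {
  cs <- makeCalphaSet(cbind(seq_len(5) * 3.8, 0, 0), resno = 1:5)
  f <- writeTempFile(dsspText(rep("A", 5), 1:5,
                              c("E", "E", " ", "E", "H"),
                              sheet = c("A", "A", "A", "B", "B")))
  ann <- parseDSSP(f, cs)
  expect_equal(attr(ann, "sheet"), c("A", "A", NA, "B", NA))
})

test_that("the TSV annotation path matches the DSSP mapping rules", {
  cs <- makeCalphaSet(cbind(seq_len(4) * 3.8, 0, 0), resno = 1:4)
  f <- writeTempFile(c("A\t1\tH", "A\t2\tG", "A\t3\tE", "A\t4\tX"))
  expect_equal(readSSTable(f, cs), c("H", "H", "E", "C"))
})

test_that("element vectors: collinear case, orientation, projections", {
  p <- cbind(0, 0, c(0, 1, 2, 3))
  ev <- elementVector(p, p[1, ], p[4, ])
  expect_equal(ev$direction, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(ev$start, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(ev$end, c(0, 0, 3), tolerance = 1e-6)
  # swapping r1/r2 flips the direction (N-to-C orientation rule)
  ev2 <- elementVector(p, p[4, ], p[1, ])
  expect_equal(ev2$direction, c(0, 0, -1), tolerance = 1e-9)
  # degenerate geometry errors
  expect_error(elementVector(matrix(1, 4, 3), c(1, 1, 1), c(1, 1, 1)),
               "degenerate")
})

test_that("element vector of an ideal helix is within 3 degrees of its axis", {
  for (axis in list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 1) / sqrt(3))) {
    h <- makeIdealHelix(12, axis = axis)
    ev <- elementVector(h, h[1, ], h[12, ])
    ang <- acos(abs(sum(ev$direction * axis / sqrt(sum(axis^2))))) * 180 / pi
    expect_lt(ang, 3)
    # orientation points from first towards last residue
    expect_gte(sum(ev$direction * (h[12, ] - h[1, ])), 0)
  }
})

test_that("endpoint projection formulas hold exactly on every element", {
  g <- makeGlobuleStructure(globuleSpec(nDomains = 1, seed = 5))
  cs <- g$calphas
  ann <- rep("H", nResidues(cs))
  els <- extractElements(ann, cs)
  for (e in seq_len(nElements(els))) {
    ctr <- els@center[e, ]; v <- els@direction[e, ]
    r1 <- cs@coords[els@firstIndex[e], ]
    r2 <- cs@coords[els@lastIndex[e], ]
    expect_equal(els@start[e, ], ctr + sum((r1 - ctr) * v) * v,
                 tolerance = 1e-6)
    expect_equal(els@end[e, ], ctr + sum((r2 - ctr) * v) * v,
                 tolerance = 1e-6)
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-9)
    expect_gte(sum(v * (r2 - r1)), 0)
  }
})

test_that("runs split at chain breaks and short runs are demoted", {
  # 10-residue ideal helix labelled helix -> one element spanning all 10
  h <- makeIdealHelix(10, axis = c(0, 0, 1))
  cs <- makeCalphaSet(h)
  els <- extractElements(rep("H", 10), cs)
  expect_equal(nElements(els), 1L)
  expect_equal(els@firstIndex, 1L)
  expect_equal(els@lastIndex, 10L)
  # run of length 2 is demoted
  cs2 <- makeCalphaSet(cbind(seq_len(5) * 3.8, 0, 0))
  expect_equal(nElements(extractElements(c("H", "H", "C", "C", "C"), cs2)),
               0L)
  # 8-residue helix run with a 20 A jump between residues 4 and 5
  jump <- rbind(makeIdealHelix(4), makeIdealHelix(4, origin = c(20, 0, 0)))
  cs3 <- makeCalphaSet(jump)
  expect_equal(nElements(extractElements(rep("H", 8), cs3, minLen = 5)), 0L)
  expect_equal(nElements(extractElements(rep("H", 8), cs3, minLen = 3)), 2L)
  # a gap in author numbering also splits
  cs4 <- makeCalphaSet(cbind(seq_len(8) * 3.8, 0, 0),
                       resno = c(1:4, 15:18))
  expect_equal(nElements(extractElements(rep("H", 8), cs4, minLen = 3)), 2L)
})

test_that("element distances: parallel, collinear and brute-force cases", {
  segs <- function(starts, ends, kinds = NULL) {
    nE <- nrow(starts)
    new("SSElementSet", kind = rep("helix", nE), chainId = rep("A", nE),
        firstIndex = seq(1L, by = 10L, length.out = nE),
        lastIndex = seq(10L, by = 10L, length.out = nE),
        center = (starts + ends) / 2,
        direction = (ends - starts) /
          sqrt(rowSums((ends - starts)^2)),
        start = starts, end = ends)
  }
  # parallel unit segments offset by 5 perpendicular
  e <- segs(rbind(c(0, 0, 0), c(0, 5, 0)), rbind(c(1, 0, 0), c(1, 5, 0)))
  expect_equal(elementDistance(e, 1, 2, "closest"), 5)
  expect_equal(elementDistance(e, 1, 2, "midpoint"), 5)
  # collinear [0,1] and [3,4] on the x axis
  e2 <- segs(rbind(c(0, 0, 0), c(3, 0, 0)), rbind(c(1, 0, 0), c(4, 0, 0)))
  expect_equal(elementDistance(e2, 1, 2, "closest"), 2)
  expect_equal(elementDistance(e2, 1, 2, "midpoint"), 3)
})

test_that("closest approach matches a dense-sampling oracle on random pairs", {
  set.seed(42)
  for (rep in 1:100) {
    p1 <- runif(3, -5, 5); q1 <- p1 + runif(3, -4, 4)
    p2 <- runif(3, -5, 5); q2 <- p2 + runif(3, -4, 4)
    e <- new("SSElementSet", kind = c("helix", "helix"),
             chainId = c("A", "A"), firstIndex = c(1L, 11L),
             lastIndex = c(10L, 20L),
             center = rbind((p1 + q1) / 2, (p2 + q2) / 2),
             direction = rbind((q1 - p1) / sqrt(sum((q1 - p1)^2)),
                               (q2 - p2) / sqrt(sum((q2 - p2)^2))),
             start = rbind(p1, p2), end = rbind(q1, q2))
    exact <- elementDistance(e, 1, 2, "closest")
    approx <- sampledSegmentDistance(p1, q1, p2, q2)
    expect_lt(abs(exact - approx), 1e-3)
    expect_lte(exact, approx + 1e-12)  # sampling can only overestimate
  }
})

test_that("element distances are invariant under rigid-body motion", {
  h <- rbind(makeIdealHelix(8, axis = c(1, 0, 0)),
             makeIdealHelix(8, axis = c(0, 1, 0), origin = c(0, 12, 3)),
             makeIdealHelix(8, axis = c(1, 1, 0), origin = c(15, 0, -4)))
  ann <- rep("H", 24)
  cs <- makeCalphaSet(h)
  csR <- makeCalphaSet(rigidTransform(h, seed = 9))
  for (metric in c("midpoint", "closest")) {
    d0 <- elementDistance(extractElements(ann, cs), metric = metric)
    d1 <- elementDistance(extractElements(ann, csR), metric = metric)
    expect_equal(d1, d0, tolerance = 1e-6)
  }
})
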