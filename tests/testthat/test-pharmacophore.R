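test_that("benzene yields exactly one aromatic-ring feature at the centroid", {
  b <- compound("benz", "c1ccccc1", conformer = benzeneConformer())
  f <- perceiveFeatures(b)
  expect_equal(f$ftype, "R")
  expect_equal(c(f$x, f$y, f$z), colMeans(as.matrix(benzeneConformer()[, 2:4])),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("methanol gives hydroxyl donor + acceptor; methane gives nothing", {
  m <- compound("meoh", "CO",
                conformer = data.frame(element = c("C", "O"),
                                       x = c(0, 1.43), y = 0, z = 0))
  f <- perceiveFeatures(m)
  expect_setequal(f$ftype, c("D", "A"))
  expect_equal(f$x, c(1.43, 1.43))  # both on the oxygen
  met <- compound("met", "C",
                  conformer = data.frame(element = "C", x = 0, y = 0, z = 0))
  expect_equal(nrow(perceiveFeatures(met)), 0L)
  expect_error(perceiveFeatures(compound("noconf", "CO")), "no conformer")
})

test_that("distance binning places a 3-Angstrom D/A pair in the [2,4) bin", {
  fp <- pharmFingerprint(data.frame(ftype = c("D", "A"),
                                    x = c(0, 3), y = 0, z = 0))
  expect_equal(unname(fpCounts(fp)), 1L)
  expect_equal(names(fpCounts(fp)), "A|D|2")  # 1-based bin over edges 0,2,4,...
  # three features -> exactly choose(3,2) pairs
  fp3 <- pharmFingerprint(data.frame(ftype = c("D", "A", "H"),
                                     x = c(0, 3, 9), y = 0, z = 0))
  expect_equal(sum(fpCounts(fp3)), 3L)
  # beyond the last edge -> overflow bin, still counted
  far <- pharmFingerprint(data.frame(ftype = c("D", "A"),
                                     x = c(0, 50), y = 0, z = 0))
  expect_equal(sum(fpCounts(far)), 1L)
  expect_error(pharmFingerprint(data.frame(ftype = "D", x = 0, y = 0, z = 0),
                                binEdges = c(1, 2)), "start at 0")
})

test_that("fingerprints are invariant under rigid motion", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    f <- data.frame(ftype = sample(c("D", "A", "H", "R", "N", "P"), n, TRUE),
                    x = runif(n, -6, 6), y = runif(n, -6, 6),
                    z = runif(n, -6, 6), stringsAsFactors = FALSE)
    R <- randomRotation()
    g <- f
    g[, c("x", "y", "z")] <- sweep(as.matrix(f[, c("x", "y", "z")]) %*% R,
                                   2, rnorm(3, 0, 10), "+")
    expect_identical(fpCounts(pharmFingerprint(f)),
                     fpCounts(pharmFingerprint(g)))
  }
})

test_that("similarity identities: 100 iff equal, 0 when disjoint, min/max ratio", {
  a <- pharmFingerprint(refGeometry())
  expect_equal(pharmSimilarity(a, a), 100)
  mk <- function(counts) new("PharmFingerprint", counts = counts,
                             binEdges = c(0, 2, 4, 6, 8, 10, 12))
  expect_equal(pharmSimilarity(mk(c(`A|D|1` = 2L)),
                               mk(c(`A|D|1` = 1L, `A|H|1` = 1L))),
               100 / 3)
  expect_equal(pharmSimilarity(mk(c(`A|D|1` = 1L)), mk(c(`H|R|2` = 1L))), 0)
  empty <- pharmFingerprint(refGeometry()[0, ])
  expect_equal(pharmSimilarity(empty, empty), 100)
  expect_equal(pharmSimilarity(empty, a), 0)
})

test_that("similarity is symmetric, bounded, and 100 only for equal maps", {
  set.seed(9)
  for (i in 1:20) {
    f1 <- geomLibrary(i, nAnalogs = 1, nDecoys = 1)
    s <- pharmSimilarity(pharmFingerprint(f1[[1]]), pharmFingerprint(f1[[2]]))
    expect_identical(s, pharmSimilarity(pharmFingerprint(f1[[2]]),
                                        pharmFingerprint(f1[[1]])))
    expect_gte(s, 0); expect_lte(s, 100)
    if (s == 100)
      expect_mapequal(as.list(fpCounts(pharmFingerprint(f1[[1]]))),
                      as.list(fpCounts(pharmFingerprint(f1[[2]]))))
  }
  # differing bin edges are a configuration error
  expect_error(pharmSimilarity(pharmFingerprint(refGeometry()),
                               pharmFingerprint(refGeometry(),
                                                binEdges = c(0, 3, 6))),
               "bin edges")
})

test_that("pooled references take per-key count maxima", {
  a <- pharmFingerprint(refGeometry())
  b <- pharmFingerprint(geomLibrary(3, nAnalogs = 0, nDecoys = 1)[[1]])
  pooled <- poolPharmFingerprints(list(a, b))
  for (k in names(fpCounts(a)))
    expect_gte(pooled@counts[[k]], a@counts[[k]])
  for (k in names(fpCounts(b)))
    expect_gte(pooled@counts[[k]], b@counts[[k]])
})

test_that("ranking selects exactly the planted geometric analogs at 70", {
  lib <- geomLibrary(21, nAnalogs = 10, nDecoys = 90)
  rk <- rankAndSelect(lib, refGeometry(), threshold = 70)
  expect_setequal(rk$selected, sprintf("A%03d", 1:10))
  # selection equals the brute-force score set
  brute <- vapply(lib, function(f) bruteScore(refGeometry(), f), numeric(1))
  expect_setequal(rk$selected, names(brute)[brute > 70])
  expect_equal(rk$ranking$score[match(names(brute), rk$ranking$compound_id)],
               unname(brute), tolerance = 1e-12)
  # ranking is a total order: descending score, ties by id
  expect_true(all(diff(rk$ranking$score) <= 0))
  # selection is monotone in threshold
  n70 <- length(rk$selected)
  n90 <- length(rankAndSelect(lib, refGeometry(), threshold = 90)$selected)
  expect_lte(n90, n70)
  # strict inequality at 100 excludes even identity matches
  selfLib <- list(REF = refGeometry())
  expect_length(rankAndSelect(selfLib, refGeometry(), 100)$selected, 0L)
  rkSelf <- rankAndSelect(selfLib, refGeometry(), 70)
  expect_equal(rkSelf$ranking$score[1], 100)
  expect_equal(rkSelf$selected, "REF")
})

test_that("chemical ranking works end to end on real conformers", {
  b1 <- compound("b1", "c1ccccc1O",
                 conformer = rbind(benzeneConformer(),
                                   data.frame(element = "O", x = 2.75,
                                              y = 0, z = 0)))
  shifted <- benzeneConformer()
  shifted$x <- shifted$x + 10
  lib <- hitlead:::.newLibrary(list(
    b1, compound("b2", "c1ccccc1", conformer = shifted)))
  rk <- rankAndSelect(lib, b1, threshold = 70)
  expect_equal(rk$ranking$compound_id[1], "b1")
  expect_equal(rk$ranking$score[1], 100)
})
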