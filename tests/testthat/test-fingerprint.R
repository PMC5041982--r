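test_that("a single-heavy-atom molecule yields the empty fingerprint", {
  fp <- fingerprint2d(compound("met", "C"))
  expect_length(fpBits(fp), 0L)
  # two empty fingerprints are defined as identical
  expect_equal(tanimoto(fp, fp), 1)
})

test_that("fingerprints are invariant to atom order and kekulization", {
  expect_equal(fpBits(fingerprint2d(compound("a", "OCC"))),
               fpBits(fingerprint2d(compound("b", "CCO"))))
  # phenol written from either end; aromatic bonds typed as aromatic, so
  # the kekulized alternation cannot leak into the path tokens
  expect_equal(fpBits(fingerprint2d(compound("p1", "c1ccccc1O"))),
               fpBits(fingerprint2d(compound("p2", "Oc1ccccc1"))))
})

test_that("path multisets distinguish constitutional isomers", {
  # ethanol paths: C-C, C-O, C-C-O -> 3 distinct tokens; dimethyl ether:
  # C-O (twice, same token) and C-O-C -> 2 distinct tokens
  etoh <- fingerprint2d(compound("etoh", "CCO"))
  dme <- fingerprint2d(compound("dme", "COC"))
  expect_length(fpBits(etoh), 3L)
  expect_length(fpBits(dme), 2L)
  expect_false(identical(fpBits(etoh), fpBits(dme)))
})

test_that("tanimoto identities and bounds hold", {
  mk <- function(bits, nbits = 2048L)
    new("Fingerprint2D", bits = sort(unique(as.integer(bits))),
        nbits = nbits)
  expect_equal(tanimoto(mk(c(1, 5, 9)), mk(c(1, 5, 9))), 1)
  expect_equal(tanimoto(mk(1:3), mk(4:6)), 0)
  expect_equal(tanimoto(mk(1:3), mk(2:4)), 0.5)  # |I|=2, |U|=4
  expect_error(tanimoto(mk(1:3), mk(1:3, nbits = 1024L)), "different length")
  set.seed(42)
  for (i in 1:25) {
    a <- mk(sample(0:2047, sample(0:40, 1)))
    b <- mk(sample(0:2047, sample(0:40, 1)))
    s <- tanimoto(a, b)
    expect_identical(s, tanimoto(b, a))
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("screening finds the reference and its elaborated analogs", {
  ref <- compound("ref", "O=S(=O)(Nc1cccc2ccccc12)c1ccccc1")
  analog <- compound("an", "O=S(=O)(Nc1cccc2ccccc12)c1ccc(CCO)cc1")
  other <- compound("x", "CCOC(=O)CN")
  lib <- hitlead:::.newLibrary(list(other, analog,
                                    compound("ref", ref@smiles)))
  for (mode in c("containment", "tanimoto")) {
    hits <- screenLibrary(lib, ref, mode = mode, cutoff = 1.0)
    expect_true(hits$passes[hits$compound_id == "ref"])
  }
  # a supergraph that destroys no path keeps every reference bit
  hits <- screenLibrary(lib, ref, mode = "containment")
  expect_true(hits$passes[hits$compound_id == "an"])
  expect_false(hits$passes[hits$compound_id == "x"])
  # output sorted by descending similarity
  expect_true(!is.unsorted(rev(hits$tanimoto)))
})

test_that("planted analogs are recovered with a low decoy pass rate", {
  gen <- genLibrary(7, nDecoys = 100L, nAnalogs = 5L)
  expect_equal(length(gen$library), 105L)
  expect_equal(sum(gen$truth$is_analog), 5L)
  hits <- screenLibrary(gen$library, gen$reference, mode = "containment")
  m <- merge(hits, gen$truth, by.x = "compound_id", by.y = "id")
  expect_equal(mean(m$passes[m$is_analog]), 1)       # 100% sensitivity
  expect_lt(mean(m$passes[!m$is_analog]), 0.05)      # decoys rejected
  # brute-force containment check on the bit sets themselves
  refBits <- fpBits(fingerprint2d(gen$reference))
  for (id in gen$truth$id[gen$truth$is_analog])
    expect_true(all(refBits %in%
                    fpBits(fingerprint2d(gen$library[[id]]))))
})

test_that("hit count is monotone in cutoff; containment covers tanimoto-1", {
  gen <- genLibrary(11, nDecoys = 40L, nAnalogs = 5L)
  cuts <- c(0, 0.25, 0.5, 0.75, 1)
  sizes <- vapply(cuts, function(ct)
    sum(screenLibrary(gen$library, gen$reference, mode = "tanimoto",
                      cutoff = ct)$passes), numeric(1))
  expect_true(all(diff(sizes) <= 0))
  t1 <- screenLibrary(gen$library, gen$reference, "tanimoto", cutoff = 1)
  cn <- screenLibrary(gen$library, gen$reference, "containment")
  expect_true(all(t1$compound_id[t1$passes] %in% cn$compound_id[cn$passes]))
  expect_error(screenLibrary(gen$library, gen$reference, cutoff = 1.2),
               "cutoff")
})
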