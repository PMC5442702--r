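test_that("B-factor normalization gives exact z-scores with sample sd", {
  p <- new("BFactorProfile", resnums = 1:3, values = c(10, 20, 30))
  np <- normalizeBFactors(p)
  expect_equal(bValues(np), c(-1, 0, 1))   # sample sd = 10
  expect_equal(meanB(np), 20)
  expect_equal(sdB(np), 10)
  expect_error(normalizeBFactors(c(5, 5, 5)), "degenerate")
  expect_error(normalizeBFactors(c(1, 2)), "too short")
})

test_that("normalized profiles have mean 0 and sample sd 1 to 1e-12", {
  set.seed(1)
  v <- runif(1000, 5, 80)
  np <- normalizeBFactors(v)
  expect_lt(abs(mean(bValues(np))), 1e-12)
  expect_lt(abs(sd(bValues(np)) - 1), 1e-12)
})

test_that("normalization is invariant under positive affine transforms", {
  set.seed(42)
  for (k in 1:20) {
    v <- runif(50, 10, 60)
    a <- runif(1, 0.1, 5)
    c0 <- runif(1, -5, 40)
    ref <- bValues(normalizeBFactors(v))
    tr <- bValues(normalizeBFactors(a * v + c0))
    expect_equal(tr, ref, tolerance = 1e-10)
  }
})

test_that("identity alignment maps residues one to one", {
  aln <- alignPair("ACDE", "ACDE")
  p <- alignmentPairs(aln)
  expect_equal(p$idxA, 1:4)
  expect_equal(p$idxB, 1:4)
  expect_equal(aln@alignedA, "ACDE")
})

test_that("a single-deletion alignment opens exactly one gap at the best score", {
  aln <- alignPair("ACDE", "ACE")
  expect_equal(sum(is.na(alignmentPairs(aln)$idxB)), 1)
  expect_equal(alignmentScore(aln), gotohScore("ACDE", "ACE"))
  expect_error(alignPair("", "ACD"), "empty")
  expect_error(alignPair("AC1D", "ACD"), "alphabet")
})

test_that("the Gotoh oracle matches exhaustive enumeration on short pairs", {
  set.seed(7)
  for (k in 1:30) {
    a <- randAaSeq(sample(1:5, 1))
    b <- randAaSeq(sample(1:5, 1))
    expect_equal(gotohScore(a, b), enumAlignScore(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment scores equal the independent optimum on random pairs", {
  set.seed(11)
  for (k in 1:40) {
    a <- randAaSeq(sample(1:8, 1))
    b <- randAaSeq(sample(1:8, 1))
    expect_equal(alignmentScore(alignPair(a, b)), gotohScore(a, b),
                 info = paste(a, b))
  }
})

test_that("profile pairing places values by alignment column", {
  npA <- normalizeBFactors(new("BFactorProfile", resnums = 11:14,
                               values = c(10, 20, 30, 40)))
  aln <- alignPair("ACDE", "ACDE")
  pp <- pairProfiles(aln, npA, npA)
  d <- profileColumns(pp)
  expect_equal(d$delta, rep(0, 4))
  expect_equal(d$resnumA, 11:14)

  # gap in B: that column keeps B'_A but has no delta
  npB <- normalizeBFactors(new("BFactorProfile", resnums = 1:3,
                               values = c(12, 22, 32)))
  aln2 <- alignPair("ACDE", "ACE")
  d2 <- profileColumns(pairProfiles(aln2, npA, npB))
  gapcol <- which(is.na(d2$resnumB))
  expect_length(gapcol, 1)
  expect_false(is.na(d2$bpA[gapcol]))
  expect_true(is.na(d2$delta[gapcol]))

  expect_error(pairProfiles(aln2, npB, npB), "profile A")
})

test_that("shuffling one profile's residues breaks the pairing", {
  set.seed(3)
  v <- runif(20, 10, 50)
  npA <- normalizeBFactors(new("BFactorProfile", resnums = 1:20,
                               values = v))
  npShuf <- normalizeBFactors(new("BFactorProfile", resnums = 1:20,
                                  values = sample(v)))
  s <- randAaSeq(20)
  aln <- alignPair(s, s)
  dOk <- profileColumns(pairProfiles(aln, npA, npA))$delta
  dBad <- profileColumns(pairProfiles(aln, npA, npShuf))$delta
  expect_true(all(abs(dOk) < 1e-12))
  expect_gt(max(abs(dBad)), 0.1)
})

test_that("segment calling recovers a planted run and nothing else", {
  mkPP <- function(delta) {
    n <- length(delta)
    new("PairedProfile", columns = data.frame(
      col = 1:n, resnumA = 1:n, resnumB = 1:n,
      aaA = "A", aaB = "A", bA = 10, bB = 10,
      bpA = delta, bpB = 0, delta = delta))
  }
  expect_equal(nrow(callFlexibleSegments(mkPP(rep(0, 60)))), 0)

  set.seed(5)
  delta <- runif(60, -0.2, 0.2)
  delta[50:53] <- 1.2
  segs <- callFlexibleSegments(mkPP(delta), deltaMin = 0.5, minRun = 3)
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start, 50)
  expect_equal(segs$end, 53)
  expect_equal(segs$kind, "matched")
  expect_equal(segs$meanDelta, 1.2)
})

test_that("called segments are disjoint, maximal, and above threshold", {
  set.seed(13)
  for (k in 1:20) {
    n <- 80
    delta <- rnorm(n, 0, 0.4)
    d <- data.frame(col = 1:n, resnumA = 1:n, resnumB = 1:n,
                    aaA = "A", aaB = "A", bA = 10, bB = 10,
                    bpA = delta, bpB = 0, delta = delta)
    segs <- callFlexibleSegments(new("PairedProfile", columns = d),
                                 deltaMin = 0.5, minRun = 2)
    if (nrow(segs) == 0) next
    # every covered position satisfies the threshold
    for (i in seq_len(nrow(segs))) {
      run <- segs$start[i]:segs$end[i]
      expect_true(all(delta[run] >= 0.5))
      # maximality: the flanking positions fail the threshold
      if (segs$start[i] > 1) expect_lt(delta[segs$start[i] - 1], 0.5)
      if (segs$end[i] < n) expect_lt(delta[segs$end[i] + 1], 0.5)
    }
    # disjoint and sorted
    if (nrow(segs) > 1)
      expect_true(all(segs$start[-1] > segs$end[-nrow(segs)]))
  }
})

test_that("gap-opposite runs are reported as their own kind", {
  n <- 30
  resB <- as.integer(1:n)
  resB[10:14] <- NA   # homolog gapped opposite target 10..14
  d <- data.frame(col = 1:n, resnumA = 1:n, resnumB = resB,
                  aaA = "A", aaB = ifelse(is.na(resB), NA, "A"),
                  bA = 10, bB = ifelse(is.na(resB), NA, 10),
                  bpA = 0, bpB = ifelse(is.na(resB), NA, 0),
                  delta = ifelse(is.na(resB), NA, 0))
  pp <- new("PairedProfile", columns = d)
  segs <- callFlexibleSegments(pp, deltaMin = 0.5, minRun = 3)
  expect_equal(segs$kind, "gap-opposite")
  expect_equal(c(segs$start, segs$end), c(10, 14))
  expect_true(is.na(segs$meanDelta))
  expect_equal(nrow(callFlexibleSegments(pp, deltaMin = 0.5, minRun = 3,
                                         includeGapOpposite = FALSE)), 0)
})
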