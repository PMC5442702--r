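test_that("generators are byte-deterministic for a fixed seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  genStructurePair(nRes = 40, plantedSegments = list(c(20, 23, 1.2)),
                   gapBlocks = list(c(8, 3)), seed = 9, dir = d1)
  genStructurePair(nRes = 40, plantedSegments = list(c(20, 23, 1.2)),
                   gapBlocks = list(c(8, 3)), seed = 9, dir = d2)
  for (f in c("target.pdb", "homolog.pdb", "truth.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))

  f1 <- file.path(d1, "m.fasta"); f2 <- file.path(d2, "m.fasta")
  genMsa(nSeq = 30, refLength = 50,
         columns = list("10" = c(S = 0.4)), seed = 5, file = f1)
  genMsa(nSeq = 30, refLength = 50,
         columns = list("10" = c(S = 0.4)), seed = 5, file = f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  t1 <- file.path(d1, "t.pdb"); t2 <- file.path(d2, "t.pdb")
  genTrajectory("harmonic", nRes = 4, nFrames = 10, seed = 3, file = t1)
  genTrajectory("harmonic", nRes = 4, nFrames = 10, seed = 3, file = t2)
  expect_identical(unname(tools::md5sum(t1)), unname(tools::md5sum(t2)))

  k1 <- genKinetics(278, 1.5, noiseCv = 0.05, seed = 5)
  k2 <- genKinetics(278, 1.5, noiseCv = 0.05, seed = 5)
  expect_identical(k1$data, k2$data)
})

test_that("structure pairs carry their planted truth", {
  g <- genStructurePair(nRes = 220,
                        plantedSegments = list(c(207, 210, 1.2)),
                        gapBlocks = list(c(86, 6)), noiseSd = 0.1,
                        seed = 7)
  expect_equal(g$truth$start, c(86, 207))
  expect_equal(g$truth$end, c(91, 210))
  expect_equal(g$truth$kind, c("gap-opposite", "matched"))
  # target has all residues, homolog lacks the gap block
  expect_equal(length(extractSequence(g$target)$resnums), 220)
  expect_equal(length(extractSequence(g$homolog)$resnums), 214)
  # sequences agree outside the gap block
  tseq <- strsplit(extractSequence(g$target)$sequence, "")[[1]]
  hseq <- strsplit(extractSequence(g$homolog)$sequence, "")[[1]]
  expect_equal(tseq[-(86:91)], hseq)

  expect_error(genStructurePair(plantedSegments = list(c(10, 20, 1),
                                                       c(15, 25, 1))),
               "overlap")
  expect_error(genStructurePair(nRes = 50,
                                plantedSegments = list(c(48, 55, 1))),
               "outside")
})

test_that("a clean pair with no planted signal calls no segments", {
  g <- genStructurePair(nRes = 100, plantedSegments = list(),
                        gapBlocks = list(), noiseSd = 0, seed = 2)
  cmp <- compareFlexibility(g$target, g$homolog)
  expect_equal(nrow(cmp$segments), 0)
})

test_that("planted segments are recovered through the whole pipeline", {
  g <- genStructurePair(nRes = 220,
                        plantedSegments = list(c(207, 210, 1.2)),
                        gapBlocks = list(c(86, 6)), noiseSd = 0.1,
                        seed = 7)
  segs <- compareFlexibility(g$target, g$homolog)$segments
  expect_equal(segs$start, g$truth$start)
  expect_equal(segs$end, g$truth$end)
  expect_equal(segs$kind, g$truth$kind)
})

test_that("MSA generation plants exact counts and validates its spec", {
  g <- genMsa(nSeq = 100, refLength = 30,
              columns = list("10" = c(S = 0.31, N = 0.07)),
              refResidues = c("10" = "N"), seed = 3)
  cf <- columnFrequencies(g$msa, "ref")
  expect_equal(cf$freq.S[cf$refPos == 10], 0.31)
  expect_equal(cf$freq.N[cf$refPos == 10], 0.07)
  expect_equal(g$truth$count, c(31L, 7L))

  one <- genMsa(nSeq = 1, refLength = 12, columns = list(), seed = 1)
  cf1 <- columnFrequencies(one$msa, "ref")
  expect_equal(cf1$consensusFreq, rep(1, 12))

  expect_error(genMsa(columns = list("5" = c(S = 0.9, T = 0.2))),
               "exceed")
  expect_error(genMsa(columns = list("5" = c(s2 = 0.5))), "invalid")
})

test_that("trajectory generators expose their scheduled truth", {
  expect_error(genTrajectory("harmonic", sigma = 0), "positive")
  expect_error(genTrajectory("hbond_schedule", schedule = logical(0)),
               "non-empty")
  g <- genTrajectory("hbond_schedule",
                     schedule = c(TRUE, TRUE, FALSE, TRUE))
  oc <- hbondOccupancy(g$traj, g$truth$donorRes, g$truth$donorAtom,
                       g$truth$acceptorRes, g$truth$acceptorAtom)
  expect_equal(oc$occupancy, g$truth$occupancy)
  expect_equal(oc$occupancy, 0.75)
})

test_that("noiseless kinetics data are exact Michaelis-Menten values", {
  g <- genKinetics(278, 1.5, noiseCv = 0)
  expect_equal(g$data$v, 278 * g$data$S / (1.5 + g$data$S))
  expect_equal(nrow(g$data), 8)
  expect_equal(range(g$data$S), c(0.5, 5))
  f <- lineweaverBurkFit(g$data$S, g$data$v)
  expect_equal(c(f$Vmax, f$Km), c(278, 1.5), tolerance = 1e-9)
})
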