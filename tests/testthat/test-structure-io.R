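test_that("a handcrafted ATOM block parses with numbering and B-factors intact", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toyPdbLines(resnums = c(2, 3, 4)), f)
  m <- readStructure(f)
  a <- atomTable(m)
  expect_equal(nrow(a), 3)
  expect_equal(a$resnum, c(2, 3, 4))
  expect_equal(a$bfactor, c(10, 20, 30))
  p <- extractCaProfile(m)
  expect_equal(bValues(p), c(10, 20, 30))
  # profile labels carry author numbering: first index is resnum 2
  expect_equal(residueNumbers(p), c(2L, 3L, 4L))
})

test_that("altloc collapsing keeps the highest occupancy, ties alphabetical", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60 11.00           C",
    "ATOM      2  CA BALA A   1       1.000   0.000   0.000  0.40 12.00           C",
    "ATOM      3  CA BGLY A   2       5.000   0.000   0.000  0.50 21.00           C",
    "ATOM      4  CA AGLY A   2       6.000   0.000   0.000  0.50 22.00           C"),
    f)
  a <- atomTable(readStructure(f))
  expect_equal(nrow(a), 2)
  expect_equal(a$altloc, c("A", "A"))       # occ 0.6 wins; tie -> "A"
  expect_equal(a$bfactor, c(11, 22))
})

test_that("chain selection works and a missing chain is reported", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CA  GLY B   1       5.000   0.000   0.000  1.00 20.00           C"),
    f)
  mB <- readStructure(f, chain = "B")
  expect_equal(atomTable(mB)$chain, "B")
  expect_error(readStructure(f, chain = "Z"), "chain 'Z' not found")
})

test_that("sequence extraction uses the standard 3-to-1 mapping", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toyPdbLines(resnames = c("ALA", "GLY", "SER")), f)
  expect_equal(extractSequence(readStructure(f))$sequence, "AGS")
  writeLines(toyPdbLines(resnames = c("MSE", "UNK", "TRP")), f)
  s <- extractSequence(readStructure(f))
  expect_equal(s$sequence, "MXW")   # selenomethionine -> M, unknown -> X
  expect_equal(s$resnums, 1:3)
})

test_that("residues without a CA atom are skipped with a warning", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CB  GLY A   2       4.000   0.000   0.000  1.00 99.00           C",
    "ATOM      3  CA  SER A   3       8.000   0.000   0.000  1.00 30.00           C"),
    f)
  m <- readStructure(f)
  expect_warning(p <- extractCaProfile(m), "1 residue")
  expect_equal(bValues(p), c(10, 30))
})

test_that("parse and empty-profile errors name the problem", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CA  GLY A   x       4.000   0.000   0.000  1.00 20.00           C"),
    f)
  expect_error(readStructure(f), "line 2")
  writeLines("REMARK nothing here", f)
  expect_error(readStructure(f), "no ATOM records")
  writeLines(c(
    "ATOM      1  CB  ALA A   1       0.000   0.000   0.000  1.00 10.00           C"), f)
  expect_error(extractCaProfile(readStructure(f)), "no CA atoms")
})

test_that("write/read round trip preserves coordinates to 3 decimals, B to 2", {
  g <- genStructurePair(nRes = 30, plantedSegments = list(),
                        gapBlocks = list(), noiseSd = 0.05, seed = 4)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(g$target, f)
  m2 <- readStructure(f)
  a1 <- atomTable(g$target)
  a2 <- atomTable(m2)
  expect_equal(nrow(a1), nrow(a2))
  expect_equal(a2$x, round(a1$x, 3))
  expect_equal(a2$y, round(a1$y, 3))
  expect_equal(a2$z, round(a1$z, 3))
  expect_equal(a2$bfactor, round(a1$bfactor, 2))
  expect_equal(a2$resnum, a1$resnum)
  expect_equal(a2$name, a1$name)
  # reparsing the rewritten file gives an equal model
  f2 <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(m2, f2)
  expect_identical(atomTable(readStructure(f2)), a2)
})

test_that("an independent PDB reader agrees on coordinates and B-factors", {
  g <- genStructurePair(nRes = 12, plantedSegments = list(),
                        gapBlocks = list(), seed = 5)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(g$target, f)
  ours <- atomTable(readStructure(f))
  ref <- bio3d::read.pdb(f)$atom
  expect_equal(nrow(ours), nrow(ref))
  expect_equal(ours$x, ref$x)
  expect_equal(ours$y, ref$y)
  expect_equal(ours$z, ref$z)
  expect_equal(ours$bfactor, ref$b)
  expect_equal(ours$resnum, ref$resno)
})

test_that("multi-model files read as trajectories with topology checks", {
  g <- genTrajectory("harmonic", nRes = 3, nFrames = 5, sigma = 0.2,
                     seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeStructure(g$traj, f)
  tr <- readTrajectory(f, dt = 2)
  expect_equal(nFrames(tr), 5)
  expect_equal(timeStep(tr), 2)
  expect_equal(tr@coords, round(g$traj@coords, 3), tolerance = 1e-12)

  # drop one atom from frame 3
  lines <- readLines(f)
  starts <- grep("^MODEL", lines)
  atom3 <- which(seq_along(lines) > starts[3] & grepl("^ATOM", lines))[1]
  writeLines(lines[-atom3], f)
  expect_error(readTrajectory(f), "frame 3")

  # single-model file: 1-frame trajectory
  f1 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(toyPdbLines(), f1)
  expect_equal(nFrames(readTrajectory(f1)), 1)
})
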