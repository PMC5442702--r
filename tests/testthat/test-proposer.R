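# Conservation table mirroring the C-terminal 207-210 design scenario:
# consensus S/S/G/S at 31/31/48/31%, wild type N/G/G/A at 7/4/48/11%.
ctermCols <- function() {
  data.frame(refPos = 207:210,
             consensusAa = c("S", "S", "G", "S"),
             consensusFreq = c(0.31, 0.31, 0.48, 0.31),
             freq.N = c(0.07, 0.01, 0.01, 0.00),
             freq.G = c(0.02, 0.04, 0.48, 0.03),
             freq.A = c(0.01, 0.02, 0.01, 0.11),
             freq.S = c(0.31, 0.31, 0.04, 0.31),
             stringsAsFactors = FALSE)
}

test_that("the consensus policy proposes N207S, G208S, A210S and keeps G209", {
  segs <- data.frame(start = 207, end = 210)
  pr <- proposeMutations(segs, ctermCols(), "NGGA", 207:210,
                         minConsensus = 0.25)
  expect_equal(pr$label, c("N207S", "G208S", "A210S"))
  expect_false(209 %in% pr$position)
  expect_equal(pr$proposedAa, c("S", "S", "S"))
  expect_true(all(pr$serThrPreferred))
})

test_that("no proposals when the wild type already matches the consensus", {
  segs <- data.frame(start = 207, end = 210)
  pr <- proposeMutations(segs, ctermCols(), "SSGS", 207:210)
  expect_equal(nrow(pr), 0)
})

test_that("missing conservation positions are reported", {
  segs <- data.frame(start = 207, end = 211)
  expect_error(proposeMutations(segs, ctermCols(), "NGGAK", 207:211),
               "211")
})

test_that("emitted proposals satisfy the policy predicates and omissions violate one", {
  set.seed(21)
  for (k in 1:50) {
    n <- 10
    pos <- 100 + (1:n)
    cons <- sample(aaLetters, n, replace = TRUE)
    consFreq <- runif(n, 0.05, 0.9)
    wt <- sample(aaLetters, n, replace = TRUE)
    wtFreq <- pmin(runif(n, 0, 0.5), 1 - consFreq)
    wtFreq[wt == cons] <- consFreq[wt == cons]
    cols <- data.frame(refPos = pos, consensusAa = cons,
                       consensusFreq = consFreq,
                       stringsAsFactors = FALSE)
    for (aa in aaLetters) cols[[paste0("freq.", aa)]] <- 0
    for (i in 1:n) {
      cols[i, paste0("freq.", cons[i])] <- consFreq[i]
      cols[i, paste0("freq.", wt[i])] <- wtFreq[i]
    }
    segs <- data.frame(start = min(pos), end = max(pos))
    pr <- proposeMutations(segs, cols, paste(wt, collapse = ""), pos,
                           minConsensus = 0.25)
    for (i in 1:n) {
      should <- cons[i] != wt[i] && consFreq[i] >= 0.25 &&
        consFreq[i] > wtFreq[i]
      expect_equal(pos[i] %in% pr$position, should,
                   info = paste("seed-case", k, "pos", pos[i]))
    }
  }
})

test_that("the Ser/Thr bonus lowers the frequency floor only for S/T", {
  cols <- ctermCols()
  cols$consensusFreq[1] <- 0.22   # below the default floor
  segs <- data.frame(start = 207, end = 210)
  prOff <- proposeMutations(segs, cols, "NGGA", 207:210)
  expect_false(207 %in% prOff$position)
  prOn <- proposeMutations(segs, cols, "NGGA", 207:210,
                           serThrBonus = TRUE)
  expect_true(207 %in% prOn$position)
})

test_that("mutations apply only at listed positions and check the wild type", {
  pr <- data.frame(position = c(207, 208, 210),
                   wtAa = c("N", "G", "A"), proposedAa = c("S", "S", "S"))
  seq <- "KVNGGASG"
  out <- applyMutations(seq, pr, resnums = 205:212)
  expect_equal(out, "KVSSGSSG")
  expect_equal(applyMutations(seq, pr[0, ], 205:212), seq)
  bad <- transform(pr, wtAa = c("Q", "G", "A"))
  expect_error(applyMutations(seq, bad, 205:212), "position 207")

  # applying the inverse proposals restores the original
  inv <- data.frame(position = pr$position, wtAa = pr$proposedAa,
                    proposedAa = pr$wtAa)
  expect_equal(applyMutations(out, inv, 205:212), seq)
})

test_that("codon edits reproduce the single-nucleotide primer changes", {
  e1 <- minimalCodonEdit("AAC", "S")
  expect_equal(e1$newCodon, "AGC")
  expect_equal(e1$edits, 1L)
  e2 <- minimalCodonEdit("GGT", "S")
  expect_equal(e2$newCodon, "AGT")
  expect_equal(e2$edits, 1L)
  e3 <- minimalCodonEdit("GCC", "S")
  expect_equal(e3$newCodon, "TCC")
  expect_equal(e3$edits, 1L)
  expect_equal(minimalCodonEdit("GCT", "A")$edits, 0L)
  expect_error(minimalCodonEdit("GC", "A"), "invalid codon")
  expect_error(minimalCodonEdit("GCT", "*"), "not encodable")
})

test_that("codon edits are Hamming-minimal over all 64 x 20 inputs", {
  code <- Biostrings::getGeneticCode("1")
  codons <- names(code)
  for (wt in codons) {
    wtc <- strsplit(wt, "")[[1]]
    for (aa in aaLetters) {
      res <- minimalCodonEdit(wt, aa)
      # check against every codon of the target amino acid
      alts <- codons[code == aa]
      dists <- vapply(strsplit(alts, ""),
                      function(cc) sum(cc != wtc), integer(1))
      expect_equal(res$edits, min(dists), info = paste(wt, aa))
      # lexicographic tie-break among minimal codons
      expect_equal(res$newCodon, min(alts[dists == min(dists)]),
                   info = paste(wt, aa))
      # the returned codon translates to the target
      expect_equal(unname(code[res$newCodon]), aa)
    }
  }
})
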