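test_that("makeTypeLibrary plants separable, reproducible type libraries", {
  # k = 1: the consensus itself
  expect_identical(makeTypeLibrary(1), consChar())

  set.seed(501)
  lib <- makeTypeLibrary(3, interTypeDiv = 0.15)
  dv <- c(pairwiseDivergence(lib[1], lib[2:3]),
          pairwiseDivergence(lib[2], lib[3]))
  expect_true(all(dv >= 0.15 & dv <= 0.25))
  # every type stays within scan reach of the consensus
  expect_true(all(pairwiseDivergence(consChar(), lib) <= 0.1))

  # same seed, same library
  set.seed(77)
  l1 <- makeTypeLibrary(10, interTypeDiv = 0.12)
  set.seed(77)
  l2 <- makeTypeLibrary(10, interTypeDiv = 0.12)
  expect_identical(l1, l2)
})

test_that("horSimSpec validates its contract", {
  expect_error(horSimSpec(c(1, 2), nCopies = 5, cvPattern = "CC"),
               "length")
  expect_error(horSimSpec(c(1, 2), nCopies = 2, cvPattern = "CX"),
               "C and V")
  # planted types must be unambiguously separable from the 5% rule
  expect_error(horSimSpec(c(1, 2), nCopies = 5, interTypeDiv = 0.08),
               "twice")
  expect_error(horSimSpec(c(1, 2), nCopies = 5, kTypes = 1), "cover")
})

test_that("simulateHORArray truth tables tile the sequence consistently", {
  spec <- horSimSpec(c(1, 2, 3), nCopies = 6, perBaseMutRate = 0,
                     interTypeDiv = 0.12, flankBp = 500L, seed = 9)
  sim <- simulateHORArray(spec)
  tr <- sim$truth$monomers
  expect_identical(nrow(tr), 18L)
  expect_identical(tr$start[1], 500L)
  expect_true(all(tr$end - tr$start == 171))
  expect_identical(tr$start[-1L], head(tr$end, -1L)) # gapless tandem
  expect_identical(sim$truth$copies$label, rep("C", 6))
  # zero mutation: monomer sequences are exactly the library types
  g <- as.character(sim$genome[[1]])
  expect_identical(substring(g, tr$start + 1L, tr$end),
                   sim$library[tr$type])
})

test_that("a zero-noise Willard fixture runs through the whole pipeline", {
  spec <- horSimSpec(c(1, 2, 3), nCopies = 10, perBaseMutRate = 0,
                     interTypeDiv = 0.12, seed = 19)
  res <- runDeskPipeline(spec, minIdentity = 0.9, minRun = 5L)
  f <- res$det$families[[1]]
  expect_identical(period(f), 3L)
  expect_identical(nrow(copyTable(f)), 9L) # trailing copy edge-dropped
  expect_true(all(copyTable(f)$label == "C"))
  expect_identical(classifyHORType(layoutCascade(canonicalTypeSeq(f))),
                   "Willard")
  expect_identical(divergencePct(f)$meanPct, 0)
})

test_that("planted N-gaps knock out the overlapped monomers and copies", {
  spec0 <- horSimSpec(c(1, 2, 3), nCopies = 10, perBaseMutRate = 0,
                      interTypeDiv = 0.12, flankBp = 400L, seed = 29)
  sim0 <- simulateHORArray(spec0)
  # place a single undefined base inside copy 3: the monomer is still
  # detectable (one edit) but must be excluded by the gap filter
  gapAt <- sim0$truth$copies$start[3] + 200L
  spec <- horSimSpec(c(1, 2, 3), nCopies = 10, perBaseMutRate = 0,
                     interTypeDiv = 0.12, flankBp = 400L,
                     nGap = c(gapAt, 1L), seed = 29)
  sim <- simulateHORArray(spec)
  expect_identical(as.character(Biostrings::subseq(sim$genome[[1]],
                                                   gapAt + 1L,
                                                   gapAt + 1L)), "N")
  hits <- scanMonomers(sim$genome, minIdentity = 0.9)
  expect_identical(length(hits), 30L)
  kept <- filterGapOverlaps(hits, sim$genome)
  expect_identical(length(kept), 29L)
  tab <- hitsTable(kept)
  expect_true(all(tab$end <= gapAt | tab$start >= gapAt + 1L))
  # a larger N-run makes the monomer undetectable in the first place:
  # either way nothing overlapping the gap survives
  spec2 <- horSimSpec(c(1, 2, 3), nCopies = 10, perBaseMutRate = 0,
                      interTypeDiv = 0.12, flankBp = 400L,
                      nGap = c(gapAt, 60L), seed = 29)
  sim2 <- simulateHORArray(spec2)
  kept2 <- hitsTable(filterGapOverlaps(
    scanMonomers(sim2$genome, minIdentity = 0.9), sim2$genome))
  expect_true(all(kept2$end <= gapAt | kept2$start >= gapAt + 60L))
  expect_lt(nrow(kept2), 30L)
})

test_that("detectable truth monomers are recovered with >=95% reciprocal overlap", {
  mi <- 0.88
  spec <- horSimSpec(cascadeUnit(list(1:4, c(2, 3, 4, 5))), nCopies = 12,
                     perBaseMutRate = 0.005, interTypeDiv = 0.15,
                     seed = 39)
  sim <- simulateHORArray(spec)
  hits <- hitsTable(scanMonomers(sim$genome, minIdentity = mi))
  tr <- sim$truth$monomers
  g <- as.character(sim$genome[[1]])
  trSeqs <- substring(g, tr$start + 1L, tr$end)
  detectable <- 1 - pairwiseDivergence(consChar(), trSeqs) >= mi
  expect_gt(mean(detectable), 0.9) # the generator targets this regime
  recovered <- 0L
  for (i in which(detectable)) {
    ov <- pmin(tr$end[i], hits$end) - pmax(tr$start[i], hits$start)
    j <- which.max(ov)
    if (ov[j] / (tr$end[i] - tr$start[i]) >= 0.95 &&
        ov[j] / (hits$end[j] - hits$start[j]) >= 0.95) {
      recovered <- recovered + 1L
    }
  }
  expect_identical(recovered, sum(detectable))
})

test_that("cascadeUnit validates its row design", {
  expect_error(cascadeUnit(list(c(2, 1))), "strictly increasing")
  expect_error(cascadeUnit(list(1:3, c(5, 6))), "row break")
  expect_identical(cascadeUnit(list(1:3)), 1:3)
})
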