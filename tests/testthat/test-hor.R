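test_that("anchor segmentation cuts exact cycles and drops edges", {
  # 10 exact cycles of a 5-type unit: cuts at each unit start give 9 full
  # copies; the trailing stretch has no closing anchor and is dropped
  ts <- rep(1:5, 10)
  cp <- segmentHORCopies(ts, c(1L, 50L), 5L)
  expect_identical(nrow(cp), 9L)
  expect_true(all(cp$m == 5L))
  expect_identical(cp$startEnum, as.integer(seq(1, 41, by = 5)))
  expect_true(all(vapply(cp$typeSeq, identical, TRUE, y = 1:5)))
})

test_that("an insertion shows up as one longer inter-anchor copy", {
  # one unit carries a 2-monomer insertion
  ts <- c(rep(1:5, 3), c(1L, 2L, 3L, 8L, 9L, 4L, 5L), rep(1:5, 3))
  cp <- segmentHORCopies(ts, c(1L, length(ts)), 5L)
  expect_identical(sum(cp$m == 7L), 1L)
  expect_identical(cp$typeSeq[[which(cp$m == 7L)]],
                   c(1L, 2L, 3L, 8L, 9L, 4L, 5L))
})

test_that("aperiodic or too-short regions yield no copies", {
  expect_identical(nrow(segmentHORCopies(1:40, c(1L, 40L), 5L)), 0L)
  # region shorter than 2n
  expect_identical(nrow(segmentHORCopies(rep(1:5, 10), c(1L, 9L), 5L)), 0L)
})

test_that("defineCanonical takes the majority, ties to earliest occurrence", {
  mk <- function(tss) {
    cp <- data.frame(copy = seq_along(tss),
                     startEnum = cumsum(c(1L, head(lengths(tss), -1L))),
                     m = lengths(tss))
    cp$typeSeq <- tss
    cp
  }
  X <- c(1L, 2L, 3L)
  Y <- c(1L, 3L, 2L)
  expect_identical(defineCanonical(mk(rep(list(X), 9)), 3L), X)
  expect_identical(defineCanonical(mk(c(rep(list(X), 6), rep(list(Y), 3))),
                                   3L), X)
  # 3 vs 3 tie: earliest-occurring sequence wins
  expect_identical(defineCanonical(mk(c(list(Y), rep(list(X), 3),
                                        rep(list(Y), 2))), 3L), Y)
  # only full n-mers compete
  expect_identical(defineCanonical(mk(list(c(1L, 2L))), 3L), NULL)
})

test_that("classifyCopies labels C by exact match and variants by monomer count", {
  canonical <- c(1L, 2L, 3L, 4L, 5L)
  tss <- list(canonical,
              c(1L, 2L, 3L, 2L, 3L, 4L, 5L),     # internal duplication -> V7
              canonical,
              c(1L, 2L, 9L, 4L, 5L))             # substituted type -> V5
  cp <- data.frame(copy = 1:4,
                   startEnum = cumsum(c(1L, head(lengths(tss), -1L))),
                   m = lengths(tss))
  cp$typeSeq <- tss
  fam <- classifyCopies(cp, canonical)
  expect_identical(copyTable(fam)$label, c("C", "V7", "C", "V5"))
  expect_identical(cvString(fam), "CVCV")
  # count conservation
  ct <- copyTable(fam)
  expect_identical(sum(ct$label == "C") + sum(ct$label != "C"), nrow(ct))
  expect_identical(nchar(cvString(fam)), nrow(ct))
  expect_true(validObject(fam))
})

test_that("re-running classification against the recovered canonical is idempotent", {
  canonical <- c(1L, 2L, 3L, 4L)
  tss <- c(rep(list(canonical), 5), list(c(1L, 2L, 4L)))
  cp <- data.frame(copy = 1:6,
                   startEnum = cumsum(c(1L, head(lengths(tss), -1L))),
                   m = lengths(tss))
  cp$typeSeq <- tss
  fam1 <- classifyCopies(cp, defineCanonical(cp, 4L))
  fam2 <- classifyCopies(copyTable(fam1)[names(cp)],
                         canonicalTypeSeq(fam1))
  expect_identical(copyTable(fam2)$label, copyTable(fam1)$label)
  expect_identical(cvString(fam2), cvString(fam1))
})

# Builds a small in-memory family from explicit monomer sequences, one
# type per unit position.
familyFixture <- function(monomerMatrix, centroids) {
  nCopies <- nrow(monomerMatrix)
  n <- ncol(monomerMatrix)
  seqs <- as.vector(t(monomerMatrix))
  cp <- data.frame(copy = seq_len(nCopies),
                   startEnum = seq(1L, by = n, length.out = nCopies),
                   m = rep(n, nCopies))
  cp$typeSeq <- rep(list(seq_len(n)), nCopies)
  fam <- classifyCopies(cp, seq_len(n))
  asn <- new("TypeAssignment",
             typeIds = rep(seq_len(n), nCopies),
             centroids = setNames(centroids, seq_len(n)),
             divergence = numeric(length(seqs)),
             threshold = 0.05)
  list(fam = fam, seqs = seqs, asn = asn)
}

test_that("familyConsensus votes per aligned column, ties alphabetical", {
  set.seed(301)
  m1 <- randomDnaStr(171)
  m2 <- randomDnaStr(171)

  # identical copies: consensus is any copy's sequence
  fx <- familyFixture(rbind(c(m1, m2), c(m1, m2), c(m1, m2)), c(m1, m2))
  fam <- familyConsensus(fx$fam, fx$seqs, fx$asn)
  expect_identical(consensusSeq(fam), paste0(m1, m2))

  # one copy with a single substitution: 2-vs-1 vote restores the base
  m1mut <- substituteAt(m1, 1, pos = 50)
  fx2 <- familyFixture(rbind(c(m1, m2), c(m1mut, m2), c(m1, m2)),
                       c(m1, m2))
  fam2 <- familyConsensus(fx2$fam, fx2$seqs, fx2$asn)
  expect_identical(consensusSeq(fam2), paste0(m1, m2))

  # 1-vs-1 discordance resolves alphabetically
  v <- strsplit(m1, "")[[1]]
  v[10] <- "A"
  mA <- paste(v, collapse = "")
  v[10] <- "C"
  mC <- paste(v, collapse = "")
  fx3 <- familyFixture(rbind(c(mA, m2), c(mC, m2)), c(mA, m2))
  fam3 <- familyConsensus(fx3$fam, fx3$seqs, fx3$asn)
  expect_identical(substr(consensusSeq(fam3), 10, 10), "A")
})

test_that("divergenceStats measures consensus-referenced percent divergence", {
  set.seed(311)
  m1 <- randomDnaStr(171)
  m2 <- randomDnaStr(171)

  fx <- familyFixture(rbind(c(m1, m2), c(m1, m2)), c(m1, m2))
  fam <- divergenceStats(familyConsensus(fx$fam, fx$seqs, fx$asn), fx$seqs)
  expect_identical(divergencePct(fam)$perCopy, c(0, 0))
  expect_identical(divergencePct(fam)$meanPct, 0)

  # a single canonical copy is its own consensus: divergence 0
  fx1 <- familyFixture(rbind(c(m1, m2)), c(m1, m2))
  fam1 <- divergenceStats(familyConsensus(fx1$fam, fx1$seqs, fx1$asn),
                          fx1$seqs)
  expect_identical(divergencePct(fam1)$perCopy, 0)

  # 3 copies, one with 4 substitutions in one monomer: that copy diverges
  # by 4/342, the others by 0
  m1mut <- substituteAt(m1, 4)
  fx3 <- familyFixture(rbind(c(m1, m2), c(m1mut, m2), c(m1, m2)),
                       c(m1, m2))
  fam3 <- divergenceStats(familyConsensus(fx3$fam, fx3$seqs, fx3$asn),
                          fx3$seqs)
  expect_equal(divergencePct(fam3)$perCopy, c(0, 100 * 4 / 342, 0))
})

test_that("divergence calibration: planted 0.25% mutation recovers within 2 SE", {
  set.seed(321)
  rows58 <- list(1:13, c(12, 13, 14:27), c(22:27, 28), c(20, 21, 28, 29),
                 c(17, 18, 19, 30:44))
  unit <- cascadeUnit(rows58)
  spec <- horSimSpec(unit, nCopies = 50, perBaseMutRate = 0.0025,
                     interTypeDiv = 0.12, flankBp = 0L, seed = 33)
  sim <- simulateHORArray(spec)
  # read the planted monomers straight from the truth table (the scan
  # path is exercised elsewhere; this isolates the divergence estimator)
  tr <- sim$truth$monomers
  seqs <- substring(as.character(sim$genome[[1]]), tr$start + 1L, tr$end)
  n <- length(unit)
  cp <- data.frame(copy = 1:50, startEnum = seq(1L, by = n, length.out = 50),
                   m = rep(n, 50))
  cp$typeSeq <- rep(list(unit), 50)
  asn <- clusterTypes(seqs)
  fam <- classifyCopies(cp, unit)
  fam <- divergenceStats(familyConsensus(fam, seqs, asn), seqs)
  dv <- divergencePct(fam)
  se <- sd(dv$perCopy) / sqrt(dv$nCanonical)
  expect_lt(abs(dv$meanPct - 0.25), 2 * se + 1e-9)
  expect_identical(dv$nCanonical, 50L)
})

test_that("detectHORs recovers planted structure end to end", {
  set.seed(331)
  unit <- cascadeUnit(list(1:4, c(2, 3, 4, 5)))
  cv <- paste(c(rep("C", 5), "V", rep("C", 18), "V", rep("C", 5)),
              collapse = "")
  res <- runDeskPipeline(horSimSpec(unit, nCopies = 30, cvPattern = cv,
                                    perBaseMutRate = 0.0025,
                                    interTypeDiv = 0.15, seed = 44))
  fams <- res$det$families
  expect_identical(length(fams), 1L)
  f <- fams[[1]]
  expect_identical(period(f), 8L)
  # recovered CV string is a prefix of the planted pattern (the final
  # copy has no closing anchor and is dropped)
  expect_identical(cvString(f),
                   substr(cv, 1, nchar(cvString(f))))
  expect_gte(nchar(cvString(f)), 28L)
  # variant copies carry the duplicated-row length
  ct <- copyTable(f)
  expect_true(all(ct$m[ct$label != "C"] == 12L))
})
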