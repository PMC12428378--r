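test_that("exact tandem copies are each recovered at identity 1.0", {
  cons <- consChar()
  g <- Biostrings::DNAStringSet(paste(rep(cons, 10), collapse = ""))
  names(g) <- "t"
  hits <- scanMonomers(g, cons, minIdentity = 0.95)
  tab <- hitsTable(hits)
  expect_identical(nrow(tab), 10L)
  expect_true(all(tab$identity == 1))
  expect_identical(tab$start, as.integer(171 * (0:9))) # 0-based half-open
  expect_identical(tab$end, as.integer(171 * (1:10)))
  expect_true(all(tab$strand == "+"))
  expect_true(all(tab$orientedSeq == cons))
})

test_that("random sequence yields no hits; the exhaustive oracle agrees", {
  set.seed(101)
  cons <- consChar()
  rand <- randomDnaStr(5000)
  hits <- scanMonomers(rand, cons, minIdentity = 0.95)
  expect_identical(length(hits), 0L)
  # exhaustive confirmation on a slice: no window of any plausible length
  # reaches 95% identity
  oracle <- bruteForceScan(substr(rand, 1, 1500), cons, 0.95)
  expect_identical(nrow(oracle), 0L)
})

test_that("a 12-substitution monomer (7% divergence) is rejected at 95%", {
  set.seed(111)
  cons <- consChar()
  diverged <- substituteAt(cons, 12)
  expect_lt(1 - pairwiseDivergence(cons, diverged), 0.95)
  g <- paste0(randomDnaStr(400), diverged, randomDnaStr(400))
  expect_identical(length(scanMonomers(g, cons, minIdentity = 0.95)), 0L)
  # the same monomer is found once the threshold admits it
  expect_identical(length(scanMonomers(g, cons, minIdentity = 0.9)), 1L)
})

test_that("scan equals the exhaustive alignment oracle on small sequences", {
  set.seed(121)
  cons <- consChar()
  for (noise in c(0L, 4L)) {
    mons <- vapply(1:4, function(i) substituteAt(cons, noise), "")
    seqChar <- paste0(randomDnaStr(150), paste(mons, collapse = ""),
                      randomDnaStr(150))
    oracle <- bruteForceScan(seqChar, cons, 0.95)
    tab <- hitsTable(scanMonomers(seqChar, cons, minIdentity = 0.95))
    expect_identical(nrow(tab), nrow(oracle))
    expect_identical(nrow(tab), 4L)
    expect_identical(tab$start + 1L, oracle$start) # 0-based vs 1-based
    expect_identical(tab$end, oracle$end)
    expect_equal(tab$identity, oracle$identity)
  }
})

test_that("reverse-complement symmetry: hits mirror with flipped strands", {
  set.seed(131)
  lib <- makeTypeLibrary(3, interTypeDiv = 0.12)
  mons <- lib[c(1, 2, 3, 1, 2, 3, 1, 2, 3)]
  seqChar <- paste0(randomDnaStr(250), paste(mons, collapse = ""),
                    randomDnaStr(250))
  g <- Biostrings::DNAStringSet(seqChar)
  names(g) <- "f"
  rc <- Biostrings::reverseComplement(g)
  names(rc) <- "f"
  fwd <- hitsTable(scanMonomers(g, minIdentity = 0.9))
  rev <- hitsTable(scanMonomers(rc, minIdentity = 0.9))
  expect_identical(nrow(fwd), 9L)
  expect_true(all(fwd$strand == "+"))
  expect_true(all(rev$strand == "-"))
  L <- nchar(seqChar)
  expect_identical(sort(L - rev$end), sort(fwd$start))
  expect_identical(sort(L - rev$start), sort(fwd$end))
  # oriented sequences read identically in consensus orientation
  expect_setequal(rev$orientedSeq, fwd$orientedSeq)
})

test_that("monomers overlapping N-gaps are excluded", {
  set.seed(141)
  cons <- consChar()
  mons <- rep(cons, 10)
  # plant one N in the middle of copy 5
  v <- strsplit(mons[5], "")[[1]]
  v[85] <- "N"
  mons[5] <- paste(v, collapse = "")
  g <- tandemGenome(mons, flank = 200L)
  hits <- scanMonomers(g, cons, minIdentity = 0.95)
  filtered <- filterGapOverlaps(hits, g)
  expect_identical(length(filtered), 9L)
  # identity case: nothing removed when the assembly has no N
  g2 <- tandemGenome(rep(cons, 10), flank = 200L)
  hits2 <- scanMonomers(g2, cons, minIdentity = 0.95)
  expect_identical(length(filterGapOverlaps(hits2, g2)), 10L)
})

test_that("arrays split where the joining gap is exceeded", {
  set.seed(151)
  cons <- consChar()
  block <- paste(rep(cons, 10), collapse = "")
  # contiguous: one array of 20
  g1 <- tandemGenome(rep(cons, 20), flank = 100L)
  h1 <- segmentArrays(scanMonomers(g1, cons))
  expect_identical(max(S4Vectors::mcols(h1)$arrayId), 1L)
  expect_identical(S4Vectors::mcols(h1)$enumeration, 1:20)

  # 2 kb random spacer > 500 bp default: two arrays
  g2 <- Biostrings::DNAStringSet(paste0(randomDnaStr(100), block,
                                        randomDnaStr(2000), block,
                                        randomDnaStr(100)))
  names(g2) <- "two"
  h2 <- segmentArrays(scanMonomers(g2, cons))
  at <- arrayTable(h2)
  expect_identical(nrow(at), 2L)
  expect_identical(at$nMonomers, c(10L, 10L))
  expect_identical(at$orientation, c("+", "+"))

  # empty hit set: empty array list
  empty <- segmentArrays(scanMonomers(randomDnaStr(2000), cons))
  expect_identical(length(empty), 0L)
  expect_identical(nrow(arrayTable(empty)), 0L)
})

test_that("strand coherence within a single-orientation array", {
  set.seed(161)
  spec <- horSimSpec(c(1, 2, 3), nCopies = 8, perBaseMutRate = 0,
                     interTypeDiv = 0.12, flankBp = 300L, seed = 7)
  sim <- simulateHORArray(spec)
  hits <- scanMonomers(sim$genome, minIdentity = 0.9)
  expect_identical(length(unique(as.character(GenomicRanges::strand(hits)))),
                   1L)
})

test_that("retained hits are non-overlapping, sorted, within length bounds", {
  set.seed(171)
  spec <- horSimSpec(c(1, 2, 3, 4), nCopies = 10,
                     perBaseMutRate = 0.005, interTypeDiv = 0.12,
                     flankBp = 400L, seed = 13)
  sim <- simulateHORArray(spec)
  tab <- hitsTable(scanMonomers(sim$genome, minIdentity = 0.9))
  expect_false(is.unsorted(tab$start, strictly = TRUE))
  expect_true(all(tab$start[-1L] >= head(tab$end, -1L)))
  w <- tab$end - tab$start
  expect_true(all(w >= 150 & w <= 200))
  expect_true(all(tab$identity >= 0.9))
})
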