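# Shared fixture builders. Everything is generated in code; seeds are
# fixed per test so reruns are deterministic.

consChar <- function() as.character(defaultConsensus())

randomDnaStr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Substitute exactly `k` positions of `s` (never restoring the original
# base), at sampled or given positions.
substituteAt <- function(s, k, pos = NULL) {
  v <- strsplit(s, "")[[1]]
  if (is.null(pos)) {
    pos <- sample(length(v), k)
  }
  for (p in pos) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1L)
  }
  paste(v, collapse = "")
}

# A plain tandem head-to-tail repeat of `copies` monomer sequences with
# random flanks, as a DNAStringSet.
tandemGenome <- function(monomers, flank = 300L) {
  g <- Biostrings::DNAStringSet(paste0(
    randomDnaStr(flank), paste(monomers, collapse = ""),
    randomDnaStr(flank)))
  names(g) <- "fixture"
  g
}

# Independent exhaustive scan oracle built on utils::adist: aligns the
# consensus globally against every window (all starts x all plausible
# lengths), computes identity as 1 - edits / alignment columns, then
# greedily tiles by identity (ties to leftmost start). 1-based closed
# coordinates, '+' strand only.
bruteForceScan <- function(seqChar, cons, minIdentity) {
  L <- nchar(seqChar)
  Lc <- nchar(cons)
  budget <- floor((1 - minIdentity) / minIdentity * Lc)
  lens <- max(150L, Lc - budget):min(200L, Lc + budget)
  cand <- list()
  for (w in lens) {
    if (w > L) next
    starts <- seq_len(L - w + 1L)
    wins <- substring(seqChar, starts, starts + w - 1L)
    d <- utils::adist(cons, wins, counts = TRUE)
    cols <- nchar(attr(d, "trafos")[1L, ])
    idy <- 1 - as.numeric(d) / cols
    keep <- idy >= minIdentity
    if (any(keep)) {
      cand[[length(cand) + 1L]] <- data.frame(
        start = starts[keep], end = starts[keep] + w - 1L,
        identity = idy[keep])
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      identity = numeric(0)))
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$identity, cand$start), , drop = FALSE]
  occ <- logical(L)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    span <- cand$start[i]:cand$end[i]
    if (!any(occ[span])) {
      occ[span] <- TRUE
      keep[i] <- TRUE
    }
  }
  res <- cand[keep, , drop = FALSE]
  res[order(res$start), , drop = FALSE]
}

# O(n^2) MD-point definition, straight from first principles.
bruteForceMdPoints <- function(typeSeq, maxPeriod = 90L) {
  out <- list()
  n <- length(typeSeq)
  for (l in seq_len(n)) {
    for (j in (l + 1L):n) {
      if (j > n) break
      if (typeSeq[j] == typeSeq[l]) {
        p <- j - l
        if (p <= maxPeriod) {
          out[[length(out) + 1L]] <- c(l, p)
        }
        break
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(enumeration = integer(0), period = integer(0)))
  }
  m <- do.call(rbind, out)
  data.frame(enumeration = m[, 1L], period = m[, 2L])
}

# End-to-end helper: simulate, scan, type, detect; returns the detection
# plus the simulation truth.
runDeskPipeline <- function(spec, minIdentity = 0.88, minRun = 10L) {
  sim <- simulateHORArray(spec)
  hits <- scanMonomers(sim$genome, minIdentity = minIdentity)
  hits <- filterGapOverlaps(hits, sim$genome)
  hits <- segmentArrays(hits)
  asn <- clusterTypes(hits)
  det <- detectHORs(asn, hits, minRun = minRun)
  list(sim = sim, hits = hits, assignment = asn, det = det)
}
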