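#' Scan a genome sequence for alpha-satellite monomers
#'
#' Locates monomers by aligning a consensus monomer against the sequence in
#' both orientations and retaining matches whose alignment identity
#' (matching columns / alignment columns, indel-tolerant) reaches
#' `minIdentity`. Candidate locations are seeded with exact k-mers of the
#' consensus, refined to exact boundaries by a fit alignment (consensus
#' global, window free at both ends), extended through tandem gap-filling
#' (a monomer missed by seeding is recovered by aligning into the gap left
#' between its accepted neighbours), and finally tiled greedily: where
#' refined hits overlap, higher identity wins, ties break to the leftmost
#' start.
#'
#' @param genome a `DNAStringSet` (e.g. from [readGenome()]), `DNAString`,
#'   or character vector of sequences.
#' @param consensus consensus monomer (150-200 bp, no N); default the
#'   shipped synthetic stand-in, see [defaultConsensus()].
#' @param minIdentity minimum alignment identity for a retained monomer.
#'   The default follows the conventional 95% threshold; for arrays whose
#'   monomer types diverge more than `2 * (1 - minIdentity)` from each
#'   other, no single consensus can sit within reach of all types, so the
#'   threshold must be lowered accordingly (see the package vignette).
#' @param seedK,seedStep exact-seed length and spacing along the consensus.
#' @return a `GRanges` (1-based, Bioconductor convention) with metadata
#'   columns `identity` and `orientedSeq` (reverse-complemented for `-`
#'   hits so all monomers read in consensus orientation). Use
#'   [hitsTable()] for the 0-based half-open tabular view.
#' @seealso [filterGapOverlaps()], [segmentArrays()]
#' @export
scanMonomers <- function(genome, consensus = defaultConsensus(),
                         minIdentity = 0.95, seedK = 12L, seedStep = 2L) {
  cons <- checkConsensus(consensus)
  if (minIdentity <= 0.5 || minIdentity > 1) {
    stop("minIdentity must be in (0.5, 1]")
  }
  genome <- asGenome(genome)
  res <- lapply(seq_along(genome), function(i) {
    scanOneSequence(names(genome)[i], genome[[i]], cons, minIdentity,
                    seedK, seedStep)
  })
  gr <- do.call(c, res)
  GenomeInfoDb::seqlengths(gr) <-
    setNames(Biostrings::width(genome), names(genome))[
      GenomeInfoDb::seqlevels(gr)]
  gr
}

# Coerce supported genome inputs to a named DNAStringSet.
asGenome <- function(genome) {
  if (is(genome, "DNAString")) {
    genome <- Biostrings::DNAStringSet(genome)
    names(genome) <- "seq1"
  } else if (is.character(genome)) {
    nm <- names(genome)
    genome <- Biostrings::DNAStringSet(toupper(genome))
    names(genome) <- if (is.null(nm)) paste0("seq", seq_along(genome)) else nm
  } else if (!is(genome, "DNAStringSet")) {
    stop("genome must be a DNAStringSet, DNAString or character vector")
  }
  if (is.null(names(genome))) {
    names(genome) <- paste0("seq", seq_along(genome))
  }
  genome
}

scanOneSequence <- function(seqName, subject, cons, minIdentity,
                            seedK, seedStep) {
  s <- as.character(subject)
  Ls <- nchar(s)
  Lc <- nchar(cons)
  consRc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(cons)))
  budget <- floor((1 - minIdentity) / minIdentity * Lc) # max edits at threshold
  pad <- budget + 6L

  emptyHits <- function() {
    GenomicRanges::GRanges(
      seqnames = character(0), ranges = IRanges::IRanges(),
      strand = character(0),
      identity = numeric(0), orientedSeq = character(0))
  }
  if (Ls < Lc) {
    return(emptyHits())
  }

  fwd <- seedCandidates(cons, subject, seedK, seedStep, Lc)
  rev <- seedCandidates(consRc, subject, seedK, seedStep, Lc)
  cand <- data.frame(start = c(fwd, rev),
                     strand = rep(c("+", "-"), c(length(fwd), length(rev))))
  hits <- refineCandidates(cand, s, cons, consRc, Lc, pad, minIdentity)
  hits <- tileGreedy(hits, Ls)
  hits <- fillGaps(hits, s, cons, consRc, Lc, pad, minIdentity, Ls)
  if (nrow(hits) == 0L) {
    return(emptyHits())
  }
  orientedSeq <- substr(rep(s, nrow(hits)), hits$start, hits$end)
  neg <- hits$strand == "-"
  if (any(neg)) {
    orientedSeq[neg] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(orientedSeq[neg])))
  }
  GenomicRanges::GRanges(
    seqnames = seqName,
    ranges = IRanges::IRanges(start = hits$start, end = hits$end),
    strand = hits$strand,
    identity = hits$identity,
    orientedSeq = orientedSeq
  )
}

# Exact k-mer seeding: each seed match back-projects to an estimated
# monomer start; estimates within 40 bp collapse to one candidate.
seedCandidates <- function(pattern, subject, seedK, seedStep, Lc) {
  offs <- seq(1L, Lc - seedK + 1L, by = seedStep)
  kmers <- Biostrings::DNAStringSet(substring(pattern, offs,
                                              offs + seedK - 1L))
  keep <- !grepl("N", as.character(kmers), fixed = TRUE)
  offs <- offs[keep]
  kmers <- kmers[keep]
  pd <- Biostrings::PDict(kmers)
  m <- Biostrings::matchPDict(pd, subject)
  starts <- unlist(lapply(seq_along(offs), function(i) {
    IRanges::start(m[[i]]) - (offs[i] - 1L)
  }), use.names = FALSE)
  if (length(starts) == 0L) {
    return(integer(0))
  }
  starts <- sort(pmax(starts, 1L))
  grp <- cumsum(c(1L, diff(starts) > 40L))
  as.integer(tapply(starts, grp, function(x) x[ceiling(length(x) / 2)]))
}

refineCandidates <- function(cand, s, cons, consRc, Lc, pad, minIdentity) {
  out <- list()
  for (st in c("+", "-")) {
    starts <- cand$start[cand$strand == st]
    if (length(starts) == 0L) next
    ws <- pmax(starts - pad, 1L)
    we <- pmin(starts + Lc - 1L + pad, nchar(s))
    windows <- substring(s, ws, we)
    fit <- fit_align_cpp(if (st == "+") cons else consRc, windows)
    identity <- 1 - fit$ed / fit$cols
    hs <- ws + fit$start      # fit$start is 0-based offset in window
    he <- ws + fit$end - 1L
    len <- he - hs + 1L
    keep <- identity >= minIdentity & len >= 150L & len <= 200L
    if (any(keep)) {
      out[[st]] <- data.frame(start = hs[keep], end = he[keep],
                              strand = st, identity = identity[keep])
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), identity = numeric(0)))
  }
  hits <- do.call(rbind, out)
  hits[!duplicated(hits[c("start", "end", "strand")]), , drop = FALSE]
}

# Greedy tiling: higher identity wins, ties to leftmost start ('+' before
# '-' on a full tie, for determinism).
tileGreedy <- function(hits, Ls) {
  if (nrow(hits) <= 1L) {
    return(hits[order(hits$start), , drop = FALSE])
  }
  ord <- order(-hits$identity, hits$start, hits$strand)
  hits <- hits[ord, , drop = FALSE]
  occ <- logical(Ls)
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    span <- hits$start[i]:hits$end[i]
    if (!any(occ[span])) {
      occ[span] <- TRUE
      keep[i] <- TRUE
    }
  }
  res <- hits[keep, , drop = FALSE]
  res[order(res$start), , drop = FALSE]
}

# Tandem gap-filling: monomers missed by exact seeding (too divergent for
# any intact seed) sit in >=150 bp gaps between accepted hits; align the
# consensus strictly inside each gap and accept while the identity
# threshold holds. Accepted fills never overlap existing hits, so each
# round shrinks the uncovered sequence and the loop terminates.
fillGaps <- function(hits, s, cons, consRc, Lc, pad, minIdentity, Ls) {
  repeat {
    gaps <- uncoveredGaps(hits, Ls)
    gaps <- gaps[gaps$width >= 150L, , drop = FALSE]
    if (nrow(gaps) == 0L) {
      return(hits)
    }
    added <- FALSE
    for (g in seq_len(nrow(gaps))) {
      win <- substring(s, gaps$start[g], gaps$end[g])
      best <- NULL
      for (st in c("+", "-")) {
        fit <- fit_align_cpp(if (st == "+") cons else consRc, win)
        identity <- 1 - fit$ed / fit$cols
        hs <- gaps$start[g] + fit$start
        he <- gaps$start[g] + fit$end - 1L
        len <- he - hs + 1L
        if (identity >= minIdentity && len >= 150L && len <= 200L &&
            (is.null(best) || identity > best$identity)) {
          best <- data.frame(start = hs, end = he, strand = st,
                             identity = identity)
        }
      }
      if (!is.null(best)) {
        hits <- rbind(hits, best)
        added <- TRUE
      }
    }
    if (!added) {
      return(hits)
    }
    hits <- hits[order(hits$start), , drop = FALSE]
  }
}

uncoveredGaps <- function(hits, Ls) {
  if (nrow(hits) == 0L) {
    return(data.frame(start = 1L, end = Ls, width = Ls))
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  bounds <- c(0L, hits$end, Ls + 1L)
  starts <- head(bounds, -1L) + 1L
  ends <- c(hits$start - 1L, Ls)
  keep <- ends >= starts
  data.frame(start = starts[keep], end = ends[keep],
             width = ends[keep] - starts[keep] + 1L)
}

#' Exclude monomers overlapping assembly gaps
#'
#' Undefined bases (`N`) in the assembly mark gaps; any monomer whose span
#' contains at least one `N` is excluded to prevent spurious HOR calls
#' across gapped sequence.
#'
#' @param hits `GRanges` from [scanMonomers()].
#' @param genome the genome the hits were scanned from.
#' @return the filtered `GRanges`.
#' @export
filterGapOverlaps <- function(hits, genome) {
  if (length(hits) == 0L) {
    return(hits)
  }
  genome <- asGenome(genome)
  seqs <- genome[as.character(GenomicRanges::seqnames(hits))]
  frag <- Biostrings::subseq(seqs, start = GenomicRanges::start(hits),
                             end = GenomicRanges::end(hits))
  nN <- Biostrings::letterFrequency(frag, "N")[, 1L]
  hits[nN == 0L]
}

#' Group tandem monomer hits into arrays and enumerate them
#'
#' Partitions the (sorted, non-overlapping) hits into tandem arrays
#' wherever the gap between consecutive monomers exceeds `maxJoinGap` (or
#' the sequence changes), and assigns the global 1-based monomer
#' enumeration used by the MD diagram, concatenating arrays in genomic
#' order.
#'
#' @param hits `GRanges` from [scanMonomers()] (after
#'   [filterGapOverlaps()]).
#' @param maxJoinGap maximum base-pair gap joining two monomers into one
#'   array (default 500, about three monomer lengths).
#' @return the `GRanges` with metadata columns `arrayId` and `enumeration`
#'   added.
#' @seealso [arrayTable()]
#' @export
segmentArrays <- function(hits, maxJoinGap = 500L) {
  if (length(hits) == 0L) {
    S4Vectors::mcols(hits)$arrayId <- integer(0)
    S4Vectors::mcols(hits)$enumeration <- integer(0)
    return(hits)
  }
  ord <- order(match(as.character(GenomicRanges::seqnames(hits)),
                     GenomeInfoDb::seqlevels(hits)),
               GenomicRanges::start(hits))
  hits <- hits[ord]
  sq <- as.character(GenomicRanges::seqnames(hits))
  gap <- GenomicRanges::start(hits)[-1L] -
    GenomicRanges::end(hits)[-length(hits)] - 1L
  newArray <- c(TRUE, sq[-1L] != sq[-length(sq)] | gap > maxJoinGap)
  S4Vectors::mcols(hits)$arrayId <- cumsum(newArray)
  S4Vectors::mcols(hits)$enumeration <- seq_along(hits)
  hits
}

#' Summarise monomer arrays
#'
#' @param hits enumerated `GRanges` from [segmentArrays()].
#' @return data.frame with one row per array: `arrayId`, `seqName`,
#'   `start`, `end` (0-based half-open), `nMonomers`, `orientation`
#'   (`+`/`-`/`mixed`).
#' @export
arrayTable <- function(hits) {
  if (length(hits) == 0L) {
    return(data.frame(arrayId = integer(0), seqName = character(0),
                      start = integer(0), end = integer(0),
                      nMonomers = integer(0), orientation = character(0)))
  }
  id <- S4Vectors::mcols(hits)$arrayId
  df <- data.frame(
    arrayId = unique(id),
    seqName = tapply(as.character(GenomicRanges::seqnames(hits)), id,
                     `[`, 1L),
    start = as.integer(tapply(GenomicRanges::start(hits), id, min)) - 1L,
    end = as.integer(tapply(GenomicRanges::end(hits), id, max)),
    nMonomers = as.integer(tapply(id, id, length)),
    orientation = tapply(as.character(GenomicRanges::strand(hits)), id,
                         function(x) {
                           u <- unique(x)
                           if (length(u) == 1L) u else "mixed"
                         })
  )
  rownames(df) <- NULL
  df
}

#' Tabular (0-based half-open) view of monomer hits
#'
#' @param hits `GRanges` of monomer hits, optionally enumerated.
#' @return data.frame with columns `enumeration` (NA before
#'   [segmentArrays()]), `seqName`, `start`, `end` (0-based half-open),
#'   `strand`, `identity`, `orientedSeq`.
#' @export
hitsTable <- function(hits) {
  mc <- S4Vectors::mcols(hits)
  data.frame(
    enumeration = if ("enumeration" %in% names(mc)) {
      mc$enumeration
    } else {
      rep(NA_integer_, length(hits))
    },
    seqName = as.character(GenomicRanges::seqnames(hits)),
    start = GenomicRanges::start(hits) - 1L,
    end = GenomicRanges::end(hits),
    strand = as.character(GenomicRanges::strand(hits)),
    identity = mc$identity,
    orientedSeq = mc$orientedSeq
  )
}
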