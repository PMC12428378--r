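#' Segment a candidate array region into HOR copies
#'
#' Picks an anchor monomer type and cuts the region at every occurrence of
#' it. Anchor selection: positions `i` where the next two `n`-windows of
#' the type sequence coincide (`typeSeq[i..i+n) == typeSeq[i+n..i+2n)`)
#' begin exact cycles; among types occurring once per cycle (types
#' repeated within the unit would cut units apart), the type most
#' frequently beginning an exact cycle becomes the anchor, ties broken by
#' earliest occurrence. The stretches between consecutive anchors are the
#' HOR copies; stretches whose length differs from `n` are variant
#' candidates; partial stretches before the first and after the last
#' anchor are dropped.
#'
#' Because structural variants depress the exact-period MD density, the
#' called region can underestimate the array's extent (a variant-rich
#' head or tail); the anchor itself delimits the array more reliably, so
#' after anchor selection all anchor occurrences chained at gaps of at
#' most `2n` (and not crossing a tandem-array boundary) define the copy
#' run, extending the called region where the array genuinely continues.
#'
#' @param typeSeq full monomer type sequence in enumeration order.
#' @param region length-2 integer (start, end enumeration) from
#'   [horRegions()] or [mdLineSegments()].
#' @param n the HOR unit period.
#' @param arrayIds optional integer vector parallel to `typeSeq` (the
#'   `arrayId` column from [segmentArrays()]); copies never span two
#'   arrays.
#' @return data.frame with one row per copy: `copy`, `startEnum`, `m`
#'   (monomer count) and list-column `typeSeq`; zero rows if the region is
#'   shorter than `2n` or no anchor is found.
#' @export
segmentHORCopies <- function(typeSeq, region, n, arrayIds = NULL) {
  if (is(typeSeq, "TypeAssignment")) {
    typeSeq <- typeIds(typeSeq)
  }
  s <- as.integer(region[1L])
  e <- as.integer(region[2L])
  ts <- typeSeq[s:e]
  len <- length(ts)
  if (len < 2L * n) {
    return(emptyCopies())
  }
  eq <- ts[seq_len(len - n)] == ts[seq_len(len - n) + n]
  win <- cumsum(c(0L, as.integer(eq)))
  nCyc <- len - 2L * n + 1L
  cycStart <- which(win[seq_len(nCyc) + n] - win[seq_len(nCyc)] == n)
  if (length(cycStart) == 0L) {
    return(emptyCopies())
  }
  unit0 <- ts[cycStart[1L] + 0:(n - 1L)]
  singles <- as.integer(names(which(table(unit0) == 1L)))
  starterTypes <- ts[cycStart]
  pool <- if (any(starterTypes %in% singles)) {
    unique(starterTypes[starterTypes %in% singles])
  } else {
    unique(starterTypes)
  }
  # prefer the candidate occurring least often overall (variants that
  # duplicate a block inflate the counts of the duplicated types, and
  # cutting at a duplicated type would split those variants in two), then
  # the most frequent cycle starter, then the earliest occurrence
  occ <- vapply(pool, function(t) sum(ts == t), integer(1))
  starts <- vapply(pool, function(t) sum(starterTypes == t), integer(1))
  ord <- order(occ, -starts, match(pool, ts))
  anchor <- pool[ord[1L]]

  # chain anchor occurrences across the whole enumeration: gaps over 2n
  # (or a tandem-array boundary) end the array
  allCuts <- which(typeSeq == anchor)
  if (length(allCuts) < 2L) {
    return(emptyCopies())
  }
  brk <- diff(allCuts) > 2L * n
  if (!is.null(arrayIds)) {
    brk <- brk | (arrayIds[allCuts[-1L]] !=
                    arrayIds[allCuts[-length(allCuts)]])
  }
  chain <- cumsum(c(1L, as.integer(brk)))
  # keep the chain overlapping the called region
  inRegion <- allCuts >= s & allCuts <= e
  if (!any(inRegion)) {
    return(emptyCopies())
  }
  keep <- chain == chain[which(inRegion)[1L]]
  cuts <- allCuts[keep]
  if (length(cuts) < 2L) {
    return(emptyCopies())
  }
  starts <- cuts[-length(cuts)]
  ends <- cuts[-1L] - 1L
  m <- ends - starts + 1L
  ok <- m <= 2L * n # a stretch beyond 2n is a break, not a copy
  if (!is.null(arrayIds)) {
    ok <- ok & vapply(seq_along(starts), function(i) {
      length(unique(arrayIds[starts[i]:ends[i]])) == 1L
    }, logical(1))
  }
  starts <- starts[ok]
  ends <- ends[ok]
  out <- data.frame(copy = seq_along(starts),
                    startEnum = starts,
                    m = ends - starts + 1L)
  out$typeSeq <- lapply(seq_along(starts), function(i) {
    typeSeq[starts[i]:ends[i]]
  })
  out
}

emptyCopies <- function() {
  out <- data.frame(copy = integer(0), startEnum = integer(0),
                    m = integer(0))
  out$typeSeq <- list()
  out
}

#' Define the canonical HOR unit
#'
#' The canonical HOR is the most frequent complete `n`-mer type sequence
#' among the segmented copies; ties break to the earliest-occurring
#' sequence.
#'
#' @param copies copy table from [segmentHORCopies()].
#' @param n the unit period.
#' @return integer vector of `n` type ids, or `NULL` when no complete
#'   `n`-mer copy exists.
#' @export
defineCanonical <- function(copies, n) {
  full <- copies[copies$m == n, , drop = FALSE]
  if (nrow(full) == 0L) {
    return(NULL)
  }
  keys <- vapply(full$typeSeq, paste, character(1), collapse = ",")
  tab <- table(keys)
  best <- names(tab)[tab == max(tab)]
  key <- keys[keys %in% best][1L] # earliest occurrence among tied
  full$typeSeq[[match(key, keys)]]
}

#' Classify HOR copies as canonical or variant
#'
#' A copy is canonical (`C`) iff its type sequence matches the canonical
#' exactly; any deviation (insertion, deletion or internal duplication of
#' monomers, or a substituted type) makes it a variant labelled `V<m>` by
#' its monomer count, following the field's convention (e.g. a copy that
#' duplicates a 16-monomer row of a 58mer becomes `V74`). The per-copy
#' monomer-level edit operations against the canonical are recorded.
#'
#' @param copies copy table from [segmentHORCopies()].
#' @param canonical integer vector from [defineCanonical()].
#' @return a [HORFamily-class] (without consensus/divergence, which are
#'   added by [familyConsensus()] and [divergenceStats()]).
#' @export
classifyCopies <- function(copies, canonical) {
  n <- length(canonical)
  canonKey <- paste(canonical, collapse = ",")
  keys <- vapply(copies$typeSeq, paste, character(1), collapse = ",")
  labels <- ifelse(keys == canonKey, "C", paste0("V", copies$m))
  copies$label <- labels
  copies$editOps <- vapply(seq_len(nrow(copies)), function(i) {
    if (labels[i] == "C") {
      ""
    } else {
      typeEditOps(canonical, copies$typeSeq[[i]])
    }
  }, character(1))
  span <- if (nrow(copies)) {
    c(min(copies$startEnum),
      max(copies$startEnum + copies$m - 1L))
  } else {
    c(NA_integer_, NA_integer_)
  }
  new("HORFamily",
      period = as.integer(n),
      canonicalTypeSeq = as.integer(canonical),
      copies = copies,
      cvString = paste(ifelse(labels == "C", "C", "V"), collapse = ""),
      span = as.integer(span))
}

# Compact edit script of a variant type sequence against the canonical,
# e.g. "=13 +16 =45" (monomers kept / inserted / deleted).
typeEditOps <- function(canonical, ts) {
  aln <- alignIntSeqs(canonical, ts)
  ops <- character(0)
  ri <- 0L
  qi <- 0L
  k <- 0L
  flush <- function(ops, k) {
    if (k > 0L) c(ops, paste0("=", k)) else ops
  }
  for (t in seq_along(aln$refIdx)) {
    dr <- aln$refIdx[t] - ri - 1L
    dq <- aln$qryIdx[t] - qi - 1L
    if (dr > 0L || dq > 0L) {
      ops <- flush(ops, k)
      k <- 0L
      if (dr > 0L) ops <- c(ops, paste0("-", dr))
      if (dq > 0L) ops <- c(ops, paste0("+", dq))
    }
    mism <- canonical[aln$refIdx[t]] != ts[aln$qryIdx[t]]
    if (mism) {
      ops <- flush(ops, k)
      k <- 0L
      ops <- c(ops, "x1")
    } else {
      k <- k + 1L
    }
    ri <- aln$refIdx[t]
    qi <- aln$qryIdx[t]
  }
  ops <- flush(ops, k)
  dr <- length(canonical) - ri
  dq <- length(ts) - qi
  if (dr > 0L) ops <- c(ops, paste0("-", dr))
  if (dq > 0L) ops <- c(ops, paste0("+", dq))
  paste(ops, collapse = " ")
}

#' Family consensus sequence from canonical copies
#'
#' Builds the consensus nucleotide sequence of the canonical HOR unit by
#' majority vote per aligned column: canonical copies share the canonical
#' type sequence, so columns pair up monomer-by-monomer; within a monomer,
#' positions are aligned by a unit-cost global alignment to the type
#' centroid. Base ties break alphabetically.
#'
#' @param family a [HORFamily-class].
#' @param orientedSeqs oriented monomer sequences in enumeration order.
#' @param assignment the [TypeAssignment-class] providing type centroids.
#' @return the family with `consensus` and `consensusMonomers` filled in.
#' @export
familyConsensus <- function(family, orientedSeqs, assignment) {
  if (is(orientedSeqs, "GRanges")) {
    orientedSeqs <- S4Vectors::mcols(orientedSeqs)$orientedSeq
  }
  canon <- family@canonicalTypeSeq
  copies <- family@copies
  cIdx <- which(copies$label == "C")
  if (length(cIdx) == 0L) {
    stop("family has no canonical copy")
  }
  consMon <- vapply(seq_along(canon), function(j) {
    cent <- assignment@centroids[[canon[j]]]
    seqs <- vapply(cIdx, function(ci) {
      orientedSeqs[copies$startEnum[ci] + j - 1L]
    }, character(1))
    proj <- align_map_cpp(cent, seqs)
    mat <- do.call(rbind, strsplit(proj, ""))
    cons <- vapply(seq_len(ncol(mat)), function(p) {
      v <- mat[, p]
      v <- v[v != "-"]
      if (length(v) == 0L) {
        return("")
      }
      tab <- table(v)
      sort(names(tab)[tab == max(tab)])[1L] # alphabetical tie-break
    }, character(1))
    paste(cons, collapse = "")
  }, character(1))
  family@consensusMonomers <- consMon
  family@consensus <- paste(consMon, collapse = "")
  family
}

#' Divergence of canonical copies from the family consensus
#'
#' Per-copy percent divergence is measured monomer-by-monomer against the
#' consensus unit (total edits over total alignment columns, times 100);
#' the family statistic is the arithmetic mean over canonical copies.
#'
#' @param family a [HORFamily-class] with consensus computed.
#' @param orientedSeqs oriented monomer sequences in enumeration order.
#' @return the family with `divergencePerCopy` filled in; retrieve with
#'   [divergencePct()].
#' @export
divergenceStats <- function(family, orientedSeqs) {
  if (is(orientedSeqs, "GRanges")) {
    orientedSeqs <- S4Vectors::mcols(orientedSeqs)$orientedSeq
  }
  if (length(family@consensusMonomers) == 0L) {
    stop("compute familyConsensus() first")
  }
  copies <- family@copies
  cIdx <- which(copies$label == "C")
  per <- vapply(cIdx, function(ci) {
    eds <- 0
    cols <- 0
    for (j in seq_along(family@consensusMonomers)) {
      st <- edit_stats_cpp(family@consensusMonomers[j],
                           orientedSeqs[copies$startEnum[ci] + j - 1L])
      eds <- eds + st[1L, 1L]
      cols <- cols + st[2L, 1L]
    }
    100 * eds / cols
  }, numeric(1))
  family@divergencePerCopy <- per
  family
}

#' Detect and classify all HOR families in an enumerated monomer array
#'
#' End-to-end HOR detection on a typed monomer enumeration: computes
#' MD-points, locates candidate array regions and their unit periods
#' ([horRegions()]), segments each region into copies, defines the
#' canonical unit, classifies copies as canonical/variant, reconciles
#' monomer types with the column structure, and computes the family
#' consensus and divergence statistics. Families are returned in
#' decreasing order of copy count.
#'
#' @param assignment a [TypeAssignment-class].
#' @param orientedSeqs oriented monomer sequences in enumeration order (or
#'   the enumerated `GRanges`).
#' @param maxPeriod,minRun,minDensity,coherenceFrac see [horRegions()].
#' @return list with elements `families` (list of [HORFamily-class]),
#'   `assignment` (possibly column-reconciled), `points` (MD-points) and
#'   `histogram` (period frequencies).
#' @export
detectHORs <- function(assignment, orientedSeqs, maxPeriod = 90L,
                       minRun = 20L, minDensity = 0.3,
                       coherenceFrac = 0.95) {
  arrayIds <- NULL
  if (is(orientedSeqs, "GRanges")) {
    mc <- S4Vectors::mcols(orientedSeqs)
    if ("arrayId" %in% names(mc)) {
      arrayIds <- mc$arrayId
    }
    orientedSeqs <- mc$orientedSeq
  }
  points <- mdPoints(assignment, maxPeriod)
  hist <- periodHistogram(points, maxPeriod)
  regions <- horRegions(points, assignment, maxPeriod, minRun, minDensity,
                        coherenceFrac)
  families <- list()
  claimed <- logical(length(typeIds(assignment)))
  for (ri in seq_len(nrow(regions))) {
    n <- regions$period[ri]
    # anchor chains may extend past their called region; skip regions an
    # earlier family has already absorbed
    if (mean(claimed[regions$startEnum[ri]:regions$endEnum[ri]]) > 0.5) {
      next
    }
    # MD-points at subfragment periods only begin at the first
    # repeated-type offset of a unit, so the called region can truncate
    # the first and last copies (a leading structural variant spans more
    # than one period); two unit periods of slack on each side restores
    # them, and anchor cutting trims any excess
    region <- c(max(1L, regions$startEnum[ri] - 2L * n),
                min(length(typeIds(assignment)),
                    regions$endEnum[ri] + 2L * n))
    copies <- segmentHORCopies(typeIds(assignment), region, n, arrayIds)
    if (nrow(copies) == 0L) next
    canonical <- defineCanonical(copies, n)
    if (is.null(canonical)) next
    # integrate positional context into the typing, then re-segment once
    reconciled <- reconcileTypesWithColumns(assignment, copies, canonical,
                                            orientedSeqs)
    if (!identical(typeIds(reconciled), typeIds(assignment))) {
      assignment <- reconciled
      copies <- segmentHORCopies(typeIds(assignment), region, n, arrayIds)
      canonical <- defineCanonical(copies, n)
      if (is.null(canonical)) next
    }
    fam <- classifyCopies(copies, canonical)
    fam <- familyConsensus(fam, orientedSeqs, assignment)
    fam <- divergenceStats(fam, orientedSeqs)
    claimed[fam@span[1L]:fam@span[2L]] <- TRUE
    families[[length(families) + 1L]] <- fam
  }
  if (length(families) > 1L) {
    families <- families[order(-vapply(families,
                                       function(f) nrow(f@copies),
                                       numeric(1)))]
  }
  list(families = families, assignment = assignment, points = points,
       histogram = hist)
}
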