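#' Classify monomers into types by greedy centroid clustering
#'
#' Walks the monomers in enumeration order; each monomer joins the first
#' existing type whose centroid lies strictly within `typeThreshold`
#' divergence (see [pairwiseDivergence()]), otherwise it founds a new type
#' whose centroid is its own sequence. Centroids are static (the founding
#' monomer), which keeps assignment order-stable and prevents the chaining
#' that single-linkage clustering would allow across the threshold.
#' Clustering always operates on strand-corrected (oriented) sequences: a
#' monomer and its reverse complement are the same biological monomer.
#'
#' @param orientedSeqs character vector of oriented monomer sequences in
#'   enumeration order, or an enumerated `GRanges` from [segmentArrays()]
#'   (its `orientedSeq` column is used).
#' @param typeThreshold divergence threshold, strict `<` (default 0.05).
#' @return a [TypeAssignment-class].
#' @export
clusterTypes <- function(orientedSeqs, typeThreshold = 0.05) {
  if (is(orientedSeqs, "GRanges")) {
    orientedSeqs <- S4Vectors::mcols(orientedSeqs)$orientedSeq
  }
  orientedSeqs <- toupper(as.character(orientedSeqs))
  if (length(orientedSeqs) == 0L) {
    stop("cannot cluster an empty monomer array")
  }
  if (typeThreshold <= 0 || typeThreshold >= 1) {
    stop("typeThreshold must be a fraction in (0, 1)")
  }
  n <- length(orientedSeqs)
  ids <- integer(n)
  divs <- numeric(n)
  centroids <- character(0)
  for (i in seq_len(n)) {
    if (length(centroids)) {
      d <- boundedDivergence(orientedSeqs[i], centroids, typeThreshold)
      hit <- which(!is.na(d) & d < typeThreshold)
    } else {
      hit <- integer(0)
    }
    if (length(hit)) {
      ids[i] <- hit[1L]
      divs[i] <- d[hit[1L]]
    } else {
      centroids <- c(centroids, orientedSeqs[i])
      ids[i] <- length(centroids)
      divs[i] <- 0
    }
  }
  new("TypeAssignment",
      typeIds = ids,
      centroids = setNames(centroids, seq_along(centroids)),
      divergence = divs,
      threshold = typeThreshold)
}

#' Reconcile monomer types with the column structure of a HOR array
#'
#' Once a provisional HOR segmentation exists, monomers occupying the same
#' aligned column across copies are re-checked: a monomer whose
#' column-majority type lies strictly within the divergence threshold of
#' its own sequence is reassigned to that majority type. This integrates
#' positional context with sequence similarity and protects borderline
#' monomers (near the 5% boundary against several centroids) from
#' fragmenting into spurious singleton types. Monomers further than the
#' threshold from the column majority always keep their type. The
#' operation is idempotent.
#'
#' @param assignment a [TypeAssignment-class].
#' @param copies copy table (data.frame with `startEnum`, `m` and
#'   list-column `typeSeq`) from [segmentHORCopies()] or
#'   [copyTable()], plus the canonical type sequence used for column
#'   alignment.
#' @param canonical integer vector: canonical type sequence defining the
#'   columns.
#' @param orientedSeqs oriented monomer sequences in enumeration order
#'   (needed to verify the threshold rule).
#' @return a new `TypeAssignment` satisfying the same invariants.
#' @export
reconcileTypesWithColumns <- function(assignment, copies, canonical,
                                      orientedSeqs) {
  if (is(orientedSeqs, "GRanges")) {
    orientedSeqs <- S4Vectors::mcols(orientedSeqs)$orientedSeq
  }
  orientedSeqs <- toupper(as.character(orientedSeqs))
  thr <- assignment@threshold
  ids <- assignment@typeIds
  cents <- assignment@centroids
  n <- length(canonical)

  # map each monomer of each copy onto a canonical column via a unit-cost
  # alignment of the copy's type sequence against the canonical
  colOf <- rep(NA_integer_, length(ids))
  for (ci in seq_len(nrow(copies))) {
    ts <- copies$typeSeq[[ci]]
    aln <- alignIntSeqs(canonical, ts)
    pos <- copies$startEnum[ci] + seq_along(ts) - 1L
    colOf[pos[aln$qryIdx]] <- aln$refIdx
  }

  changed <- FALSE
  inCol <- !is.na(colOf)
  for (col in seq_len(n)) {
    members <- which(inCol & colOf == col)
    if (length(members) < 2L) next
    tab <- table(ids[members])
    maj <- as.integer(names(tab)[which.max(tab)])
    off <- members[ids[members] != maj]
    for (i in off) {
      d <- boundedDivergence(orientedSeqs[i], cents[[maj]], thr)
      if (!is.na(d) && d < thr) {
        ids[i] <- maj
        changed <- TRUE
      }
    }
  }
  if (!changed) {
    return(assignment)
  }
  renumberTypes(ids, cents, orientedSeqs, thr)
}

# Dense renumbering by first occurrence after reassignment; centroids of
# emptied types are dropped.
renumberTypes <- function(ids, cents, orientedSeqs, thr) {
  keep <- sort(unique(ids))
  keep <- keep[order(match(keep, ids))] # order surviving types by first occurrence
  newIds <- match(ids, keep)
  newCents <- unname(cents[as.character(keep)])
  divs <- vapply(seq_along(newIds), function(i) {
    if (orientedSeqs[i] == newCents[newIds[i]]) {
      0
    } else {
      pairwiseDivergence(orientedSeqs[i], newCents[newIds[i]])
    }
  }, numeric(1))
  new("TypeAssignment",
      typeIds = newIds,
      centroids = setNames(newCents, seq_along(newCents)),
      divergence = divs,
      threshold = thr)
}

# Unit-cost global alignment of two integer sequences (type ids); returns
# the matched index pairs (refIdx[i] aligned to qryIdx[i]).
alignIntSeqs <- function(ref, qry) {
  m <- length(ref)
  n <- length(qry)
  D <- matrix(0L, m + 1L, n + 1L)
  D[, 1L] <- 0:m
  D[1L, ] <- 0:n
  for (i in seq_len(m)) {
    sub <- D[i, 1:n] + (ref[i] != qry)
    del <- D[i, 2:(n + 1L)] + 1L
    row <- integer(n)
    prev <- D[i + 1L, 1L]
    for (j in seq_len(n)) {
      v <- min(sub[j], del[j], prev + 1L)
      row[j] <- v
      prev <- v
    }
    D[i + 1L, 2:(n + 1L)] <- row
  }
  refIdx <- integer(0)
  qryIdx <- integer(0)
  i <- m
  j <- n
  while (i > 0L && j > 0L) {
    if (D[i + 1L, j + 1L] == D[i, j] + (ref[i] != qry[j])) {
      refIdx <- c(i, refIdx)
      qryIdx <- c(j, qryIdx)
      i <- i - 1L
      j <- j - 1L
    } else if (D[i + 1L, j + 1L] == D[i, j + 1L] + 1L) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(refIdx = refIdx, qryIdx = qryIdx)
}

#' Tabular view of a type assignment
#'
#' @param assignment a [TypeAssignment-class].
#' @return data.frame: `enumeration`, `type`, `divergenceToCentroid`.
#' @export
typeTable <- function(assignment) {
  data.frame(
    enumeration = seq_along(assignment@typeIds),
    type = assignment@typeIds,
    divergenceToCentroid = assignment@divergence
  )
}
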