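#' TypeAssignment: monomer-to-type classification
#'
#' Maps every monomer of an enumerated array to an integer monomer type id.
#' Two monomers belong to the same type when their sequences differ by less
#' than the divergence threshold (default 5%). Type ids are dense
#' `1..nTypes`, numbered by first occurrence in enumeration order; each type
#' keeps the sequence of its founding monomer as a static centroid.
#'
#' @slot typeIds integer vector, one type id per monomer in enumeration
#'   order.
#' @slot centroids named character vector of centroid (founder) sequences,
#'   one per type id.
#' @slot divergence numeric vector: divergence of each monomer to its own
#'   centroid.
#' @slot threshold the divergence threshold used (strict `<`).
#'
#' @seealso [clusterTypes()], [reconcileTypesWithColumns()]
#' @exportClass TypeAssignment
setClass("TypeAssignment",
  representation(
    typeIds = "integer",
    centroids = "character",
    divergence = "numeric",
    threshold = "numeric"
  )
)

setValidity("TypeAssignment", function(object) {
  msg <- NULL
  n <- length(object@typeIds)
  k <- length(object@centroids)
  if (n > 0L) {
    ids <- sort(unique(object@typeIds))
    if (!identical(ids, seq_len(k))) {
      msg <- c(msg, "type ids must be dense 1..nTypes")
    }
    first <- match(seq_len(k), object@typeIds)
    if (is.unsorted(first)) {
      msg <- c(msg, "type ids must be numbered by first occurrence")
    }
  }
  if (length(object@divergence) != n) {
    msg <- c(msg, "divergence must have one entry per monomer")
  } else if (n > 0L && any(object@divergence >= object@threshold)) {
    msg <- c(msg, "all monomers must lie strictly within threshold of their centroid")
  }
  if (length(object@threshold) != 1L || object@threshold <= 0 ||
      object@threshold >= 1) {
    msg <- c(msg, "threshold must be a single fraction in (0, 1)")
  }
  if (is.null(msg)) TRUE else msg
})

#' HORFamily: one detected higher-order repeat array
#'
#' Holds the segmented copies of one HOR family: the canonical period and
#' type sequence, the per-copy table (start enumeration, monomer count,
#' canonical/variant label, type sequence), the C/V string summarising the
#' array organisation, the family consensus nucleotide sequence and
#' consensus-referenced divergence statistics of the canonical copies.
#'
#' @slot period canonical unit length n (monomers).
#' @slot canonicalTypeSeq integer vector of n type ids.
#' @slot copies data.frame with columns `copy`, `startEnum`, `m`, `label`,
#'   and list-column `typeSeq`.
#' @slot cvString character scalar over `{C,V}`, one letter per copy.
#' @slot consensus character scalar: concatenated consensus of the
#'   canonical unit (empty until computed).
#' @slot consensusMonomers character vector of per-unit-position consensus
#'   monomers.
#' @slot divergencePerCopy numeric: percent divergence of each canonical
#'   copy from the consensus.
#' @slot span integer length-2: first and last monomer enumeration covered.
#'
#' @seealso [classifyCopies()], [familyConsensus()], [divergenceStats()]
#' @exportClass HORFamily
setClass("HORFamily",
  representation(
    period = "integer",
    canonicalTypeSeq = "integer",
    copies = "data.frame",
    cvString = "character",
    consensus = "character",
    consensusMonomers = "character",
    divergencePerCopy = "numeric",
    span = "integer"
  ),
  prototype(
    consensus = "",
    consensusMonomers = character(0),
    divergencePerCopy = numeric(0)
  )
)

setValidity("HORFamily", function(object) {
  msg <- NULL
  if (length(object@period) != 1L || object@period < 1L) {
    msg <- c(msg, "period must be a single positive integer")
  }
  if (length(object@canonicalTypeSeq) != object@period) {
    msg <- c(msg, "canonicalTypeSeq length must equal period")
  }
  nc <- nrow(object@copies)
  if (nchar(object@cvString) != nc) {
    msg <- c(msg, "cvString length must equal the number of copies")
  } else if (nc > 0L) {
    cv <- strsplit(object@cvString, "")[[1]]
    isC <- object@copies$label == "C"
    if (!identical(cv == "C", isC)) {
      msg <- c(msg, "cvString must mirror the copy labels")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' CascadeScheme: column-aligned multi-row layout of a HOR unit
#'
#' The aligned schematic of one HOR unit: monomers are placed left to right
#' into rows so that every row holds distinct monomer types and every
#' column holds a single type. Units without internal type repetition
#' occupy a single row (Willard-type); repeated types force additional rows
#' (cascading).
#'
#' @slot columns integer vector of type ids in column order.
#' @slot placements data.frame with columns `row`, `column`, `offset`
#'   (1-based position within the unit) and `type`.
#' @slot nRows number of rows.
#' @slot rowCounts integer vector: monomers per row.
#'
#' @seealso [layoutCascade()], [classifyHORType()]
#' @exportClass CascadeScheme
setClass("CascadeScheme",
  representation(
    columns = "integer",
    placements = "data.frame",
    nRows = "integer",
    rowCounts = "integer"
  )
)

setValidity("CascadeScheme", function(object) {
  msg <- NULL
  p <- object@placements
  if (nrow(p) > 0L) {
    if (!identical(p$offset, seq_len(nrow(p)))) {
      msg <- c(msg, "placements must be ordered by unit offset 1..m")
    }
    if (any(tapply(p$type, p$row, anyDuplicated) > 0L)) {
      msg <- c(msg, "types within a row must be distinct")
    }
    bycol <- tapply(p$type, p$column, function(x) length(unique(x)))
    if (any(bycol != 1L)) {
      msg <- c(msg, "each column must hold exactly one type")
    }
    if (!identical(object@columns[p$column], p$type)) {
      msg <- c(msg, "column type registry must agree with placements")
    }
  }
  if (sum(object@rowCounts) != nrow(p)) {
    msg <- c(msg, "rowCounts must sum to the unit length")
  }
  if (length(object@rowCounts) != object@nRows) {
    msg <- c(msg, "rowCounts must have one entry per row")
  }
  if (is.null(msg)) TRUE else msg
})
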