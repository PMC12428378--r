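#' Lay a HOR unit out as a column-aligned multi-row scheme
#'
#' Greedy left-to-right placement of the unit's monomers into a grid in
#' which every row holds distinct monomer types and every column holds a
#' single type. A cursor tracks the last placement column: a monomer of an
#' already-columned type is placed at its column if that column lies right
#' of the cursor, otherwise it starts a new row at its column; a monomer
#' of a new type inserts a fresh column immediately right of the cursor.
#' The cursor then advances to the placement column. Units without
#' repeated types come out as a single row (Willard-type); internal type
#' repetition forces the multi-row cascading layout.
#'
#' @param unitTypeSeq integer vector of monomer type ids of one HOR unit.
#' @param columnOrder optional integer vector of type ids fixing an
#'   initial column order (used to lay variant units out against the
#'   canonical column universe).
#' @return a [CascadeScheme-class]; flattening it reproduces
#'   `unitTypeSeq` exactly.
#' @examples
#' rowCounts(layoutCascade(c(1, 2, 3, 4, 2, 3, 4, 5))) # 4 4
#' @export
layoutCascade <- function(unitTypeSeq, columnOrder = NULL) {
  unitTypeSeq <- as.integer(unitTypeSeq)
  if (length(unitTypeSeq) == 0L) {
    stop("unit must be non-empty")
  }
  cols <- if (is.null(columnOrder)) integer(0) else as.integer(columnOrder)
  cursor <- 0L # column index of the previous placement
  row <- 1L
  rowIdx <- integer(length(unitTypeSeq))
  colIdx <- integer(length(unitTypeSeq))
  for (i in seq_along(unitTypeSeq)) {
    t <- unitTypeSeq[i]
    at <- match(t, cols)
    if (is.na(at)) {
      cols <- append(cols, t, after = cursor)
      # placements at columns right of the insertion point shift right
      shift <- colIdx[seq_len(i - 1L)] > cursor
      colIdx[seq_len(i - 1L)][shift] <- colIdx[seq_len(i - 1L)][shift] + 1L
      at <- cursor + 1L
    } else if (at <= cursor) {
      row <- row + 1L
    }
    rowIdx[i] <- row
    colIdx[i] <- at
    cursor <- at
  }
  pl <- data.frame(row = rowIdx, column = colIdx,
                   offset = seq_along(unitTypeSeq), type = unitTypeSeq)
  rc <- as.integer(table(factor(rowIdx, levels = seq_len(row))))
  new("CascadeScheme", columns = cols, placements = pl,
      nRows = row, rowCounts = rc)
}

#' Willard-type or cascading?
#'
#' A HOR unit is Willard-type when every monomer type occurs exactly once
#' (single-row scheme) and cascading when types repeat within the unit
#' (multi-row scheme).
#'
#' @param scheme a [CascadeScheme-class].
#' @return `"Willard"` or `"Cascading"`.
#' @export
classifyHORType <- function(scheme) {
  if (nRows(scheme) == 1L) "Willard" else "Cascading"
}

#' Row-align variant schemes against the canonical scheme
#'
#' Produces the per-copy row-count table in which each variant's rows are
#' matched to canonical rows by maximal type overlap: rows align through a
#' global alignment of the two row lists scored by shared types; a variant
#' row with no canonical partner becomes an inserted row slot (placed
#' after the canonical row it best resembles), and a canonical row absent
#' from a variant shows as a dash. Variant types absent from the canonical
#' column universe are flagged.
#'
#' @param canonical [CascadeScheme-class] of the canonical unit.
#' @param variants named list of [CascadeScheme-class] objects (names
#'   become copy labels; the canonical is reported first as `"C<n>"`).
#' @return list with `table` (data.frame: one row per copy, columns
#'   `label`, `row1`..`rowK` monomer counts with `NA` for dashes, and
#'   `nRows`) and `novelTypes` (named list of type ids absent from the
#'   canonical, per variant).
#' @export
alignVariantSchemes <- function(canonical, variants = list()) {
  canonRows <- rowTypes(canonical)
  nr <- length(canonRows)
  aligned <- lapply(variants, function(v) {
    alignRowLists(canonRows, rowTypes(v))
  })
  # slot expansion: after canonical row j, as many insert slots as the
  # deepest variant repeats there
  insAfter <- integer(nr + 1L) # index 1 = before row 1
  for (a in aligned) {
    ins <- a$insertAfter[a$matchedRow == 0L]
    tab <- table(factor(ins, levels = 0:nr))
    insAfter <- pmax(insAfter, as.integer(tab))
  }
  slotRow <- integer(0) # canonical row of each slot (0 = insert slot)
  slotAnchor <- integer(0) # canonical row an insert slot follows
  for (j in 0:nr) {
    if (j > 0L) {
      slotRow <- c(slotRow, j)
      slotAnchor <- c(slotAnchor, j)
    }
    if (insAfter[j + 1L] > 0L) {
      slotRow <- c(slotRow, rep(0L, insAfter[j + 1L]))
      slotAnchor <- c(slotAnchor, rep(j, insAfter[j + 1L]))
    }
  }
  nSlots <- length(slotRow)

  fillRow <- function(counts, matchedRow, insertAfter) {
    out <- rep(NA_integer_, nSlots)
    usedIns <- integer(nr + 1L)
    for (k in seq_along(counts)) {
      if (matchedRow[k] > 0L) {
        out[which(slotRow == matchedRow[k])] <- counts[k]
      } else {
        a <- insertAfter[k]
        usedIns[a + 1L] <- usedIns[a + 1L] + 1L
        slot <- which(slotRow == 0L & slotAnchor == a)[usedIns[a + 1L]]
        out[slot] <- counts[k]
      }
    }
    out
  }

  rows <- list()
  rows[["canonical"]] <- fillRow(canonical@rowCounts, seq_len(nr),
                                 integer(nr))
  for (nm in names(aligned)) {
    a <- aligned[[nm]]
    rows[[nm]] <- fillRow(a$counts, a$matchedRow, a$insertAfter)
  }
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- paste0("row", seq_len(nSlots))
  labels <- c(paste0("C", sum(canonical@rowCounts)),
              if (length(variants)) names(variants))
  tab <- cbind(label = labels, tab,
               nRows = vapply(rows, function(r) sum(!is.na(r)),
                              integer(1)))
  rownames(tab) <- NULL

  novel <- lapply(variants, function(v) {
    setdiff(unique(flattenScheme(v)), canonical@columns)
  })
  list(table = tab, novelTypes = novel)
}

rowTypes <- function(scheme) {
  pl <- scheme@placements
  lapply(seq_len(scheme@nRows), function(r) pl$type[pl$row == r])
}

# Global alignment of a variant's row list against the canonical's,
# scored by type overlap; unmatched variant rows are annotated with the
# canonical row they follow (0 = before row 1) and, via best overlap,
# the canonical row they repeat.
alignRowLists <- function(canonRows, varRows) {
  m <- length(canonRows)
  n <- length(varRows)
  ov <- matrix(0, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      ov[i, j] <- length(intersect(canonRows[[i]], varRows[[j]])) /
        max(length(canonRows[[i]]), length(varRows[[j]]))
    }
  }
  gap <- -0.01
  S <- matrix(0, m + 1L, n + 1L)
  S[, 1L] <- gap * (0:m)
  S[1L, ] <- gap * (0:n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      S[i + 1L, j + 1L] <- max(S[i, j] + ov[i, j],
                               S[i, j + 1L] + gap,
                               S[i + 1L, j] + gap)
    }
  }
  matchedRow <- integer(n)
  insertAfter <- integer(n)
  eps <- 1e-9
  i <- m
  j <- n
  while (j > 0L) {
    # on score ties an insertion is preferred over a diagonal match, so a
    # duplicated row reads as "first occurrence matched, repeat inserted"
    if (abs(S[i + 1L, j + 1L] - (S[i + 1L, j] + gap)) < eps &&
        !(i > 0L && ov[i, j] > 0 &&
          S[i, j] + ov[i, j] > S[i + 1L, j] + gap + eps)) {
      matchedRow[j] <- 0L
      insertAfter[j] <- i
      j <- j - 1L
    } else if (i > 0L && ov[i, j] > 0 &&
               abs(S[i + 1L, j + 1L] - (S[i, j] + ov[i, j])) < eps) {
      matchedRow[j] <- i
      i <- i - 1L
      j <- j - 1L
    } else if (i > 0L &&
               abs(S[i + 1L, j + 1L] - (S[i, j + 1L] + gap)) < eps) {
      i <- i - 1L
    } else {
      matchedRow[j] <- 0L
      insertAfter[j] <- i
      j <- j - 1L
    }
  }
  list(counts = lengths(varRows), matchedRow = matchedRow,
       insertAfter = insertAfter)
}
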