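#' @rdname TypeAssignment-class
#' @param object,x a `TypeAssignment`, `HORFamily` or `CascadeScheme`.
#' @export
setGeneric("typeIds", function(x) standardGeneric("typeIds"))

#' @rdname TypeAssignment-class
#' @export
setGeneric("centroidSeqs", function(x) standardGeneric("centroidSeqs"))

#' @rdname TypeAssignment-class
#' @export
setGeneric("nTypes", function(x) standardGeneric("nTypes"))

#' @rdname HORFamily-class
#' @export
setGeneric("period", function(x) standardGeneric("period"))

#' @rdname HORFamily-class
#' @export
setGeneric("canonicalTypeSeq", function(x) standardGeneric("canonicalTypeSeq"))

#' @rdname HORFamily-class
#' @export
setGeneric("copyTable", function(x) standardGeneric("copyTable"))

#' @rdname HORFamily-class
#' @export
setGeneric("cvString", function(x) standardGeneric("cvString"))

#' @rdname HORFamily-class
#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))

#' @rdname HORFamily-class
#' @export
setGeneric("divergencePct", function(x) standardGeneric("divergencePct"))

#' @rdname CascadeScheme-class
#' @export
setGeneric("schemeColumns", function(x) standardGeneric("schemeColumns"))

#' @rdname CascadeScheme-class
#' @export
setGeneric("placements", function(x) standardGeneric("placements"))

#' @rdname CascadeScheme-class
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))

#' @rdname CascadeScheme-class
#' @export
setGeneric("rowCounts", function(x) standardGeneric("rowCounts"))

#' @rdname CascadeScheme-class
#' @export
setGeneric("flattenScheme", function(x) standardGeneric("flattenScheme"))

#' @rdname TypeAssignment-class
#' @export
setMethod("typeIds", "TypeAssignment", function(x) x@typeIds)

#' @rdname TypeAssignment-class
#' @export
setMethod("centroidSeqs", "TypeAssignment", function(x) x@centroids)

#' @rdname TypeAssignment-class
#' @export
setMethod("nTypes", "TypeAssignment", function(x) length(x@centroids))

setMethod("show", "TypeAssignment", function(object) {
  cat("TypeAssignment:", length(object@typeIds), "monomers,",
      length(object@centroids), "types (threshold <",
      format(object@threshold), ")\n")
  if (length(object@typeIds)) {
    tab <- sort(table(object@typeIds), decreasing = TRUE)
    cat("  largest types:",
        paste0("t", names(head(tab, 5L)), "=", head(tab, 5L),
               collapse = ", "), "\n")
  }
})

#' @rdname HORFamily-class
#' @export
setMethod("period", "HORFamily", function(x) x@period)

#' @rdname HORFamily-class
#' @export
setMethod("canonicalTypeSeq", "HORFamily", function(x) x@canonicalTypeSeq)

#' @rdname HORFamily-class
#' @export
setMethod("copyTable", "HORFamily", function(x) x@copies)

#' @rdname HORFamily-class
#' @export
setMethod("cvString", "HORFamily", function(x) x@cvString)

#' @rdname HORFamily-class
#' @export
setMethod("consensusSeq", "HORFamily", function(x) x@consensus)

#' @rdname HORFamily-class
#' @export
setMethod("divergencePct", "HORFamily", function(x) {
  list(
    perCopy = x@divergencePerCopy,
    meanPct = if (length(x@divergencePerCopy)) {
      mean(x@divergencePerCopy)
    } else {
      NA_real_
    },
    nCanonical = sum(x@copies$label == "C")
  )
})

setMethod("show", "HORFamily", function(object) {
  nc <- sum(object@copies$label == "C")
  cat("HORFamily: ", object@period, "mer, ", nrow(object@copies),
      " copies (", nc, " canonical, ", nrow(object@copies) - nc,
      " variant)\n", sep = "")
  cat("  span (monomer enumeration):", object@span[1L], "-",
      object@span[2L], "\n")
  if (length(object@divergencePerCopy)) {
    cat("  mean canonical divergence:",
        sprintf("%.3f%%", mean(object@divergencePerCopy)), "\n")
  }
  if (nchar(object@cvString) > 0L) {
    cv <- object@cvString
    if (nchar(cv) > 60L) cv <- paste0(substr(cv, 1L, 57L), "...")
    cat("  CV string:", cv, "\n")
  }
})

#' @rdname CascadeScheme-class
#' @export
setMethod("schemeColumns", "CascadeScheme", function(x) x@columns)

#' @rdname CascadeScheme-class
#' @export
setMethod("placements", "CascadeScheme", function(x) x@placements)

#' @rdname CascadeScheme-class
#' @export
setMethod("nRows", "CascadeScheme", function(x) x@nRows)

#' @rdname CascadeScheme-class
#' @export
setMethod("rowCounts", "CascadeScheme", function(x) x@rowCounts)

#' @rdname CascadeScheme-class
#' @export
setMethod("flattenScheme", "CascadeScheme", function(x) {
  x@placements$type[order(x@placements$offset)]
})

setMethod("show", "CascadeScheme", function(object) {
  cat("CascadeScheme: ", nrow(object@placements), " monomers, ",
      length(object@columns), " columns, ", object@nRows, " row",
      if (object@nRows != 1L) "s", " (",
      if (object@nRows == 1L) "Willard-type" else "cascading", ")\n",
      sep = "")
  cat("  row counts:", paste(object@rowCounts, collapse = ", "), "\n")
})
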