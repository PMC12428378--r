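#' Read a genome FASTA with N-aware normalisation
#'
#' Reads a plain or gzipped FASTA into a [Biostrings::DNAStringSet].
#' Sequences are uppercased (soft-masking removed) and every IUPAC
#' ambiguity code other than `N` is mapped to `N`, so downstream code only
#' ever sees the alphabet `{A,C,G,T,N}`. Undefined stretches (`N`) are kept:
#' monomers overlapping them are excluded later by [filterGapOverlaps()].
#'
#' @param path path to a FASTA file (optionally `.gz`).
#' @return a named `DNAStringSet`, one element per record, order preserved.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s", "acgrn"), fa)
#' as.character(readGenome(fa)) # "ACGNN"
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path)
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(x) == 0L) {
    stop("malformed FASTA '", path, "': no records")
  }
  empty <- which(Biostrings::width(x) == 0L)
  if (length(empty)) {
    stop("malformed FASTA '", path, "': empty sequence in record '",
         names(x)[empty[1L]], "'")
  }
  # first whitespace-delimited token as the sequence name, BED-style
  names(x) <- sub("\\s.*$", "", names(x))
  Biostrings::replaceAmbiguities(x, new = "N")
}

#' Write records as 6-column BED
#'
#' All intervals in this package are 0-based half-open; BED output uses
#' them as-is. Scores are clamped to the BED 0-1000 range.
#'
#' @param records data.frame with columns `name` (sequence name), `start`,
#'   `end`, `label`, `score`, `strand`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeBed <- function(records, path) {
  need <- c("name", "start", "end", "label", "score", "strand")
  if (!all(need %in% names(records))) {
    stop("records must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(records) > 0L) {
    if (any(records$start >= records$end)) {
      stop("invalid interval: start must be < end (0-based half-open)")
    }
    if (!all(records$strand %in% c("+", "-"))) {
      stop("strand must be '+' or '-'")
    }
  }
  out <- data.frame(
    records$name,
    format(records$start, scientific = FALSE, trim = TRUE),
    format(records$end, scientific = FALSE, trim = TRUE),
    records$label,
    pmin(pmax(as.integer(round(records$score)), 0L), 1000L),
    records$strand
  )
  if (nrow(records) == 0L) {
    file.create(path)
  } else {
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# Uniform TSV writer so reruns are byte-identical.
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Default consensus monomer
#'
#' Returns the consensus alpha-satellite monomer shipped with the package:
#' a 171 bp synthetic stand-in (AT-rich random sequence, fixed once) used
#' as the scanning reference and as the root from which simulated type
#' libraries are derived. For real assemblies, supply your own consensus
#' monomer via the `consensus` arguments; all identity thresholds are
#' interpreted relative to whatever consensus is configured.
#'
#' @return a `DNAString` of length 171.
#' @export
defaultConsensus <- function() {
  fa <- system.file("extdata", "synthetic_alpha_consensus.fa",
                    package = "horscan", mustWork = TRUE)
  readGenome(fa)[[1L]]
}

# Validates a user-supplied consensus monomer (sanity bounds only).
checkConsensus <- function(consensus) {
  s <- toupper(as.character(consensus))
  n <- nchar(s)
  if (n < 150L || n > 200L) {
    stop("consensus monomer length must be in [150, 200] bp, got ", n)
  }
  if (grepl("[^ACGT]", s)) {
    stop("consensus monomer must contain only A, C, G, T")
  }
  s
}
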