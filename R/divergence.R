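#' Pairwise sequence divergence
#'
#' Divergence between two DNA sequences is the unit-cost (Levenshtein)
#' global alignment edit distance divided by the number of alignment
#' columns. Among cost-optimal alignments the one with the fewest columns
#' (most matches) is used, which makes the ratio well-defined and
#' symmetric. Two identical 171-mers have divergence 0; 171-mers differing
#' at 8 positions have divergence 8/171.
#'
#' This is the primitive behind monomer type classification (`< 5%` rule),
#' scan identity (`identity = 1 - divergence`) and HOR copy divergence
#' statistics.
#'
#' @param a a single DNA sequence (character or `DNAString`).
#' @param b one or more DNA sequences to compare against `a`.
#' @return numeric vector of divergences in `[0, 1]`, one per element of
#'   `b`.
#' @examples
#' pairwiseDivergence("ACGTACGT", "ACGTACGT") # 0
#' pairwiseDivergence("ACGTACGT", "ACGAACGT") # 1/8
#' @export
pairwiseDivergence <- function(a, b) {
  a <- toupper(as.character(a))
  b <- toupper(as.character(b))
  if (length(a) != 1L || is.na(a) || nchar(a) == 0L) {
    stop("'a' must be a single non-empty sequence")
  }
  if (length(b) == 0L || any(is.na(b)) || any(nchar(b) == 0L)) {
    stop("'b' must contain only non-empty sequences")
  }
  st <- edit_stats_cpp(a, b)
  as.numeric(st[1L, ]) / as.numeric(st[2L, ])
}

# Fast thresholded divergence: exact value where divergence could be below
# `threshold` (banded alignment), NA where it is certainly >= threshold.
boundedDivergence <- function(a, b, threshold) {
  bounded_divergence_cpp(as.character(a), as.character(b), threshold)
}
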