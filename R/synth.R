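#' Plant a library of monomer type sequences
#'
#' Derives `kTypes` monomer sequences from a consensus so that every pair
#' diverges by at least `interTypeDiv` while each type stays within
#' `interTypeDiv / 2` (plus copy noise) of the consensus — the geometry a
#' detectable multi-type satellite library must have. Each type carries
#' `ceiling(interTypeDiv * L / 2)` substitutions planted preferentially at
#' positions unused by other types; draws violating the pairwise
#' constraints are rejected and resampled.
#'
#' @param kTypes number of types (>= 1).
#' @param consensus root monomer (default the shipped consensus).
#' @param interTypeDiv minimum pairwise divergence between types (default
#'   0.15; must exceed twice the type threshold in use so planted types
#'   are unambiguously separable).
#' @param maxTries resampling attempts before giving up.
#' @return character vector of `kTypes` monomer sequences. `kTypes = 1`
#'   returns the consensus itself.
#' @export
makeTypeLibrary <- function(kTypes, consensus = defaultConsensus(),
                            interTypeDiv = 0.15, maxTries = 200L) {
  cons <- checkConsensus(consensus)
  if (kTypes < 1L) {
    stop("kTypes must be >= 1")
  }
  if (kTypes == 1L) {
    return(cons)
  }
  L <- nchar(cons)
  d <- ceiling(interTypeDiv * L / 2) + 2L # +2: slack against position reuse
  if (d * 2 > L) {
    stop("interTypeDiv ", interTypeDiv, " unsatisfiable for monomer length ",
         L)
  }
  bases <- c("A", "C", "G", "T")
  consV <- strsplit(cons, "")[[1]]
  unused <- seq_len(L)
  lib <- character(kTypes)
  for (t in seq_len(kTypes)) {
    placed <- FALSE
    for (try in seq_len(maxTries)) {
      if (length(unused) >= d) {
        pos <- sample(unused, d)
      } else {
        pos <- c(unused,
                 sample(setdiff(seq_len(L), unused), d - length(unused)))
      }
      v <- consV
      v[pos] <- vapply(pos, function(p) {
        sample(setdiff(bases, consV[p]), 1L)
      }, character(1))
      cand <- paste(v, collapse = "")
      if (t == 1L ||
          all(pairwiseDivergence(cand, lib[seq_len(t - 1L)]) >=
              interTypeDiv)) {
        lib[t] <- cand
        unused <- setdiff(unused, pos)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not plant ", kTypes, " types at pairwise divergence >= ",
           interTypeDiv, " within ", maxTries, " attempts per type")
    }
  }
  lib
}

#' Specification of a synthetic HOR array
#'
#' Bundles and validates the parameters of one simulated alpha-satellite
#' array: the type library geometry, the HOR unit (type repeats allowed —
#' cascading — or not — Willard-type), the copy count and
#' canonical/variant pattern, the per-base substitution rate emulating
#' copy-to-copy divergence, flanking non-satellite sequence, and an
#' optional assembly gap.
#'
#' @param unitTypeSeq integer vector: the canonical unit's type sequence
#'   (ids in `1..kTypes`).
#' @param nCopies number of tandem copies.
#' @param kTypes library size; defaults to `max(unitTypeSeq)`.
#' @param cvPattern optional string over `{C,V}` of length `nCopies`.
#' @param variants optional named list mapping copy index (as character)
#'   to an explicit variant type sequence; V copies without an entry get a
#'   deterministic row-level edit (a duplicated cascade row, mirroring the
#'   most common structural variants in real arrays).
#' @param perBaseMutRate i.i.d. substitution rate per base per copy
#'   (default 0.0025, the sub-percent regime of recently homogenised
#'   arrays).
#' @param interTypeDiv see [makeTypeLibrary()] (default 0.15; must exceed
#'   twice the 5% type threshold).
#' @param flankBp random non-satellite flank on each side (default 2000).
#' @param nGap optional `c(position, length)`: an N-run injected at that
#'   0-based offset of the final sequence.
#' @param seed RNG seed applied by [simulateHORArray()]; `NULL` leaves the
#'   caller's RNG state untouched.
#' @param consensus root consensus monomer.
#' @return a validated spec (list) for [simulateHORArray()].
#' @export
horSimSpec <- function(unitTypeSeq, nCopies, kTypes = max(unitTypeSeq),
                       cvPattern = NULL, variants = NULL,
                       perBaseMutRate = 0.0025, interTypeDiv = 0.15,
                       flankBp = 2000L, nGap = NULL, seed = NULL,
                       consensus = defaultConsensus()) {
  unitTypeSeq <- as.integer(unitTypeSeq)
  if (length(unitTypeSeq) < 1L || any(unitTypeSeq < 1L)) {
    stop("unitTypeSeq must contain positive type ids")
  }
  if (kTypes < max(unitTypeSeq)) {
    stop("kTypes must cover all ids used in unitTypeSeq")
  }
  if (!is.null(cvPattern)) {
    if (nchar(cvPattern) != nCopies) {
      stop("cvPattern length must equal nCopies")
    }
    if (grepl("[^CV]", cvPattern)) {
      stop("cvPattern must use only C and V")
    }
  }
  if (interTypeDiv <= 2 * 0.05) {
    stop("interTypeDiv must exceed twice the 5% type threshold so planted ",
         "types are unambiguously separable")
  }
  if (perBaseMutRate < 0 || perBaseMutRate > 0.1) {
    stop("perBaseMutRate must be in [0, 0.1]")
  }
  list(unitTypeSeq = unitTypeSeq, nCopies = as.integer(nCopies),
       kTypes = as.integer(kTypes), cvPattern = cvPattern,
       variants = variants, perBaseMutRate = perBaseMutRate,
       interTypeDiv = interTypeDiv, flankBp = as.integer(flankBp),
       nGap = nGap, seed = seed,
       consensus = checkConsensus(consensus))
}

#' Simulate an alpha-satellite HOR array with known ground truth
#'
#' Generates `flank + copies + flank` where each copy is its type
#' sequence's monomers with i.i.d. per-base substitutions, plus optional
#' N-gap. Ground truth lists every monomer (0-based half-open coordinates,
#' type, copy, unit position) and every copy (span, planted label).
#'
#' @param spec a spec from [horSimSpec()].
#' @return list: `genome` (named `DNAStringSet`), `truth` (list with
#'   data.frames `monomers` and `copies`), `library` (planted type
#'   sequences), `unit` (canonical type sequence) and `spec`.
#' @export
simulateHORArray <- function(spec) {
  if (!is.null(spec$seed)) {
    set.seed(spec$seed)
  }
  lib <- makeTypeLibrary(spec$kTypes, spec$consensus, spec$interTypeDiv)
  cv <- if (is.null(spec$cvPattern)) {
    rep("C", spec$nCopies)
  } else {
    strsplit(spec$cvPattern, "")[[1]]
  }
  canonScheme <- layoutCascade(spec$unitTypeSeq)

  copySeqs <- vector("list", spec$nCopies)
  for (i in seq_len(spec$nCopies)) {
    if (cv[i] == "C") {
      copySeqs[[i]] <- spec$unitTypeSeq
    } else if (!is.null(spec$variants) &&
               !is.null(spec$variants[[as.character(i)]])) {
      copySeqs[[i]] <- as.integer(spec$variants[[as.character(i)]])
    } else {
      copySeqs[[i]] <- duplicateRowVariant(spec$unitTypeSeq, canonScheme)
    }
  }

  flank1 <- randomDna(spec$flankBp)
  flank2 <- randomDna(spec$flankBp)
  monRows <- list()
  seqParts <- list(flank1)
  at <- spec$flankBp # 0-based cursor
  for (i in seq_len(spec$nCopies)) {
    ts <- copySeqs[[i]]
    mons <- mutateSeqs(lib[ts], spec$perBaseMutRate)
    w <- nchar(mons)
    starts <- as.integer(at + cumsum(c(0L, head(w, -1L))))
    monRows[[i]] <- data.frame(
      start = starts, end = starts + w, strand = "+",
      type = ts, copy = i, unitPos = seq_along(ts))
    seqParts[[length(seqParts) + 1L]] <- paste(mons, collapse = "")
    at <- at + sum(w)
  }
  seqParts[[length(seqParts) + 1L]] <- flank2
  genomeSeq <- paste(unlist(seqParts), collapse = "")

  monomers <- do.call(rbind, monRows)
  copies <- data.frame(
    copy = seq_len(spec$nCopies),
    start = vapply(monRows, function(r) r$start[1L], integer(1)),
    end = vapply(monRows, function(r) r$end[nrow(r)], integer(1)),
    m = lengths(copySeqs),
    label = ifelse(cv == "C", "C",
                   paste0("V", lengths(copySeqs)))
  )

  if (!is.null(spec$nGap)) {
    pos <- spec$nGap[1L]
    len <- spec$nGap[2L]
    substr(genomeSeq, pos + 1L, pos + len) <-
      paste(rep("N", len), collapse = "")
  }
  genome <- Biostrings::DNAStringSet(genomeSeq)
  names(genome) <- "synthetic_array"
  list(genome = genome,
       truth = list(monomers = monomers, copies = copies),
       library = lib, unit = spec$unitTypeSeq, spec = spec)
}

# Default structural variant: duplicate one cascade row in place (the
# analogue of real variants that repeat a canonical row). The unit's first
# row (or leading block, for Willard units) is left alone so the variant
# never duplicates the segmentation anchor, which would make one planted
# variant read as two structural copies.
duplicateRowVariant <- function(unit, scheme) {
  rt <- rowTypes(scheme)
  if (length(rt) == 1L) {
    # Willard unit: duplicate a random sub-block of about a quarter unit,
    # never including the first monomer
    n <- length(unit)
    w <- min(max(1L, ceiling(n / 4)), n - 1L)
    s <- if (n - w >= 2L) sample(2:(n - w + 1L), 1L) else 2L
    append(unit, unit[s:(s + w - 1L)], after = s + w - 1L)
  } else {
    r <- if (length(rt) == 2L) 2L else sample(2:length(rt), 1L)
    pl <- scheme@placements
    last <- max(pl$offset[pl$row == r])
    append(unit, rt[[r]], after = last)
  }
}

randomDna <- function(n) {
  if (n <= 0L) {
    return("")
  }
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# i.i.d. substitutions at the given rate, applied jointly for speed.
mutateSeqs <- function(seqs, rate) {
  if (rate <= 0) {
    return(seqs)
  }
  w <- nchar(seqs)
  all <- strsplit(paste(seqs, collapse = ""), "")[[1]]
  hit <- which(stats::runif(length(all)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    all[hit] <- vapply(all[hit], function(b) {
      sample(setdiff(bases, b), 1L)
    }, character(1), USE.NAMES = FALSE)
  }
  joined <- paste(all, collapse = "")
  ends <- cumsum(w)
  substring(joined, c(1L, head(ends, -1L) + 1L), ends)
}

#' Build a cascading HOR unit from a row/column design
#'
#' Convenience constructor for simulation studies: given rows as vectors
#' of column indices (each row strictly increasing; each row after the
#' first starting at a column at or left of the previous row's last
#' column), returns the unit type sequence whose [layoutCascade()] layout
#' reproduces exactly those rows. Column indices double as type ids.
#'
#' @param rows list of strictly increasing integer vectors of column
#'   indices.
#' @return integer vector: the unit type sequence.
#' @examples
#' # a two-row cascading 8mer
#' cascadeUnit(list(1:4, c(2, 3, 4, 5)))
#' @export
cascadeUnit <- function(rows) {
  for (r in seq_along(rows)) {
    v <- as.integer(rows[[r]])
    if (is.unsorted(v, strictly = TRUE)) {
      stop("row ", r, " must be strictly increasing in column order")
    }
    if (r > 1L && v[1L] > tail(rows[[r - 1L]], 1L)) {
      stop("row ", r, " must start at or left of the previous row's ",
           "last column to trigger a row break")
    }
  }
  unit <- as.integer(unlist(rows))
  sc <- layoutCascade(unit)
  if (!identical(rowCounts(sc), lengths(rows, use.names = FALSE))) {
    stop("row design is not reproduced by the greedy layout; ",
         "check the column structure")
  }
  unit
}
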