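#' MD-points of a monomer type sequence
#'
#' An MD-point `(l, p)` records that the monomer at enumeration `l` is
#' followed by the next occurrence of the same monomer type at distance
#' `p` (no intervening occurrence). Monomers whose next same-type
#' occurrence lies beyond `maxPeriod`, or that have none, contribute no
#' point. The scatter of these points against enumeration is the MD
#' diagram; their per-period counts form the repeat-period (GRM) frequency
#' table.
#'
#' @param typeSeq integer (or factor-like) vector of monomer type ids in
#'   enumeration order, or a [TypeAssignment-class].
#' @param maxPeriod largest period recorded (default 90).
#' @return data.frame with columns `enumeration` and `period`, sorted by
#'   enumeration.
#' @export
mdPoints <- function(typeSeq, maxPeriod = 90L) {
  if (is(typeSeq, "TypeAssignment")) {
    typeSeq <- typeIds(typeSeq)
  }
  n <- length(typeSeq)
  if (n < 2L) {
    return(data.frame(enumeration = integer(0), period = integer(0)))
  }
  nxt <- integer(n)
  last <- new.env(hash = TRUE, parent = emptyenv())
  for (i in n:1) {
    key <- as.character(typeSeq[i])
    nxt[i] <- if (is.null(last[[key]])) NA_integer_ else last[[key]]
    last[[key]] <- i
  }
  p <- nxt - seq_len(n)
  keep <- !is.na(p) & p <= maxPeriod
  data.frame(enumeration = which(keep), period = p[keep])
}

#' Per-period frequency table (GRM diagram content)
#'
#' Counts MD-points per period. Frequencies of absent periods are zero.
#'
#' @param points data.frame from [mdPoints()].
#' @param maxPeriod largest period of the table.
#' @return data.frame with columns `period` (1..maxPeriod) and `freq`.
#' @export
periodHistogram <- function(points, maxPeriod = 90L) {
  freq <- tabulate(points$period, nbins = maxPeriod)
  data.frame(period = seq_len(maxPeriod), freq = freq)
}

#' Call horizontal MD-line segments at one period
#'
#' A HOR array shows up in the MD diagram as a dense horizontal line of
#' points at its characteristic period. This finds maximal enumeration
#' intervals in which at least `minDensity` of the monomers carry an
#' MD-point of exactly this period and which contain at least `minRun`
#' such points. Points are chained while the enumeration gap between
#' consecutive points stays within two periods (so a structural-variant
#' copy does not break the array in two); chains failing the density or
#' run-length rule are discarded.
#'
#' The density default (0.3) reflects cascading HORs: only monomer types
#' occurring once per unit produce MD-points at exactly the unit period,
#' so a unit of n monomers with s singleton types has expected density
#' s/n, further reduced by variant copies; 0.3 keeps such arrays while
#' still rejecting random type sequences (no 20-point chain at uniform
#' type usage survives it).
#'
#' @param points data.frame from [mdPoints()].
#' @param period the period whose line segments to call.
#' @param minRun minimum number of points per segment (default 20).
#' @param minDensity minimum fraction of monomers in the interval carrying
#'   a point of this period (default 0.3).
#' @return data.frame with columns `startEnum`, `endEnum`, `nPoints`,
#'   `density`.
#' @export
mdLineSegments <- function(points, period, minRun = 20L, minDensity = 0.3) {
  e <- points$enumeration[points$period == period]
  if (length(e) == 0L) {
    return(emptySegments())
  }
  e <- sort(e)
  maxGap <- max(2L, 2L * period)
  grp <- cumsum(c(1L, diff(e) > maxGap))
  segs <- lapply(split(e, grp), function(x) {
    data.frame(startEnum = x[1L], endEnum = x[length(x)],
               nPoints = length(x),
               density = length(x) / (x[length(x)] - x[1L] + 1L))
  })
  segs <- do.call(rbind, segs)
  rownames(segs) <- NULL
  segs <- segs[segs$nPoints >= minRun & segs$density >= minDensity, ,
               drop = FALSE]
  rownames(segs) <- NULL
  segs
}

emptySegments <- function() {
  data.frame(startEnum = integer(0), endEnum = integer(0),
             nPoints = integer(0), density = numeric(0))
}

#' Candidate HOR array regions and their unit periods
#'
#' Unions the qualifying MD-line segments over all periods from 2 to
#' `maxPeriod` into candidate array regions, then determines each region's
#' HOR unit period by type-sequence autocorrelation: the coherence of lag
#' `p` is the fraction of monomers in the region whose type recurs exactly
#' `p` positions later. The unit period is the smallest lag whose
#' coherence reaches `coherenceFrac` of the maximum (and an absolute floor
#' of 0.5). Coherence rather than the raw MD-frequency argmax is used
#' because in cascading HORs internally repeated types concentrate
#' MD-points on subfragment periods, which can outnumber the points at the
#' true unit period.
#'
#' @param points data.frame from [mdPoints()].
#' @param typeSeq monomer type sequence (or [TypeAssignment-class]).
#' @param maxPeriod largest period considered.
#' @param minRun,minDensity segment-calling parameters, see
#'   [mdLineSegments()].
#' @param coherenceFrac fraction of the maximal coherence at which the
#'   smallest qualifying lag is taken as the unit period (default 0.95).
#' @return data.frame with columns `startEnum`, `endEnum`, `period`,
#'   `coherence`; one row per candidate region, in enumeration order.
#' @export
horRegions <- function(points, typeSeq, maxPeriod = 90L, minRun = 20L,
                       minDensity = 0.3, coherenceFrac = 0.95) {
  if (is(typeSeq, "TypeAssignment")) {
    typeSeq <- typeIds(typeSeq)
  }
  segs <- lapply(2:maxPeriod, function(p) {
    mdLineSegments(points, p, minRun = minRun, minDensity = minDensity)
  })
  segs <- do.call(rbind, segs)
  if (is.null(segs) || nrow(segs) == 0L) {
    return(data.frame(startEnum = integer(0), endEnum = integer(0),
                      period = integer(0), coherence = numeric(0)))
  }
  # variant copies interrupt the point chains of individual periods;
  # allowing up to maxPeriod monomers of slack when unioning keeps one
  # array one region while genuinely separate arrays (thousands of
  # monomers apart) stay distinct
  merged <- IRanges::reduce(IRanges::IRanges(segs$startEnum, segs$endEnum),
                            min.gapwidth = maxPeriod)
  out <- lapply(seq_along(merged), function(i) {
    s <- IRanges::start(merged)[i]
    e <- IRanges::end(merged)[i]
    pc <- regionPeriod(typeSeq[s:e], maxPeriod, coherenceFrac)
    data.frame(startEnum = s, endEnum = e, period = pc$period,
               coherence = pc$coherence)
  })
  out <- do.call(rbind, out)
  out[!is.na(out$period), , drop = FALSE]
}

# Coherence-based period call within one region.
regionPeriod <- function(ts, maxPeriod, coherenceFrac) {
  n <- length(ts)
  pmax_ <- min(maxPeriod, n - 1L)
  if (pmax_ < 2L) {
    return(list(period = NA_integer_, coherence = NA_real_))
  }
  coh <- vapply(2:pmax_, function(p) {
    mean(ts[seq_len(n - p)] == ts[seq_len(n - p) + p])
  }, numeric(1))
  top <- max(coh)
  if (top < 0.5) {
    return(list(period = NA_integer_, coherence = NA_real_))
  }
  p <- which(coh >= coherenceFrac * top)[1L] + 1L
  list(period = p, coherence = coh[p - 1L])
}
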