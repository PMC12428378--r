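#' Assemble and validate a pipeline run configuration
#'
#' @param fasta path to the assembly FASTA (plain or gzipped).
#' @param outDir output directory (created if needed).
#' @param consensus path to a consensus monomer FASTA, or a sequence;
#'   `NULL` uses the shipped default.
#' @param minIdentity monomer retention threshold (default 0.95).
#' @param typeThreshold monomer type divergence threshold (default 0.05,
#'   strict `<`).
#' @param maxPeriod largest MD period (default 90).
#' @param maxJoinGap array-joining gap in bp (default 500).
#' @param minRun,minDensity MD-line-segment calling, see
#'   [mdLineSegments()].
#' @param freqThreshold only periods with frequency above this appear in
#'   the period-frequency TSV (default 90).
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return validated config list for [runPipeline()].
#' @export
runConfig <- function(fasta, outDir, consensus = NULL, minIdentity = 0.95,
                      typeThreshold = 0.05, maxPeriod = 90L,
                      maxJoinGap = 500L, minRun = 20L, minDensity = 0.3,
                      freqThreshold = 90L, seed = 1L) {
  if (!file.exists(fasta)) {
    stop("input FASTA not found: ", fasta)
  }
  stopifnot(minIdentity > 0.5, minIdentity <= 1,
            typeThreshold > 0, typeThreshold < 1,
            maxPeriod >= 2L, maxJoinGap >= 0L, minRun >= 1L,
            minDensity > 0, minDensity <= 1)
  consSeq <- if (is.null(consensus)) {
    as.character(defaultConsensus())
  } else if (file.exists(consensus)) {
    as.character(readGenome(consensus)[[1L]])
  } else {
    checkConsensus(consensus)
  }
  list(fasta = fasta, outDir = outDir, consensus = consSeq,
       consensusPath = if (!is.null(consensus) && file.exists(consensus)) {
         consensus
       } else {
         NA_character_
       },
       minIdentity = minIdentity, typeThreshold = typeThreshold,
       maxPeriod = as.integer(maxPeriod),
       maxJoinGap = as.integer(maxJoinGap), minRun = as.integer(minRun),
       minDensity = minDensity, freqThreshold = as.integer(freqThreshold),
       seed = as.integer(seed))
}

#' Run the full HOR detection pipeline
#'
#' Chains monomer extraction, gap filtering, array segmentation, type
#' classification, MD/GRM computation, HOR family detection and cascade
#' layout, and writes all outputs to `outDir`:
#' `monomers.bed` / `monomers.tsv`, `md_points.tsv`,
#' `period_freq.tsv`, and per family `family<i>_copies.tsv`,
#' `family<i>_cv.txt`, `family<i>_consensus.fa`, `family<i>_scheme.tsv`,
#' `family<i>_variant_table.tsv`, plus `summary.json` and
#' `manifest.json`. Reruns with identical config and inputs produce
#' byte-identical tabular outputs.
#'
#' @param config from [runConfig()].
#' @return invisibly, a list with the in-memory results (`hits`,
#'   `assignment`, `detection`, `summary`).
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(config$outDir)) {
    stop("cannot create output directory: ", config$outDir)
  }
  genome <- readGenome(config$fasta)

  hits <- scanMonomers(genome, config$consensus,
                       minIdentity = config$minIdentity)
  hits <- filterGapOverlaps(hits, genome)
  hits <- segmentArrays(hits, maxJoinGap = config$maxJoinGap)

  monTab <- hitsTable(hits)
  writeTsv(monTab, file.path(config$outDir, "monomers.tsv"))
  writeBed(data.frame(name = monTab$seqName, start = monTab$start,
                      end = monTab$end,
                      label = paste0("mon_", monTab$enumeration),
                      score = round(1000 * monTab$identity),
                      strand = monTab$strand),
           file.path(config$outDir, "monomers.bed"))
  writeTsv(arrayTable(hits), file.path(config$outDir, "arrays.tsv"))

  summary <- list(
    nMonomers = length(hits),
    nArrays = if (length(hits)) {
      max(S4Vectors::mcols(hits)$arrayId)
    } else {
      0L
    },
    families = list()
  )

  if (length(hits) > 0L) {
    assignment <- clusterTypes(hits, typeThreshold = config$typeThreshold)
    det <- detectHORs(assignment, hits, maxPeriod = config$maxPeriod,
                      minRun = config$minRun,
                      minDensity = config$minDensity)
    assignment <- det$assignment
    writeTsv(typeTable(assignment),
             file.path(config$outDir, "monomer_types.tsv"))
    writeTsv(det$points, file.path(config$outDir, "md_points.tsv"))
    hist <- det$histogram
    writeTsv(hist[hist$freq > config$freqThreshold, , drop = FALSE],
             file.path(config$outDir, "period_freq.tsv"))

    summary$nTypes <- nTypes(assignment)
    for (fi in seq_along(det$families)) {
      fam <- det$families[[fi]]
      pre <- file.path(config$outDir, paste0("family", fi))
      cp <- copyTable(fam)
      div <- rep(NA_real_, nrow(cp))
      div[cp$label == "C"] <- fam@divergencePerCopy
      writeTsv(data.frame(copy = cp$copy, startEnum = cp$startEnum,
                          m = cp$m, label = cp$label,
                          divergencePct = round(div, 4),
                          editOps = cp$editOps),
               paste0(pre, "_copies.tsv"))
      writeLines(cvString(fam), paste0(pre, "_cv.txt"))
      writeLines(c(paste0(">family", fi, "_consensus_", period(fam),
                          "mer"),
                   consensusSeq(fam)),
                 paste0(pre, "_consensus.fa"))

      scheme <- layoutCascade(canonicalTypeSeq(fam))
      writeTsv(placements(scheme), paste0(pre, "_scheme.tsv"))
      vt <- variantSchemeTable(fam, scheme)
      writeTsv(vt, paste0(pre, "_variant_table.tsv"))

      dv <- divergencePct(fam)
      summary$families[[fi]] <- list(
        nmer = period(fam),
        nCopies = nrow(cp),
        nCanonical = sum(cp$label == "C"),
        horType = if (classifyHORType(scheme) == "Willard") {
          "Willard's"
        } else {
          "Cascading"
        },
        nRows = nRows(scheme),
        rowCounts = rowCounts(scheme),
        distinctTypes = length(unique(canonicalTypeSeq(fam))),
        meanDivergencePct = round(dv$meanPct, 4),
        spanEnum = fam@span,
        cvString = cvString(fam)
      )
    }
  }

  jsonlite::write_json(summary, file.path(config$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    package = "horscan",
    version = as.character(utils::packageVersion("horscan")),
    config = config[setdiff(names(config), "consensus")],
    consensusLength = nchar(config$consensus),
    inputMd5 = unname(tools::md5sum(config$fasta))
  )
  jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(hits = hits,
                 assignment = if (length(hits)) assignment else NULL,
                 detection = if (length(hits)) det else NULL,
                 summary = summary))
}

# Table-1-style row-count matrix: canonical plus one row per distinct
# variant type sequence (labelled by monomer count, distinguished by
# occurrence order when same-length variants differ structurally).
variantSchemeTable <- function(fam, canonScheme) {
  cp <- copyTable(fam)
  vIdx <- which(cp$label != "C")
  if (length(vIdx) == 0L) {
    return(alignVariantSchemes(canonScheme, list())$table)
  }
  keys <- vapply(cp$typeSeq[vIdx], paste, character(1), collapse = ",")
  firstOfKind <- vIdx[!duplicated(keys)]
  variants <- lapply(firstOfKind, function(i) {
    layoutCascade(cp$typeSeq[[i]], columnOrder = canonScheme@columns)
  })
  names(variants) <- make.unique(cp$label[firstOfKind], sep = ".")
  alignVariantSchemes(canonScheme, variants)$table
}
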