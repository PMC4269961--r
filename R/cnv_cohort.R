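## CNV-level prioritization (>= 1 prioritized gene, with a benign-catalog
## veto) and cohort summarization (per-patient distribution, diagnostic
## yield).

#' Genes contained in a CNV call
#'
#' @param call a single-range `GRanges` (one CNV segment).
#' @param annotation gene annotation `GRanges` (see
#'   [readGeneAnnotation()]).
#' @return Character vector of overlapping gene symbols (>= 1 bp
#'   overlap), sorted by start then symbol.
#' @export
annotateCnv <- function(call, annotation) {
  suppressWarnings(genesInInterval(annotation, call, minOverlap = 1L))
}

#' Match a CNV against a benign-variant catalog
#'
#' `TRUE` when some catalog entry on the same chromosome has reciprocal
#' overlap `overlap_bp / max(len_call, len_entry) >= minReciprocalOverlap`
#' and population frequency `>= minFrequency`. Such a call looks like a
#' common, phenotypically neutral variant.
#'
#' @param call a single-range `GRanges`.
#' @param catalog catalog `GRanges` with a `frequency` column (see
#'   [readVariantCatalog()]).
#' @param minReciprocalOverlap reciprocal-overlap threshold in `(0, 1]`
#'   (default 0.5).
#' @param minFrequency population-frequency threshold in `(0, 1]`
#'   (default 0.01).
#' @return Logical scalar.
#' @export
benignMatch <- function(call, catalog, minReciprocalOverlap = 0.5,
                        minFrequency = 0.01) {
  stopifnot(length(call) == 1L,
            minReciprocalOverlap > 0, minReciprocalOverlap <= 1,
            minFrequency > 0, minFrequency <= 1)
  if (!length(catalog)) return(FALSE)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(call, catalog))
  if (!length(hits)) return(FALSE)
  ent <- catalog[S4Vectors::subjectHits(hits)]
  ov <- GenomicRanges::width(IRanges::pintersect(
    rep(GenomicRanges::ranges(call), length(ent)),
    GenomicRanges::ranges(ent)))
  rec <- ov / pmax(GenomicRanges::width(call), GenomicRanges::width(ent))
  any(rec >= minReciprocalOverlap & ent$frequency >= minFrequency)
}

#' Prioritize CNV calls
#'
#' Applies the CNV-level rule: a call is `prioritized` when it contains
#' at least one prioritized gene and does not match the benign catalog;
#' a catalog match makes it `benign` (the veto: population evidence
#' outranks gene content); anything else is `unranked`. With
#' `benignVeto = FALSE` the catalog match is still reported but does not
#' veto, so a call with a prioritized gene is `prioritized` regardless.
#' Dosage (gain/loss) never alters the verdict; it is carried through.
#'
#' @param calls CNV `GRanges` with `patient_id` and `dosage` columns
#'   (see [readCnvCalls()]).
#' @param prioritizedGenes character vector of prioritized symbols (from
#'   [prioritizeGenes()]).
#' @param annotation gene annotation `GRanges`.
#' @param catalog benign-variant catalog `GRanges` (may be empty).
#' @param benignVeto should a catalog match veto prioritization?
#' @param minReciprocalOverlap,minFrequency passed to [benignMatch()].
#' @return Data frame ordered by (patient, chrom, start): `patient_id`,
#'   `chrom`, `start`, `end` (0-based half-open), `dosage`, `nGenes`,
#'   `genes`, `prioritizedGenes` (comma-joined), `benignMatch`,
#'   `verdict`.
#' @export
prioritizeCnvs <- function(calls, prioritizedGenes, annotation, catalog,
                           benignVeto = TRUE,
                           minReciprocalOverlap = 0.5,
                           minFrequency = 0.01) {
  if (length(calls) && length(annotation))
    checkChromCompat(calls, annotation, "CNV calls", "annotation")
  if (length(calls) && length(catalog))
    checkChromCompat(calls, catalog, "CNV calls", "catalog")
  calls <- sortCnv(calls)
  n <- length(calls)
  genesL <- character(n); prioL <- character(n)
  nGenes <- integer(n); benign <- logical(n)

  ## gene content: one overlap join, genes sorted by start then symbol
  if (n && length(annotation)) {
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(calls, annotation))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ord <- order(q, GenomicRanges::start(annotation)[s],
                 annotation$symbol[s])
    q <- q[ord]; s <- s[ord]
    byCall <- split(annotation$symbol[s], q)
    idx <- as.integer(names(byCall))
    genesL[idx] <- vapply(byCall, joinSymbols, "")
    nGenes[idx] <- lengths(byCall)
    prioL[idx] <- vapply(byCall, function(g)
      joinSymbols(g[g %in% prioritizedGenes]), "")
  }

  ## benign screen: one overlap join plus reciprocal-overlap arithmetic
  if (n && length(catalog)) {
    hits <- suppressWarnings(GenomicRanges::findOverlaps(calls, catalog))
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    if (length(q)) {
      ov <- pmin(GenomicRanges::end(calls)[q],
                 GenomicRanges::end(catalog)[s]) -
        pmax(GenomicRanges::start(calls)[q],
             GenomicRanges::start(catalog)[s]) + 1
      rec <- ov / pmax(GenomicRanges::width(calls)[q],
                       GenomicRanges::width(catalog)[s])
      ok <- rec >= minReciprocalOverlap &
        catalog$frequency[s] >= minFrequency
      benign[unique(q[ok])] <- TRUE
    }
  }

  hasPrio <- nzchar(prioL)
  verdict <- ifelse(benignVeto & benign, "benign",
                    ifelse(hasPrio, "prioritized",
                           ifelse(benign, "benign", "unranked")))
  data.frame(patient_id = calls$patient_id,
             chrom = as.character(GenomicRanges::seqnames(calls)),
             start = GenomicRanges::start(calls) - 1L,
             end = GenomicRanges::end(calls),
             dosage = calls$dosage,
             nGenes = nGenes, genes = genesL,
             prioritizedGenes = prioL,
             benignMatch = benign, verdict = verdict,
             stringsAsFactors = FALSE)
}

#' Summarize prioritized CNVs over a cohort
#'
#' Counts prioritized CNVs per patient over the full roster (patients
#' with none still count), builds the count histogram including the zero
#' bin, and computes the diagnostic yield: the percentage of patients
#' carrying at least one prioritized CNV, rounded half-up to one
#' decimal.
#'
#' @param results data frame from [prioritizeCnvs()].
#' @param roster character vector of all patient identifiers in the
#'   cohort; must cover every patient appearing in `results`.
#' @return List of class `"cohortSummary"`: `nPatients`,
#'   `nCnvPrioritizedTotal`, `perPatientCounts` (named integer),
#'   `histogram` (data frame `count`, `nPatients`), `yieldPercent`.
#' @examples
#' res <- data.frame(patient_id = c("P1", "P1", "P2"),
#'                   verdict = c("prioritized", "benign", "prioritized"))
#' summarizeCohort(res, c("P1", "P2", "P3"))
#' @export
summarizeCohort <- function(results, roster) {
  roster <- unique(as.character(roster))
  if (!length(roster)) stop("empty patient roster")
  extra <- setdiff(unique(results$patient_id), roster)
  if (length(extra))
    stop("result references patient(s) not on roster: ",
         joinSymbols(extra))
  prio <- results[results$verdict == "prioritized", , drop = FALSE]
  counts <- setNames(integer(length(roster)), roster)
  if (nrow(prio)) {
    tab <- table(prio$patient_id)
    counts[names(tab)] <- as.integer(tab)
  }
  hist <- as.data.frame(table(counts), stringsAsFactors = FALSE)
  colnames(hist) <- c("count", "nPatients")
  hist$count <- as.integer(hist$count)
  hist <- hist[order(hist$count), , drop = FALSE]
  rownames(hist) <- NULL
  carriers <- sum(counts >= 1L)
  structure(list(
    nPatients = length(roster),
    nCnvPrioritizedTotal = nrow(prio),
    perPatientCounts = counts,
    histogram = hist,
    yieldPercent = roundHalfUp(100 * carriers / length(roster), 1)),
    class = "cohortSummary")
}

#' @export
print.cohortSummary <- function(x, ...) {
  cat("cohortSummary:", x$nPatients, "patients;",
      x$nCnvPrioritizedTotal, "CNV prioritized in",
      sum(x$perPatientCounts >= 1), "patients; diagnostic yield ",
      x$yieldPercent, "%\n", sep = " ")
  invisible(x)
}
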