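## Locus queries and the expression filter: map an imbalance to its genes,
## then flag genes expressed more abundantly in the affected tissue, by a
## locus-aligned Tukey fence and/or a cross-tissue robust z-score. All
## statistics operate on log2(x + 1) transformed values.

MAD_FLOOR <- 0.01

log2p1 <- function(x) log2(x + 1)

#' Genes overlapping a genomic interval
#'
#' Returns the symbols of annotated genes whose overlap with the query
#' interval is at least `minOverlap` base pairs, sorted by start position
#' then symbol. Intervals are half-open: a gene `[100, 200)` does not
#' overlap `[200, 300)`.
#'
#' @param annotation a `GRanges` with a `symbol` column
#'   (see [readGeneAnnotation()]).
#' @param interval a single-range `GRanges`, or a string
#'   `"chrom:start-end"` in 0-based half-open coordinates.
#' @param minOverlap minimum overlap in bp (integer `>= 1`).
#' @return Character vector of gene symbols (possibly empty). A query
#'   chromosome absent from the annotation yields an empty result with a
#'   warning, not an error.
#' @examples
#' ann <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(c(101, 501), c(200, 600)),
#'     symbol = c("A", "B"))
#' genesInInterval(ann, "chr1:0-300")
#' @export
genesInInterval <- function(annotation, interval, minOverlap = 1L) {
  stopifnot(minOverlap >= 1L)
  iv <- parseInterval(interval)
  if (!length(annotation)) return(character())
  chromQ <- as.character(GenomicRanges::seqnames(iv))
  if (!chromQ %in% as.character(GenomicRanges::seqnames(annotation))) {
    warning("chromosome '", chromQ, "' absent from annotation")
    return(character())
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(
    annotation, iv, minoverlap = minOverlap))
  hit <- annotation[S4Vectors::queryHits(hits)]
  hit <- hit[order(GenomicRanges::start(hit), hit$symbol)]
  as.character(hit$symbol)
}

#' Tissue-specificity robust z-score
#'
#' For one gene, how far its expression in the target tissue sits above
#' (or below) its own cross-tissue distribution:
#' `z = (y_t - median(y)) / max(1.4826 * MAD(y), 0.01)` with
#' `y = log2(x + 1)` over all tissues. The MAD floor keeps a flat profile
#' at `z = 0` rather than an infinity.
#'
#' @param expr a [TissueExpression-class] with at least two tissues.
#' @param gene gene symbol present in `expr`.
#' @param tissue tissue name present in `expr`.
#' @return A single finite numeric z-score.
#' @examples
#' m <- matrix(c(7, 7, 7, 63), 1, 4,
#'             dimnames = list("G", paste0("t", 1:4)))
#' tissueSpecificityZ(TissueExpression(m), "G", "t4")
#' @export
tissueSpecificityZ <- function(expr, gene, tissue) {
  m <- exprValues(expr)
  if (ncol(m) < 2L)
    stop("specificity scoring requires at least two tissues")
  if (!gene %in% rownames(m)) stop("gene '", gene, "' not in matrix")
  if (!tissue %in% colnames(m)) stop("tissue '", tissue, "' not in matrix")
  y <- log2p1(m[gene, ])
  robustZ(y, y[[tissue]])
}

robustZ <- function(y, target) {
  scale <- max(stats::mad(y), MAD_FLOOR)  # mad() already applies 1.4826
  (target - stats::median(y)) / scale
}

tukeyUpperFence <- function(v, k) {
  q <- stats::quantile(v, c(0.25, 0.75), type = 7, names = FALSE)
  q[2] + k * (q[2] - q[1])
}

#' Select tissue-specific outlier genes within a locus
#'
#' The expression filter. A locus gene is selected when, in ANY of the
#' requested target tissues, either
#' \itemize{
#'   \item its log2 target-tissue expression exceeds the Tukey upper fence
#'     `Q3 + fenceK * IQR` computed over the locus genes' target-tissue
#'     log2 values (applied only when the locus holds >= 4 scorable
#'     genes), or
#'   \item its cross-tissue robust z-score ([tissueSpecificityZ()]) is at
#'     least `zMin`.
#' }
#' The dual rule captures both "high relative to its locus neighbours"
#' and "high relative to the same gene's other tissues".
#'
#' @param expr a [TissueExpression-class] (>= 2 tissues).
#' @param locusGenes character vector of locus gene symbols. Genes absent
#'   from `expr` are unscorable: skipped with a message and reported in
#'   the `unscorable` element, never silently dropped.
#' @param tissues one or more target tissue names.
#' @param zMin robust z threshold (default 2.0).
#' @param fenceK Tukey fence multiplier (default 1.5).
#' @return A list of class `"locusSelection"`:
#'   \describe{
#'     \item{selected}{selected symbols, sorted by descending target
#'       expression (max over requested tissues), ties by symbol.}
#'     \item{scores}{data frame with one row per gene x tissue: `gene`,
#'       `tissue`, `targetLog2`, `z`, `fenceOutlier`, `zOutlier`,
#'       `passed`.}
#'     \item{unscorable}{locus symbols absent from the matrix.}
#'     \item{fence}{named numeric of per-tissue fence values (`NA` when
#'       the fence rule was skipped).}
#'   }
#' @export
selectLocusOutliers <- function(expr, locusGenes, tissues,
                                zMin = 2.0, fenceK = 1.5) {
  m <- exprValues(expr)
  if (ncol(m) < 2L)
    stop("specificity scoring requires at least two tissues")
  missingT <- setdiff(tissues, colnames(m))
  if (length(missingT))
    stop("tissue '", missingT[1], "' not in matrix")
  locusGenes <- as.character(locusGenes)
  unscorable <- setdiff(locusGenes, rownames(m))
  if (length(unscorable))
    message(length(unscorable),
            " locus gene(s) absent from expression matrix (unscorable): ",
            joinSymbols(unscorable))
  genes <- intersect(locusGenes, rownames(m))
  if (!length(genes)) {
    return(structure(list(selected = character(),
                          scores = emptyScores(),
                          unscorable = unscorable,
                          fence = setNames(rep(NA_real_, length(tissues)),
                                           tissues)),
                     class = "locusSelection"))
  }
  y <- log2p1(m[genes, , drop = FALSE])
  fence <- setNames(rep(NA_real_, length(tissues)), tissues)
  useFence <- length(genes) >= 4L
  if (!useFence)
    message("locus holds fewer than 4 scorable genes; ",
            "Tukey fence rule skipped, z rule alone applies")
  rows <- vector("list", length(tissues))
  for (i in seq_along(tissues)) {
    tt <- tissues[i]
    target <- y[, tt]
    if (useFence) fence[tt] <- tukeyUpperFence(target, fenceK)
    z <- vapply(genes, function(g) robustZ(y[g, ], y[g, tt]), 0)
    fenceOut <- if (useFence) target > fence[tt] else rep(FALSE, length(genes))
    zOut <- z >= zMin
    rows[[i]] <- data.frame(gene = genes, tissue = tt,
                            targetLog2 = unname(target), z = unname(z),
                            fenceOutlier = unname(fenceOut),
                            zOutlier = unname(zOut),
                            passed = unname(fenceOut | zOut),
                            stringsAsFactors = FALSE)
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  passed <- unique(scores$gene[scores$passed])
  maxExpr <- vapply(passed, function(g)
    max(scores$targetLog2[scores$gene == g]), 0)
  ord <- order(-maxExpr, passed)
  structure(list(selected = passed[ord], scores = scores,
                 unscorable = unscorable, fence = fence),
            class = "locusSelection")
}

emptyScores <- function() {
  data.frame(gene = character(), tissue = character(),
             targetLog2 = numeric(), z = numeric(),
             fenceOutlier = logical(), zOutlier = logical(),
             passed = logical(), stringsAsFactors = FALSE)
}

#' @export
print.locusSelection <- function(x, ...) {
  cat("locusSelection:", length(x$selected), "gene(s) selected of",
      length(unique(x$scores$gene)) + length(x$unscorable),
      "locus gene(s)\n")
  if (length(x$selected))
    cat("  selected:", joinSymbols(x$selected), "\n")
  if (length(x$unscorable))
    cat("  unscorable:", joinSymbols(x$unscorable), "\n")
  invisible(x)
}
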