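## Evidence fusion: competition ranks per evidence stream, weighted
## rank-product (geometric mean of rank ratios), and the final gene
## prioritization in which the expression filter is a hard gate and the
## fused network/pathway evidence orders the survivors.

#' Competition ranks per evidence stream
#'
#' Turns per-gene scores into ranks (1 = best). Ties share the minimum
#' rank (competition ranking). `NA` scores are unscorable and receive the
#' worst rank `N` (the number of candidates), with a message — absence of
#' evidence must not silently drop a candidate.
#'
#' @param scores data frame or matrix of numeric scores, one row per
#'   candidate (rownames = symbols, or a `gene` column), one column per
#'   evidence stream.
#' @param higherIsBetter named logical, one entry per evidence column;
#'   default `TRUE` for every column.
#' @return List with `ranks` (integer matrix, rownames = genes), and `n`
#'   (number of candidates).
#' @examples
#' s <- data.frame(ev = c(10, 7, 7, 1),
#'                 row.names = c("A", "B", "C", "D"))
#' rankEvidence(s)$ranks  # 1, 2, 2, 4
#' @export
rankEvidence <- function(scores, higherIsBetter = NULL) {
  if (is.data.frame(scores) && "gene" %in% colnames(scores)) {
    rownames(scores) <- scores$gene
    scores <- scores[, setdiff(colnames(scores), "gene"), drop = FALSE]
  }
  scores <- as.matrix(scores)
  if (!nrow(scores)) stop("empty candidate list")
  if (is.null(rownames(scores))) stop("candidates must be named")
  if (is.null(higherIsBetter))
    higherIsBetter <- setNames(rep(TRUE, ncol(scores)), colnames(scores))
  n <- nrow(scores)
  ranks <- matrix(NA_integer_, n, ncol(scores),
                  dimnames = dimnames(scores))
  for (j in seq_len(ncol(scores))) {
    v <- scores[, j]
    hib <- higherIsBetter[[colnames(scores)[j]]]
    if (is.null(hib) || is.na(hib)) hib <- TRUE
    key <- if (hib) -v else v
    ok <- !is.na(key)
    if (any(!ok))
      message(sum(!ok), " unscorable candidate(s) in evidence '",
              colnames(scores)[j], "' given worst rank ", n)
    r <- rep(n, n)
    if (any(ok)) {
      ## competition rank: 1 + number of strictly better scores
      kv <- key[ok]
      r[ok] <- vapply(kv, function(k) 1L + sum(kv < k), 1L)
    }
    ranks[, j] <- as.integer(r)
  }
  list(ranks = ranks, n = n)
}

#' Fuse evidence ranks into one score
#'
#' Weighted rank product: for each gene,
#' `fused = exp( sum_e w_e * log(rank_e / N) / sum_e w_e )`,
#' the weighted geometric mean of its rank ratios across evidence
#' streams. Lower is better; a gene ranked first everywhere scores
#' `1 / N`. The geometric mean is scale-free, insensitive to evidence
#' ordering, and invariant to duplicating a stream with split weights.
#'
#' @param ranked value of [rankEvidence()] (or a list with integer matrix
#'   `ranks` and count `n`).
#' @param weights named non-negative weights per evidence column;
#'   default 1 each. At least one must be positive.
#' @return Named numeric vector of fused scores in `(0, 1]`, in candidate
#'   order.
#' @export
fuseRanks <- function(ranked, weights = NULL) {
  ranks <- ranked$ranks
  n <- ranked$n
  if (is.null(weights))
    weights <- setNames(rep(1, ncol(ranks)), colnames(ranks))
  w <- setNames(rep(0, ncol(ranks)), colnames(ranks))
  w[names(weights)] <- weights
  if (any(w < 0)) stop("weights must be >= 0")
  if (sum(w) == 0) stop("at least one evidence weight must be positive")
  lr <- log(ranks / n)
  fused <- exp(as.vector(lr %*% w) / sum(w))
  setNames(fused, rownames(ranks))
}

#' Prioritize candidate genes
#'
#' Final gene-level verdict. The expression filter is hard: a gene that
#' failed it is never selected, whatever its network evidence. Among
#' filter passers, the `topK` best fused scores are selected (default:
#' all passers), ties broken by symbol. With
#' `requireNetworkEvidence = TRUE` a passer additionally needs at least
#' one strictly positive network/pathway evidence value — the strict
#' "confirmation" mode in which interactome and pathway data must
#' corroborate the expression signal.
#'
#' @param candidates character vector of candidate symbols.
#' @param expressionSelected symbols that passed the expression filter
#'   (e.g. `selectLocusOutliers(...)$selected`).
#' @param fused named numeric of fused scores from [fuseRanks()].
#' @param topK optional integer; keep only the best `topK` passers.
#' @param requireNetworkEvidence require >= 1 positive network evidence.
#' @param evidence data frame from [scoreNetworkEvidence()]; required
#'   when `requireNetworkEvidence = TRUE`.
#' @return Data frame sorted by ascending fused score (ties by symbol):
#'   `gene`, `fused`, `passesExpressionFilter`, `hasNetworkEvidence`,
#'   `selected`.
#' @export
prioritizeGenes <- function(candidates, expressionSelected, fused,
                            topK = NULL, requireNetworkEvidence = FALSE,
                            evidence = NULL) {
  candidates <- as.character(candidates)
  passes <- candidates %in% expressionSelected
  fusedV <- unname(fused[candidates])
  hasEv <- rep(NA, length(candidates))
  if (requireNetworkEvidence) {
    if (is.null(evidence))
      stop("requireNetworkEvidence = TRUE needs the evidence table")
    ev <- evidence[match(candidates, evidence$gene),
                   c("proximity", "pathwayOverlap", "perturbationImpact")]
    hasEv <- apply(ev, 1, function(r) any(!is.na(r) & r > 0))
    hasEv[is.na(hasEv)] <- FALSE
  }
  df <- data.frame(gene = candidates, fused = fusedV,
                   passesExpressionFilter = passes,
                   hasNetworkEvidence = hasEv,
                   stringsAsFactors = FALSE)
  df <- df[order(df$fused, df$gene), , drop = FALSE]
  eligible <- df$passesExpressionFilter &
    (!requireNetworkEvidence | df$hasNetworkEvidence)
  sel <- eligible
  if (!is.null(topK)) {
    keep <- which(eligible)[seq_len(min(topK, sum(eligible)))]
    sel <- rep(FALSE, nrow(df))
    sel[keep] <- TRUE
  }
  df$selected <- sel
  stopifnot(all(df$passesExpressionFilter[df$selected]))  # hard filter
  rownames(df) <- NULL
  df
}
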