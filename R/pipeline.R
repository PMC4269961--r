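## End-to-end pipeline: locus genes -> expression filter -> network
## evidence -> rank fusion -> gene prioritization -> (optional extended
## candidates) -> CNV prioritization -> cohort summary, with a run
## manifest embedded in the report.

pkgVersion <- function() {
  as.character(utils::packageVersion("cytoPrior"))
}

defaultWeights <- c(specificity = 1, proximity = 1, pathway = 1,
                    perturbation = 1)

#' Run the full prioritization pipeline
#'
#' Executes every stage of the method on in-memory objects and returns a
#' consolidated report. Analysis loci default to one locus per
#' chromosome (the full annotated extent — the aneuploidy-style
#' screening mode); pass explicit `loci` to restrict to imbalances of
#' interest.
#'
#' The expression filter is a hard gate; evidence streams
#' (cross-tissue specificity z, seed proximity, pathway overlap,
#' perturbation impact) are fused by a weighted rank product; by default
#' a selected gene must also carry at least one positive network or
#' pathway evidence (`requireNetworkEvidence = TRUE`) — the
#' interactome/pathway confirmation step of the procedure. Set it to
#' `FALSE` to rank on expression alone.
#'
#' @param annotation annotation `GRanges` ([readGeneAnnotation()]).
#' @param expression a [TissueExpression-class].
#' @param network an [InteractionNetwork-class].
#' @param pathways a [PathwaySet-class].
#' @param seeds character vector of phenotype seed symbols.
#' @param tissues target tissue name(s).
#' @param calls optional CNV `GRanges` ([readCnvCalls()]).
#' @param catalog optional benign-variant `GRanges`
#'   ([readVariantCatalog()]).
#' @param roster optional full patient roster; defaults to the patients
#'   present in `calls`.
#' @param loci optional list/vector of intervals (`GRanges` or
#'   `"chrom:start-end"` strings); default one locus per chromosome.
#' @param zMin,fenceK expression-filter thresholds
#'   (see [selectLocusOutliers()]).
#' @param weights named fusion weights for `specificity`, `proximity`,
#'   `pathway`, `perturbation`.
#' @param topK optional cap on selected genes per run.
#' @param requireNetworkEvidence see above; default `TRUE`.
#' @param extendCandidates also report second-pass candidates outside
#'   the loci ([extendedCandidates()]) with their network evidence.
#' @param benignVeto,minReciprocalOverlap,minFrequency CNV-stage
#'   parameters (see [prioritizeCnvs()]).
#' @param manifestExtra optional named list merged into the manifest
#'   (e.g. input file digests).
#' @return A named list (the report): `reportVersion`, `manifest`,
#'   `loci`, `expression` (selection per gene), `evidence`, `genes`
#'   (prioritization table), `selectedGenes`, and when CNVs are given
#'   `cnv` and `cohort`.
#' @export
runAll <- function(annotation, expression, network, pathways, seeds,
                   tissues, calls = NULL, catalog = NULL, roster = NULL,
                   loci = NULL, zMin = 2.0, fenceK = 1.5,
                   weights = defaultWeights, topK = NULL,
                   requireNetworkEvidence = TRUE,
                   extendCandidates = FALSE, benignVeto = TRUE,
                   minReciprocalOverlap = 0.5, minFrequency = 0.01,
                   manifestExtra = NULL) {
  if (!length(annotation)) stop("validation error in stage 'loci': ",
                                "empty gene annotation")
  if (is.null(loci)) loci <- chromosomeLoci(annotation)
  lociChr <- vapply(loci, function(l) {
    iv <- parseInterval(l)
    sprintf("%s:%d-%d", as.character(GenomicRanges::seqnames(iv)),
            GenomicRanges::start(iv) - 1L, GenomicRanges::end(iv))
  }, "")

  ## stage 1: locus gene content
  locusGenes <- lapply(loci, function(l) genesInInterval(annotation, l))
  candidates <- sort(unique(unlist(locusGenes)))
  if (!length(candidates))
    stop("validation error in stage 'loci': no genes in any locus")

  ## stage 2: expression filter, per locus
  selections <- lapply(locusGenes, function(g)
    selectLocusOutliers(expression, g, tissues, zMin = zMin,
                        fenceK = fenceK))
  expressionSelected <- sort(unique(unlist(
    lapply(selections, `[[`, "selected"))))

  ## stage 3: evidence (specificity z + network/pathway)
  evidence <- scoreNetworkEvidence(network, pathways, candidates, seeds)
  evidence$specificityZ <- specificityForRanking(expression, candidates,
                                                 tissues)
  ## stage 4: rank fusion
  sc <- data.frame(row.names = evidence$gene,
                   specificity = evidence$specificityZ,
                   proximity = evidence$proximity,
                   pathway = evidence$pathwayOverlap,
                   perturbation = evidence$perturbationImpact)
  ranked <- rankEvidence(sc)
  fused <- fuseRanks(ranked, weights)

  ## stage 5: gene prioritization
  genes <- prioritizeGenes(candidates, expressionSelected, fused,
                           topK = topK,
                           requireNetworkEvidence = requireNetworkEvidence,
                           evidence = evidence)
  selected <- genes$gene[genes$selected]

  report <- list(
    reportVersion = 1,
    manifest = c(list(tool = "cytoPrior", version = pkgVersion(),
                      created = format(Sys.time(), tz = "UTC"),
                      parameters = list(
                        tissues = as.list(tissues), zMin = zMin,
                        fenceK = fenceK, weights = as.list(weights),
                        topK = topK,
                        requireNetworkEvidence = requireNetworkEvidence,
                        benignVeto = benignVeto,
                        minReciprocalOverlap = minReciprocalOverlap,
                        minFrequency = minFrequency)),
                 manifestExtra),
    loci = lociChr,
    expression = list(selected = expressionSelected,
                      scores = do.call(rbind,
                                       lapply(selections, `[[`, "scores")),
                      unscorable = sort(unique(unlist(
                        lapply(selections, `[[`, "unscorable"))))),
    evidence = evidence,
    genes = genes,
    selectedGenes = selected)

  ## optional second pass: candidates outside the imbalance
  if (extendCandidates && length(selected)) {
    ext <- extendedCandidates(network, pathways, selected)
    report$extendedCandidates <-
      if (length(ext)) scoreNetworkEvidence(network, pathways, ext, seeds)
      else data.frame()
  }

  ## stage 6-7: CNV prioritization and cohort summary
  if (!is.null(calls)) {
    cnv <- prioritizeCnvs(calls, selected, annotation, catalog,
                          benignVeto = benignVeto,
                          minReciprocalOverlap = minReciprocalOverlap,
                          minFrequency = minFrequency)
    report$cnv <- cnv
    if (is.null(roster)) roster <- unique(calls$patient_id)
    summary <- summarizeCohort(cnv, roster)
    report$cohort <- list(
      nPatients = summary$nPatients,
      nCnvPrioritizedTotal = summary$nCnvPrioritizedTotal,
      perPatientCounts = as.list(summary$perPatientCounts),
      histogram = summary$histogram,
      yieldPercent = summary$yieldPercent)
  }
  report
}

chromosomeLoci <- function(annotation) {
  chroms <- unique(as.character(GenomicRanges::seqnames(annotation)))
  lapply(chroms, function(ch) {
    sub <- annotation[
      as.character(GenomicRanges::seqnames(annotation)) == ch]
    GenomicRanges::GRanges(ch, IRanges::IRanges(
      min(GenomicRanges::start(sub)), max(GenomicRanges::end(sub))))
  })
}

## max robust z over the requested tissues; NA for genes without
## expression data (-> worst rank in fusion)
specificityForRanking <- function(expression, candidates, tissues) {
  m <- exprValues(expression)
  y <- log2p1(m)
  vapply(candidates, function(g) {
    if (!g %in% rownames(y)) return(NA_real_)
    yg <- y[g, ]
    max(vapply(tissues, function(tt) robustZ(yg, yg[[tt]]), 0))
  }, 0)
}

#' Run the pipeline from input files
#'
#' Thin file-based front end to [runAll()]: reads every input with the
#' package readers, records their MD5 digests in the manifest, runs the
#' pipeline and optionally writes the JSON report.
#'
#' @param annotationFile,expressionFile,networkFile,genesetsFile,seedsFile
#'   input paths (see the corresponding readers).
#' @param cnvFile,catalogFile,rosterFile optional input paths.
#' @param tissues target tissue name(s).
#' @param out optional path for the JSON report.
#' @param ... further arguments passed to [runAll()].
#' @return The report list, invisibly when `out` is given.
#' @export
runAllFiles <- function(annotationFile, expressionFile, networkFile,
                        genesetsFile, seedsFile, tissues,
                        cnvFile = NULL, catalogFile = NULL,
                        rosterFile = NULL, out = NULL, ...) {
  paths <- c(annotation = annotationFile, expression = expressionFile,
             network = networkFile, genesets = genesetsFile,
             seeds = seedsFile, cnv = cnvFile, catalog = catalogFile,
             roster = rosterFile)
  missingF <- paths[!file.exists(paths)]
  if (length(missingF))
    stop("configuration error: input file not found: ", missingF[1])
  digests <- as.list(tools::md5sum(paths))
  names(digests) <- names(paths)
  report <- runAll(
    annotation = readGeneAnnotation(annotationFile),
    expression = readExpressionMatrix(expressionFile),
    network = readNetwork(networkFile),
    pathways = readGeneSetsGmt(genesetsFile),
    seeds = readSeeds(seedsFile),
    tissues = tissues,
    calls = if (!is.null(cnvFile)) readCnvCalls(cnvFile),
    catalog = if (!is.null(catalogFile)) readVariantCatalog(catalogFile),
    roster = if (!is.null(rosterFile)) readLines(rosterFile),
    manifestExtra = list(inputDigests = digests),
    ...)
  if (!is.null(out)) {
    writeReport(report, out)
    return(invisible(report))
  }
  report
}
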