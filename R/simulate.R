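## Synthetic-study generator: every input format the pipeline consumes,
## with planted ground truth (tissue-specific disease genes, a wired
## disease network module, a mixed pathogenic/benign CNV cohort), so the
## whole method is testable end to end without any external database.

#' Simulation configuration
#'
#' Parameters of a complete synthetic study. One master `seed` fans out
#' into independent substreams per component (genome, planting,
#' expression, network, cohort), so identical configurations reproduce
#' byte-identical files.
#'
#' Defaults describe the study conditions the package is evaluated
#' under: 4 chromosomes of 50 genes (a 7q36-like gene density), a
#' 30-tissue expression panel with the disease tissue first, 5 planted
#' disease genes per chromosome raised by +3 log2 units in the target
#' tissue over log2-scale Gaussian noise (sd 0.5), a scale-free
#' interactome over all genes (preferential attachment, m = 2) with 8
#' phenotype seed genes, and a 205-patient cohort in which a patient
#' carries 1-3 pathogenic CNVs with probability 181/205.
#'
#' @slot seed master RNG seed (integer).
#' @slot nChrom number of chromosomes.
#' @slot genesPerChrom genes per chromosome.
#' @slot nTissues number of tissues (>= 2).
#' @slot nPlanted planted disease genes per chromosome.
#' @slot effectLog2fc planted target-tissue effect, log2 units.
#' @slot noiseSd log2-scale Gaussian noise sd.
#' @slot attachmentM preferential-attachment edges per new node.
#' @slot nSeeds number of phenotype seed genes.
#' @slot nDistractorPathways distractor pathways beside the disease
#'   module pathway.
#' @slot pathwaySize genes per distractor pathway.
#' @slot nPatients cohort size.
#' @slot pathogenicProb probability a patient carries pathogenic CNVs.
#' @slot benignCatalogSize entries in the benign-variant catalog.
#' @slot benignFreqRange numeric length 2, population-frequency range of
#'   catalog entries (within `[0, 1]`, lower bound >= 0.01 so catalog
#'   draws always pass the frequency gate).
#' @slot targetTissue name of the affected tissue.
#' @export
setClass("SimulationConfig", representation(
  seed = "numeric", nChrom = "numeric", genesPerChrom = "numeric",
  nTissues = "numeric", nPlanted = "numeric", effectLog2fc = "numeric",
  noiseSd = "numeric", attachmentM = "numeric", nSeeds = "numeric",
  nDistractorPathways = "numeric", pathwaySize = "numeric",
  nPatients = "numeric", pathogenicProb = "numeric",
  benignCatalogSize = "numeric", benignFreqRange = "numeric",
  targetTissue = "character"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  pos <- c("nChrom", "nTissues", "nPatients",
           "attachmentM", "nSeeds", "pathwaySize")
  for (s in pos)
    if (slot(object, s) < 1) msg <- c(msg, paste(s, "must be positive"))
  for (s in c("genesPerChrom", "nPlanted", "nDistractorPathways",
              "benignCatalogSize", "effectLog2fc", "noiseSd"))
    if (slot(object, s) < 0) msg <- c(msg, paste(s, "must be >= 0"))
  if (object@nTissues < 2)
    msg <- c(msg, "nTissues must be >= 2 (specificity needs >= 2 tissues)")
  if (object@pathogenicProb < 0 || object@pathogenicProb > 1)
    msg <- c(msg, "pathogenicProb must be in [0, 1]")
  if (length(object@benignFreqRange) != 2 ||
      object@benignFreqRange[1] > object@benignFreqRange[2] ||
      object@benignFreqRange[1] < 0 || object@benignFreqRange[2] > 1)
    msg <- c(msg, "benignFreqRange must be an increasing pair in [0, 1]")
  if (object@nPlanted > object@genesPerChrom)
    msg <- c(msg, "nPlanted cannot exceed genesPerChrom")
  if (length(msg)) msg else TRUE
})

#' @describeIn SimulationConfig constructor with study-default values.
#' @param seed,nChrom,genesPerChrom,nTissues,nPlanted,effectLog2fc
#'   see slots.
#' @param noiseSd,attachmentM,nSeeds,nDistractorPathways,pathwaySize
#'   see slots.
#' @param nPatients,pathogenicProb,benignCatalogSize,benignFreqRange
#'   see slots.
#' @param targetTissue see slots.
#' @export
simulationConfig <- function(seed = 1, nChrom = 4, genesPerChrom = 50,
                             nTissues = 30, nPlanted = 5,
                             effectLog2fc = 3.0, noiseSd = 0.5,
                             attachmentM = 2, nSeeds = 8,
                             nDistractorPathways = 10, pathwaySize = 15,
                             nPatients = 205,
                             pathogenicProb = 181 / 205,
                             benignCatalogSize = 60,
                             benignFreqRange = c(0.01, 0.25),
                             targetTissue = "tissue01") {
  new("SimulationConfig", seed = seed, nChrom = nChrom,
      genesPerChrom = genesPerChrom, nTissues = nTissues,
      nPlanted = nPlanted, effectLog2fc = effectLog2fc,
      noiseSd = noiseSd, attachmentM = attachmentM, nSeeds = nSeeds,
      nDistractorPathways = nDistractorPathways,
      pathwaySize = pathwaySize, nPatients = nPatients,
      pathogenicProb = pathogenicProb,
      benignCatalogSize = benignCatalogSize,
      benignFreqRange = benignFreqRange, targetTissue = targetTissue)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: seed", object@seed, "|",
      object@nChrom, "chrom x", object@genesPerChrom, "genes |",
      object@nTissues, "tissues |", object@nPlanted,
      "planted/chrom (effect +", object@effectLog2fc, "log2) |",
      object@nPatients, "patients\n")
})

tissueNames <- function(config) sprintf("tissue%02d", seq_len(config@nTissues))

#' Generate a synthetic genome annotation
#'
#' Non-overlapping genes laid left to right per chromosome (lengths
#' 5-50 kb, gaps 2-20 kb), deterministic under the configuration seed.
#'
#' @param config a [SimulationConfig-class].
#' @return Annotation `GRanges` with a `symbol` column, sorted.
#' @export
generateGenome <- function(config) {
  validObject(config)
  set.seed(childSeed(config@seed, 1))
  out <- vector("list", config@nChrom)
  for (ci in seq_len(config@nChrom)) {
    n <- config@genesPerChrom
    if (n == 0) next
    len <- round(runif(n, 5000, 50000))
    gap <- round(runif(n, 2000, 20000))
    start1 <- 10000 + cumsum(gap) + c(0, cumsum(len))[seq_len(n)]
    out[[ci]] <- GenomicRanges::GRanges(
      sprintf("chr%d", ci),
      IRanges::IRanges(start1, width = len),
      symbol = sprintf("G%02d%03d", ci, seq_len(n)))
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (!length(out)) return(emptyAnnotation())
  sortAnnotation(suppressWarnings(do.call(c, out)))
}

plantGenes <- function(config, annotation) {
  set.seed(childSeed(config@seed, 2))
  chroms <- as.character(GenomicRanges::seqnames(annotation))
  planted <- character()
  for (ch in unique(chroms)) {
    sym <- annotation$symbol[chroms == ch]
    planted <- c(planted, sample(sym, min(config@nPlanted, length(sym))))
  }
  sort(planted)
}

#' Generate a synthetic expression matrix with planted outliers
#'
#' Baseline log2 values ~ Normal(5, `noiseSd`) per gene and tissue;
#' planted genes get `+effectLog2fc` in the target tissue only. Values
#' are stored on the raw scale (`2^y - 1`, floored at 0).
#'
#' @param config a [SimulationConfig-class].
#' @param annotation annotation `GRanges` (defines the gene set).
#' @param planted character vector of planted disease-gene symbols.
#' @return A [TissueExpression-class].
#' @export
generateExpression <- function(config, annotation, planted) {
  validObject(config)
  set.seed(childSeed(config@seed, 3))
  genes <- annotation$symbol
  tis <- tissueNames(config)
  y <- matrix(rnorm(length(genes) * length(tis), 5, config@noiseSd),
              length(genes), length(tis),
              dimnames = list(genes, tis))
  y[intersect(planted, genes), config@targetTissue] <-
    y[intersect(planted, genes), config@targetTissue] + config@effectLog2fc
  TissueExpression(pmax(2^y - 1, 0))
}

#' Generate a synthetic interactome, pathways and seed set
#'
#' A preferential-attachment (scale-free) graph over all gene symbols
#' (hub identity randomized), plus a planted disease module: `nSeeds`
#' phenotype seed genes drawn from the non-planted genes, each planted
#' gene wired to 2 seeds, and one `disease_module` pathway containing
#' seeds and planted genes. Distractor pathways are drawn from the
#' remaining genes, so they carry no phenotype signal.
#'
#' @param config a [SimulationConfig-class].
#' @param annotation annotation `GRanges`.
#' @param planted planted disease-gene symbols.
#' @return List: `network` ([InteractionNetwork-class]), `pathways`
#'   ([PathwaySet-class]), `seeds` (character).
#' @export
generateNetworkAndPathways <- function(config, annotation, planted) {
  validObject(config)
  set.seed(childSeed(config@seed, 4))
  genes <- annotation$symbol
  n <- length(genes)
  if (n < 2) stop("need at least 2 genes for a network")
  g <- igraph::sample_pa(n, m = min(config@attachmentM, n - 1),
                         directed = FALSE)
  igraph::V(g)$name <- sample(genes)
  seeds <- sort(sample(setdiff(genes, planted),
                       min(config@nSeeds, n - length(planted))))
  wires <- do.call(rbind, lapply(planted, function(p)
    cbind(p, sample(seeds, min(2, length(seeds))))))
  if (!is.null(wires))
    g <- igraph::add_edges(g, t(wires))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  network <- new("InteractionNetwork", graph = g)
  sets <- list(disease_module = sort(unique(c(seeds, planted))))
  pool <- setdiff(genes, c(seeds, planted))
  if (length(pool))
    for (i in seq_len(config@nDistractorPathways)) {
      sets[[sprintf("pathway%02d", i)]] <-
        sort(sample(pool, min(config@pathwaySize, length(pool))))
    }
  list(network = network, pathways = PathwaySet(sets), seeds = seeds)
}

#' Generate a synthetic CNV cohort, benign catalog and truth table
#'
#' The catalog holds common variants (frequency in `benignFreqRange`)
#' placed away from planted genes. Each patient carries, with
#' probability `pathogenicProb`, 1-3 pathogenic CNVs (a planted gene
#' plus random flanks) and, independently, 0-5 benign CNVs (catalog
#' entries with a small positional jitter that preserves reciprocal
#' overlap with their source entry). The truth table records each call's
#' class.
#'
#' @param config a [SimulationConfig-class].
#' @param annotation annotation `GRanges`.
#' @param planted planted disease-gene symbols.
#' @return List: `calls` (CNV `GRanges`), `catalog` (`GRanges` with
#'   `frequency`), `truth` (data frame `patient_id`, `chrom`, `start`,
#'   `end`, `dosage`, `class`), `roster` (character).
#' @export
generateCohort <- function(config, annotation, planted) {
  validObject(config)
  set.seed(childSeed(config@seed, 5))
  chroms <- unique(as.character(GenomicRanges::seqnames(annotation)))
  extent <- vapply(chroms, function(ch)
    max(GenomicRanges::end(annotation[
      as.character(GenomicRanges::seqnames(annotation)) == ch])) + 50000, 0)
  plantedGr <- annotation[annotation$symbol %in% planted]
  pChrom <- as.character(GenomicRanges::seqnames(plantedGr))
  pStart <- GenomicRanges::start(plantedGr)
  pEnd <- GenomicRanges::end(plantedGr)
  hitsPlanted <- function(ch, st, en) {
    k <- pChrom == ch
    any(pStart[k] <= en & pEnd[k] >= st)
  }

  ## benign catalog: common variants sparing the planted disease genes
  ncat <- config@benignCatalogSize
  catChrom <- character(ncat); catStart <- numeric(ncat)
  catEnd <- numeric(ncat)
  i <- 0L
  while (i < ncat) {
    ch <- sample(chroms, 1)
    len <- round(runif(1, 20000, 200000))
    st <- round(runif(1, 1, max(extent[[ch]] - len, 2)))
    if (hitsPlanted(ch, st, st + len - 1)) next
    i <- i + 1L
    catChrom[i] <- ch; catStart[i] <- st; catEnd[i] <- st + len - 1
  }
  catalog <- GenomicRanges::GRanges(
    catChrom, IRanges::IRanges(catStart, catEnd),
    frequency = round(runif(ncat, config@benignFreqRange[1],
                            config@benignFreqRange[2]), 4))
  ord <- order(as.character(GenomicRanges::seqnames(catalog)),
               GenomicRanges::start(catalog))
  catalog <- catalog[ord]

  catChr <- as.character(GenomicRanges::seqnames(catalog))
  catSt <- GenomicRanges::start(catalog)
  catW <- GenomicRanges::width(catalog)

  roster <- sprintf("PT%03d", seq_len(config@nPatients))
  acc <- list(patient_id = character(), chrom = character(),
              start1 = numeric(), end1 = numeric(),
              dosage = character(), class = character())
  push <- function(p, ch, st, en, dos, cl) {
    acc$patient_id[[length(acc$patient_id) + 1L]] <<- p
    acc$chrom[[length(acc$chrom) + 1L]] <<- ch
    acc$start1[[length(acc$start1) + 1L]] <<- st
    acc$end1[[length(acc$end1) + 1L]] <<- en
    acc$dosage[[length(acc$dosage) + 1L]] <<- dos
    acc$class[[length(acc$class) + 1L]] <<- cl
  }
  for (p in roster) {
    if (runif(1) < config@pathogenicProb) {
      for (k in seq_len(sample(1:3, 1))) {
        gi <- sample(length(plantedGr), 1)
        fl <- round(runif(2, 1000, 30000))
        push(p, pChrom[gi], max(1, pStart[gi] - fl[1]),
             pEnd[gi] + fl[2], sample(dosageTokens, 1), "pathogenic")
      }
    }
    nb <- sample(0:min(5, length(catalog)), 1)
    if (nb > 0) {
      for (j in sample(length(catalog), nb)) {
        shift <- round(runif(1, -0.05, 0.05) * catW[j])
        st <- max(1, catSt[j] + shift)
        push(p, catChr[j], st, st + catW[j] - 1,
             sample(dosageTokens, 1), "benign")
      }
    }
  }
  truth <- data.frame(acc, stringsAsFactors = FALSE)
  truth <- truth[order(truth$patient_id, truth$chrom, truth$start1), ,
                 drop = FALSE]
  calls <- GenomicRanges::GRanges(
    truth$chrom, IRanges::IRanges(truth$start1, truth$end1),
    patient_id = truth$patient_id, dosage = truth$dosage)
  truthOut <- data.frame(patient_id = truth$patient_id,
                         chrom = truth$chrom,
                         start = truth$start1 - 1,
                         end = truth$end1,
                         dosage = truth$dosage,
                         class = truth$class, stringsAsFactors = FALSE)
  rownames(truthOut) <- NULL
  list(calls = calls, catalog = catalog, truth = truthOut,
       roster = roster)
}

#' Simulate a complete study
#'
#' Runs every generator with the configuration's fanned-out seed and
#' returns (optionally writes) the full set of inputs plus ground truth.
#'
#' @param config a [SimulationConfig-class].
#' @param dir optional directory; when given, all standard-format files
#'   plus truth tables are written there (`annotation.bed`,
#'   `expression.tsv`, `network.tsv`, `pathways.gmt`, `seeds.txt`,
#'   `cnv_calls.tsv`, `variant_catalog.tsv`, `truth.tsv`, `roster.txt`,
#'   `config.yaml`).
#' @return List: `config`, `annotation`, `planted`, `expression`,
#'   `network`, `pathways`, `seeds`, `calls`, `catalog`, `truth`,
#'   `roster`.
#' @export
simulateStudy <- function(config = simulationConfig(), dir = NULL) {
  validObject(config)
  annotation <- generateGenome(config)
  planted <- plantGenes(config, annotation)
  expression <- generateExpression(config, annotation, planted)
  np <- generateNetworkAndPathways(config, annotation, planted)
  cohort <- generateCohort(config, annotation, planted)
  study <- list(config = config, annotation = annotation,
                planted = planted, expression = expression,
                network = np$network, pathways = np$pathways,
                seeds = np$seeds, calls = cohort$calls,
                catalog = cohort$catalog, truth = cohort$truth,
                roster = cohort$roster)
  if (!is.null(dir)) writeStudy(study, dir)
  study
}

#' Write a simulated study to disk
#' @param study value of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  writeGeneAnnotation(study$annotation, fp("annotation.bed"))
  writeExpressionMatrix(study$expression, fp("expression.tsv"))
  writeNetwork(study$network, fp("network.tsv"))
  writeGeneSetsGmt(study$pathways, fp("pathways.gmt"))
  writeSeeds(study$seeds, fp("seeds.txt"))
  writeCnvCalls(study$calls, fp("cnv_calls.tsv"))
  writeVariantCatalog(study$catalog, fp("variant_catalog.tsv"))
  write.table(study$truth, fp("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(study$roster, fp("roster.txt"))
  writeLines(paste0("planted: [", joinSymbols(study$planted), "]"),
             fp("planted.yaml"))
  cfg <- study$config
  yaml::write_yaml(list(
    seed = cfg@seed, nChrom = cfg@nChrom,
    genesPerChrom = cfg@genesPerChrom, nTissues = cfg@nTissues,
    nPlanted = cfg@nPlanted, effectLog2fc = cfg@effectLog2fc,
    noiseSd = cfg@noiseSd, attachmentM = cfg@attachmentM,
    nSeeds = cfg@nSeeds,
    nDistractorPathways = cfg@nDistractorPathways,
    pathwaySize = cfg@pathwaySize, nPatients = cfg@nPatients,
    pathogenicProb = cfg@pathogenicProb,
    benignCatalogSize = cfg@benignCatalogSize,
    benignFreqRange = cfg@benignFreqRange,
    targetTissue = cfg@targetTissue), fp("config.yaml"))
  invisible(dir)
}

#' Score recovery of planted truth
#'
#' Compares a pipeline result against the generator's ground truth:
#' precision and recall of the prioritized genes against the planted
#' set, and sensitivity/specificity/balanced accuracy of the CNV
#' verdicts against the truth-table classes (`prioritized` vs
#' `pathogenic`).
#'
#' @param selectedGenes character vector of prioritized gene symbols.
#' @param planted character vector of planted gene symbols.
#' @param cnvReport data frame from [prioritizeCnvs()], or `NULL`.
#' @param truth truth table from [generateCohort()], or `NULL`.
#' @return List: `genePrecision`, `geneRecall`, `tp`, `fp`, `fn`, and
#'   (when CNVs given) `cnvSensitivity`, `cnvSpecificity`,
#'   `cnvBalancedAccuracy`.
#' @export
evaluateRecovery <- function(selectedGenes, planted, cnvReport = NULL,
                             truth = NULL) {
  tp <- length(intersect(selectedGenes, planted))
  fp <- length(setdiff(selectedGenes, planted))
  fn <- length(setdiff(planted, selectedGenes))
  out <- list(genePrecision = if (tp + fp) tp / (tp + fp) else NA_real_,
              geneRecall = if (tp + fn) tp / (tp + fn) else NA_real_,
              tp = tp, fp = fp, fn = fn)
  if (!is.null(cnvReport) && !is.null(truth)) {
    key <- function(d) paste(d$patient_id, d$chrom, d$start, d$end,
                             d$dosage)
    m <- match(key(cnvReport), key(truth))
    if (anyNA(m)) stop("CNV report contains calls absent from truth")
    pred <- cnvReport$verdict == "prioritized"
    pos <- truth$class[m] == "pathogenic"
    sens <- if (sum(pos)) sum(pred & pos) / sum(pos) else NA_real_
    spec <- if (sum(!pos)) sum(!pred & !pos) / sum(!pos) else NA_real_
    out$cnvSensitivity <- sens
    out$cnvSpecificity <- spec
    out$cnvBalancedAccuracy <- mean(c(sens, spec), na.rm = TRUE)
  }
  out
}
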