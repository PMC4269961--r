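# Small in-code fixtures shared across tests.

makeAnnotation <- function(chrom, start0, end0, symbol) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         symbol = symbol)
}

# n genes laid end to end on one chromosome, 10 kb each with 5 kb gaps
tinyAnnotation <- function(n = 6, chrom = "chr1", prefix = "G") {
  if (n == 0)
    return(GenomicRanges::GRanges(character(), IRanges::IRanges(),
                                  symbol = character()))
  start0 <- 1000 + (0:(n - 1)) * 15000
  makeAnnotation(chrom, start0, start0 + 10000,
                 sprintf("%s%02d", prefix, seq_len(n)))
}

tinyExpression <- function(genes, tissues = c("brain", "liver", "lung",
                                              "kidney", "heart", "skin"),
                           base = 10) {
  m <- matrix(base, length(genes), length(tissues),
              dimnames = list(genes, tissues))
  TissueExpression(m)
}

# raise `genes` to `value` in `tissue` only
withSignal <- function(expr, genes, tissue, value) {
  m <- exprValues(expr)
  m[genes, tissue] <- value
  TissueExpression(m)
}

tinyCnv <- function(patient, chrom, start0, end0, dosage = "loss") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         patient_id = patient, dosage = dosage)
}

tinyCatalog <- function(chrom, start0, end0, frequency) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0),
                         frequency = frequency)
}

emptyCatalogFixture <- function() {
  tinyCatalog(character(), numeric(), numeric(), numeric())
}

# a fast, scaled-down simulated study for structural tests
smallConfig <- function(seed = 5, ...) {
  args <- utils::modifyList(
    list(seed = seed, nChrom = 2, genesPerChrom = 20, nTissues = 8,
         nPlanted = 3, nPatients = 15, benignCatalogSize = 10),
    list(...))
  do.call(simulationConfig, args)
}

# a 7q36-like locus: 45 genes between ~152 and ~158 Mb on chr7, two of
# which (LIMBR1, MNX1) carry a strong brain-specific signal and direct
# seed interactions
locus7q36Fixture <- function() {
  n <- 45
  start0 <- seq(152e6, 157.9e6, length.out = n)
  sym <- c(sprintf("GENE%02d", seq_len(n - 2)), "LIMBR1", "MNX1")
  ann <- makeAnnotation("chr7", round(start0), round(start0) + 60000, sym)
  expr <- tinyExpression(sym)
  expr <- withSignal(expr, c("LIMBR1", "MNX1"), "brain", 300)
  seeds <- c("SEED1", "SEED2")
  net <- InteractionNetwork(rbind(
    c("LIMBR1", "SEED1"), c("MNX1", "SEED2"),
    c("GENE01", "GENE02"), c("GENE03", "GENE04")))
  pw <- PathwaySet(list(lumbosacral = c("SEED1", "SEED2", "LIMBR1",
                                        "MNX1"),
                        other = c("GENE01", "GENE05", "GENE09")))
  list(annotation = ann, expression = expr, network = net,
       pathways = pw, seeds = seeds)
}

# brute-force oracle: genes overlapping an interval by >= minOverlap bp
scanGenesOracle <- function(annotation, chrom, start0, end0,
                            minOverlap = 1) {
  ac <- as.character(GenomicRanges::seqnames(annotation))
  s0 <- GenomicRanges::start(annotation) - 1
  e0 <- GenomicRanges::end(annotation)
  keep <- ac == chrom &
    (pmin(e0, end0) - pmax(s0, start0)) >= minOverlap
  hit <- annotation[keep]
  hit <- hit[order(GenomicRanges::start(hit), hit$symbol)]
  as.character(hit$symbol)
}

# brute-force oracle for the perturbation impact: adjacency-list BFS,
# seeds counted per component, dominant seed count before vs after
bfsSeedImpactOracle <- function(edges, nodes, seeds, removed) {
  countL <- function(nodes, edges, seeds) {
    seeds <- intersect(seeds, nodes)
    if (!length(seeds)) return(0L)
    adj <- lapply(setNames(nm = nodes), function(v) character())
    if (length(edges) && nrow(edges))
      for (i in seq_len(nrow(edges))) {
        a <- edges[i, 1]; b <- edges[i, 2]
        adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
      }
    unseen <- nodes
    best <- 0L
    while (length(unseen)) {
      queue <- unseen[1]; comp <- character()
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        if (!v %in% unseen) next
        unseen <- setdiff(unseen, v)
        comp <- c(comp, v)
        queue <- c(queue, adj[[v]])
      }
      best <- max(best, length(intersect(comp, seeds)))
    }
    best
  }
  before <- countL(nodes, edges, seeds)
  if (before == 0L) return(0)
  keep <- setdiff(nodes, removed)
  keptEdges <- if (length(edges) && nrow(edges))
    edges[edges[, 1] %in% keep & edges[, 2] %in% keep, , drop = FALSE]
  else edges
  1 - countL(keep, keptEdges, seeds) / before
}

# type-7 quantile written out by hand, independent of stats::quantile
quantile7Oracle <- function(x, p) {
  x <- sort(unname(x))
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
}
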