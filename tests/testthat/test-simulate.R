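test_that("generated genomes are sorted, non-overlapping and seeded", {
  cfg <- smallConfig()
  ann <- generateGenome(cfg)
  expect_length(ann, 40)
  expect_identical(ann, generateGenome(cfg))  # determinism

  # pairwise overlap oracle per chromosome
  for (ch in unique(as.character(GenomicRanges::seqnames(ann)))) {
    sub <- ann[as.character(GenomicRanges::seqnames(ann)) == ch]
    s <- GenomicRanges::start(sub); e <- GenomicRanges::end(sub)
    expect_true(all(diff(s) > 0))
    expect_true(all(utils::head(e, -1) < s[-1]))  # no overlap
  }

  none <- simulationConfig(seed = 1, genesPerChrom = 0, nPlanted = 0)
  expect_length(generateGenome(none), 0)
})

test_that("planted expression effects are recoverable by the z-score", {
  # Monte-Carlo: with effect +3 log2 over sd 0.5 noise, the planted
  # gene's robust z (computed by the direct formula, independently)
  # clears 2 in the vast majority of replicates
  hits <- 0L
  reps <- 60
  for (s in seq_len(reps)) {
    cfg <- smallConfig(seed = 200 + s)
    ann <- generateGenome(cfg)
    planted <- cytoPrior:::plantGenes(cfg, ann)
    expr <- generateExpression(cfg, ann, planted)
    y <- log2(exprValues(expr)[planted[1], ] + 1)
    z <- (y[["tissue01"]] - median(y)) / max(1.4826 * mad(y, constant = 1),
                                             0.01)
    hits <- hits + (z >= 2)
  }
  expect_gt(hits / reps, 0.95)

  # null effect: planted genes look like everything else
  cfg0 <- smallConfig(seed = 77, effectLog2fc = 0)
  ann <- generateGenome(cfg0)
  planted <- cytoPrior:::plantGenes(cfg0, ann)
  expr <- generateExpression(cfg0, ann, planted)
  sel <- selectLocusOutliers(expr, ann$symbol, "tissue01")
  expect_lt(length(intersect(sel$selected, planted)),
            length(planted))

  expect_error(simulationConfig(nTissues = 1), "nTissues")
})

test_that("generated networks wire the disease module as promised", {
  cfg <- smallConfig(seed = 9)
  ann <- generateGenome(cfg)
  planted <- cytoPrior:::plantGenes(cfg, ann)
  np <- generateNetworkAndPathways(cfg, ann, planted)
  # every planted gene touches >= 1 seed directly
  for (p in planted)
    expect_gt(seedProximity(np$network, p, np$seeds), 0)
  # the disease pathway holds seeds and planted genes
  expect_setequal(pathwayGenes(np$pathways)$disease_module,
                  union(np$seeds, planted))
  # determinism
  np2 <- generateNetworkAndPathways(cfg, ann, planted)
  expect_identical(networkEdges(np$network), networkEdges(np2$network))

  # preferential attachment with m = 1 grows a tree
  cfgTree <- smallConfig(seed = 10, attachmentM = 1, nPlanted = 0)
  annT <- generateGenome(cfgTree)
  npT <- generateNetworkAndPathways(cfgTree, annT, character())
  g <- networkGraph(npT$network)
  expect_identical(igraph::ecount(g), igraph::vcount(g) - 1)
})

test_that("cohort truth tables honour the pathogenic probability", {
  cfg <- smallConfig(seed = 13, pathogenicProb = 0)
  ann <- generateGenome(cfg)
  planted <- cytoPrior:::plantGenes(cfg, ann)
  coh <- generateCohort(cfg, ann, planted)
  expect_true(all(coh$truth$class == "benign"))

  cfg1 <- smallConfig(seed = 14, pathogenicProb = 1)
  coh1 <- generateCohort(cfg1, ann, planted)
  carriers <- unique(coh1$truth$patient_id[coh1$truth$class ==
                                             "pathogenic"])
  expect_setequal(carriers, coh1$roster)
  # every pathogenic call covers a planted gene
  patho <- coh1$truth[coh1$truth$class == "pathogenic", ]
  for (i in seq_len(nrow(patho)))
    expect_true(any(planted %in% scanGenesOracle(
      ann, patho$chrom[i], patho$start[i], patho$end[i])))
  # benign calls never do (the catalog spares planted genes)
  ben <- coh1$truth[coh1$truth$class == "benign", ]
  for (i in seq_len(min(nrow(ben), 20)))
    expect_false(any(planted %in% scanGenesOracle(
      ann, ben$chrom[i], ben$start[i], ben$end[i])))
})

test_that("identical configurations write byte-identical studies", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateStudy(smallConfig(seed = 21), dir = d1)
  simulateStudy(smallConfig(seed = 21), dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  simulateStudy(smallConfig(seed = 22), dir = d3)
  expect_false(identical(readLines(file.path(d1, "expression.tsv")),
                         readLines(file.path(d3, "expression.tsv"))))
})

test_that("written studies can be read back by the package readers", {
  d <- withr::local_tempdir()
  study <- simulateStudy(smallConfig(seed = 23), dir = d)
  expect_identical(readGeneAnnotation(file.path(d, "annotation.bed")),
                   study$annotation)
  expect_equal(exprValues(readExpressionMatrix(
    file.path(d, "expression.tsv"))),
    exprValues(study$expression), tolerance = 1e-9)
  expect_identical(
    networkEdges(readNetwork(file.path(d, "network.tsv"))),
    networkEdges(study$network))
  expect_identical(readCnvCalls(file.path(d, "cnv_calls.tsv")),
                   study$calls)
  expect_identical(pathwayGenes(readGeneSetsGmt(
    file.path(d, "pathways.gmt"))), pathwayGenes(study$pathways))
})
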