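test_that("CNV gene annotation matches a linear scan", {
  ann <- tinyAnnotation(10)
  expect_identical(annotateCnv(tinyCnv("P1", "chr2", 0, 5000), ann),
                   character())
  g1 <- makeAnnotation("chr1", 100, 200, "ONLY")
  expect_identical(annotateCnv(tinyCnv("P1", "chr1", 100, 200), g1),
                   "ONLY")
  set.seed(67)
  for (rep in 1:10) {
    qs <- sample.int(80000, 1); qe <- qs + sample.int(40000, 1)
    expect_identical(annotateCnv(tinyCnv("P", "chr1", qs, qe), ann),
                     scanGenesOracle(ann, "chr1", qs, qe))
  }
})

test_that("benign matching needs reciprocal overlap and frequency", {
  call <- tinyCnv("P1", "chr1", 1000, 2000)
  expect_false(benignMatch(call, emptyCat <- tinyCatalog(character(),
                                                         numeric(),
                                                         numeric(),
                                                         numeric())))
  same <- tinyCatalog("chr1", 1000, 2000, 0.05)
  expect_true(benignMatch(call, same))            # reciprocal = 1.0
  rare <- tinyCatalog("chr1", 1000, 2000, 0.001)
  expect_false(benignMatch(call, rare))           # frequency gate

  # reciprocal overlap arithmetic: overlap / max(lengths)
  half <- tinyCatalog("chr1", 1500, 2500, 0.5)    # overlap 500 of 1000
  expect_true(benignMatch(call, half, minReciprocalOverlap = 0.5))
  expect_false(benignMatch(call, half, minReciprocalOverlap = 0.51))
  big <- tinyCatalog("chr1", 0, 10000, 0.5)       # rec = 1000/10000
  expect_false(benignMatch(call, big))
  expect_true(benignMatch(call, big, minReciprocalOverlap = 0.1))
})

test_that("the verdict rule holds on all eight evidence combinations", {
  ann <- makeAnnotation("chr1", c(1000, 5000), c(2000, 6000),
                        c("PRIO", "OTHER"))
  commonVar <- tinyCatalog("chr1", 9000, 12000, 0.2)
  desert <- c(20000, 23000)

  cases <- list(
    # hasGenes, hasPrioritizedGene, benignMatch -> expected verdict
    list(c(1000, 2000), "PRIO", FALSE, "prioritized"),
    list(c(1000, 2000), character(), FALSE, "unranked"),
    list(c(5000, 6000), character(), FALSE, "unranked"),
    list(desert, character(), FALSE, "unranked"),
    list(c(9000, 12000), character(), TRUE, "benign"))
  # gene-containing + benign combinations need an interval with both
  annB <- makeAnnotation("chr1", c(9000, 5000), c(10000, 6000),
                         c("PRIO", "OTHER"))
  for (prio in list("PRIO", character())) {
    res <- prioritizeCnvs(tinyCnv("P1", "chr1", 9000, 12000), prio,
                          annB, commonVar)
    expect_identical(res$verdict, "benign")  # veto beats gene content
  }
  for (cs in cases) {
    res <- prioritizeCnvs(tinyCnv("P1", "chr1", cs[[1]][1], cs[[1]][2]),
                          cs[[2]], ann, commonVar)
    expect_identical(res$verdict, cs[[4]])
    expect_identical(res$benignMatch, cs[[3]])
  }

  # without the veto, gene content wins over the catalog match
  res <- prioritizeCnvs(tinyCnv("P1", "chr1", 9000, 12000), "PRIO",
                        annB, commonVar, benignVeto = FALSE)
  expect_identical(res$verdict, "prioritized")
  expect_true(res$benignMatch)
})

test_that("mismatched chromosome naming styles are a hard error", {
  ann <- makeAnnotation("21", 100, 200, "A")
  expect_error(prioritizeCnvs(tinyCnv("P1", "chr21", 100, 200), "A",
                              ann, emptyCatalogFixture()),
               "naming styles")
})

test_that("cohort summary computes yield, histogram and counts", {
  # the reference arithmetic: 181 carriers of 205 -> 88.3
  res <- data.frame(patient_id = sprintf("PT%03d", 1:181),
                    verdict = "prioritized")
  s <- summarizeCohort(res, sprintf("PT%03d", 1:205))
  expect_identical(s$yieldPercent, 88.3)
  expect_identical(s$nPatients, 205L)
  expect_identical(s$nCnvPrioritizedTotal, 181L)
  expect_identical(s$histogram$nPatients[s$histogram$count == 0], 24L)

  # empty results: zero yield, all-zero histogram bin
  empty <- data.frame(patient_id = character(), verdict = character())
  s0 <- summarizeCohort(empty, c("A", "B", "C"))
  expect_identical(s0$yieldPercent, 0)
  expect_identical(s0$histogram,
                   data.frame(count = 0L, nPatients = 3L))

  # every patient exactly two prioritized CNVs
  res2 <- data.frame(patient_id = rep(c("A", "B"), each = 2),
                     verdict = "prioritized")
  s2 <- summarizeCohort(res2, c("A", "B"))
  expect_identical(s2$yieldPercent, 100)
  expect_identical(s2$histogram,
                   data.frame(count = 2L, nPatients = 2L))

  expect_error(summarizeCohort(res2, "A"), "not on roster")
})

test_that("yield is order-invariant and monotone in prioritized CNVs", {
  set.seed(71)
  res <- data.frame(patient_id = sample(sprintf("p%d", 1:10), 25,
                                        replace = TRUE),
                    verdict = sample(c("prioritized", "benign",
                                       "unranked"), 25, replace = TRUE))
  roster <- sprintf("p%d", 1:12)
  base <- summarizeCohort(res, roster)
  shuffled <- summarizeCohort(res[sample(nrow(res)), ], roster)
  expect_identical(base$yieldPercent, shuffled$yieldPercent)
  expect_identical(base$histogram, shuffled$histogram)

  # split across "files": summaries of concatenated halves agree
  half <- summarizeCohort(rbind(res[1:10, ], res[11:25, ]), roster)
  expect_identical(base$perPatientCounts, half$perPatientCounts)

  # a new prioritized CNV for a zero patient never lowers the yield
  zeroPatients <- names(base$perPatientCounts)[base$perPatientCounts == 0]
  if (length(zeroPatients)) {
    more <- rbind(res, data.frame(patient_id = zeroPatients[1],
                                  verdict = "prioritized"))
    expect_gte(summarizeCohort(more, roster)$yieldPercent,
               base$yieldPercent)
  }
})
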