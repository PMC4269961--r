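test_that("genesInInterval handles boundaries and missing chromosomes", {
  expect_identical(genesInInterval(tinyAnnotation(0), "chr1:0-100"),
                   character())

  ann <- makeAnnotation("chr1", 100, 200, "A")
  expect_identical(genesInInterval(ann, "chr1:200-300"), character())
  expect_identical(genesInInterval(ann, "chr1:199-300"), "A")
  expect_identical(genesInInterval(ann, "chr1:0-100"), character())
  expect_identical(genesInInterval(ann, "chr1:0-101"), "A")
  expect_warning(out <- genesInInterval(ann, "chr9:0-500"), "absent")
  expect_identical(out, character())
})

test_that("genesInInterval agrees with a linear-scan oracle", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(20:60, 1)
    chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
    s0 <- sample.int(100000, n)
    ann <- makeAnnotation(chrom, s0, s0 + sample.int(5000, n),
                          sprintf("g%03d", seq_len(n)))
    qs <- sample.int(90000, 1)
    qe <- qs + sample.int(30000, 1)
    minOv <- sample(c(1, 10, 500), 1)
    expect_identical(
      genesInInterval(ann, sprintf("chr1:%d-%d", qs, qe), minOv),
      scanGenesOracle(ann, "chr1", qs, qe, minOv))
  }
})

test_that("tissue specificity z matches direct formula evaluation", {
  m <- matrix(c(7, 7, 7, 63), 1, 4,
              dimnames = list("G", paste0("t", 1:4)))
  expr <- TissueExpression(m)

  # independent evaluation: log2(x+1), median, scaled MAD with floor
  y <- log2(c(7, 7, 7, 63) + 1)
  med <- mean(sort(y)[2:3])  # median of 4 values by hand
  madScaled <- 1.4826 * mean(sort(abs(y - med))[2:3])
  expected <- (y[4] - med) / max(madScaled, 0.01)
  expect_equal(tissueSpecificityZ(expr, "G", "t4"), expected,
               tolerance = 1e-12)

  # flat gene: z exactly 0, never infinite
  flat <- TissueExpression(matrix(5, 1, 3,
                                  dimnames = list("F", paste0("t", 1:3))))
  expect_identical(tissueSpecificityZ(flat, "F", "t2"), 0)

  # below-median target gives a negative z
  m2 <- matrix(c(10, 20, 30, 2), 1, 4,
               dimnames = list("G", paste0("t", 1:4)))
  expect_lt(tissueSpecificityZ(TissueExpression(m2), "G", "t4"), 0)

  expect_error(tissueSpecificityZ(expr, "NOPE", "t1"), "not in matrix")
  expect_error(tissueSpecificityZ(expr, "G", "t9"), "not in matrix")
  one <- TissueExpression(matrix(1, 1, 1, dimnames = list("G", "t1")))
  expect_error(tissueSpecificityZ(one, "G", "t1"), "two tissues")
})

test_that("locus outlier selection finds a planted gene and nothing else", {
  genes <- sprintf("g%02d", 1:20)
  expr <- tinyExpression(genes)
  expr <- withSignal(expr, "g07", "brain", 100)  # 10x the others
  sel <- selectLocusOutliers(expr, genes, "brain")
  expect_identical(sel$selected, "g07")

  # independent fence oracle on the locus target values
  y <- log2(exprValues(expr)[, "brain"] + 1)
  fence <- quantile7Oracle(y, 0.75) +
    1.5 * (quantile7Oracle(y, 0.75) - quantile7Oracle(y, 0.25))
  expect_equal(unname(sel$fence["brain"]), unname(fence),
               tolerance = 1e-9)
  expect_true(all(sel$scores$targetLog2[sel$scores$fenceOutlier] > fence))

  # no variability anywhere: nothing selected
  flat <- tinyExpression(genes)
  expect_identical(selectLocusOutliers(flat, genes, "brain")$selected,
                   character())
})

test_that("outlier selection respects threshold limits and small loci", {
  genes <- sprintf("g%02d", 1:12)
  set.seed(7)
  m <- matrix(2^rnorm(12 * 6, 5, 1), 12, 6,
              dimnames = list(genes, paste0("t", 1:6)))
  expr <- TissueExpression(m)

  none <- selectLocusOutliers(expr, genes, "t1", zMin = Inf,
                              fenceK = Inf)
  expect_identical(none$selected, character())
  all <- selectLocusOutliers(expr, genes, "t1", zMin = -Inf)
  expect_setequal(all$selected, genes)

  # < 4 scorable genes: fence skipped with a notice, z rule still works
  expect_message(
    small <- selectLocusOutliers(expr, genes[1:3], "t1"),
    "fewer than 4")
  expect_true(all(is.na(small$fence)))

  # genes missing from the matrix are reported, never silently dropped
  expect_message(
    sel <- selectLocusOutliers(expr, c(genes, "GHOST"), "t1"),
    "unscorable")
  expect_identical(sel$unscorable, "GHOST")
})

test_that("selection is invariant to rescaling all expression values", {
  set.seed(11)
  for (rep in 1:10) {
    genes <- sprintf("g%02d", 1:15)
    m <- matrix(2^rnorm(15 * 5, 6, 1.2), 15, 5,
                dimnames = list(genes, paste0("t", 1:5)))
    m[m < 1] <- 1
    base <- selectLocusOutliers(TissueExpression(m), genes, "t1")
    for (const in c(2, 10)) {
      scaled <- selectLocusOutliers(TissueExpression(m * const), genes,
                                    "t1")
      expect_identical(scaled$selected, base$selected)
    }
  }
})

test_that("raising a selected gene's target value never de-selects it", {
  set.seed(23)
  genes <- sprintf("g%02d", 1:15)
  m <- matrix(2^rnorm(15 * 5, 6, 1), 15, 5,
              dimnames = list(genes, paste0("t", 1:5)))
  m["g03", "t1"] <- 2000
  sel <- selectLocusOutliers(TissueExpression(m), genes, "t1")
  expect_true("g03" %in% sel$selected)
  for (bump in c(1.5, 4, 50)) {
    m2 <- m; m2["g03", "t1"] <- m["g03", "t1"] * bump
    expect_true("g03" %in%
                  selectLocusOutliers(TissueExpression(m2), genes,
                                      "t1")$selected)
  }
})

test_that("a gene passing in any requested tissue is selected", {
  genes <- sprintf("g%02d", 1:10)
  expr <- tinyExpression(genes)
  expr <- withSignal(expr, "g02", "liver", 100)
  both <- selectLocusOutliers(expr, genes, c("brain", "liver"))
  expect_identical(both$selected, "g02")
  brainOnly <- selectLocusOutliers(expr, genes, "brain")
  expect_identical(brainOnly$selected, character())
})
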