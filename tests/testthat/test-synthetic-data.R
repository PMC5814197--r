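test_that("class apportionment follows the largest-remainder rule", {
  f <- c(continuous_up = 0.1, continuous_down = 0.1, null = 0.8)
  expect_equal(apportionClasses(1000, f),
               c(continuous_up = 100L, continuous_down = 100L, null = 800L))
  # 7 * (1/3, 1/3, 1/3): floors give 2+2+2, last unit to the first class
  g <- apportionClasses(7, c(a = 1/3, b = 1/3, c = 1/3))
  expect_equal(sum(g), 7L)
  expect_equal(unname(g), c(3L, 2L, 2L))
  # remainders decide, not magnitudes: 0.55/0.45 of 10 -> 6/4? no: 5.5 -> 5+1
  h <- apportionClasses(10, c(a = 0.55, b = 0.45))
  expect_equal(unname(h), c(6L, 4L))
  expect_error(apportionClasses(10, c(a = 0.6, b = 0.6)), "sum to 1")
})

test_that("the generator is deterministic and parameter-checked", {
  d <- toyDesign()
  a <- simulateExpression(d, nGenes = 40, seed = 11)
  b <- simulateExpression(d, nGenes = 40, seed = 11)
  expect_identical(SummarizedExperiment::assay(expressionData(a), "log2"),
                   SummarizedExperiment::assay(expressionData(b), "log2"))
  expect_identical(truthTable(a), truthTable(b))
  c <- simulateExpression(d, nGenes = 40, seed = 12)
  expect_false(identical(
    SummarizedExperiment::assay(expressionData(a), "log2"),
    SummarizedExperiment::assay(expressionData(c), "log2")))
  expect_error(simulateExpression(d, 40, effect = -1), "non-negative")
  expect_error(simulateExpression(d, 40, sigma = 0), "positive")
})

test_that("planted stage means are monotone and flat after the drop stage", {
  d <- makeStageDesign(c("s1", "s2", "s3", "s4"), c(30L, 30L, 30L, 30L))
  ds <- simulateExpression(d, nGenes = 200, effect = 2, sigma = 0.3,
                           seed = 3)
  mat <- SummarizedExperiment::assay(expressionData(ds), "log2")
  stage <- as.character(expressionData(ds)$stage)
  truth <- truthTable(ds)
  groupMeans <- sapply(stageLabels(d), function(s)
    rowMeans(mat[, stage == s, drop = FALSE]))
  for (i in which(truth$class == "continuous_up")) {
    dm <- diff(groupMeans[i, ])
    drop <- truth$drop_stage[i]
    # strictly increasing up to the drop transition (noise-robust margin)
    expect_true(all(dm[seq_len(drop)] > 1))
    if (drop < 3) expect_true(all(abs(dm[(drop + 1):3]) < 1))
  }
  for (i in which(truth$class == "continuous_down")) {
    dm <- diff(groupMeans[i, ])
    expect_true(all(dm[seq_len(truth$drop_stage[i])] < -1))
  }
  for (i in which(truth$class == "null"))
    expect_true(all(abs(diff(groupMeans[i, ])) < 1))
})

test_that("zero effect yields a screen indistinguishable from the null", {
  d <- toyDesign()
  ds <- simulateExpression(d, nGenes = 100, effect = 0, seed = 5)
  sel <- screenTransitions(expressionData(ds), d)
  hits <- sum(vapply(sel, function(s)
    length(upGenes(s)) + length(downGenes(s)), numeric(1)))
  expect_lte(hits, 2)  # Bonferroni at alpha 0.05: chance-level leakage only
})

test_that("annotation labelling matches its planted probabilities", {
  d <- toyDesign()
  ds <- simulateExpression(d, nGenes = 1000, seed = 21)
  truth <- truthTable(ds)

  # perfect labelling: filter recovers exactly the planted up genes
  annPerfect <- simulateAnnotations(truth, pUp = 1, pDown = 1,
                                    background = 0, seed = 2)
  got <- filterByTerms(truth$gene, annPerfect,
                       c("GO:0031012", "GO:0005615"))
  expect_setequal(got, truth$gene[truth$class == "continuous_up"])

  # stochastic labelling: counts inside binomial 99% bounds
  ann <- simulateAnnotations(truth, pUp = 0.8, pDown = 0.8,
                             background = 0.1,
                             extracellularTerms = "GO:0031012", seed = 3)
  ec <- genesWithTerm(ann, "GO:0031012")
  nUp <- sum(truth$class == "continuous_up")
  nOther <- nrow(truth) - nUp
  expected <- 0.8 * nUp + 0.1 * nOther
  sdv <- sqrt(0.8 * 0.2 * nUp + 0.1 * 0.9 * nOther)
  expect_lt(abs(length(ec) - expected), 2.58 * sdv + 1)

  badTruth <- truth; badTruth$class[1] <- "mystery"
  expect_error(simulateAnnotations(badTruth), "unknown gene class")
})

test_that("interaction generator plants recoverable cliques", {
  d <- toyDesign()
  ds <- simulateExpression(d, nGenes = 60, seed = 31)
  truth <- truthTable(ds)

  # ideal modules: disjoint cliques, no background
  net <- simulateInteractions(truth, nModules = 2, moduleSize = 4,
                              intraDensity = 1, backgroundDensity = 0,
                              seed = 1)
  g <- readInteractions(net$edges)
  expect_equal(igraph::vcount(g), 8L)
  expect_equal(igraph::ecount(g), 2L * choose(4, 2))
  comps <- igraph::components(g)
  expect_equal(comps$no, 2L)
  for (m in 1:2) {
    planted <- sort(net$truth$gene[!is.na(net$truth$module_id) &
                                     net$truth$module_id == m])
    expect_equal(sum(comps$membership[planted] ==
                       comps$membership[planted[1]]), 4L)
  }

  # empty case
  empty <- simulateInteractions(truth, nModules = 0, backgroundDensity = 0,
                                seed = 1)
  expect_equal(nrow(empty$edges), 0L)

  expect_error(simulateInteractions(truth, nModules = 10, moduleSize = 10,
                                    seed = 1), "not enough")
  expect_error(simulateInteractions(truth, nModules = 1, moduleSize = 2,
                                    seed = 1), "at least 3")
})

test_that("emitted files round-trip through the package readers", {
  d <- toyDesign()
  ds <- simulateDataset(d, nGenes = 50, seed = 9,
                        interArgs = list(nModules = 1, moduleSize = 4,
                                         backgroundDensity = 0.05))
  out <- withr::local_tempdir()
  p <- writeDataset(ds, out)

  se2 <- readExpression(p[["expression"]], p[["samples"]], d)
  expect_equal(SummarizedExperiment::assay(se2, "log2"),
               SummarizedExperiment::assay(expressionData(ds), "log2"),
               tolerance = 1e-12)
  expect_equal(as.character(se2$stage),
               as.character(expressionData(ds)$stage))

  tr2 <- readTruth(p[["truth"]])
  expect_equal(tr2, truthTable(ds))

  ann2 <- readAnnotationTables(p[["annotation"]], p[["terms"]])
  expect_equal(annotationMapping(ann2), annotationMapping(geneAnnotation(ds)))
  expect_equal(termInfo(ann2), termInfo(geneAnnotation(ds)))

  edges2 <- read.table(p[["interactions"]], header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
  expect_equal(edges2, interactionTable(ds))

  # GMT round-trip
  sets <- list(alpha = c("g1", "g2", "g3"), beta = "g9")
  gmt <- file.path(out, "sets.gmt")
  writeGMT(sets, gmt)
  expect_equal(readGMT(gmt), sets)
})
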