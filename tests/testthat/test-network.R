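edgeRow <- function(a, b, experimental = 500L, combined = 500L) {
  data.frame(protein1 = a, protein2 = b, neighborhood = 0L,
             coexpression = 0L, experimental = experimental,
             combined_score = combined, stringsAsFactors = FALSE)
}

test_that("graph construction filters, deduplicates and drops self-loops", {
  # channel score of zero: edge rejected under the experimental-only filter
  g <- readInteractions(edgeRow("a", "b", experimental = 0L))
  expect_equal(igraph::vcount(g), 0L)

  # both orientations plus a self-loop collapse to one undirected edge
  tab <- rbind(edgeRow("a", "b", 300L), edgeRow("b", "a", 700L),
               edgeRow("c", "c", 900L))
  g <- readInteractions(tab)
  expect_equal(igraph::ecount(g), 1L)
  expect_equal(sort(igraph::V(g)$name), c("a", "b"))
  expect_equal(igraph::E(g)$experimental, 700L)  # max score kept

  expect_error(readInteractions(tab[, -4], channel = "coexpression"),
               "missing required column")

  # generator oracle: node and edge counts match the planted truth
  truth <- data.frame(gene = sprintf("g%02d", 1:30),
                      class = rep(c("continuous_up", "null"), c(10, 20)),
                      drop_stage = NA_integer_, module_id = NA_integer_,
                      stringsAsFactors = FALSE)
  net <- simulateInteractions(truth, nModules = 2, moduleSize = 5,
                              intraDensity = 1, backgroundDensity = 0,
                              seed = 4)
  g <- readInteractions(net$edges)
  expect_equal(igraph::vcount(g), 10L)
  expect_equal(igraph::ecount(g), 2L * choose(5, 2))
})

test_that("induced subgraphs match a brute-force pair scan", {
  set.seed(12)
  adj <- randomAdj(40, 0.15)
  g <- readInteractions(adjToEdgeTable(adj))
  expect_equal(igraph::induced_subgraph(g, igraph::V(g)) |> igraph::ecount(),
               sum(adj) / 2)

  keep <- sample(rownames(adj), 15)
  sub <- induceGraph(g, keep)
  inKeep <- rownames(adj) %in% intersect(keep, igraph::V(g)$name)
  expect_equal(igraph::ecount(sub), sum(adj[inKeep, inKeep]) / 2)

  expect_equal(igraph::vcount(induceGraph(g, character())), 0L)
  full <- induceGraph(g, igraph::V(g)$name)
  expect_true(igraph::isomorphic(full, g))
})

test_that("term-based node removal deletes nodes and incident edges", {
  # toy: triangle a-b-c plus pendant d on a; remove term hits {b, d}
  tab <- rbind(edgeRow("a", "b"), edgeRow("b", "c"), edgeRow("a", "c"),
               edgeRow("a", "d"))
  g <- readInteractions(tab)
  ann <- new("GeneAnnotation",
             mapping = data.frame(gene = c("b", "d"), term = "GO:RESP",
                                  stringsAsFactors = FALSE),
             terms = data.frame(term = "GO:RESP", name = "respiratory chain",
                                namespace = "CC", stringsAsFactors = FALSE))
  g2 <- removeTermNodes(g, ann, "GO:RESP")
  expect_setequal(igraph::V(g2)$name, c("a", "c"))
  expect_equal(unname(igraph::degree(g2)[c("a", "c")]), c(1, 1))
  expect_error(removeTermNodes(g, ann, "GO:NOPE"), "unknown term")

  # no node carries the term: identity
  annNone <- new("GeneAnnotation",
                 mapping = data.frame(gene = "zz", term = "GO:RESP",
                                      stringsAsFactors = FALSE),
                 terms = ann@terms)
  expect_true(igraph::isomorphic(removeTermNodes(g, annNone, "GO:RESP"), g))
})

test_that("vertex weights follow the closed-neighborhood core density", {
  # (k+1)-clique: every weight k
  clique <- matrix(TRUE, 5, 5); diag(clique) <- FALSE
  dimnames(clique) <- list(letters[1:5], letters[1:5])
  w <- mcodeWeights(adjToIgraph(clique))
  expect_equal(unname(w), rep(4, 5))

  # star with 4 leaves: highest core is the 1-core (the whole star),
  # density 2*4/(5*4), so every weight is 2/5
  star <- matrix(FALSE, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- TRUE
  dimnames(star) <- list(letters[1:5], letters[1:5])
  w <- mcodeWeights(adjToIgraph(star))
  expect_equal(unname(w[1]), 2 / 5)
  expect_equal(w, oracleMcodeWeights(star))

  # isolated vertex weighs zero
  iso <- matrix(FALSE, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(mcodeWeights(adjToIgraph(iso))), c(0, 0))

  # random graphs against the brute-force oracle
  set.seed(21)
  for (i in 1:30) {
    adj <- randomAdj(sample(5:60, 1), runif(1, 0.05, 0.4))
    g <- adjToIgraph(adj)
    expect_equal(mcodeWeights(g), oracleMcodeWeights(adj),
                 tolerance = 1e-12)
  }
})

test_that("module detection separates ideal complexes and rejects trees", {
  # two disjoint 5-cliques: two modules, each scoring 5
  adj <- matrix(FALSE, 10, 10)
  adj[1:5, 1:5] <- TRUE; adj[6:10, 6:10] <- TRUE; diag(adj) <- FALSE
  dimnames(adj) <- list(sprintf("n%02d", 1:10), sprintf("n%02d", 1:10))
  mods <- mcodeModules(adjToIgraph(adj))
  expect_length(mods, 2L)
  expect_equal(vapply(mods, moduleScore, numeric(1)), c(5, 5))
  expect_setequal(moduleMembers(mods[[1]]), sprintf("n%02d", 1:5))
  expect_setequal(moduleMembers(mods[[2]]), sprintf("n%02d", 6:10))
  expect_length(intersect(moduleMembers(mods[[1]]),
                          moduleMembers(mods[[2]])), 0L)

  # a pure tree has no 2-core: no modules at all
  tree <- matrix(FALSE, 7, 7)
  for (i in 2:7) tree[i %/% 2, i] <- tree[i, i %/% 2] <- TRUE
  dimnames(tree) <- list(letters[1:7], letters[1:7])
  expect_length(mcodeModules(adjToIgraph(tree)), 0L)

  expect_error(mcodeModules(adjToIgraph(tree), vwp = 1), "vwp")
})

test_that("a planted clique in sparse background is the top module", {
  d <- makeStageDesign(c("A", "B"), c(3L, 3L))
  ds <- simulateExpression(d, nGenes = 500, seed = 41)
  net <- simulateInteractions(truthTable(ds), nModules = 1, moduleSize = 6,
                              intraDensity = 1, backgroundDensity = 0.01,
                              seed = 42)
  g <- readInteractions(net$edges)
  mods <- mcodeModules(g)
  planted <- net$truth$gene[!is.na(net$truth$module_id)]
  expect_gte(jaccard(moduleMembers(mods[[1]]), planted), 0.8)
  # score never exceeds size; members pairwise disjoint
  for (m in mods)
    expect_lte(moduleScore(m), length(moduleMembers(m)))
  all <- unlist(lapply(mods, moduleMembers))
  expect_equal(anyDuplicated(all), 0L)
})

test_that("hub extraction is a degree filter with monotone range", {
  # complete K5 at lo = hi = 4 keeps everything
  k5 <- matrix(TRUE, 5, 5); diag(k5) <- FALSE
  dimnames(k5) <- list(letters[1:5], letters[1:5])
  hub <- hubSubnetwork(adjToIgraph(k5), 4, 4)
  expect_setequal(hubGenes(hub), letters[1:5])

  set.seed(33)
  adj <- randomAdj(60, 0.1)
  g <- adjToIgraph(adj)
  deg <- rowSums(adj)
  hub <- hubSubnetwork(g, 3, 8)
  expect_setequal(hubGenes(hub), names(deg)[deg >= 3 & deg <= 8])
  expect_equal(hubDegrees(hub)[hubGenes(hub)],
               setNames(as.integer(deg[hubGenes(hub)]), hubGenes(hub)))
  # raising lo / lowering hi never adds hubs
  expect_true(all(hubGenes(hubSubnetwork(g, 4, 8)) %in% hubGenes(hub)))
  expect_true(all(hubGenes(hubSubnetwork(g, 3, 7)) %in% hubGenes(hub)))
  # lo = 0, hi = Inf keeps all nodes
  expect_setequal(hubGenes(hubSubnetwork(g, 0)), rownames(adj))
  expect_error(hubSubnetwork(g, 5, 2), "invalid degree range")
})

test_that("the key chain maximises total parent degree over simple paths", {
  # path graph a-b-c: the chain is the whole path from the smaller endpoint
  tab <- rbind(edgeRow("a", "b"), edgeRow("b", "c"))
  g <- readInteractions(tab)
  hub <- hubSubnetwork(g, 0)
  expect_equal(keyChain(hub), c("a", "b", "c"))

  # a hub band catching a single node yields a length-1 chain
  tri <- rbind(edgeRow("a", "b"), edgeRow("b", "c"), edgeRow("a", "c"),
               edgeRow("a", "d"))
  one <- hubSubnetwork(readInteractions(tri), 1, 1)
  expect_equal(keyChain(one), "d")
  expect_error(keyChain(hubSubnetwork(readInteractions(tri), 9, 9)),
               "empty")

  # random graphs against exhaustive enumeration
  set.seed(55)
  for (i in 1:10) {
    adj <- randomAdj(sample(5:10, 1), runif(1, 0.2, 0.5))
    g <- adjToIgraph(adj)
    hub <- hubSubnetwork(g, 0)
    got <- keyChain(hub)
    best <- oracleBestPath(adj, hubDegrees(hub))
    expect_equal(sum(hubDegrees(hub)[got]), best$sum)
    expect_equal(got, best$path)
  }

  # the guard refuses oversized hub sets
  big <- adjToIgraph(randomAdj(30, 0.3))
  expect_error(keyChain(hubSubnetwork(big, 0)), "guard")
})

test_that("stage annotation maps deviation sets onto node attributes", {
  C <- list(c("a", "b", "c", "d"), c("b", "c"), "c")
  tr <- new("TrajectoryResult", direction = "up", continuing = C,
            deviated = partitionDeviated(C),
            stageLabels = c("I", "II", "III"))
  tab <- rbind(edgeRow("a", "b"), edgeRow("b", "c"), edgeRow("c", "z"))
  g <- annotateStage(readInteractions(tab), tr)
  attr <- setNames(igraph::V(g)$stage, igraph::V(g)$name)
  expect_equal(unname(attr["a"]), "I")        # left after transition 1
  expect_equal(unname(attr["b"]), "II")       # left after transition 2
  expect_equal(unname(attr["c"]), "persistent")
  expect_equal(unname(attr["z"]), "unclassified")
  dirs <- setNames(igraph::V(g)$direction, igraph::V(g)$name)
  expect_equal(unname(dirs[c("a", "c", "z")]), c("up", "up", "none"))
})

test_that("attributed graphs survive a GraphML round-trip", {
  d <- makeStageDesign(c("A", "B"), c(3L, 3L))
  ds <- simulateDataset(d, nGenes = 80, seed = 51,
                        interArgs = list(nModules = 1, moduleSize = 5,
                                         backgroundDensity = 0.05))
  g <- readInteractions(interactionTable(ds))
  path <- withr::local_tempfile(fileext = ".graphml")
  writeGraphML(g, path)
  g2 <- readGraphML(path)
  expect_true(igraph::isomorphic(g, g2))
  expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
  expect_equal(sort(igraph::E(g2)$experimental),
               sort(igraph::E(g)$experimental))
})
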