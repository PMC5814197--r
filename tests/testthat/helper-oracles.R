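# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph, where the implementation uses it):
# plain matrix peeling, exhaustive enumeration, brute-force scans.

# --- graphs as logical adjacency matrices -----------------------------------

# random named undirected graph as an adjacency matrix
randomAdj <- function(n, p) {
  adj <- matrix(FALSE, n, n)
  ut <- upper.tri(adj)
  adj[ut] <- runif(sum(ut)) < p
  adj <- adj | t(adj)
  dimnames(adj) <- list(sprintf("v%03d", 1:n), sprintf("v%03d", 1:n))
  adj
}

adjToEdgeTable <- function(adj, score = 800L) {
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  data.frame(protein1 = rownames(adj)[idx[, 1]],
             protein2 = colnames(adj)[idx[, 2]],
             neighborhood = 0L, coexpression = 0L,
             experimental = score, combined_score = score,
             stringsAsFactors = FALSE)
}

adjToIgraph <- function(adj) {
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::set_vertex_attr(g, "name", value = rownames(adj))
}

# core numbers by classic minimum-degree peeling (no igraph)
oracleCoreNumbers <- function(adj) {
  n <- nrow(adj)
  core <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0L
  while (any(alive)) {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    deg[!alive] <- NA
    v <- which.min(deg)
    k <- max(k, as.integer(deg[v]))
    core[v] <- k
    alive[v] <- FALSE
  }
  setNames(core, rownames(adj))
}

# brute-force MCODE vertex weight: explicit core decomposition of every
# closed neighborhood
oracleMcodeWeights <- function(adj) {
  n <- nrow(adj)
  w <- setNames(numeric(n), rownames(adj))
  for (v in seq_len(n)) {
    nb <- c(v, which(adj[v, ]))
    if (length(nb) < 2L) next
    sub <- adj[nb, nb, drop = FALSE]
    core <- oracleCoreNumbers(sub)
    kmax <- max(core)
    if (kmax == 0L) next
    keep <- which(core >= kmax)
    csub <- sub[keep, keep, drop = FALSE]
    nv <- length(keep)
    ne <- sum(csub) / 2
    dens <- if (nv < 2L) 0 else 2 * ne / (nv * (nv - 1))
    w[v] <- kmax * dens
  }
  w
}

# exhaustive best simple path by total node score: plain DFS, no pruning.
# Tie rules: higher sum, then longer path, then lexicographically smaller.
oracleBestPath <- function(adj, score) {
  vs <- rownames(adj)
  best <- list(sum = -Inf, path = character())
  lexLess <- function(a, b) {
    n <- min(length(a), length(b))
    for (i in seq_len(n)) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
    length(a) < length(b)
  }
  walk <- function(path, s) {
    if (s > best$sum ||
        (s == best$sum && length(path) > length(best$path)) ||
        (s == best$sum && length(path) == length(best$path) &&
           lexLess(path, best$path)))
      best <<- list(sum = s, path = path)
    for (u in vs[adj[path[length(path)], ]])
      if (!(u %in% path)) walk(c(path, u), s + score[[u]])
  }
  for (v in vs) walk(v, score[[v]])
  best
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
oracleHypergeomTail <- function(N, K, n, k) {
  draws <- combn(N, n)
  special <- seq_len(K)        # first K elements carry the term
  hits <- colSums(matrix(draws %in% special, nrow = n))
  mean(hits >= k)
}

# hypergeometric PMF from binomial coefficients only
oracleHyperPMF <- function(N, K, n) {
  i <- max(0, n + K - N):min(n, K)
  setNames(choose(K, i) * choose(N - K, n - i) / choose(N, n), i)
}

# per-gene brute-force trajectory scan: first transition at which the gene
# leaves the DE set series
oracleContinuing <- function(sets) {
  lapply(seq_along(sets), function(k) {
    genes <- unique(unlist(sets))
    sort(genes[vapply(genes, function(g)
      all(vapply(sets[seq_len(k)], function(s) g %in% s, logical(1))),
      logical(1))])
  })
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# small fixed toy design used by several tests
toyDesign <- function() makeStageDesign(c("A", "B", "C"), c(4L, 4L, 4L))
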