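#' Build an interaction graph from a STRING-dialect edge table
#'
#' Reads a tab-separated edge table with columns `protein1`, `protein2`,
#' per-channel integer scores (STRING 0-1000 convention) and
#' `combined_score`, keeps only edges whose chosen evidence channel reaches
#' `minScore` (the default — `experimental >= 1` — retains experimentally
#' verified links only), drops self-loops, and collapses symmetric duplicate
#' rows into single undirected edges (keeping the maximum score seen).
#'
#' @param edges a file path or a data.frame
#' @param channel evidence channel column to filter on
#' @param minScore minimum channel score for an edge to be retained
#' @return undirected igraph; edges carry the channel score and
#'   `combined_score` as attributes
#' @export
readInteractions <- function(edges, channel = "experimental",
                             minScore = 1L) {
  if (is.character(edges))
    edges <- read.table(edges, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", channel, "combined_score")
  miss <- setdiff(need, names(edges))
  if (length(miss))
    stop("edge table is missing required column(s): ",
         paste(miss, collapse = ", "))
  keep <- edges[[channel]] >= minScore & edges$protein1 != edges$protein2
  edges <- edges[keep, , drop = FALSE]
  if (!nrow(edges))
    return(igraph::make_empty_graph(0, directed = FALSE))
  # canonical orientation, then collapse duplicates keeping the max scores
  a <- pmin(edges$protein1, edges$protein2)
  b <- pmax(edges$protein1, edges$protein2)
  key <- paste(a, b, sep = "\r")
  o <- order(key, -edges[[channel]])
  first <- !duplicated(key[o])
  sel <- o[first]
  df <- data.frame(from = a[sel], to = b[sel], stringsAsFactors = FALSE)
  df[[channel]] <- edges[[channel]][sel]
  df$combined_score <- edges$combined_score[sel]
  igraph::graph_from_data_frame(df, directed = FALSE)
}

#' Induce a subgraph on a gene set
#'
#' @param graph igraph
#' @param genes character vector; the subgraph is taken on
#'   `genes` intersected with the graph's nodes, with all edges among them
#' @return igraph
#' @export
induceGraph <- function(graph, genes) {
  igraph::induced_subgraph(graph,
                           intersect(igraph::V(graph)$name, genes))
}

#' Remove all nodes annotated with a term
#'
#' Generalises the exclusion of a functional group from a network (e.g.
#' cancelling out respiratory-chain nodes from a mitochondrial interaction
#' network before module analysis): deletes every node carrying the term,
#' together with its incident edges.
#'
#' @param graph igraph
#' @param annotation a [GeneAnnotation-class]
#' @param term a single term id known to the annotation
#' @return igraph without the term's nodes
#' @export
removeTermNodes <- function(graph, annotation, term) {
  drop <- intersect(igraph::V(graph)$name, genesWithTerm(annotation, term))
  igraph::delete_vertices(graph, drop)
}

.simpleDensity <- function(nv, ne) {
  if (nv < 2L) 0 else 2 * ne / (nv * (nv - 1))
}

#' MCODE-style vertex weights
#'
#' Weights every vertex by the local density of its neighborhood: take the
#' closed neighborhood of v (v plus its neighbors), find the highest k-core
#' of that subgraph, and set \eqn{weight(v) = k_{max} \times density} of that
#' core, with simple-graph density 2E/(V(V-1)). Isolated vertices weigh 0.
#' In a (k+1)-clique every vertex weighs k.
#'
#' @param graph igraph with named vertices
#' @return named numeric vector of weights
#' @seealso [mcodeModules()]
#' @export
mcodeWeights <- function(graph) {
  vs <- igraph::V(graph)$name
  w <- setNames(numeric(length(vs)), vs)
  deg <- igraph::degree(graph)
  for (i in seq_along(vs)) {
    if (deg[[i]] == 0L) next
    nb <- igraph::neighbors(graph, vs[i])
    sub <- igraph::induced_subgraph(graph, c(vs[i], nb$name))
    core <- igraph::coreness(sub)
    kmax <- max(core)
    if (kmax == 0L) next
    keep <- names(core)[core >= kmax]
    csub <- igraph::induced_subgraph(sub, keep)
    w[i] <- kmax * .simpleDensity(igraph::vcount(csub),
                                  igraph::ecount(csub))
  }
  w
}

#' MCODE-style molecular complex detection
#'
#' Re-implementation of the molecular-complex detection procedure used by
#' the Cytoscape MCODE plug-in, with the plug-in's published defaults:
#' vertices are weighted by [mcodeWeights()] and visited in decreasing weight
#' order; from each unvisited seed a complex is grown by breadth-first
#' inclusion of reachable neighbors whose weight is at least
#' `seedWeight * (1 - vwp)`; each vertex joins at most one complex.
#' Complexes whose induced subgraph lacks a 2-core are discarded; with
#' `haircut` (default on) degree-1 members are stripped iteratively; with
#' `fluff` (default off) outside neighbors whose closed-neighborhood density
#' exceeds `fluffThreshold` are added (restricted to unassigned vertices so
#' complexes stay pairwise disjoint). Complexes are scored
#' `density * size` and ranked by score, ties broken by size then by
#' lexicographically smallest seed.
#'
#' @param graph igraph with named vertices
#' @param vwp vertex weight percentage in `[0, 1)`; larger values grow looser
#'   complexes
#' @param haircut strip degree-1 members iteratively
#' @param fluff add dense outside neighbors
#' @param fluffThreshold closed-neighborhood density cutoff for fluff
#' @return list of [NetworkModule-class], ranked best first
#' @export
mcodeModules <- function(graph, vwp = 0.2, haircut = TRUE, fluff = FALSE,
                         fluffThreshold = 0.2) {
  if (vwp < 0 || vwp >= 1) stop("vwp must lie in [0, 1)")
  vs <- igraph::V(graph)$name
  if (!length(vs)) return(list())
  w <- mcodeWeights(graph)
  ord <- vs[order(-w[vs], vs)]
  assigned <- setNames(logical(length(vs)), vs)
  raw <- list()
  for (seed in ord) {
    if (assigned[[seed]]) next
    thr <- w[[seed]] * (1 - vwp)
    members <- seed
    assigned[[seed]] <- TRUE
    queue <- seed
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      for (u in igraph::neighbors(graph, v)$name) {
        if (!assigned[[u]] && w[[u]] >= thr) {
          assigned[[u]] <- TRUE
          members <- c(members, u)
          queue <- c(queue, u)
        }
      }
    }
    raw[[length(raw) + 1L]] <- list(seed = seed, members = members)
  }
  modules <- list()
  for (cand in raw) {
    members <- cand$members
    sub <- igraph::induced_subgraph(graph, members)
    if (!length(members) || max(igraph::coreness(sub)) < 2L) next
    if (haircut) {
      repeat {
        d <- igraph::degree(sub)
        drop <- names(d)[d <= 1L]
        if (!length(drop)) break
        sub <- igraph::delete_vertices(sub, drop)
      }
      members <- igraph::V(sub)$name
      if (!length(members)) next
    }
    if (fluff) {
      outside <- setdiff(unique(unlist(lapply(members, function(v)
        igraph::neighbors(graph, v)$name))), members)
      outside <- outside[!assigned[outside]]
      add <- character()
      for (u in outside) {
        nb <- c(u, igraph::neighbors(graph, u)$name)
        s <- igraph::induced_subgraph(graph, nb)
        if (.simpleDensity(igraph::vcount(s), igraph::ecount(s)) >
            fluffThreshold) add <- c(add, u)
      }
      if (length(add)) {
        assigned[add] <- TRUE
        members <- c(members, add)
        sub <- igraph::induced_subgraph(graph, members)
      }
    }
    dens <- .simpleDensity(igraph::vcount(sub), igraph::ecount(sub))
    seed <- if (cand$seed %in% members) cand$seed else sort(members)[1L]
    modules[[length(modules) + 1L]] <-
      new("NetworkModule", members = sort(members), seed = seed,
          density = dens, score = dens * length(members))
  }
  if (!length(modules)) return(list())
  score <- vapply(modules, function(m) m@score, numeric(1))
  size <- vapply(modules, function(m) length(m@members), numeric(1))
  seedId <- vapply(modules, function(m) m@seed, character(1))
  modules[order(-score, -size, seedId)]
}

#' @rdname moduleMembers
#' @export
setMethod("moduleMembers", "NetworkModule", function(x) x@members)

#' @rdname moduleScore
#' @export
setMethod("moduleScore", "NetworkModule", function(x) x@score)

#' @rdname moduleDensity
#' @export
setMethod("moduleDensity", "NetworkModule", function(x) x@density)

#' @rdname moduleSeed
#' @export
setMethod("moduleSeed", "NetworkModule", function(x) x@seed)

setMethod("show", "NetworkModule", function(object) {
  cat(sprintf("Module (seed %s): %d members, density %.3f, score %.3f\n",
              object@seed, length(object@members), object@density,
              object@score))
})

#' Summarise a ranked module list as a table
#'
#' @param modules list of [NetworkModule-class] from [mcodeModules()]
#' @return data.frame with columns `rank`, `score`, `size`, `density`,
#'   `seed`, `members` (comma-separated)
#' @export
moduleTable <- function(modules) {
  if (!length(modules))
    return(data.frame(rank = integer(), score = numeric(),
                      size = integer(), density = numeric(),
                      seed = character(), members = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    rank = seq_along(modules),
    score = vapply(modules, moduleScore, numeric(1)),
    size = vapply(modules, function(m) length(moduleMembers(m)),
                  integer(1)),
    density = vapply(modules, moduleDensity, numeric(1)),
    seed = vapply(modules, moduleSeed, character(1)),
    members = vapply(modules, function(m)
      paste(moduleMembers(m), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}

#' Degree-ranged hub subnetwork
#'
#' Extracts the nodes whose degree in the parent graph lies inside
#' `[lo, hi]` — the high-connectivity "hub" band used to keep a signal
#' network readable — together with the subgraph they induce and their
#' parent-graph degrees.
#'
#' @param graph igraph with named vertices
#' @param lo,hi inclusive degree bounds, `0 <= lo <= hi`
#' @return a [HubNetwork-class]
#' @export
hubSubnetwork <- function(graph, lo, hi = Inf) {
  if (lo < 0 || lo > hi) stop("invalid degree range: need 0 <= lo <= hi")
  deg <- igraph::degree(graph)
  hubs <- names(deg)[deg >= lo & deg <= hi]
  new("HubNetwork", graph = induceGraph(graph, hubs),
      parentDegree = setNames(as.integer(deg[hubs]), hubs),
      lo = lo, hi = hi)
}

#' @rdname hubGenes
#' @export
setMethod("hubGenes", "HubNetwork",
          function(x) sort(names(x@parentDegree)))

#' @rdname hubGraph
#' @export
setMethod("hubGraph", "HubNetwork", function(x) x@graph)

#' @rdname hubDegrees
#' @export
setMethod("hubDegrees", "HubNetwork", function(x) x@parentDegree)

setMethod("show", "HubNetwork", function(object) {
  cat(sprintf("HubNetwork: %d hubs (parent degree in [%g, %g]), %d edges\n",
              length(object@parentDegree), object@lo, object@hi,
              igraph::ecount(object@graph)))
})

# lexicographic comparison of two node sequences; TRUE if a < b
.pathLess <- function(a, b) {
  n <- min(length(a), length(b))
  for (i in seq_len(n)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Extract the key signal chain of a hub subnetwork
#'
#' A deterministic stand-in for reading a signal-transmission route off a
#' hierarchical network layout: the simple path in the hub-induced subgraph
#' that maximises the sum of the parent-graph degrees of its nodes.
#' Ties are broken in favour of the longer path, then the lexicographically
#' smallest node sequence. The search is exhaustive with branch-and-bound
#' and is guarded to at most 25 hub nodes.
#'
#' @param hub a [HubNetwork-class] with a non-empty subgraph
#' @return ordered character vector of node ids (the chain)
#' @export
keyChain <- function(hub) {
  g <- hubGraph(hub)
  vs <- igraph::V(g)$name
  if (!length(vs)) stop("hub subgraph is empty")
  if (length(vs) > 25L)
    stop(length(vs), " hub nodes exceed the chain-search guard of 25; ",
         "tighten the degree range")
  deg <- hubDegrees(hub)
  adj <- lapply(setNames(vs, vs), function(v)
    sort(igraph::neighbors(g, v)$name))
  best <- list(sum = -Inf, path = character())
  totalRemaining <- function(visited)
    sum(deg[setdiff(vs, visited)])
  consider <- function(path, s) {
    if (s > best$sum ||
        (s == best$sum && length(path) > length(best$path)) ||
        (s == best$sum && length(path) == length(best$path) &&
           .pathLess(path, best$path)))
      best <<- list(sum = s, path = path)
  }
  recurse <- function(path, s) {
    consider(path, s)
    tip <- path[length(path)]
    if (s + totalRemaining(path) < best$sum) return()
    for (u in adj[[tip]]) {
      if (!(u %in% path)) recurse(c(path, u), s + deg[[u]])
    }
  }
  for (v in sort(vs)) recurse(v, deg[[v]])
  best$path
}

#' Annotate graph nodes with their deviation stage
#'
#' Marks every node of an interaction graph with the stage at which it
#' deviates from the trajectory (the earlier stage of the deviation
#' transition), `"persistent"` for genes continuing through the whole
#' series, and `"unclassified"` for nodes absent from the trajectory;
#' a `direction` attribute is set alongside. Calling the function again with
#' the opposite-direction trajectory fills in further nodes without
#' disturbing ones already classified.
#'
#' @param graph igraph with named vertices
#' @param trajectory a [TrajectoryResult-class]
#' @return igraph with vertex attributes `stage` and `direction`
#' @export
annotateStage <- function(graph, trajectory) {
  vs <- igraph::V(graph)$name
  stage <- igraph::vertex_attr(graph, "stage")
  if (is.null(stage)) stage <- rep("unclassified", length(vs))
  dirAttr <- igraph::vertex_attr(graph, "direction")
  if (is.null(dirAttr)) dirAttr <- rep("none", length(vs))
  D <- deviatedSets(trajectory)
  labels <- names(D)
  for (k in seq_along(D)) {
    hit <- vs %in% D[[k]]
    stage[hit] <- labels[k]
    dirAttr[hit] <- trajectoryDirection(trajectory)
  }
  C <- continuingSets(trajectory)
  persistent <- vs %in% C[[length(C)]]
  stage[persistent] <- "persistent"
  dirAttr[persistent] <- trajectoryDirection(trajectory)
  graph <- igraph::set_vertex_attr(graph, "stage", value = stage)
  igraph::set_vertex_attr(graph, "direction", value = dirAttr)
}

#' Write / read an attributed graph as GraphML
#'
#' @param graph igraph
#' @param path file path
#' @export
writeGraphML <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname writeGraphML
#' @export
readGraphML <- function(path) {
  igraph::read_graph(path, format = "graphml")
}
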