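#' Cumulative intersection of per-transition DE sets
#'
#' The screen's core set operation: given the direction-matched DE sets
#' \eqn{S_1, \dots, S_K} of the ordered transitions, the continuing set at
#' stage k is \eqn{C_k = \bigcap_{j=1}^{k} S_j} — the genes significantly
#' regulated in the same direction in every comparison up to and including
#' transition k. \eqn{C_1 = S_1} and the series is monotone non-increasing.
#'
#' @param sets list of character vectors, ordered by the design's transition
#'   sequence
#' @return list of sorted character vectors \eqn{C_1, \dots, C_K}
#' @examples
#' cumulativeContinuing(list(c("a", "b", "c"), c("b", "c"), "c"))
#' @export
cumulativeContinuing <- function(sets) {
  if (!length(sets)) stop("empty transition list")
  out <- vector("list", length(sets))
  cur <- sort(unique(as.character(sets[[1L]])))
  out[[1L]] <- cur
  for (k in seq_along(sets)[-1L]) {
    cur <- cur[cur %in% sets[[k]]]
    out[[k]] <- cur
  }
  out
}

#' Partition continuing sets into deviated sets
#'
#' Deviated genes at the transition from stage k to stage k+1 are the
#' continuing genes at stage k that fail to remain continuing:
#' \eqn{D_k = C_k \setminus C_{k+1}}. The disjoint-union identity
#' \eqn{|C_k| = |C_{k+1}| + |D_k|} holds exactly. Deviated sets are attached
#' to the earlier stage of their transition.
#'
#' @param continuing list of monotone non-increasing (nested) gene sets
#' @return list of sorted character vectors \eqn{D_1, \dots, D_{K-1}}
#' @export
partitionDeviated <- function(continuing) {
  K <- length(continuing)
  if (K < 1L) stop("empty continuing list")
  if (K == 1L) return(list())
  out <- vector("list", K - 1L)
  for (k in seq_len(K - 1L)) {
    Ck <- continuing[[k]]; Ck1 <- continuing[[k + 1L]]
    if (!all(Ck1 %in% Ck))
      stop("invariant violation: continuing sets are not nested at index ", k)
    out[[k]] <- sort(setdiff(Ck, Ck1))
  }
  out
}

#' Build a trajectory result from per-transition DE selections
#'
#' Runs [cumulativeContinuing()] on the direction-matched gene sets of an
#' ordered list of [DESelection-class] objects (or plain character vectors)
#' and partitions the deviated sets.
#'
#' @param selections ordered list of [DESelection-class] or character vectors
#' @param direction `"up"` or `"down"`
#' @param stageLabels labels of the K stages the continuing sets are indexed
#'   by (the later stage of each transition); defaults to `"stage1"..`
#' @return a [TrajectoryResult-class]
#' @export
makeTrajectory <- function(selections, direction = c("up", "down"),
                           stageLabels = NULL) {
  direction <- match.arg(direction)
  sets <- lapply(selections, function(s) {
    if (is(s, "DESelection")) {
      if (direction == "up") upGenes(s) else downGenes(s)
    } else as.character(s)
  })
  C <- cumulativeContinuing(sets)
  D <- partitionDeviated(C)
  if (is.null(stageLabels))
    stageLabels <- paste0("stage", seq_along(C))
  new("TrajectoryResult", direction = direction, continuing = C,
      deviated = D, stageLabels = as.character(stageLabels))
}

#' Restrict a trajectory to genes in a compartment
#'
#' Filters every continuing set by membership in the given cellular-component
#' terms and re-partitions the deviated sets. Filtering a nested family by a
#' fixed gene set preserves nesting, so the result is a valid trajectory.
#'
#' @param trajectory a [TrajectoryResult-class]
#' @param annotation a [GeneAnnotation-class]
#' @param terms CC term ids defining the compartment (union semantics)
#' @return a [TrajectoryResult-class] over the compartment genes only
#' @export
filterTrajectory <- function(trajectory, annotation, terms) {
  keep <- genesWithTerm(annotation, terms)
  C <- lapply(continuingSets(trajectory), function(s) sort(intersect(s, keep)))
  new("TrajectoryResult", direction = trajectoryDirection(trajectory),
      continuing = C, deviated = partitionDeviated(C),
      stageLabels = trajectory@stageLabels)
}

#' @rdname trajectoryDirection
#' @export
setMethod("trajectoryDirection", "TrajectoryResult", function(x) x@direction)

#' @rdname continuingSets
#' @export
setMethod("continuingSets", "TrajectoryResult", function(x) {
  setNames(x@continuing, x@stageLabels)
})

#' @rdname deviatedSets
#' @export
setMethod("deviatedSets", "TrajectoryResult", function(x) {
  K <- length(x@continuing)
  setNames(x@deviated, x@stageLabels[seq_len(K - 1L)])
})

#' @rdname countTable
#' @export
setMethod("countTable", "TrajectoryResult", function(x) {
  K <- length(x@continuing)
  nC <- lengths(x@continuing)
  nD <- c(lengths(x@deviated), NA_integer_)
  for (k in seq_len(K - 1L))
    if (nC[k] != nC[k + 1L] + nD[k])
      stop("internal-consistency error: |C_k| != |C_{k+1}| + |D_k| at k = ", k)
  data.frame(stage = x@stageLabels, direction = x@direction,
             n_continuing = as.integer(nC), n_deviated = as.integer(nD),
             stringsAsFactors = FALSE, row.names = NULL)
})

setMethod("show", "TrajectoryResult", function(object) {
  cat("TrajectoryResult (", object@direction, "), ",
      length(object@continuing), " stages\n", sep = "")
  print(countTable(object))
})

#' Nested gene sets with prescribed continuing counts
#'
#' Builds a family of nested gene sets whose sizes equal `counts` (which must
#' be non-increasing): useful for reconstructing a published continuing-count
#' series as concrete gene sets and re-deriving its deviated counts. When
#' `seed` is given, the universe of ids is shuffled first so set membership
#' is not a trivial prefix.
#'
#' @param counts non-increasing positive integer vector
#' @param prefix gene id prefix
#' @param seed optional integer seed for shuffling
#' @return list of character vectors with `lengths(x) == counts`, each a
#'   superset of the next
#' @examples
#' lengths(nestedSetsFromCounts(c(357, 242, 131, 79, 21, 10)))
#' @export
nestedSetsFromCounts <- function(counts, prefix = "g", seed = NULL) {
  if (any(diff(counts) > 0)) stop("counts must be non-increasing")
  if (any(counts < 0)) stop("counts must be non-negative")
  ids <- sprintf("%s%06d", prefix, seq_len(max(counts, 1L)))
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    ids <- sample(ids)
  }
  lapply(counts, function(n) sort(ids[seq_len(n)]))
}
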