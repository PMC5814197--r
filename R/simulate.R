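#' Largest-remainder apportionment of gene classes
#'
#' Rounds `n * fractions` to integers that sum exactly to `n`: floors first,
#' then hands the remaining units to the classes with the largest fractional
#' remainders (ties broken by class order).
#'
#' @param n total number of genes
#' @param fractions named non-negative numeric vector summing to 1
#' @return named integer vector summing to `n`
#' @export
apportionClasses <- function(n, fractions) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8)
    stop("class fractions must be non-negative and sum to 1")
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    take <- order(-frac, seq_along(frac))[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  setNames(as.integer(base), names(fractions))
}

#' Simulate a stage-wise log2 expression study with planted trajectories
#'
#' Generates a gene x sample log2 expression matrix over an ordered stage
#' design, with three planted gene classes: `continuous_up` genes whose
#' population mean rises by `effect` log2 units at every transition up to
#' their drop stage and is flat after, `continuous_down` genes as the mirror
#' image, and `null` genes that are flat throughout. Sample values are the
#' stage mean plus independent Gaussian noise of standard deviation `sigma`
#' (homoscedastic on the log2 scale). Baseline log2 means are drawn from
#' Normal(`baselineMean`, `baselineSD`), mimicking the intensity scale of a
#' normalised expression microarray.
#'
#' The drop stage d of a trending gene is a transition index in 1..K
#' (K = number of transitions): the gene trends through transitions 1..d and
#' is flat afterwards, so a correct screen places it in continuing set
#' \eqn{C_d} and — when d < K — in deviated set \eqn{D_d}. `d = K` means the
#' gene never drops (continuous through the whole series).
#'
#' @param design a [StageDesign-class]
#' @param nGenes number of genes
#' @param classFractions named fractions for `continuous_up`,
#'   `continuous_down`, `null`; must sum to 1. Counts per class are fixed by
#'   largest-remainder rounding ([apportionClasses()]).
#' @param effect per-transition log2 shift (>= 0; 0 gives a global null in
#'   which every gene is statistically indistinguishable from flat).
#' @param sigma within-group standard deviation on the log2 scale (> 0).
#' @param dropSchedule named list mapping class (`continuous_up`,
#'   `continuous_down`) to a probability vector over drop stages 1..K;
#'   `NULL` means uniform over 1..K.
#' @param baselineMean,baselineSD parameters of the baseline log2 intensity
#'   distribution.
#' @param seed integer RNG seed; identical seed and parameters regenerate the
#'   dataset byte-for-byte.
#' @return a [SyntheticDataset-class] (annotation slot NULL, empty edge table)
#' @examples
#' ds <- simulateExpression(makeStageDesign(c("A", "B"), c(3, 3)),
#'                          nGenes = 50, seed = 1)
#' head(truthTable(ds))
#' @export
simulateExpression <- function(design, nGenes = 1000L,
    classFractions = c(continuous_up = 0.1, continuous_down = 0.1,
                       null = 0.8),
    effect = 1.5, sigma = 0.5, dropSchedule = NULL,
    baselineMean = 8, baselineSD = 1.5, seed = 1L) {
  stopifnot(is(design, "StageDesign"))
  if (effect < 0) stop("effect must be non-negative")
  if (sigma <= 0) stop("sigma must be positive")
  need <- c("continuous_up", "continuous_down", "null")
  if (!all(need %in% names(classFractions)))
    stop("classFractions must name continuous_up, continuous_down and null")
  classFractions <- classFractions[need]

  labels <- stageLabels(design)
  counts <- unname(stageCounts(design))
  S <- length(labels)            # stages
  K <- S - 1L                    # transitions
  set.seed(as.integer(seed))

  nPerClass <- apportionClasses(nGenes, classFractions)
  gene <- sprintf("g%06d", seq_len(nGenes))
  cls <- rep(names(nPerClass), nPerClass)

  drawDrop <- function(class, n) {
    if (n == 0L) return(integer())
    p <- if (!is.null(dropSchedule) && !is.null(dropSchedule[[class]])) {
      pr <- dropSchedule[[class]]
      if (length(pr) != K || any(pr < 0) || sum(pr) <= 0)
        stop("dropSchedule entries must be non-negative vectors of length K")
      pr / sum(pr)
    } else rep(1 / K, K)
    sample.int(K, n, replace = TRUE, prob = p)
  }
  drop <- rep(NA_integer_, nGenes)
  drop[cls == "continuous_up"] <-
    drawDrop("continuous_up", nPerClass[["continuous_up"]])
  drop[cls == "continuous_down"] <-
    drawDrop("continuous_down", nPerClass[["continuous_down"]])

  base <- rnorm(nGenes, baselineMean, baselineSD)
  sign <- ifelse(cls == "continuous_up", 1,
                 ifelse(cls == "continuous_down", -1, 0))
  # stage mean for gene g at stage s: base + sign*effect*min(s-1, drop)
  steps <- vapply(seq_len(S), function(s)
    pmin(s - 1L, ifelse(is.na(drop), 0L, drop)), numeric(nGenes))
  mu <- base + sign * effect * steps          # nGenes x S

  sampleStage <- rep(labels, counts)
  sampleId <- unlist(lapply(seq_len(S), function(s)
    sprintf("%s_%03d", labels[s], seq_len(counts[s]))), use.names = FALSE)
  mat <- mu[, match(sampleStage, labels), drop = FALSE] +
    matrix(rnorm(nGenes * length(sampleId), 0, sigma),
           nrow = nGenes)
  dimnames(mat) <- list(gene, sampleId)

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = mat),
    colData = S4Vectors::DataFrame(
      sample_id = sampleId,
      stage = factor(sampleStage, levels = labels),
      row.names = sampleId))
  truth <- data.frame(gene = gene, class = cls, drop_stage = drop,
                      module_id = NA_integer_, stringsAsFactors = FALSE)
  new("SyntheticDataset", experiment = se, design = design, truth = truth,
      annotation = NULL,
      interactions = emptyInteractionTable(), seed = as.integer(seed))
}

#' Simulate a flat GO annotation over a planted truth table
#'
#' Assigns cellular-component terms so the compartment filter downstream is
#' informative: planted up-regulated genes carry an extracellular term with
#' probability `pUp`, planted down-regulated genes a mitochondrial term with
#' probability `pDown`, and every gene carries each compartment term with
#' probability `background` regardless of class. Biological-process terms are
#' assigned so that the term/class pairs in `bpEnrichment` are genuinely
#' over-represented against a background assignment rate `bpBackground`.
#'
#' @param truth truth table (data.frame with `gene`, `class`) as produced by
#'   [simulateExpression()]
#' @param extracellularTerms,mitochondrionTerms CC term ids standing for the
#'   extracellular matrix / extracellular space and the mitochondrion.
#' @param pUp,pDown,background compartment labelling probabilities in `[0,1]`.
#' @param bpEnrichment data.frame with columns `term`, `class`, `prob`: each
#'   row plants term `term` on genes of `class` with probability `prob`.
#'   Defaults to one term enriched in each trending class.
#' @param bpBackground background probability of each BP term on every gene.
#' @param nBpTerms number of BP terms in the vocabulary.
#' @param seed integer RNG seed.
#' @return a [GeneAnnotation-class]
#' @export
simulateAnnotations <- function(truth,
    extracellularTerms = c("GO:0031012", "GO:0005615"),
    mitochondrionTerms = "GO:0005739",
    pUp = 0.9, pDown = 0.9, background = 0.05,
    bpEnrichment = NULL, bpBackground = 0.05, nBpTerms = 10L,
    seed = 1L) {
  probs <- c(pUp, pDown, background, bpBackground)
  if (any(probs < 0 | probs > 1))
    stop("annotation probabilities must lie in [0, 1]")
  known <- c("continuous_up", "continuous_down", "null")
  if (!all(truth$class %in% known))
    stop("unknown gene class label: ",
         paste(setdiff(truth$class, known), collapse = ", "))
  set.seed(as.integer(seed))

  bpTerms <- sprintf("GO:BP%04d", seq_len(nBpTerms))
  if (is.null(bpEnrichment))
    bpEnrichment <- data.frame(
      term = bpTerms[c(1L, 2L)],
      class = c("continuous_up", "continuous_down"),
      prob = c(0.6, 0.6), stringsAsFactors = FALSE)
  if (!all(bpEnrichment$term %in% bpTerms))
    stop("bpEnrichment terms must come from the BP vocabulary")
  if (!all(bpEnrichment$class %in% known))
    stop("unknown gene class label in bpEnrichment")

  n <- nrow(truth)
  rows <- list()
  addTerm <- function(term, hit) {
    if (any(hit)) rows[[length(rows) + 1L]] <<-
      data.frame(gene = truth$gene[hit], term = term,
                 stringsAsFactors = FALSE)
  }
  # CC: planted signal on top of a uniform background
  for (term in extracellularTerms) {
    p <- ifelse(truth$class == "continuous_up", pUp, background)
    addTerm(term, runif(n) < p)
  }
  for (term in mitochondrionTerms) {
    p <- ifelse(truth$class == "continuous_down", pDown, background)
    addTerm(term, runif(n) < p)
  }
  # BP
  for (term in bpTerms) {
    p <- rep(bpBackground, n)
    sel <- bpEnrichment[bpEnrichment$term == term, , drop = FALSE]
    for (i in seq_len(nrow(sel)))
      p[truth$class == sel$class[i]] <- sel$prob[i]
    addTerm(term, runif(n) < p)
  }
  mapping <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), term = character(),
               stringsAsFactors = FALSE)
  mapping <- unique(mapping[order(mapping$gene, mapping$term), ,
                            drop = FALSE])
  rownames(mapping) <- NULL

  terms <- data.frame(
    term = c(extracellularTerms, mitochondrionTerms, bpTerms),
    name = c(paste("extracellular compartment",
                   seq_along(extracellularTerms)),
             paste("mitochondrion", seq_along(mitochondrionTerms)),
             paste("biological process", seq_len(nBpTerms))),
    namespace = c(rep("CC", length(extracellularTerms) +
                        length(mitochondrionTerms)),
                  rep("BP", nBpTerms)),
    stringsAsFactors = FALSE)
  new("GeneAnnotation", mapping = mapping, terms = terms)
}

emptyInteractionTable <- function() {
  data.frame(protein1 = character(), protein2 = character(),
             neighborhood = integer(), coexpression = integer(),
             experimental = integer(), combined_score = integer(),
             stringsAsFactors = FALSE)
}

#' Simulate a STRING-dialect interaction edge table with planted complexes
#'
#' Plants `nModules` near-cliques (edge probability `intraDensity`) among the
#' non-null genes of a truth table on top of an Erdos-Renyi background over
#' all genes (edge probability `backgroundDensity`). Every edge carries
#' per-channel integer scores in the STRING 0-1000 convention; the
#' `experimental` channel score is drawn uniformly from `scoreRange` and the
#' `combined_score` equals it (the generator emulates the
#' experimental-evidence-only usage of the database).
#'
#' @param truth truth table with columns `gene`, `class`, `module_id`
#' @param nModules number of planted complexes
#' @param moduleSize members per complex (>= 3)
#' @param intraDensity,backgroundDensity edge probabilities in `[0,1]`
#' @param scoreRange integer range the experimental channel scores are drawn
#'   from
#' @param seed integer RNG seed
#' @return list with `edges` (the edge table) and `truth` (input truth with
#'   `module_id` filled in for planted members)
#' @export
simulateInteractions <- function(truth, nModules = 2L, moduleSize = 6L,
                                 intraDensity = 1, backgroundDensity = 0.01,
                                 scoreRange = c(400L, 900L), seed = 1L) {
  if (intraDensity < 0 || intraDensity > 1 ||
      backgroundDensity < 0 || backgroundDensity > 1)
    stop("edge densities must lie in [0, 1]")
  if (nModules > 0 && moduleSize < 3L)
    stop("moduleSize must be at least 3")
  set.seed(as.integer(seed))

  genes <- truth$gene
  signal <- truth$gene[truth$class != "null"]
  if (nModules * moduleSize > length(signal))
    stop("not enough non-null genes for the requested modules")

  truth$module_id <- NA_integer_
  edges <- list()
  if (nModules > 0) {
    members <- sample(signal, nModules * moduleSize)
    for (m in seq_len(nModules)) {
      mem <- sort(members[((m - 1L) * moduleSize + 1L):(m * moduleSize)])
      truth$module_id[match(mem, truth$gene)] <- m
      pair <- combn(mem, 2L)
      keep <- runif(ncol(pair)) < intraDensity
      if (any(keep))
        edges[[length(edges) + 1L]] <-
          data.frame(protein1 = pair[1L, keep], protein2 = pair[2L, keep],
                     stringsAsFactors = FALSE)
    }
  }
  if (backgroundDensity > 0 && length(genes) >= 2L) {
    pair <- combn(genes, 2L)
    keep <- runif(ncol(pair)) < backgroundDensity
    if (any(keep))
      edges[[length(edges) + 1L]] <-
        data.frame(protein1 = pair[1L, keep], protein2 = pair[2L, keep],
                   stringsAsFactors = FALSE)
  }
  tab <- if (length(edges)) unique(do.call(rbind, edges)) else
    data.frame(protein1 = character(), protein2 = character(),
               stringsAsFactors = FALSE)
  if (nrow(tab)) {
    tab <- tab[order(tab$protein1, tab$protein2), , drop = FALSE]
    rownames(tab) <- NULL
    ne <- nrow(tab)
    tab$neighborhood <- 0L
    tab$coexpression <- as.integer(sample.int(200L, ne, replace = TRUE) - 1L)
    tab$experimental <- as.integer(
      sample(seq(scoreRange[1L], scoreRange[2L]), ne, replace = TRUE))
    tab$combined_score <- tab$experimental
  } else tab <- emptyInteractionTable()
  list(edges = tab, truth = truth)
}

# deterministic per-stage sub-seed: keeps all fan-out below 2^31 - 1
.subSeed <- function(seed, label) {
  v <- utf8ToInt(label)
  h <- sum(v * seq_along(v)) %% 100000L
  as.integer((as.double(seed) * 977 + h) %% 2147483629)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper producing expression, annotation and interactions in
#' one [SyntheticDataset-class]. All randomness fans out deterministically
#' from the single `seed` (one sub-seed per generator stage), so each
#' component is individually reproducible.
#'
#' @param design a [StageDesign-class]
#' @param nGenes number of genes
#' @param seed top-level integer seed
#' @param exprArgs,annotArgs,interArgs named lists of extra arguments passed
#'   to [simulateExpression()], [simulateAnnotations()] and
#'   [simulateInteractions()]
#' @return a [SyntheticDataset-class] with all slots populated
#' @export
simulateDataset <- function(design = makeStageDesign(), nGenes = 1000L,
                            seed = 1L, exprArgs = list(),
                            annotArgs = list(), interArgs = list()) {
  ds <- do.call(simulateExpression,
                c(list(design = design, nGenes = nGenes,
                       seed = .subSeed(seed, "expression")), exprArgs))
  ann <- do.call(simulateAnnotations,
                 c(list(truth = ds@truth,
                        seed = .subSeed(seed, "annotation")), annotArgs))
  net <- do.call(simulateInteractions,
                 c(list(truth = ds@truth,
                        seed = .subSeed(seed, "interactions")), interArgs))
  ds@annotation <- ann
  ds@truth <- net$truth
  ds@interactions <- net$edges
  ds@seed <- as.integer(seed)
  validObject(ds)
  ds
}

#' @rdname expressionData
#' @export
setMethod("expressionData", "SyntheticDataset", function(x) x@experiment)

#' @rdname truthTable
#' @export
setMethod("truthTable", "SyntheticDataset", function(x) x@truth)

#' @rdname stageDesign
#' @export
setMethod("stageDesign", "SyntheticDataset", function(x) x@design)

#' @rdname interactionTable
#' @export
setMethod("interactionTable", "SyntheticDataset", function(x) x@interactions)

#' @rdname geneAnnotation
#' @export
setMethod("geneAnnotation", "SyntheticDataset", function(x) x@annotation)

setMethod("show", "SyntheticDataset", function(object) {
  se <- object@experiment
  cat("SyntheticDataset:", nrow(se), "genes x", ncol(se), "samples,",
      length(stageLabels(object@design)), "stages\n")
  cat("  classes:",
      paste(names(table(object@truth$class)),
            table(object@truth$class), sep = "=", collapse = ", "), "\n")
  cat("  interactions:", nrow(object@interactions), "edges; seed",
      object@seed, "\n")
})
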