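#' @import methods
#' @importFrom stats pf phyper p.adjust rnorm rbinom runif setNames
#' @importFrom utils write.table read.table combn head
NULL

#' Ordered disease-stage design
#'
#' Holds the ordered stage labels of a progression series together with the
#' number of samples per stage. The adjacent stage pairs (transitions) that the
#' differential screen compares are derived from the label order.
#'
#' @slot labels character vector of stage names, in progression order.
#' @slot counts integer vector of per-stage sample counts (each >= 2, so the
#'   two-group test has replicates on both sides of every transition).
#'
#' @seealso [makeStageDesign()], [stageTransitions()]
#' @export
setClass("StageDesign",
  representation(labels = "character", counts = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@labels) != length(object@counts))
      msg <- c(msg, "labels and counts must have the same length")
    if (length(object@labels) < 2)
      msg <- c(msg, "a stage design needs at least two stages (one transition)")
    if (anyDuplicated(object@labels))
      msg <- c(msg, "stage labels must be unique")
    if (any(is.na(object@counts)) || any(object@counts < 2L))
      msg <- c(msg, "every stage needs at least 2 samples")
    if (length(msg)) msg else TRUE
  }
)

#' Stage-trajectory screen result for one direction
#'
#' Continuing sets \eqn{C_1 \supseteq \dots \supseteq C_K} (genes significantly
#' regulated in the same direction in every successive transition up to stage
#' k) and deviated sets \eqn{D_k = C_k \setminus C_{k+1}} (genes that leave the
#' trend at the transition from stage k to stage k+1). The disjoint-union
#' identity \eqn{|C_k| = |C_{k+1}| + |D_k|} is enforced by the validity method.
#'
#' Indexing convention: a deviated set is attached to the earlier stage of its
#' transition, so `deviatedSets(x)[[k]]` sits on the row of `stageLabels(x)[k]`.
#'
#' @slot direction `"up"` or `"down"`.
#' @slot continuing list of K character vectors (sorted gene ids).
#' @slot deviated list of K-1 character vectors (sorted gene ids).
#' @slot stageLabels character vector of the K stage labels the continuing
#'   sets are indexed by (the later stage of each transition).
#'
#' @seealso [cumulativeContinuing()], [partitionDeviated()], [countTable()]
#' @export
setClass("TrajectoryResult",
  representation(direction = "character", continuing = "list",
                 deviated = "list", stageLabels = "character"),
  validity = function(object) {
    msg <- character()
    if (!(length(object@direction) == 1L &&
          object@direction %in% c("up", "down")))
      msg <- c(msg, "direction must be \"up\" or \"down\"")
    K <- length(object@continuing)
    if (K < 1L) msg <- c(msg, "at least one continuing set is required")
    if (length(object@deviated) != max(K - 1L, 0L))
      msg <- c(msg, "need exactly one deviated set per internal transition")
    if (length(object@stageLabels) != K)
      msg <- c(msg, "one stage label per continuing set")
    if (K >= 2L) {
      for (k in seq_len(K - 1L)) {
        Ck <- object@continuing[[k]]; Ck1 <- object@continuing[[k + 1L]]
        Dk <- object@deviated[[k]]
        if (!all(Ck1 %in% Ck)) {
          msg <- c(msg, sprintf("continuing sets not nested at index %d", k))
          break
        }
        if (!setequal(Dk, setdiff(Ck, Ck1)) ||
            length(Ck) != length(Ck1) + length(Dk)) {
          msg <- c(msg, sprintf("deviated set %d is not C_k \\ C_{k+1}", k))
          break
        }
      }
    }
    if (length(msg)) msg else TRUE
  }
)

#' Flat gene -> GO term annotation
#'
#' A flat (non-propagated) mapping from gene ids to Gene Ontology term ids,
#' with term metadata restricted to the two namespaces the pipeline uses:
#' cellular component (`"CC"`, compartment filtering) and biological process
#' (`"BP"`, over-representation testing).
#'
#' @slot mapping data.frame with columns `gene`, `term`.
#' @slot terms data.frame with columns `term`, `name`, `namespace`.
#'
#' @seealso [filterByTerms()], [hypergeomEnrich()], [readAnnotationTables()]
#' @export
setClass("GeneAnnotation",
  representation(mapping = "data.frame", terms = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!all(c("gene", "term") %in% names(object@mapping)))
      msg <- c(msg, "mapping needs columns gene, term")
    if (!all(c("term", "name", "namespace") %in% names(object@terms)))
      msg <- c(msg, "terms needs columns term, name, namespace")
    else {
      if (!all(object@terms$namespace %in% c("CC", "BP")))
        msg <- c(msg, "term namespace must be CC or BP")
      if (anyDuplicated(object@terms$term))
        msg <- c(msg, "duplicate term metadata")
      if (nrow(object@mapping) &&
          !all(object@mapping$term %in% object@terms$term))
        msg <- c(msg, "mapping uses terms without metadata")
    }
    if (nrow(object@mapping) &&
        any(is.na(object@mapping$gene) | object@mapping$gene == ""))
      msg <- c(msg, "annotated gene ids must be non-empty")
    if (length(msg)) msg else TRUE
  }
)

#' Synthetic stage-wise expression study
#'
#' Container produced by the synthetic-data generator: a log2 expression
#' [SummarizedExperiment::SummarizedExperiment] with per-sample stage
#' assignments, the stage design, the planted ground truth (class and
#' drop stage per gene, plus module membership once interactions are
#' simulated), and optionally an annotation table and a STRING-dialect
#' interaction edge table.
#'
#' @slot experiment SummarizedExperiment, assay `"log2"`.
#' @slot design the [StageDesign-class] used.
#' @slot truth data.frame with columns `gene`, `class`
#'   (`continuous_up` / `continuous_down` / `null`), `drop_stage` (transition
#'   index in 1..K after which the planted trend stops; K means the gene never
#'   drops; NA for null genes) and `module_id`.
#' @slot annotation a [GeneAnnotation-class] or NULL.
#' @slot interactions data.frame edge table (may have zero rows).
#' @slot seed integer seed the dataset was generated from.
#'
#' @seealso [simulateExpression()], [simulateDataset()]
#' @export
setClass("SyntheticDataset",
  representation(experiment = "ANY", design = "StageDesign",
                 truth = "data.frame", annotation = "ANY",
                 interactions = "data.frame", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (!is(object@experiment, "SummarizedExperiment"))
      msg <- c(msg, "experiment must be a SummarizedExperiment")
    else {
      if (!all(object@truth$gene %in% rownames(object@experiment)))
        msg <- c(msg, "every truth gene must appear in the expression matrix")
    }
    if (!all(c("gene", "class", "drop_stage", "module_id") %in%
             names(object@truth)))
      msg <- c(msg, "truth needs columns gene, class, drop_stage, module_id")
    if (!is.null(object@annotation) && !is(object@annotation, "GeneAnnotation"))
      msg <- c(msg, "annotation must be NULL or a GeneAnnotation")
    if (length(msg)) msg else TRUE
  }
)

#' Per-transition differential-expression selection
#'
#' Genes called significantly up or down between the two groups of one stage
#' transition, under a Bonferroni-adjusted p-value cutoff and a linear
#' fold-change threshold.
#'
#' @slot transition character(2), earlier and later stage label.
#' @slot up,down sorted character vectors of selected gene ids (disjoint).
#' @slot alpha,fcThreshold the selection parameters used.
#'
#' @seealso [selectDE()], [testTransition()]
#' @export
setClass("DESelection",
  representation(transition = "character", up = "character",
                 down = "character", alpha = "numeric",
                 fcThreshold = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@transition) != 2L)
      msg <- c(msg, "transition must be a (from, to) stage pair")
    if (length(intersect(object@up, object@down)))
      msg <- c(msg, "up and down selections must be disjoint")
    if (length(msg)) msg else TRUE
  }
)

#' Detected molecular complex (MCODE-style module)
#'
#' @slot members character vector of member gene ids.
#' @slot seed the seed vertex the complex was grown from.
#' @slot density simple-graph density 2E/(V(V-1)) of the induced subgraph.
#' @slot score density x size; the ranking key.
#'
#' @seealso [mcodeModules()]
#' @export
setClass("NetworkModule",
  representation(members = "character", seed = "character",
                 density = "numeric", score = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@seed %in% object@members))
      msg <- c(msg, "seed must be a member")
    if (object@density < 0 || object@density > 1)
      msg <- c(msg, "density must lie in [0, 1]")
    if (object@score > length(object@members) + 1e-9)
      msg <- c(msg, "score cannot exceed module size")
    if (length(msg)) msg else TRUE
  }
)

#' Degree-ranged hub subnetwork
#'
#' Nodes whose degree in the parent interaction graph falls inside a
#' configured range, with the subgraph they induce and their parent-graph
#' degrees.
#'
#' @slot graph igraph induced on the hub nodes.
#' @slot parentDegree named integer vector, degree of each hub in the parent.
#' @slot lo,hi the degree range used.
#'
#' @seealso [hubSubnetwork()], [keyChain()]
#' @export
setClass("HubNetwork",
  representation(graph = "ANY", parentDegree = "integer",
                 lo = "numeric", hi = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!igraph::is_igraph(object@graph))
      msg <- c(msg, "graph must be an igraph object")
    else if (!setequal(igraph::V(object@graph)$name,
                       names(object@parentDegree)))
      msg <- c(msg, "parentDegree must cover exactly the hub nodes")
    if (any(object@parentDegree < object@lo | object@parentDegree > object@hi))
      msg <- c(msg, "every hub degree must lie inside [lo, hi]")
    if (length(msg)) msg else TRUE
  }
)
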