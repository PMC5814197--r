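#' @describeIn StageDesign-class stage labels in progression order
#' @param x object
#' @export
setGeneric("stageLabels", function(x) standardGeneric("stageLabels"))

#' @describeIn StageDesign-class per-stage sample counts (named)
#' @export
setGeneric("stageCounts", function(x) standardGeneric("stageCounts"))

#' @describeIn StageDesign-class ordered adjacent stage pairs as a data.frame
#'   with columns `from`, `to`
#' @export
setGeneric("stageTransitions", function(x) standardGeneric("stageTransitions"))

#' @describeIn TrajectoryResult-class screen direction, `"up"` or `"down"`
#' @export
setGeneric("trajectoryDirection",
           function(x) standardGeneric("trajectoryDirection"))

#' @describeIn TrajectoryResult-class list of continuing gene sets C_1..C_K
#' @export
setGeneric("continuingSets", function(x) standardGeneric("continuingSets"))

#' @describeIn TrajectoryResult-class list of deviated gene sets D_1..D_{K-1}
#' @export
setGeneric("deviatedSets", function(x) standardGeneric("deviatedSets"))

#' Stage-wise continuing / deviated count table
#'
#' @param x a [TrajectoryResult-class]
#' @return data.frame with one row per stage: `stage`, `direction`,
#'   `n_continuing`, `n_deviated` (NA on the terminal stage, which has no
#'   outgoing transition).
#' @export
setGeneric("countTable", function(x) standardGeneric("countTable"))

#' @describeIn GeneAnnotation-class the gene/term mapping data.frame
#' @param x object
#' @export
setGeneric("annotationMapping",
           function(x) standardGeneric("annotationMapping"))

#' @describeIn GeneAnnotation-class the term metadata data.frame
#' @export
setGeneric("termInfo", function(x) standardGeneric("termInfo"))

#' Genes annotated with at least one of the given terms
#'
#' @param x a [GeneAnnotation-class]
#' @param terms character vector of term ids (must exist in the metadata)
#' @return sorted character vector of gene ids
#' @export
setGeneric("genesWithTerm", function(x, terms) standardGeneric("genesWithTerm"))

#' @describeIn SyntheticDataset-class the expression SummarizedExperiment
#' @param x object
#' @export
setGeneric("expressionData", function(x) standardGeneric("expressionData"))

#' @describeIn SyntheticDataset-class the planted ground-truth table
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @describeIn SyntheticDataset-class the stage design
#' @export
setGeneric("stageDesign", function(x) standardGeneric("stageDesign"))

#' @describeIn SyntheticDataset-class the interaction edge table
#' @export
setGeneric("interactionTable",
           function(x) standardGeneric("interactionTable"))

#' @describeIn SyntheticDataset-class the gene annotation (or NULL)
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))

#' @describeIn DESelection-class genes selected as up-regulated
#' @param x object
#' @export
setGeneric("upGenes", function(x) standardGeneric("upGenes"))

#' @describeIn DESelection-class genes selected as down-regulated
#' @export
setGeneric("downGenes", function(x) standardGeneric("downGenes"))

#' @describeIn NetworkModule-class member gene ids
#' @param x object
#' @export
setGeneric("moduleMembers", function(x) standardGeneric("moduleMembers"))

#' @describeIn NetworkModule-class module score (density x size)
#' @export
setGeneric("moduleScore", function(x) standardGeneric("moduleScore"))

#' @describeIn NetworkModule-class induced-subgraph density
#' @export
setGeneric("moduleDensity", function(x) standardGeneric("moduleDensity"))

#' @describeIn NetworkModule-class the seed vertex the module was grown from
#' @export
setGeneric("moduleSeed", function(x) standardGeneric("moduleSeed"))

#' @describeIn HubNetwork-class hub gene ids
#' @param x object
#' @export
setGeneric("hubGenes", function(x) standardGeneric("hubGenes"))

#' @describeIn HubNetwork-class the induced hub subgraph (igraph)
#' @export
setGeneric("hubGraph", function(x) standardGeneric("hubGraph"))

#' @describeIn HubNetwork-class parent-graph degree of each hub (named)
#' @export
setGeneric("hubDegrees", function(x) standardGeneric("hubDegrees"))
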