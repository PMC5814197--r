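#' Construct an ordered stage design
#'
#' Defines the ordered disease stages of a progression series and the number
#' of samples observed at each stage. The default arguments reproduce the
#' seven-group colorectal-cancer design the package's synthetic data emulate:
#' normal mucosa, primary-tumor stages I-IV, liver metastasis and lung
#' metastasis, with 54, 28, 50, 49, 58, 47 and 20 samples respectively.
#'
#' @param labels character vector of stage names, in progression order.
#' @param counts integer vector of per-stage sample counts; every count must be
#'   at least 2 so each side of every transition has replicates.
#' @return a [StageDesign-class]
#' @examples
#' d <- makeStageDesign()
#' stageTransitions(d)
#' @export
makeStageDesign <- function(labels = c("normal", "I", "II", "III", "IV",
                                       "liver_met", "lung_met"),
                            counts = c(54L, 28L, 50L, 49L, 58L, 47L, 20L)) {
  if (length(labels) != length(counts))
    stop("invalid design: labels and counts must have the same length")
  if (length(labels) < 2L)
    stop("invalid design: need at least two stages to define a transition")
  if (any(counts < 2L))
    stop("invalid design: every stage needs at least 2 samples")
  new("StageDesign", labels = as.character(labels),
      counts = as.integer(counts))
}

#' @rdname stageLabels
#' @export
setMethod("stageLabels", "StageDesign", function(x) x@labels)

#' @rdname stageCounts
#' @export
setMethod("stageCounts", "StageDesign",
          function(x) setNames(x@counts, x@labels))

#' @rdname stageTransitions
#' @export
setMethod("stageTransitions", "StageDesign", function(x) {
  K <- length(x@labels) - 1L
  data.frame(from = x@labels[seq_len(K)], to = x@labels[seq_len(K) + 1L],
             stringsAsFactors = FALSE)
})

setMethod("show", "StageDesign", function(object) {
  cat("StageDesign with", length(object@labels), "stages /",
      length(object@labels) - 1L, "transitions\n")
  cat(paste0("  ", object@labels, " (n=", object@counts, ")",
             collapse = " ->\n"), "\n")
})
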