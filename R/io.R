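.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read an expression matrix with sample metadata
#'
#' Expression goes to a TSV whose first column (`gene`) holds gene ids and
#' whose remaining columns are samples; the companion metadata TSV has
#' columns `sample_id`, `stage`.
#'
#' @param se a SummarizedExperiment with assay `"log2"` and `colData$stage`
#'   (a [SyntheticDataset-class] is also accepted)
#' @param exprPath,metaPath output file paths
#' @return the paths, invisibly
#' @export
writeExpression <- function(se, exprPath, metaPath) {
  if (is(se, "SyntheticDataset")) se <- expressionData(se)
  mat <- SummarizedExperiment::assay(se, "log2")
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .writeTSV(df, exprPath)
  meta <- data.frame(sample_id = colnames(mat),
                     stage = as.character(se$stage),
                     stringsAsFactors = FALSE)
  .writeTSV(meta, metaPath)
  invisible(c(exprPath, metaPath))
}

#' @rdname writeExpression
#' @param design optional [StageDesign-class] fixing the stage order; if
#'   NULL, stages are ordered by first appearance in the metadata.
#' @return `readExpression`: a SummarizedExperiment with assay `"log2"` and
#'   per-sample `stage` in `colData`
#' @export
readExpression <- function(exprPath, metaPath, design = NULL) {
  df <- read.table(exprPath, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  meta <- read.table(metaPath, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
  if (names(df)[1L] != "gene" ||
      !all(c("sample_id", "stage") %in% names(meta)))
    stop("malformed expression/metadata tables")
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df$gene
  meta <- meta[match(colnames(mat), meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata missing samples")
  levels <- if (is.null(design)) unique(meta$stage) else stageLabels(design)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = mat),
    colData = S4Vectors::DataFrame(
      sample_id = meta$sample_id,
      stage = factor(meta$stage, levels = levels),
      row.names = meta$sample_id))
}

#' Write / read a planted-truth table
#' @param truth data.frame with columns `gene`, `class`, `drop_stage`,
#'   `module_id`
#' @param path file path
#' @export
writeTruth <- function(truth, path) .writeTSV(truth, path)

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  tr <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  tr$drop_stage <- as.integer(tr$drop_stage)
  tr$module_id <- as.integer(tr$module_id)
  tr
}

#' Write / read a flat annotation as two TSV tables
#'
#' The mapping table has columns `gene`, `term`; the metadata table `term`,
#' `name`, `namespace`.
#'
#' @param annotation a [GeneAnnotation-class]
#' @param mappingPath,termPath file paths
#' @export
writeAnnotationTables <- function(annotation, mappingPath, termPath) {
  .writeTSV(annotationMapping(annotation), mappingPath)
  .writeTSV(termInfo(annotation), termPath)
  invisible(c(mappingPath, termPath))
}

#' @rdname writeAnnotationTables
#' @export
readAnnotationTables <- function(mappingPath, termPath) {
  new("GeneAnnotation",
      mapping = read.table(mappingPath, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE),
      terms = read.table(termPath, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE))
}

#' Write / read gene sets in GMT format
#'
#' One line per set: name, description, then member genes, tab-separated.
#'
#' @param sets named list of character vectors
#' @param path file path
#' @param descriptions optional character vector of set descriptions
#'   (defaults to the set names)
#' @export
writeGMT <- function(sets, path, descriptions = names(sets)) {
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeGMT
#' @return `readGMT`: named list of character vectors
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  sets
}

#' Write a STRING-dialect interaction edge table
#' @param edges data.frame with columns `protein1`, `protein2`, per-channel
#'   scores and `combined_score`
#' @param path file path
#' @export
writeInteractions <- function(edges, path) .writeTSV(edges, path)

#' Write all artifacts of a synthetic study to a directory
#'
#' Emits `expression.tsv`, `samples.tsv`, `truth.tsv`, `annotation.tsv`,
#' `terms.tsv` and `interactions.tsv`; every file round-trips through the
#' package's own readers without loss.
#'
#' @param dataset a [SyntheticDataset-class]
#' @param outdir output directory (created if missing)
#' @return named character vector of the paths written
#' @export
writeDataset <- function(dataset, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(outdir, c("expression.tsv", "samples.tsv", "truth.tsv",
                           "annotation.tsv", "terms.tsv",
                           "interactions.tsv"))
  names(p) <- c("expression", "samples", "truth", "annotation", "terms",
                "interactions")
  writeExpression(dataset, p[["expression"]], p[["samples"]])
  writeTruth(truthTable(dataset), p[["truth"]])
  if (!is.null(geneAnnotation(dataset)))
    writeAnnotationTables(geneAnnotation(dataset), p[["annotation"]],
                          p[["terms"]])
  writeInteractions(interactionTable(dataset), p[["interactions"]])
  p
}
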