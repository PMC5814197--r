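#' Default pipeline configuration
#'
#' A complete, runnable configuration in synthetic mode. The structure is a
#' plain nested list so it can round-trip through YAML
#' ([readPipelineConfig()]); every field can be overridden.
#'
#' @param outdir output directory (NULL to skip writing artifacts)
#' @param seed top-level integer seed; all stage randomness fans out from it
#' @return nested configuration list
#' @export
defaultConfig <- function(outdir = NULL, seed = 1L) {
  list(
    synthetic = TRUE,
    seed = as.integer(seed),
    outdir = outdir,
    paths = list(expression = NULL, metadata = NULL, annotation = NULL,
                 terms = NULL, edges = NULL),
    design = list(
      labels = c("normal", "I", "II", "III", "IV", "liver_met", "lung_met"),
      counts = c(54L, 28L, 50L, 49L, 58L, 47L, 20L)),
    simulate = list(nGenes = 1000L, effect = 1.5, sigma = 0.5,
                    fractions = c(continuous_up = 0.1,
                                  continuous_down = 0.1, null = 0.8)),
    de = list(alpha = 0.05, fcThreshold = 1),
    compartments = list(
      extracellular = c("GO:0031012", "GO:0005615"),
      mitochondrion = "GO:0005739"),
    enrichment = list(namespace = "BP", correction = "bonferroni",
                      topTerms = 5L),
    network = list(channel = "experimental", minScore = 1L,
                   vwp = 0.2, haircut = TRUE, fluff = FALSE,
                   fluffThreshold = 0.2,
                   hubLo = 8, hubHi = 18, removeTerm = NULL)
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Missing fields are filled in from [defaultConfig()].
#'
#' @param path YAML file
#' @return configuration list
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  merge <- function(base, over) {
    for (k in names(over)) {
      base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
        merge(base[[k]], over[[k]]) else over[[k]]
    }
    base
  }
  merge(defaultConfig(), user)
}

#' Validate a pipeline configuration
#'
#' Problems are returned as data, not thrown: an empty character vector
#' means the configuration is runnable.
#'
#' @param config configuration list (see [defaultConfig()])
#' @return character vector of human-readable problem descriptions
#' @export
validateConfig <- function(config) {
  problems <- character()
  note <- function(x) problems <<- c(problems, x)
  d <- config$design
  if (is.null(d) || length(d$labels) != length(d$counts))
    note("design: labels and counts must have the same length")
  else {
    if (length(d$labels) < 2L) note("design: need at least two stages")
    if (any(d$counts < 2L)) note("design: every stage needs >= 2 samples")
  }
  a <- config$de$alpha
  if (is.null(a) || a < 0 || a > 1) note("de.alpha must lie in [0, 1]")
  if (is.null(config$de$fcThreshold) || config$de$fcThreshold < 1)
    note("de.fcThreshold must be at least 1")
  nw <- config$network
  if (is.null(nw$vwp) || nw$vwp < 0 || nw$vwp >= 1)
    note("network.vwp must lie in [0, 1)")
  if (is.null(nw$hubLo) || is.null(nw$hubHi) || nw$hubLo > nw$hubHi ||
      nw$hubLo < 0)
    note("network.hubLo must satisfy 0 <= hubLo <= hubHi")
  if (!isTRUE(config$synthetic)) {
    for (f in c("expression", "metadata", "annotation", "terms", "edges")) {
      p <- config$paths[[f]]
      if (is.null(p) || !file.exists(p))
        note(sprintf("paths.%s: file required when synthetic mode is off", f))
    }
  }
  if (is.null(config$seed)) note("seed is required")
  problems
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

.enrichDeviated <- function(trajectory, annotation, background, cfg) {
  D <- deviatedSets(trajectory)
  out <- list()
  for (k in seq_along(D)) {
    study <- intersect(D[[k]], background)
    if (!length(study)) next
    res <- hypergeomEnrich(study, background, annotation,
                           namespace = cfg$namespace,
                           correction = cfg$correction)
    out[[names(D)[k]]] <- head(res, cfg$topTerms)
  }
  out
}

.networkStage <- function(graph, traj, cfg) {
  g <- induceGraph(graph, continuingSets(traj)[[1L]])
  modules <- mcodeModules(g, vwp = cfg$vwp, haircut = cfg$haircut,
                          fluff = cfg$fluff,
                          fluffThreshold = cfg$fluffThreshold)
  hub <- hubSubnetwork(g, cfg$hubLo, cfg$hubHi)
  chain <- if (length(hubGenes(hub)) >= 1L &&
               length(hubGenes(hub)) <= 25L) keyChain(hub) else NULL
  g <- annotateStage(g, traj)
  list(graph = g, modules = modules, hub = hub, chain = chain)
}

#' Run the full stage-trajectory pipeline
#'
#' Executes, in order: synthetic data generation (or reading the configured
#' input files), per-transition differential screening, up/down trajectory
#' construction, compartment filtering (extracellular for the up screen,
#' mitochondrial for the down screen), biological-process enrichment of every
#' deviated set, and interaction-network analysis (module detection, hub
#' subnetwork, key chain) of each compartment trajectory. All artifacts are
#' written under `config$outdir` when set, and a consolidated report is
#' returned. Re-running with the same configuration reproduces the report
#' exactly.
#'
#' @param config configuration list; see [defaultConfig()]
#' @return a run report: nested list with per-transition DE counts,
#'   trajectory count tables, top enriched terms per deviated set, module
#'   and hub summaries, and provenance (seed, config hash)
#' @export
runPipeline <- function(config = defaultConfig()) {
  problems <- validateConfig(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  design <- makeStageDesign(config$design$labels,
                            config$design$counts)

  if (isTRUE(config$synthetic)) {
    sim <- config$simulate
    ds <- simulateDataset(design, nGenes = sim$nGenes, seed = config$seed,
                          exprArgs = list(effect = sim$effect,
                                          sigma = sim$sigma,
                                          classFractions = sim$fractions))
    se <- expressionData(ds)
    annotation <- geneAnnotation(ds)
    edgeTable <- interactionTable(ds)
  } else {
    se <- readExpression(config$paths$expression, config$paths$metadata,
                         design)
    annotation <- readAnnotationTables(config$paths$annotation,
                                       config$paths$terms)
    edgeTable <- read.table(config$paths$edges, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    ds <- NULL
  }

  selections <- screenTransitions(se, design,
                                  alpha = config$de$alpha,
                                  fcThreshold = config$de$fcThreshold)
  later <- stageTransitions(design)$to
  trajUp <- makeTrajectory(selections, "up", stageLabels = later)
  trajDown <- makeTrajectory(selections, "down", stageLabels = later)

  cmp <- config$compartments
  ecUp <- filterTrajectory(trajUp, annotation, cmp$extracellular)
  mtDown <- filterTrajectory(trajDown, annotation, cmp$mitochondrion)

  background <- intersect(rownames(se),
                          unique(annotationMapping(annotation)$gene))
  enrichment <- list(
    extracellular_up = .enrichDeviated(ecUp, annotation, background,
                                       config$enrichment),
    mitochondrion_down = .enrichDeviated(mtDown, annotation, background,
                                         config$enrichment))

  graph <- readInteractions(edgeTable, channel = config$network$channel,
                            minScore = config$network$minScore)
  if (!is.null(config$network$removeTerm))
    graph <- removeTermNodes(graph, annotation, config$network$removeTerm)
  nets <- list(extracellular_up = .networkStage(graph, ecUp,
                                                config$network),
               mitochondrion_down = .networkStage(graph, mtDown,
                                                  config$network))

  report <- list(
    provenance = list(seed = config$seed, config_hash = .configHash(config),
                      n_genes = nrow(se), n_samples = ncol(se)),
    de = lapply(selections, function(s)
      list(up = length(upGenes(s)), down = length(downGenes(s)))),
    trajectory = list(up = countTable(trajUp), down = countTable(trajDown),
                      extracellular_up = countTable(ecUp),
                      mitochondrion_down = countTable(mtDown)),
    enrichment = enrichment,
    network = lapply(nets, function(n) list(
      n_nodes = igraph::vcount(n$graph),
      n_edges = igraph::ecount(n$graph),
      modules = moduleTable(n$modules),
      n_hubs = length(hubGenes(n$hub)),
      chain = n$chain)))

  if (!is.null(config$outdir)) {
    outdir <- config$outdir
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(ds)) writeDataset(ds, file.path(outdir, "synthetic"))
    for (nm in names(report$trajectory))
      .writeTSV(report$trajectory[[nm]],
                file.path(outdir, paste0("trajectory_", nm, ".tsv")))
    for (nm in names(nets)) {
      writeGraphML(nets[[nm]]$graph,
                   file.path(outdir, paste0("network_", nm, ".graphml")))
      .writeTSV(moduleTable(nets[[nm]]$modules),
                file.path(outdir, paste0("modules_", nm, ".tsv")))
    }
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                                null = "null", dataframe = "columns"),
               file.path(outdir, "report.json"))
  }
  report
}
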