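#' Default pipeline configuration
#'
#' All quoted study parameters surfaced with their conventional values: QC
#' bounds 200 / 10000 detected genes, log-normalization to 1e4, k = 5
#' potential ancestors, subcluster fraction threshold > 0.10, edge support
#' threshold >= 10.
#'
#' @return nested named list of defaults; see [validateConfig()].
#' @export
defaultPipelineConfig <- function() {
  list(
    stages = c("0w", "2w", "5w", "8w", "11w"),
    qc = list(minGenes = 200L, maxGenes = 10000L),
    normalize = list(scaleFactor = 1e4),
    score = list(geneSetPath = NULL, nBins = 24L, nCtrl = 100L, seed = 0L,
                 restrictType = "CM"),
    ancestry = list(k = 5L, minFrac = 0.10, minSupport = 10L, genes = "hvg",
                    nHVG = 500L, consistency = "lenient"),
    trend = list(genes = c("Mfn1", "Hspa9"), window = 51L,
                 epsilonFrac = 0.05),
    coupling = list(subtypes = c("CM2", "CM3")),
    simulate = list(enabled = TRUE, nGenes = 1200L, nCellsPerStage = 3333L,
                    conversionCells = 60L, seed = 1L))
}

mergeConfig <- function(defaults, user, path = character(0)) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) stop("config section '", paste(path, collapse = "$"),
                           "' must be a mapping")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ",
         paste(paste(c(path, ""), collapse = "$"), unknown, sep = "",
               collapse = ", "))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      mergeConfig(defaults[[k]], user[[k]], c(path, k))
    } else user[[k]]
  }
  defaults
}

#' Validate and default a pipeline configuration
#'
#' Accepts a YAML file path, a nested list, or NULL (pure defaults). Unknown
#' keys are an error (no silent typos); numeric parameters are range-checked.
#'
#' @param x path to a YAML file, a list, or NULL.
#' @return the merged, validated configuration list.
#' @export
validateConfig <- function(x = NULL) {
  user <- if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    yaml::read_yaml(x)
  } else x
  cfg <- mergeConfig(defaultPipelineConfig(), user)
  bad <- character(0)
  chk <- function(cond, msg) if (!cond) bad <<- c(bad, msg)
  chk(length(cfg$stages) >= 1 && !anyDuplicated(cfg$stages),
      "stages must be unique")
  chk(cfg$qc$minGenes >= 0, "qc$minGenes must be >= 0")
  chk(cfg$qc$maxGenes >= cfg$qc$minGenes, "qc$maxGenes must be >= qc$minGenes")
  chk(cfg$normalize$scaleFactor > 0, "normalize$scaleFactor must be > 0")
  chk(cfg$score$nBins >= 1, "score$nBins must be >= 1")
  chk(cfg$score$nCtrl >= 1, "score$nCtrl must be >= 1")
  chk(cfg$ancestry$k >= 1, "ancestry$k must be >= 1")
  chk(cfg$ancestry$minFrac >= 0 && cfg$ancestry$minFrac < 1,
      "ancestry$minFrac must lie in [0, 1)")
  chk(cfg$ancestry$minSupport >= 0, "ancestry$minSupport must be >= 0")
  chk(cfg$ancestry$consistency %in% c("lenient", "strict"),
      "ancestry$consistency must be 'lenient' or 'strict'")
  chk(cfg$ancestry$genes %in% c("hvg", "all"),
      "ancestry$genes must be 'hvg' or 'all'")
  chk(cfg$simulate$conversionCells >= 0,
      "simulate$conversionCells must be >= 0")
  chk(cfg$trend$window >= 1, "trend$window must be >= 1")
  chk(cfg$trend$epsilonFrac >= 0, "trend$epsilonFrac must be >= 0")
  if (length(bad)) stop("invalid configuration:\n  ",
                        paste(bad, collapse = "\n  "))
  cfg
}

#' Run the full pipeline
#'
#' simulate (or take supplied data) -> QC -> log-normalize -> module score ->
#' per-stage summaries -> ancestor-voting conversion graph -> subcluster
#' selection -> stage ordering -> proportion/score coupling -> gene trends ->
#' report. Deterministic for a fixed seed and configuration.
#'
#' @param config a configuration accepted by [validateConfig()].
#' @param sce optional input SingleCellExperiment (with stage / subtype /
#'   major_type columns); when NULL and simulation is enabled, a synthetic
#'   cohort is generated.
#' @param truth optional [GroundTruth-class]; when present, planted-edge
#'   recovery is evaluated and embedded in the report.
#' @param seed overrides the configured simulation seed.
#' @param outDir optional directory for report.json / report.md, scores.tsv,
#'   proportions.tsv, edges.tsv and manifest.json.
#' @return the report list, invisibly (with `$recovery` when truth given).
#' @export
runPipeline <- function(config = NULL, sce = NULL, truth = NULL, seed = NULL,
                        outDir = NULL) {
  cfg <- validateConfig(config)
  if (!is.null(seed)) cfg$simulate$seed <- as.integer(seed)
  if (is.null(sce)) {
    if (!isTRUE(cfg$simulate$enabled)) {
      stop("no input data and simulation disabled in config")
    }
    plan <- if (length(cfg$stages) == 5L) {
      defaultConversionPlan(cfg$stages, n = cfg$simulate$conversionCells)
    } else NULL
    sim <- simulateCohort(simConfig(nGenes = cfg$simulate$nGenes,
                                    nCellsPerStage = cfg$simulate$nCellsPerStage,
                                    stages = cfg$stages,
                                    conversionPlan = plan,
                                    seed = cfg$simulate$seed))
    sce <- sim$sce
    if (is.null(truth)) truth <- sim$truth
  }
  S4Vectors::metadata(sce)$stages <- cfg$stages

  sce <- qcFilter(sce, cfg$qc$minGenes, cfg$qc$maxGenes)
  qc <- S4Vectors::metadata(sce)$qcReport
  sce <- logNormalize(sce, cfg$normalize$scaleFactor)

  set <- if (is.null(cfg$score$geneSetPath)) mamGeneSet()
    else readGeneSet(cfg$score$geneSetPath)
  sres <- moduleScore(sce, set, nBins = cfg$score$nBins,
                      nCtrl = cfg$score$nCtrl, seed = cfg$score$seed)
  stageSummary <- stageScoreSummary(sres, sce,
                                    restrictType = cfg$score$restrictType)
  props <- stageProportions(sce, restrict = "CM")
  coupling <- scoreProportionCorrelation(stageSummary, props,
                                         subtypes = cfg$coupling$subtypes)

  graph <- ancestryGraph(sce, k = cfg$ancestry$k, genes = cfg$ancestry$genes,
                         nHVG = cfg$ancestry$nHVG)
  selection <- selectTrajectorySubclusters(graph, props,
                                           minFrac = cfg$ancestry$minFrac,
                                           minSupport = cfg$ancestry$minSupport,
                                           consistency = cfg$ancestry$consistency)
  layering <- stageOrderGraph(selection)

  trendGenes <- intersect(cfg$trend$genes, rownames(sce))
  trends <- lapply(stats::setNames(trendGenes, trendGenes), function(g) {
    orderedGeneTrend(sce, g, window = min(cfg$trend$window, ncol(sce)),
                     scores = sres, epsilonFrac = cfg$trend$epsilonFrac)
  })

  report <- buildReport(qc = qc, stageSummary = stageSummary,
                        proportions = props, coupling = coupling,
                        selection = selection, trends = trends,
                        layering = layering, config = cfg,
                        seed = cfg$simulate$seed, outDir = outDir)
  if (!is.null(truth)) {
    report$recovery <- evaluateEdgeRecovery(selection, truth)
  }
  if (!is.null(outDir)) {
    write.table(data.frame(cell_id = names(scores(sres)),
                           score = unname(scores(sres))),
                file.path(outDir, "scores.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(props, file.path(outDir, "proportions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(selection$edges, file.path(outDir, "edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest <- list(seed = cfg$simulate$seed, configHash = hashObject(cfg),
                     inputDigest = hashObject(list(dim = dim(sce),
                                                   total = sum(as.numeric(sce$total_counts)))),
                     package = as.character(packageVersion("mamshift")))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
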