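#' Per-stage subtype proportions
#'
#' @param sce SingleCellExperiment with stage / subtype / major_type columns.
#' @param restrict major type to restrict to (default "CM": fractions of CM
#'   cells); NULL for all cells.
#' @return data.frame(stage, subtype, fraction, nStage) in configured stage
#'   order; subtypes absent at a stage are reported with fraction 0. A stage
#'   with no cells yields NA fractions and a warning.
#' @export
stageProportions <- function(sce, restrict = "CM") {
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  if (!is.null(restrict)) cd <- cd[cd$major_type == restrict, , drop = FALSE]
  stages <- stageLevels(sce)
  subtypes <- sort(unique(cd$subtype))
  out <- do.call(rbind, lapply(stages, function(st) {
    v <- cd$subtype[cd$stage == st]
    n <- length(v)
    if (n == 0) {
      warning("stage ", st, " has no ",
              if (is.null(restrict)) "cells" else paste(restrict, "cells"))
      return(data.frame(stage = st, subtype = subtypes, fraction = NA_real_,
                        nStage = 0L))
    }
    tab <- table(factor(v, levels = subtypes))
    data.frame(stage = st, subtype = subtypes,
               fraction = as.numeric(tab) / n, nStage = n)
  }))
  rownames(out) <- NULL
  out
}

#' Correlation between stage-mean module score and subtype proportions
#'
#' Spearman correlation across stages between the stage-mean score and the
#' summed fraction of the named subtypes. With five stages the sample size is
#' tiny; a small-n caveat flag is always set for n <= 5 and no p-value is
#' reported.
#'
#' @param stageSummary output of [stageScoreSummary()].
#' @param props output of [stageProportions()].
#' @param subtypes subtypes whose fractions are summed (default CM2 + CM3).
#' @return list(rho, n, caveat, stages, scoreMeans, fractions); `rho` is NA
#'   with a note when either vector is constant (undefined correlation).
#' @export
scoreProportionCorrelation <- function(stageSummary, props,
                                       subtypes = c("CM2", "CM3")) {
  fr <- vapply(stageSummary$stage, function(st) {
    sum(props$fraction[props$stage == st & props$subtype %in% subtypes])
  }, numeric(1))
  ok <- !is.na(stageSummary$mean) & !is.na(fr)
  sc <- stageSummary$mean[ok]
  fr <- fr[ok]
  st <- stageSummary$stage[ok]
  if (length(sc) < 3) stop("need at least 3 stages with both quantities")
  note <- NULL
  if (length(unique(sc)) < 2 || length(unique(fr)) < 2) {
    rho <- NA_real_
    note <- "undefined: constant input vector"
  } else {
    rho <- cor(sc, fr, method = "spearman")
  }
  list(rho = rho, n = length(sc), caveat = length(sc) <= 5, stages = st,
       scoreMeans = stats::setNames(sc, st), fractions = stats::setNames(fr, st),
       note = note)
}

# Direction of a stage-mean profile from the sign pattern of first
# differences, with dead zone eps = epsilonFrac * dynamic range.
classifyDirection <- function(stageMeans, epsilonFrac = 0.05) {
  d <- diff(stageMeans)
  eps <- epsilonFrac * (max(stageMeans) - min(stageMeans))
  s <- ifelse(d > eps, 1L, ifelse(d < -eps, -1L, 0L))
  nz <- s[s != 0]
  if (!length(nz)) return("flat")
  if (all(nz > 0)) return("rising")
  if (all(nz < 0)) return("falling")
  firstNeg <- which(s < 0)[1]
  if (nz[1] > 0 && !any(s[firstNeg:length(s)] > 0)) return("rise-then-fall")
  "mixed"
}

#' Gene expression trend along an ordering of cells
#'
#' Orders cells (default: stage order, within stage by decreasing module
#' score when scores are supplied, else by cell id -- a deterministic
#' stand-in for a pseudotime), applies rolling-mean smoothing, and classifies
#' the direction from the sign pattern of the first differences of
#' stage-level means with a dead zone of `epsilonFrac` of the dynamic range.
#'
#' @param sce SingleCellExperiment with `logcounts`.
#' @param gene gene id.
#' @param order optional named numeric: cell id -> position (smaller =
#'   earlier); overrides the default ordering.
#' @param window rolling-mean window (cells); 1 returns the raw ordered
#'   values. Edge windows are partial, so smoothed values are always finite.
#' @param restrictType major type to restrict to (default "CM"); NULL = all.
#' @param scores optional [ModuleScoreResult-class] for within-stage ordering.
#' @param epsilonFrac dead-zone fraction for direction calls.
#' @return list of class "TrendResult": gene, cellIds, positions, values,
#'   smoothed, stageMeans, direction, params.
#' @export
orderedGeneTrend <- function(sce, gene, order = NULL, window = 51L,
                             restrictType = "CM", scores = NULL,
                             epsilonFrac = 0.05) {
  m <- .exprMatrix(sce)
  if (!gene %in% rownames(m)) stop("gene '", gene, "' not present")
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  if (!is.null(restrictType)) cd <- cd[cd$major_type == restrictType, ,
                                       drop = FALSE]
  if (!nrow(cd)) stop("no cells after type restriction")
  if (window < 1 || window > nrow(cd)) {
    stop("window must lie in [1, number of cells used]")
  }
  stages <- stageLevels(sce)
  if (is.null(order)) {
    within <- if (!is.null(scores)) -scores(scores)[cd$cell_id] else cd$cell_id
    ord <- base::order(match(cd$stage, stages), within)
  } else {
    if (!all(cd$cell_id %in% names(order))) {
      stop("`order` must cover every cell used")
    }
    ord <- base::order(order[cd$cell_id])
  }
  cd <- cd[ord, , drop = FALSE]
  vals <- m[gene, cd$cell_id]
  smoothed <- as.numeric(zoo::rollapply(zoo::zoo(vals), width = window,
                                        FUN = mean, partial = TRUE))
  presentStages <- stages[stages %in% cd$stage]
  stageMeans <- vapply(presentStages,
                       function(st) mean(vals[cd$stage == st]), numeric(1))
  structure(list(gene = gene, cellIds = cd$cell_id,
                 positions = seq_along(vals), values = unname(vals),
                 smoothed = smoothed, stageMeans = stageMeans,
                 direction = classifyDirection(stageMeans, epsilonFrac),
                 params = list(window = as.integer(window),
                               epsilonFrac = epsilonFrac,
                               restrictType = restrictType)),
            class = "TrendResult")
}

#' @exportS3Method base::print
print.TrendResult <- function(x, ...) {
  cat("TrendResult for", x$gene, "over", length(x$values), "cells:",
      x$direction, "\n")
  print(round(x$stageMeans, 4))
  invisible(x)
}

#' Assemble a run report
#'
#' Collects the pipeline stage outputs into one deterministic structure
#' (no timestamps) and optionally writes report.json and report.md. Stages
#' not supplied are flagged "not run".
#'
#' @param qc QC report list; @param stageSummary stage score table;
#' @param proportions stage proportion table; @param coupling
#'   score/proportion correlation; @param selection subcluster selection;
#' @param trends named list of TrendResult; @param layering stage ordering;
#' @param config,seed provenance to embed; @param outDir optional output
#'   directory.
#' @return the report list, invisibly.
#' @export
buildReport <- function(qc = NULL, stageSummary = NULL, proportions = NULL,
                        coupling = NULL, selection = NULL, trends = NULL,
                        layering = NULL, config = NULL, seed = NULL,
                        outDir = NULL) {
  notRun <- list(status = "not run")
  section <- function(x, f = identity) if (is.null(x)) notRun else f(x)
  report <- list(
    package = as.character(packageVersion("mamshift")),
    rVersion = R.version.string,
    seed = seed,
    configHash = if (!is.null(config)) hashObject(config) else NULL,
    config = config,
    qc = section(qc),
    stageScores = section(stageSummary),
    proportions = section(proportions),
    coupling = section(coupling, function(x)
      x[c("rho", "n", "caveat", "scoreMeans", "fractions", "note")]),
    conversion = section(selection, function(x)
      list(retainedSubtypes = x$subtypes, edges = x$edges,
           subtypeAudit = x$subtypeAudit, params = x$params)),
    stageOrdering = section(layering),
    trends = section(trends, function(tl)
      lapply(tl, function(t) list(gene = t$gene, direction = t$direction,
                                  stageMeans = as.list(t$stageMeans)))))
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         null = "null", force = TRUE)
    writeLines(renderReportMd(report), file.path(outDir, "report.md"))
  }
  invisible(report)
}

renderReportMd <- function(report) {
  fmt <- function(df) {
    if (is.list(df) && !is.data.frame(df)) return("(not run)")
    txt <- utils::capture.output(print(df, row.names = FALSE))
    paste0("    ", txt)
  }
  c("# mamshift run report", "",
    paste0("- package: ", report$package),
    paste0("- seed: ", if (is.null(report$seed)) "NA" else report$seed),
    paste0("- config hash: ",
           if (is.null(report$configHash)) "NA" else report$configHash),
    "", "## QC",
    if (is.list(report$qc) && !is.null(report$qc$nInput)) {
      paste0("- retained ", report$qc$nRetained, "/", report$qc$nInput,
             " cells (", report$qc$removedLow, " below, ",
             report$qc$removedHigh, " above bounds)")
    } else "(not run)",
    "", "## Stage module scores", fmt(report$stageScores),
    "", "## Score/proportion coupling",
    if (is.list(report$coupling) && !is.null(report$coupling$rho)) {
      paste0("- Spearman rho = ", signif(report$coupling$rho, 4), " over n = ",
             report$coupling$n, " stages",
             if (isTRUE(report$coupling$caveat)) " (small-n caveat)" else "")
    } else "(not run)",
    "", "## Conversion edges",
    if (is.list(report$conversion) && !is.null(report$conversion$edges)) {
      fmt(report$conversion$edges)
    } else "(not run)",
    "", "## Gene trends",
    if (is.list(report$trends) && is.null(report$trends$status)) {
      vapply(report$trends, function(t)
        paste0("- ", t$gene, ": ", t$direction), character(1))
    } else "(not run)")
}
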