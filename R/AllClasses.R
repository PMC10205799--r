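#' GeneSet: a named, ordered set of gene identifiers
#'
#' Container for a gene program to be scored per cell. The packaged default is
#' the 13-gene mitochondria-associated ER membrane (MAM) program; see
#' [mamGeneSet()].
#'
#' @slot name single character, the set's name.
#' @slot genes character vector of unique gene identifiers.
#' @export
setClass("GeneSet", representation(name = "character", genes = "character"))

setValidity("GeneSet", function(object) {
  if (length(object@name) != 1L) return("name must be a single string")
  if (length(object@genes) == 0L) return("gene set is empty")
  if (anyDuplicated(object@genes)) return("duplicate gene ids in set")
  TRUE
})

#' Construct a GeneSet
#' @param name set name.
#' @param genes character vector of unique gene ids.
#' @return A [GeneSet-class] object.
#' @examples geneSet("demo", c("Mfn1", "Hspa9"))
#' @export
geneSet <- function(name, genes) new("GeneSet", name = name, genes = as.character(genes))

#' @describeIn GeneSet-class gene identifiers in the set
#' @param x,object a `GeneSet`.
#' @export
setMethod("names", "GeneSet", function(x) x@name)

#' @rdname GeneSet-class
#' @export
setGeneric("setGenes", function(x) standardGeneric("setGenes"))

#' @rdname GeneSet-class
#' @export
setMethod("setGenes", "GeneSet", function(x) x@genes)

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet '", object@name, "' with ", length(object@genes), " genes: ",
      paste(head(object@genes, 6), collapse = ", "),
      if (length(object@genes) > 6) ", ..." else "", "\n", sep = "")
})

#' SimConfig: parameters of the synthetic staged cohort
#'
#' Describes the study conditions emulated by [simulateCohort()]: five
#' post-surgery stages, major cardiac cell types with 11 cardiomyocyte (CM)
#' subtypes, a CM-restricted MAM expression program peaking at 2 weeks, planted
#' subtype conversion events between consecutive stages, and per-gene declining
#' trends for designated genes. Counts follow a gamma-Poisson (negative
#' binomial) model.
#'
#' @slot nGenes number of genes in the simulated universe.
#' @slot nCellsPerStage cells generated per stage.
#' @slot stages ordered stage labels.
#' @slot subtypeSchedule named list: stage -> named proportions over subtypes
#'   (each stage sums to 1).
#' @slot mamGenes [GeneSet-class] planted as the MAM program.
#' @slot mamOffsetByStage named numeric: stage -> log-mean offset applied to
#'   MAM genes in CM cells.
#' @slot geneTrendOffsets named list: gene -> (stage -> log-mean offset); for
#'   these genes the trend offset replaces the MAM stage offset.
#' @slot conversionPlan data.frame(ancestor, descendant, transition, n):
#'   planted ancestor->descendant conversion events.
#' @slot baselineMean,dispersion NB baseline mean scale and dispersion
#'   (size = 1/dispersion).
#' @slot librarySizeRange min/max target counts per cell.
#' @slot ancestorWeight convex weight of the ancestor cell's log-mean profile
#'   in a converting descendant (0 = no resemblance).
#' @slot cellNoiseSd sd of per-cell log-mean jitter.
#' @slot majorEffect,subtypeEffect log-mean elevation of major-type and subtype
#'   marker genes.
#' @slot mamBaseCM constant log-mean elevation of MAM genes in CM cells
#'   (stage-independent).
#' @slot assignMode "rounding" (largest-remainder, deterministic composition)
#'   or "multinomial".
#' @slot seed integer RNG seed.
#' @export
setClass("SimConfig", representation(
  nGenes = "integer", nCellsPerStage = "integer", stages = "character",
  subtypeSchedule = "list", mamGenes = "GeneSet",
  mamOffsetByStage = "numeric", geneTrendOffsets = "list",
  conversionPlan = "data.frame", baselineMean = "numeric",
  dispersion = "numeric", librarySizeRange = "numeric",
  ancestorWeight = "numeric", cellNoiseSd = "numeric",
  majorEffect = "numeric", subtypeEffect = "numeric", mamBaseCM = "numeric",
  assignMode = "character", seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (!setequal(names(object@subtypeSchedule), object@stages))
    msgs <- c(msgs, "subtypeSchedule stages must match `stages`")
  for (st in names(object@subtypeSchedule)) {
    p <- object@subtypeSchedule[[st]]
    if (abs(sum(p) - 1) > 1e-9)
      msgs <- c(msgs, sprintf("proportions at stage %s sum to %.12f, not 1", st, sum(p)))
    if (any(p < 0)) msgs <- c(msgs, sprintf("negative proportion at stage %s", st))
  }
  if (!setequal(names(object@mamOffsetByStage), object@stages))
    msgs <- c(msgs, "mamOffsetByStage must name every stage")
  cp <- object@conversionPlan
  if (nrow(cp)) {
    for (i in seq_len(nrow(cp))) {
      tr <- strsplit(cp$transition[i], "->", fixed = TRUE)[[1]]
      if (length(tr) != 2L || !all(tr %in% object@stages) ||
          match(tr[2], object@stages) != match(tr[1], object@stages) + 1L) {
        msgs <- c(msgs, sprintf("conversion transition '%s' is not between adjacent stages",
                                cp$transition[i]))
        next
      }
      if (!cp$ancestor[i] %in% names(object@subtypeSchedule[[tr[1]]]) ||
          object@subtypeSchedule[[tr[1]]][cp$ancestor[i]] <= 0)
        msgs <- c(msgs, sprintf("ancestor subtype %s absent at stage %s", cp$ancestor[i], tr[1]))
      if (!cp$descendant[i] %in% names(object@subtypeSchedule[[tr[2]]]) ||
          object@subtypeSchedule[[tr[2]]][cp$descendant[i]] <= 0)
        msgs <- c(msgs, sprintf("descendant subtype %s absent at stage %s", cp$descendant[i], tr[2]))
    }
  }
  if (object@baselineMean <= 0) msgs <- c(msgs, "baselineMean must be > 0")
  if (object@dispersion <= 0) msgs <- c(msgs, "dispersion must be > 0")
  if (length(object@librarySizeRange) != 2L ||
      any(object@librarySizeRange <= 0) ||
      diff(object@librarySizeRange) < 0)
    msgs <- c(msgs, "librarySizeRange must be (min, max) with 0 < min <= max")
  if (object@ancestorWeight < 0 || object@ancestorWeight > 1)
    msgs <- c(msgs, "ancestorWeight must lie in [0, 1]")
  if (!object@assignMode %in% c("rounding", "multinomial"))
    msgs <- c(msgs, "assignMode must be 'rounding' or 'multinomial'")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nGenes, "genes,", object@nCellsPerStage,
      "cells/stage over", length(object@stages), "stages (",
      paste(object@stages, collapse = ", "), ")\n")
  cat("  planted conversions:", nrow(object@conversionPlan),
      " | MAM offsets:", paste(sprintf("%s=%.2g", names(object@mamOffsetByStage),
                                       object@mamOffsetByStage), collapse = " "), "\n")
  cat("  seed:", object@seed, " assignMode:", object@assignMode, "\n")
})

#' GroundTruth: ledger of planted structure in a synthetic cohort
#'
#' @slot conversions data.frame(descendant, ancestor, transition,
#'   ancestorSubtype, descendantSubtype): one row per converting cell, mapping
#'   it to its assigned ancestor cell in the previous stage.
#' @slot trueProportions data.frame(stage, subtype, proportion) of the schedule.
#' @slot trueMamOffsets named numeric, stage -> planted MAM log-offset.
#' @slot plantedEdges data.frame(ancestor, descendant, transition, n).
#' @export
setClass("GroundTruth", representation(
  conversions = "data.frame", trueProportions = "data.frame",
  trueMamOffsets = "numeric", plantedEdges = "data.frame"))

setValidity("GroundTruth", function(object) {
  pe <- object@plantedEdges
  cv <- object@conversions
  if (nrow(pe)) {
    key <- paste(cv$ancestorSubtype, cv$descendantSubtype, cv$transition)
    tab <- table(key)
    want <- paste(pe$ancestor, pe$descendant, pe$transition)
    got <- as.integer(tab[want]); got[is.na(got)] <- 0L
    if (!all(got == pe$n))
      return("plantedEdges counts do not match per-cell conversion rows")
  }
  TRUE
})

#' @rdname GroundTruth-class
#' @param x a `GroundTruth`.
#' @export
setGeneric("plantedEdges", function(x) standardGeneric("plantedEdges"))

#' @rdname GroundTruth-class
#' @export
setMethod("plantedEdges", "GroundTruth", function(x) x@plantedEdges)

#' @rdname GroundTruth-class
#' @export
setGeneric("cellAncestors", function(x) standardGeneric("cellAncestors"))

#' @rdname GroundTruth-class
#' @export
setMethod("cellAncestors", "GroundTruth", function(x) {
  stats::setNames(x@conversions$ancestor, x@conversions$descendant)
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@conversions), "converting cells over",
      nrow(object@plantedEdges), "planted edges\n")
})

#' ModuleScoreResult: per-cell gene-set module scores
#'
#' Result of [moduleScore()]: per-cell mean expression of the set genes minus
#' the mean of expression-bin-matched control genes.
#'
#' @slot scores named numeric, one score per cell.
#' @slot geneSetName name of the scored set.
#' @slot genesUsed,genesMissing partition of the set's genes by presence in the
#'   matrix.
#' @slot params list(nBins, nCtrl, seed).
#' @export
setClass("ModuleScoreResult", representation(
  scores = "numeric", geneSetName = "character",
  genesUsed = "character", genesMissing = "character", params = "list"))

setValidity("ModuleScoreResult", function(object) {
  if (is.null(names(object@scores))) return("scores must be named by cell id")
  TRUE
})

#' @rdname ModuleScoreResult-class
#' @param x a `ModuleScoreResult`.
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname ModuleScoreResult-class
#' @export
setMethod("scores", "ModuleScoreResult", function(x) x@scores)

setMethod("show", "ModuleScoreResult", function(object) {
  cat("ModuleScoreResult for set '", object@geneSetName, "': ",
      length(object@scores), " cells, ", length(object@genesUsed), " genes used",
      if (length(object@genesMissing))
        paste0(" (", length(object@genesMissing), " missing)") else "",
      "\n  score range [", sprintf("%.3f", min(object@scores)), ", ",
      sprintf("%.3f", max(object@scores)), "]\n", sep = "")
})

#' ConversionGraph: inferred subtype-to-subtype transitions across stages
#'
#' Directed edges between subtypes over adjacent stage transitions, weighted by
#' the number of current-stage cells whose ancestor vote supports them. Built
#' by [conversionMatrix()] / [ancestryGraph()]; annotated and filtered by
#' [selectTrajectorySubclusters()].
#'
#' @slot edges data.frame(ancestor, descendant, transition, support,
#'   voteFraction) and, after selection, (consistent, retained, reason).
#' @slot assignments data.frame per current-stage cell: cellId, transition,
#'   subtype, votedAncestorSubtype, tally, topAncestors (comma-joined ids).
#' @slot params list(k, genes, stages, ...).
#' @export
setClass("ConversionGraph", representation(
  edges = "data.frame", assignments = "data.frame", params = "list"))

setValidity("ConversionGraph", function(object) {
  e <- object@edges
  if (nrow(e)) {
    if (any(e$support < 0)) return("negative edge support")
    if (any(e$voteFraction <= 0 | e$voteFraction > 1))
      return("voteFraction must lie in (0, 1]")
    st <- object@params$stages
    if (!is.null(st)) {
      parts <- strsplit(e$transition, "->", fixed = TRUE)
      ok <- vapply(parts, function(p) length(p) == 2L && all(p %in% st) &&
                     match(p[2], st) == match(p[1], st) + 1L, logical(1))
      if (!all(ok)) return("edge transitions must join adjacent stages")
    }
  }
  TRUE
})

#' @rdname ConversionGraph-class
#' @param x a `ConversionGraph`.
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname ConversionGraph-class
#' @export
setMethod("edges", "ConversionGraph", function(x) x@edges)

setMethod("show", "ConversionGraph", function(object) {
  cat("ConversionGraph:", nrow(object@edges), "edges from",
      nrow(object@assignments), "voted cells (k =", object@params$k, ")\n")
  if (nrow(object@edges)) {
    top <- object@edges[order(-object@edges$support), ]
    print(head(top, 5), row.names = FALSE)
  }
})
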