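# Correlations are rounded to 12 decimals before any ordering so that
# mathematically equal rho values (e.g. duplicated cells) tie exactly and the
# deterministic tie-break by cell id applies, independent of floating-point
# summation order.
.RHO_DIGITS <- 12L

#' Spearman correlation of one cell to every cell of the previous stage
#'
#' Expression values are converted to average ranks over the chosen gene
#' universe, then Pearson-correlated. Previous-stage cells with zero rank
#' variance yield NaN (excluded from top-k selection downstream).
#'
#' @param query named numeric expression vector of the current-stage cell.
#' @param prevMat genes x cells normalized matrix of the previous stage.
#' @param genes gene universe to use (default: intersection of names).
#' @return named numeric vector of Spearman rho, one per previous-stage cell.
#' @export
spearmanToPrevious <- function(query, prevMat, genes = NULL) {
  if (is.null(genes)) genes <- intersect(names(query), rownames(prevMat))
  if (length(genes) < 3) stop("need at least 3 shared genes")
  if (!ncol(prevMat)) stop("previous stage is empty")
  q <- query[genes]
  if (length(unique(q)) < 2) stop("query cell has zero expression variance over the gene universe")
  rq <- rank(q, ties.method = "average")
  rq <- rq - mean(rq)
  R <- rankColumns(prevMat[genes, , drop = FALSE])
  R <- sweep(R, 2, colMeans(R))
  denom <- sqrt(sum(rq^2) * colSums(R^2))
  rho <- as.vector(crossprod(rq, R)) / denom
  round(stats::setNames(rho, colnames(prevMat)), .RHO_DIGITS)
}

#' Top-k potential ancestors of a cell
#'
#' Keeps the k previous-stage cells with the highest correlation; NaN
#' correlations (zero-variance cells) are excluded. Ties at the cutoff are
#' broken by cell id lexicographic order. If fewer than k cells are
#' available, all are used with a warning.
#'
#' @param corr named correlation vector from [spearmanToPrevious()].
#' @param k number of potential ancestors (default 5).
#' @return list(cells, rho): ancestor cell ids and their correlations, sorted
#'   descending.
#' @export
topKAncestors <- function(corr, k = 5L) {
  stopifnot(k >= 1)
  corr <- corr[!is.na(corr)]
  if (!length(corr)) stop("all correlations are undefined (NaN)")
  if (length(corr) < k) {
    warning("previous stage has only ", length(corr),
            " usable cells; using all of them")
    k <- length(corr)
  }
  ord <- order(-corr, names(corr))[seq_len(k)]
  list(cells = names(corr)[ord], rho = unname(corr[ord]))
}

#' Vote an ancestor subtype from the top-k ancestors
#'
#' Plurality vote over the subtype labels of the potential ancestors; ties
#' are broken first by the larger summed correlation among tied subtypes,
#' then lexicographically.
#'
#' @param topk list(cells, rho) from [topKAncestors()].
#' @param prevLabels named character: previous-stage cell id -> subtype.
#' @return list(subtype, tally, k, voteFraction).
#' @export
voteAncestorSubtype <- function(topk, prevLabels) {
  labs <- prevLabels[topk$cells]
  if (anyNA(labs)) stop("unlabeled ancestor cell(s): ",
                        paste(topk$cells[is.na(labs)], collapse = ", "))
  tab <- table(labs)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1) {
    sums <- vapply(top, function(s) sum(topk$rho[labs == s]), numeric(1))
    sums <- round(sums, .RHO_DIGITS)
    top <- top[sums == max(sums)]
    top <- sort(top)[1]
  }
  k <- length(topk$cells)
  list(subtype = top, tally = as.integer(tab[[top]]), k = k,
       voteFraction = as.integer(tab[[top]]) / k)
}

# Gene universe for cross-stage correlation: HVGs of the combined two-stage
# matrix ("hvg", default) or all genes ("all").
.ancestryGenes <- function(m, curCols, prevCols, genes, nHVG) {
  if (identical(genes, "all")) return(rownames(m))
  if (identical(genes, "hvg")) {
    sub <- m[, c(prevCols, curCols), drop = FALSE]
    return(selectHVGs(sub, nTop = min(nHVG, nrow(m))))
  }
  ids <- intersect(genes, rownames(m))
  if (length(ids) < 3) stop("fewer than 3 of the requested genes are present")
  ids
}

#' Conversion edges for one stage transition
#'
#' For every current-stage cell of the query type (CM by default), computes
#' Spearman correlations to all previous-stage cells over the chosen gene
#' universe, takes the top-k as potential ancestors, and votes their subtype.
#' Edge support(A -> B) is the number of current-stage cells of subtype B
#' whose voted ancestor subtype is A; supports over all edges sum to the
#' number of current-stage cells with a valid vote.
#'
#' @param sce SingleCellExperiment with `logcounts`, stage / subtype /
#'   major_type columns.
#' @param from,to adjacent stage labels (ancestors in `from`).
#' @param k potential ancestors per cell.
#' @param genes "hvg" (HVGs of the combined two-stage matrix), "all", or an
#'   explicit gene id vector.
#' @param nHVG HVG count when `genes = "hvg"`.
#' @param queryType major type of current-stage cells to vote for (default
#'   "CM", mirroring the restriction to CM subclusters); the ancestor pool is
#'   all previous-stage cells.
#' @return a [ConversionGraph-class] for this transition.
#' @export
conversionMatrix <- function(sce, from, to, k = 5L, genes = "hvg",
                             nHVG = 500L, queryType = "CM") {
  stages <- stageLevels(sce)
  stopifnot(from %in% stages, to %in% stages)
  if (match(to, stages) != match(from, stages) + 1L) {
    stop("'", from, "' -> '", to, "' is not an adjacent stage transition")
  }
  m <- .exprMatrix(sce)
  prevCols <- which(sce$stage == from)
  curCols <- if (is.null(queryType)) which(sce$stage == to)
    else which(sce$stage == to & sce$major_type == queryType)
  if (!length(prevCols)) stop("previous stage '", from, "' is empty")
  if (!length(curCols)) stop("no query cells at stage '", to, "'")
  universe <- .ancestryGenes(m, curCols, prevCols, genes, nHVG)
  tr <- transitionLabel(from, to)

  prevR <- rankColumns(m[universe, prevCols, drop = FALSE])
  prevR <- sweep(prevR, 2, colMeans(prevR))
  prevNorm <- sqrt(colSums(prevR^2))
  curR <- rankColumns(m[universe, curCols, drop = FALSE])
  curR <- sweep(curR, 2, colMeans(curR))
  curNorm <- sqrt(colSums(curR^2))
  rho <- crossprod(curR, prevR) / outer(curNorm, prevNorm)
  rho <- round(rho, .RHO_DIGITS)

  prevIds <- colnames(m)[prevCols]
  prevLabels <- stats::setNames(as.character(sce$subtype)[prevCols], prevIds)
  curIds <- colnames(m)[curCols]
  curSub <- as.character(sce$subtype)[curCols]

  rows <- vector("list", length(curIds))
  nInvalid <- 0L
  for (i in seq_along(curIds)) {
    r <- stats::setNames(rho[i, ], prevIds)
    r <- r[!is.na(r)]
    if (!length(r) || curNorm[i] == 0) {
      nInvalid <- nInvalid + 1L
      next
    }
    kk <- min(k, length(r))
    ord <- order(-r, names(r))[seq_len(kk)]
    topk <- list(cells = names(r)[ord], rho = unname(r[ord]))
    v <- voteAncestorSubtype(topk, prevLabels)
    rows[[i]] <- data.frame(
      cellId = curIds[i], transition = tr, subtype = curSub[i],
      votedAncestorSubtype = v$subtype, tally = v$tally, k = v$k,
      voteFraction = v$voteFraction,
      topAncestors = paste(topk$cells, collapse = ","))
  }
  assignments <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(assignments)) {
    stop("no valid ancestor votes at transition ", tr)
  }
  agg <- stats::aggregate(
    cbind(support = rep(1L, nrow(assignments)),
          voteFraction = assignments$voteFraction),
    by = list(ancestor = assignments$votedAncestorSubtype,
              descendant = assignments$subtype),
    FUN = sum)
  edgesDf <- data.frame(ancestor = agg$ancestor, descendant = agg$descendant,
                        transition = tr, support = as.integer(agg$support),
                        voteFraction = agg$voteFraction / agg$support)
  edgesDf <- edgesDf[order(edgesDf$ancestor, edgesDf$descendant), ,
                     drop = FALSE]
  rownames(edgesDf) <- NULL
  new("ConversionGraph", edges = edgesDf, assignments = assignments,
      params = list(k = as.integer(k),
                    genes = if (is.character(genes) && length(genes) == 1)
                      genes else "custom",
                    nGenesUsed = length(universe), stages = stages,
                    method = "spearman", nInvalid = nInvalid))
}

#' Conversion graph over all adjacent stage transitions
#'
#' Runs [conversionMatrix()] for every consecutive stage pair and combines
#' the edge tables and per-cell assignments into one graph.
#'
#' @inheritParams conversionMatrix
#' @return a [ConversionGraph-class].
#' @export
ancestryGraph <- function(sce, k = 5L, genes = "hvg", nHVG = 500L,
                          queryType = "CM") {
  stages <- stageLevels(sce)
  if (length(stages) < 2) stop("need at least two stages")
  parts <- lapply(seq_len(length(stages) - 1L), function(i) {
    conversionMatrix(sce, stages[i], stages[i + 1L], k = k, genes = genes,
                     nHVG = nHVG, queryType = queryType)
  })
  edgesDf <- do.call(rbind, lapply(parts, edges))
  assignments <- do.call(rbind, lapply(parts, function(p) p@assignments))
  nInvalid <- sum(vapply(parts, function(p) p@params$nInvalid, integer(1)))
  new("ConversionGraph", edges = edgesDf, assignments = assignments,
      params = list(k = as.integer(k),
                    genes = if (is.character(genes) && length(genes) == 1)
                      genes else "custom",
                    stages = stages, method = "spearman",
                    nInvalid = nInvalid))
}

# Rule-3 consistency of an edge A -> B over a transition: the conversion
# direction must not conflict with the subtype proportion change.
.edgeConsistent <- function(fracA_from, fracA_to, fracB_from, fracB_to,
                            variant = c("lenient", "strict")) {
  variant <- match.arg(variant)
  if (variant == "strict") return(fracB_to >= fracB_from)
  !(fracB_to < fracB_from && fracA_to > fracA_from)
}

#' Select subclusters and conversion edges for trajectory analysis
#'
#' Applies the three selection rules conjunctively: (1) a subtype is retained
#' iff its CM fraction exceeds `minFrac` at some stage (strict inequality);
#' (2) an edge is retained iff its support is at least `minSupport`; (3) an
#' edge is retained iff its direction does not conflict with the proportion
#' change over its transition -- under the default "lenient" reading,
#' conflict means the descendant's fraction strictly fell while the
#' ancestor's strictly rose; "strict" requires the descendant's fraction to
#' be non-decreasing. Every exclusion is reported with the rules it failed.
#'
#' @param graph a [ConversionGraph-class].
#' @param proportions data.frame(stage, subtype, fraction) from
#'   [stageProportions()]. Subtypes absent from the table count as fraction 0
#'   at every stage.
#' @param minFrac rule-1 threshold (strict >).
#' @param minSupport rule-2 threshold (inclusive >=).
#' @param consistency rule-3 variant, "lenient" (default) or "strict".
#' @return list(subtypes, edges, retained, subtypeAudit): retained subtype
#'   set, the fully annotated edge table (consistent / retained / reason),
#'   the retained subset, and the per-subtype rule-1 audit.
#' @export
selectTrajectorySubclusters <- function(graph, proportions, minFrac = 0.10,
                                        minSupport = 10L,
                                        consistency = c("lenient", "strict")) {
  consistency <- match.arg(consistency)
  e <- edges(graph)
  frac <- function(subtype, stage) {
    v <- proportions$fraction[proportions$subtype == subtype &
                                proportions$stage == stage]
    if (length(v)) v[1] else 0
  }
  nodes <- sort(unique(c(e$ancestor, e$descendant)))
  stages <- unique(proportions$stage)
  maxFrac <- vapply(nodes, function(s)
    max(vapply(stages, function(st) frac(s, st), numeric(1))), numeric(1))
  keepNode <- maxFrac > minFrac
  subtypeAudit <- data.frame(subtype = nodes, maxFraction = maxFrac,
                             retained = keepNode, row.names = NULL)
  if (!any(keepNode)) {
    stop("no subtype exceeds the ", minFrac,
         " fraction threshold at any stage; retained set is empty")
  }
  ann <- e
  ann$consistent <- NA
  ann$retained <- FALSE
  ann$reason <- ""
  for (i in seq_len(nrow(ann))) {
    tr <- strsplit(ann$transition[i], "->", fixed = TRUE)[[1]]
    cons <- .edgeConsistent(frac(ann$ancestor[i], tr[1]),
                            frac(ann$ancestor[i], tr[2]),
                            frac(ann$descendant[i], tr[1]),
                            frac(ann$descendant[i], tr[2]),
                            variant = consistency)
    ann$consistent[i] <- cons
    failed <- character(0)
    if (!keepNode[[ann$ancestor[i]]] || !keepNode[[ann$descendant[i]]]) {
      failed <- c(failed, "rule1_min_fraction")
    }
    if (ann$support[i] < minSupport) failed <- c(failed, "rule2_min_support")
    if (!cons) failed <- c(failed, "rule3_proportion_conflict")
    ann$retained[i] <- !length(failed)
    ann$reason[i] <- if (length(failed)) paste(failed, collapse = ";")
      else "retained"
  }
  list(subtypes = nodes[keepNode], edges = ann,
       retained = ann[ann$retained, , drop = FALSE],
       subtypeAudit = subtypeAudit,
       params = list(minFrac = minFrac, minSupport = as.integer(minSupport),
                     consistency = consistency))
}

#' Topological stage layering of retained conversion edges
#'
#' Collapses parallel edges (same subtype pair over different transitions),
#' drops self edges (persistence, not conversion), and peels the resulting
#' DAG into layers: each layer is the current set of source nodes, sorted.
#' A cycle among distinct subtypes is an error listing the nodes involved.
#'
#' @param x a [ConversionGraph-class], a selection from
#'   [selectTrajectorySubclusters()] (its retained edges are used), or an
#'   edge data.frame with ancestor / descendant columns.
#' @return list of character vectors, ancestors first; empty list for an
#'   empty edge set.
#' @export
stageOrderGraph <- function(x) {
  e <- if (methods::is(x, "ConversionGraph")) edges(x)
    else if (is.list(x) && !is.data.frame(x) && !is.null(x$retained)) x$retained
    else x
  e <- unique(e[, c("ancestor", "descendant")])
  e <- e[e$ancestor != e$descendant, , drop = FALSE]
  if (!nrow(e)) return(list())
  nodes <- sort(unique(c(e$ancestor, e$descendant)))
  layers <- list()
  while (length(nodes)) {
    hasIncoming <- nodes %in% e$descendant
    src <- nodes[!hasIncoming]
    if (!length(src)) {
      stop("conversion edges contain a cycle among: ",
           paste(nodes, collapse = ", "))
    }
    layers[[length(layers) + 1L]] <- sort(src)
    nodes <- setdiff(nodes, src)
    e <- e[!e$ancestor %in% src, , drop = FALSE]
  }
  layers
}

#' Precision and recall of planted conversion edges
#'
#' Compares retained edges with the generator's planted edges on the
#' (ancestor, descendant, transition) key. Self edges encode persistence
#' rather than conversion and are excluded by default.
#'
#' @param selection result of [selectTrajectorySubclusters()] (or an edge
#'   data.frame).
#' @param truth a [GroundTruth-class].
#' @param ignoreSelf drop A -> A edges before comparing.
#' @return list(precision, recall, tp, fp, fn); precision is NaN when no edge
#'   was predicted.
#' @export
evaluateEdgeRecovery <- function(selection, truth, ignoreSelf = TRUE) {
  pred <- if (is.data.frame(selection)) selection else selection$retained
  if (ignoreSelf) pred <- pred[pred$ancestor != pred$descendant, , drop = FALSE]
  key <- function(d) paste(d$ancestor, d$descendant, d$transition)
  p <- unique(key(pred))
  t <- unique(key(plantedEdges(truth)))
  tp <- length(intersect(p, t))
  list(precision = if (length(p)) tp / length(p) else NaN,
       recall = if (length(t)) tp / length(t) else NaN,
       tp = tp, fp = length(p) - tp, fn = length(t) - tp)
}
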