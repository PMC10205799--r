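#' QC-filter cells by detected gene count
#'
#' Removes cells expressing fewer than `minGenes` or more than `maxGenes`
#' genes. The bounds themselves are retained (strict-inequality removal):
#' cells with exactly 200 or exactly 10000 detected genes pass the defaults.
#' The removal tally is stored as `metadata(x)$qcReport`.
#'
#' @param sce a SingleCellExperiment with a `counts` assay; the detected-gene
#'   count is taken from `colData(sce)$n_genes_detected` when present, else
#'   computed.
#' @param minGenes,maxGenes inclusive retention bounds on detected genes.
#' @return the filtered SingleCellExperiment; `metadata(.)$qcReport` lists
#'   nInput, nRetained, removedLow, removedHigh and the thresholds.
#' @examples
#' cohort <- simulateCohort(simConfig(nGenes = 80, nCellsPerStage = 40, seed = 1))
#' filtered <- qcFilter(cohort$sce, minGenes = 10)
#' S4Vectors::metadata(filtered)$qcReport
#' @export
qcFilter <- function(sce, minGenes = 200L, maxGenes = 10000L) {
  stopifnot(minGenes >= 0, maxGenes >= minGenes)
  cd <- SummarizedExperiment::colData(sce)
  detected <- if ("n_genes_detected" %in% colnames(cd)) {
    as.integer(cd$n_genes_detected)
  } else {
    as.integer(Matrix::colSums(SummarizedExperiment::assay(sce, "counts") > 0))
  }
  low <- detected < minGenes
  high <- detected > maxGenes
  keep <- !low & !high
  if (!any(keep)) stop("QC filter removed every cell (bounds ", minGenes,
                       "..", maxGenes, ")")
  out <- sce[, keep]
  if (!"n_genes_detected" %in% colnames(cd)) {
    out$n_genes_detected <- detected[keep]
  }
  S4Vectors::metadata(out)$qcReport <- list(
    nInput = ncol(sce), nRetained = sum(keep),
    removedLow = sum(low), removedHigh = sum(high),
    minGenes = minGenes, maxGenes = maxGenes,
    boundary = "inclusive (strictly < min or > max removed)")
  out
}

#' Log-normalize counts
#'
#' Per-cell library normalization to `scaleFactor` total counts followed by
#' log1p: `log1p(count / cellTotal * scaleFactor)`. Stored as the `logcounts`
#' assay.
#'
#' @param sce SingleCellExperiment with a `counts` assay.
#' @param scaleFactor target per-cell total on the expm1 scale.
#' @return `sce` with a `logcounts` assay and
#'   `metadata(.)$scaleFactor` set.
#' @export
logNormalize <- function(sce, scaleFactor = 1e4) {
  stopifnot(scaleFactor > 0)
  cnt <- SummarizedExperiment::assay(sce, "counts")
  tot <- Matrix::colSums(cnt)
  if (any(tot == 0)) {
    stop("cell(s) with zero total counts: ",
         paste(head(colnames(cnt)[tot == 0], 5), collapse = ", "))
  }
  lc <- log1p(sweep(as.matrix(cnt), 2, tot, `/`) * scaleFactor)
  SummarizedExperiment::assay(sce, "logcounts") <- lc
  S4Vectors::metadata(sce)$scaleFactor <- scaleFactor
  sce
}

# Extract the expression matrix from an SCE (preferring logcounts) or pass a
# plain matrix through.
.exprMatrix <- function(x, assay = "logcounts") {
  if (methods::is(x, "SummarizedExperiment")) {
    if (!assay %in% SummarizedExperiment::assayNames(x)) {
      stop("assay '", assay, "' not found; run logNormalize() first")
    }
    as.matrix(SummarizedExperiment::assay(x, assay))
  } else as.matrix(x)
}

#' Select highly variable genes by clipped standardized variance
#'
#' Ranks genes by the variance of their standardized expression after a
#' degree-2 polynomial mean-variance trend fit on log10 scale; standardized
#' values are clipped at sqrt(n cells). Deterministic; ties broken by gene id.
#'
#' @param x SingleCellExperiment (uses `logcounts`) or a genes x cells matrix.
#' @param nTop number of genes to return (must not exceed the gene count).
#' @return character vector of `nTop` gene ids, highest standardized variance
#'   first.
#' @export
selectHVGs <- function(x, nTop = 2000L) {
  if (nTop <= 0) stop("nTop must be positive")
  m <- .exprMatrix(x)
  if (nTop > nrow(m)) stop("nTop exceeds the number of genes")
  n <- ncol(m)
  mu <- rowMeans(m)
  v <- rowSums((m - mu)^2) / (n - 1)
  fitOn <- v > 0
  ve <- rep(NA_real_, nrow(m))
  if (sum(fitOn) >= 3) {
    lx <- log10(mu[fitOn] + 1e-12)
    fit <- stats::lm(log10(v[fitOn]) ~ stats::poly(lx, degree = min(2L, sum(fitOn) - 1L), raw = TRUE))
    ve[fitOn] <- pmax(10^stats::predict(fit), 1e-12)
  } else {
    ve[fitOn] <- v[fitOn]
  }
  stdVar <- numeric(nrow(m))
  if (any(fitOn)) {
    z <- (m[fitOn, , drop = FALSE] - mu[fitOn]) / sqrt(ve[fitOn])
    z <- pmin(z, sqrt(n))
    zm <- rowMeans(z)
    stdVar[fitOn] <- rowSums((z - zm)^2) / (n - 1)
  }
  ord <- order(-stdVar, rownames(m))
  rownames(m)[ord[seq_len(nTop)]]
}

#' Attach subtype / major-type labels to cells
#'
#' @param sce SingleCellExperiment.
#' @param labels data.frame with `cell_id` and `subtype` (and optionally
#'   `major_type`; derived from the subtype prefix otherwise).
#' @param allowPartial label uncovered cells "unassigned" instead of erroring.
#' @param ignoreUnknown drop label rows whose cell_id is absent from `sce`
#'   instead of erroring.
#' @return `sce` with subtype / major_type columns populated;
#'   `metadata(.)$labelCoverage` records counts.
#' @export
attachLabels <- function(sce, labels, allowPartial = FALSE,
                         ignoreUnknown = FALSE) {
  stopifnot(all(c("cell_id", "subtype") %in% colnames(labels)))
  if (anyDuplicated(labels$cell_id)) {
    stop("duplicate cell_id rows in label table: ",
         paste(head(unique(labels$cell_id[duplicated(labels$cell_id)]), 5),
               collapse = ", "))
  }
  unknown <- setdiff(labels$cell_id, colnames(sce))
  if (length(unknown)) {
    if (!ignoreUnknown) stop(length(unknown), " label rows reference unknown cells")
    labels <- labels[!labels$cell_id %in% unknown, , drop = FALSE]
  }
  idx <- match(colnames(sce), labels$cell_id)
  covered <- !is.na(idx)
  if (!all(covered) && !allowPartial) {
    stop(sum(!covered), " cells lack labels (use allowPartial = TRUE)")
  }
  subtype <- ifelse(covered, labels$subtype[idx], "unassigned")
  major <- if ("major_type" %in% colnames(labels)) {
    ifelse(covered, labels$major_type[idx], "unassigned")
  } else {
    ifelse(covered, majorTypeOf(subtype), "unassigned")
  }
  sce$subtype <- subtype
  sce$major_type <- major
  S4Vectors::metadata(sce)$labelCoverage <- list(
    nCells = ncol(sce), nLabeled = sum(covered),
    nUnassigned = sum(!covered), nUnknownLabels = length(unknown))
  sce
}
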