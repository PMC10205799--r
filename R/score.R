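#' The packaged MAM gene set
#'
#' The 13-gene mitochondria-associated ER membrane (MAM) program: Mfn1, Mfn2,
#' Bcap31, Pacs2, Tespa1, Hspa9, Itpr3, Sigmar1, Vapb, Fis1, Vdac, Mcu,
#' Ptpip51. Note that "Vdac" and "Ptpip51" are not standard mouse symbols and
#' may be absent from real annotations; [moduleScore()] drops missing genes
#' with a warning rather than failing, and the set is overridable.
#'
#' @return a [GeneSet-class].
#' @export
mamGeneSet <- function() {
  geneSet("MAM", c("Mfn1", "Mfn2", "Bcap31", "Pacs2", "Tespa1", "Hspa9",
                   "Itpr3", "Sigmar1", "Vapb", "Fis1", "Vdac", "Mcu",
                   "Ptpip51"))
}

#' Read a gene set from GMT or plain text
#'
#' @param path a GMT file (tab-separated: name, description, genes...) or a
#'   one-gene-per-line text file.
#' @param name for plain lists, the set name (default: file base name); for
#'   GMT files with several sets, which set to take (default: first).
#' @return a [GeneSet-class].
#' @export
readGeneSet <- function(path, name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gene-set file: ", path)
  if (grepl("\t", lines[1])) {
    rows <- strsplit(lines, "\t")
    setNames <- vapply(rows, `[`, character(1), 1L)
    i <- if (is.null(name)) 1L else match(name, setNames)
    if (is.na(i)) stop("gene set '", name, "' not found in ", path)
    genes <- rows[[i]][-(1:2)]
    geneSet(setNames[i], genes[nzchar(genes)])
  } else {
    geneSet(if (is.null(name)) sub("\\.[^.]*$", "", basename(path)) else name,
            trimws(lines))
  }
}

# Stable, order-independent per-gene seed: polynomial hash of the gene id
# folded with the user seed.
.geneSeed <- function(seed, gene) {
  h <- 0
  for (ch in utf8ToInt(gene)) h <- (h * 131 + ch) %% 2147483647
  as.integer((h + as.numeric(seed) * 7919) %% 2147483647)
}

#' Per-cell gene-set module score with bin-matched control genes
#'
#' Genes are ranked by their dataset-average expression and cut into `nBins`
#' equal-frequency bins (ties broken by gene id). For each present set gene,
#' `nCtrl` control genes are sampled without replacement from its bin,
#' excluding all set genes; bins with fewer candidates contribute all of them
#' (with a warning). The score of a cell is the mean expression of the set
#' genes minus the mean expression of the pooled control genes. Control draws
#' are seeded per gene, so results are reproducible and invariant to the
#' order of genes within the set.
#'
#' @param x SingleCellExperiment with `logcounts`, or a normalized genes x
#'   cells matrix.
#' @param set a [GeneSet-class].
#' @param nBins number of average-expression bins.
#' @param nCtrl control genes per set gene.
#' @param seed RNG seed for control sampling.
#' @return a [ModuleScoreResult-class]; missing set genes are recorded, not
#'   fatal.
#' @export
moduleScore <- function(x, set, nBins = 24L, nCtrl = 100L, seed = 0L) {
  stopifnot(nBins >= 1, nCtrl >= 1)
  m <- .exprMatrix(x)
  genes <- rownames(m)
  present <- intersect(setGenes(set), genes)
  missing <- setdiff(setGenes(set), genes)
  if (!length(present)) stop("no gene of set '", set@name,
                             "' is present in the matrix")
  if (length(missing)) {
    warning("dropping ", length(missing), " set gene(s) absent from matrix: ",
            paste(missing, collapse = ", "))
  }
  G <- nrow(m)
  nBins <- min(as.integer(nBins), G)
  avg <- rowMeans(m)
  ordIdx <- order(avg, genes)
  binId <- integer(G)
  binId[ordIdx] <- as.integer(cut(seq_len(G), breaks = nBins, labels = FALSE))
  names(binId) <- genes

  ctrl <- character(0)
  shortBins <- character(0)
  for (g in present) {
    pool <- genes[binId == binId[[g]]]
    pool <- setdiff(pool, present)
    if (!length(pool)) pool <- setdiff(genes[binId == binId[[g]]], g)
    if (!length(pool)) next
    if (length(pool) <= nCtrl) {
      if (length(pool) < nCtrl) shortBins <- c(shortBins, g)
      ctrl <- c(ctrl, pool)
    } else {
      ctrl <- c(ctrl, withLocalSeed(.geneSeed(seed, g),
                                    sample(pool, nCtrl)))
    }
  }
  if (length(shortBins)) {
    warning("control bin smaller than nCtrl for: ",
            paste(shortBins, collapse = ", "), "; using the whole bin")
  }
  setMean <- colMeans(m[present, , drop = FALSE])
  ctrlMean <- if (length(ctrl)) colMeans(m[ctrl, , drop = FALSE]) else 0
  sc <- setMean - ctrlMean
  new("ModuleScoreResult", scores = sc, geneSetName = set@name,
      genesUsed = present, genesMissing = missing,
      params = list(nBins = nBins, nCtrl = as.integer(nCtrl),
                    seed = as.integer(seed)))
}

#' Per-stage summary of module scores
#'
#' @param result a [ModuleScoreResult-class].
#' @param sce the SingleCellExperiment the scores were computed on (provides
#'   stage and major_type).
#' @param restrictType optionally restrict to one major type (e.g. "CM").
#' @return data.frame with one row per stage in configured order: n, mean, sd
#'   and a normal 95% CI (mean +/- 1.96 sd/sqrt(n)); empty stages get n = 0
#'   and NA statistics.
#' @export
stageScoreSummary <- function(result, sce, restrictType = NULL) {
  sc <- scores(result)
  cd <- as.data.frame(SummarizedExperiment::colData(sce))
  cd <- cd[intersect(names(sc), rownames(cd)), , drop = FALSE]
  cd$score <- sc[rownames(cd)]
  if (!is.null(restrictType)) cd <- cd[cd$major_type == restrictType, ,
                                       drop = FALSE]
  stages <- stageLevels(sce)
  out <- do.call(rbind, lapply(stages, function(st) {
    v <- cd$score[cd$stage == st]
    n <- length(v)
    if (n == 0) {
      data.frame(stage = st, n = 0L, mean = NA_real_, sd = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_)
    } else {
      mu <- mean(v); s <- if (n > 1) sd(v) else NA_real_
      half <- if (n > 1) 1.96 * s / sqrt(n) else NA_real_
      data.frame(stage = st, n = n, mean = mu, sd = s,
                 ci_lo = mu - half, ci_hi = mu + half)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Mean expression of a gene set by major cell type
#'
#' @param sce SingleCellExperiment with `counts` and `logcounts`.
#' @param set a [GeneSet-class].
#' @return long data.frame(major_type, gene, mean_expr, frac_nonzero): the
#'   arithmetic mean of normalized expression and the fraction of cells of
#'   that type with a nonzero count, per present set gene.
#' @export
meanSetExpressionByType <- function(sce, set) {
  m <- .exprMatrix(sce)
  cnt <- SummarizedExperiment::assay(sce, "counts")
  present <- intersect(setGenes(set), rownames(m))
  if (!length(present)) stop("no gene of the set is present")
  types <- sort(unique(sce$major_type))
  do.call(rbind, lapply(types, function(tp) {
    cols <- sce$major_type == tp
    data.frame(major_type = tp, gene = present,
               mean_expr = rowMeans(m[present, cols, drop = FALSE]),
               frac_nonzero = rowMeans(cnt[present, cols, drop = FALSE] > 0),
               row.names = NULL)
  }))
}
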