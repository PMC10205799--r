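# Shared fixtures and independent reference (oracle) implementations.

# Small cohort for fast unit tests: ~150 CM cells/stage, full default
# structure (schedule, MAM program, conversions scaled down so the rarest
# descendant subtype can still absorb them).
smallSimConfig <- function(seed = 1L, nCellsPerStage = 250L, nGenes = 300L,
                           convN = 5L, ...) {
  simConfig(nGenes = nGenes, nCellsPerStage = nCellsPerStage,
            conversionPlan = defaultConversionPlan(n = convN),
            seed = seed, ...)
}

# Default-size cohort (the study conditions: ~2000 CM cells/stage), QC'd and
# log-normalized; cached per seed because generation is the expensive step.
.cohortCache <- new.env(parent = emptyenv())
cachedDefaultCohort <- function(seed = 1L) {
  key <- paste0("s", seed)
  if (!exists(key, envir = .cohortCache)) {
    co <- simulateCohort(simConfig(seed = seed))
    sce <- logNormalize(qcFilter(co$sce))
    assign(key, list(sce = sce, truth = co$truth), envir = .cohortCache)
  }
  get(key, envir = .cohortCache)
}

# Build an SCE directly from a counts matrix and minimal metadata.
makeSCE <- function(counts, stage = NULL, subtype = NULL,
                    stages = unique(stage)) {
  n <- ncol(counts)
  if (is.null(colnames(counts))) colnames(counts) <- sprintf("c%03d", seq_len(n))
  if (is.null(rownames(counts))) rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(stage)) stage <- rep("0w", n)
  if (is.null(subtype)) subtype <- rep("CM1", n)
  cd <- S4Vectors::DataFrame(cell_id = colnames(counts), stage = stage,
                             major_type = mamshift:::majorTypeOf(subtype),
                             subtype = subtype,
                             row.names = colnames(counts))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts), colData = cd)
  S4Vectors::metadata(sce)$stages <- stages
  sce
}

# Naive two-loop log-normalization reference.
refLogNormalize <- function(counts, scaleFactor = 1e4) {
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (j in seq_len(ncol(counts))) {
    tot <- sum(counts[, j])
    for (i in seq_len(nrow(counts))) {
      out[i, j] <- log1p(counts[i, j] / tot * scaleFactor)
    }
  }
  out
}

# Naive standardized-variance HVG ranking (same definition, loop form).
refSelectHVGs <- function(m, nTop) {
  n <- ncol(m)
  mu <- apply(m, 1, mean)
  v <- apply(m, 1, var)
  ok <- v > 0
  fit <- lm(log10(v[ok]) ~ poly(log10(mu[ok] + 1e-12), degree = 2, raw = TRUE))
  ve <- rep(NA_real_, nrow(m))
  ve[ok] <- pmax(10^predict(fit), 1e-12)
  sv <- numeric(nrow(m))
  for (i in which(ok)) {
    z <- (m[i, ] - mu[i]) / sqrt(ve[i])
    z <- pmin(z, sqrt(n))
    sv[i] <- var(z)
  }
  rownames(m)[order(-sv, rownames(m))][seq_len(nTop)]
}

# Naive per-cell module-score oracle given explicit control gene choices.
refModuleScore <- function(m, setGenes, ctrlGenes) {
  vapply(seq_len(ncol(m)), function(j) {
    mean(m[setGenes, j]) - mean(m[ctrlGenes, j])
  }, numeric(1))
}

# Brute-force ancestor pipeline: per-pair stats::cor Spearman, explicit sort
# with the id tie-break, plurality vote with summed-rho then lexicographic
# tie-break, and support counting. Independent of the package's vectorised
# path (stats::cor vs rank/crossprod).
refConversionEdges <- function(m, cellTable, from, to, k = 5, genes) {
  prev <- cellTable[cellTable$stage == from, ]
  cur <- cellTable[cellTable$stage == to & cellTable$major_type == "CM", ]
  votes <- data.frame(cellId = character(0), voted = character(0),
                      subtype = character(0))
  for (ci in cur$cell_id) {
    rho <- sapply(prev$cell_id, function(pj) {
      suppressWarnings(cor(m[genes, ci], m[genes, pj], method = "spearman"))
    })
    rho <- round(rho, 12)
    rho <- rho[!is.na(rho)]
    if (!length(rho)) next
    kk <- min(k, length(rho))
    ord <- order(-rho, names(rho))[seq_len(kk)]
    topCells <- names(rho)[ord]
    labs <- prev$subtype[match(topCells, prev$cell_id)]
    tab <- table(labs)
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1) {
      sums <- sapply(best, function(s) sum(rho[topCells[labs == s]]))
      sums <- round(sums, 12)
      best <- sort(best[sums == max(sums)])[1]
    }
    votes <- rbind(votes, data.frame(
      cellId = ci, voted = best,
      subtype = cur$subtype[cur$cell_id == ci]))
  }
  agg <- aggregate(list(support = votes$cellId),
                   by = list(ancestor = votes$voted,
                             descendant = votes$subtype), FUN = length)
  agg <- agg[order(agg$ancestor, agg$descendant), ]
  rownames(agg) <- NULL
  agg
}

# Independent full-bin module-score reference: equal-frequency bins by
# (average expression, gene id), per-set-gene control pool = whole bin minus
# the set genes, concatenated with multiplicity, score by explicit loops.
refFullBinScore <- function(m, setG, nBins) {
  avg <- apply(m, 1, mean)
  ord <- order(avg, rownames(m))
  grp <- split(ord, cut(seq_along(ord), nBins))
  binOf <- integer(nrow(m))
  for (b in seq_along(grp)) binOf[grp[[b]]] <- b
  names(binOf) <- rownames(m)
  ctrl <- character(0)
  for (g in setG) {
    pool <- setdiff(rownames(m)[binOf == binOf[[g]]], setG)
    ctrl <- c(ctrl, pool)
  }
  out <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    out[j] <- mean(m[setG, j]) - mean(m[ctrl, j])
  }
  names(out) <- colnames(m)
  out
}

# Fixture in which each set gene equals its bin-mates plus a constant c.
binMateFixture <- function(c = 0.37, nBins = 4, perBin = 12, nCells = 9) {
  G <- nBins * perBin
  ids <- sprintf("g%02d", seq_len(G))
  vals <- rep(seq_len(nBins), each = perBin)   # bin baselines 1, 2, ...
  setIdx <- seq(perBin, G, by = perBin)        # one set gene per bin
  vals[setIdx] <- vals[setIdx] + c
  m <- matrix(vals, G, nCells, dimnames = list(ids, sprintf("c%02d", seq_len(nCells))))
  list(m = m, setGenes = ids[setIdx])
}
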