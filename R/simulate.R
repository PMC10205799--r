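#' Default per-stage subtype schedule
#'
#' Composition of the simulated cohort over the five post-surgery stages:
#' 11 cardiomyocyte (CM) subtypes plus five non-CM major types (EC, FB, MP, T,
#' GN). CM2/CM3 dominate early and decline while CM9/CM10 rise, mirroring the
#' subtype switch the ancestor-voting analysis is designed to detect; the
#' remaining CM subtypes share the residual CM mass evenly and the non-CM
#' composition is constant across stages.
#'
#' @param stages ordered stage labels (must have length 5 for the built-in
#'   schedule).
#' @param cmFraction fraction of all cells that are cardiomyocytes.
#' @return named list: stage -> named proportions over subtypes, each summing
#'   to 1.
#' @export
defaultSubtypeSchedule <- function(stages = c("0w", "2w", "5w", "8w", "11w"),
                                   cmFraction = 0.6) {
  stopifnot(length(stages) == 5L, cmFraction > 0, cmFraction < 1)
  cmCore <- rbind(
    CM2  = c(0.30, 0.25, 0.15, 0.08, 0.05),
    CM3  = c(0.25, 0.22, 0.14, 0.08, 0.05),
    CM9  = c(0.02, 0.05, 0.15, 0.25, 0.28),
    CM10 = c(0.02, 0.04, 0.12, 0.20, 0.24))
  rest <- c("CM1", "CM4", "CM5", "CM6", "CM7", "CM8", "CM11")
  restFrac <- (1 - colSums(cmCore)) / length(rest)
  within <- rbind(cmCore,
                  matrix(rep(restFrac, each = length(rest)),
                         nrow = length(rest), dimnames = list(rest, NULL)))
  nonCM <- c(EC = 0.15, FB = 0.12, MP = 0.06, T = 0.04, GN = 0.03)
  nonCM <- nonCM / sum(nonCM) * (1 - cmFraction)
  sched <- lapply(seq_along(stages),
                  function(i) c(within[, i] * cmFraction, nonCM))
  names(sched) <- stages
  sched
}

#' Default planted conversion plan
#'
#' CM2 -> CM9 and CM3 -> CM10 conversions at every adjacent stage transition,
#' 60 converting cells per edge per transition.
#'
#' @param stages ordered stage labels.
#' @param n converting cells per edge per transition.
#' @return data.frame(ancestor, descendant, transition, n).
#' @export
defaultConversionPlan <- function(stages = c("0w", "2w", "5w", "8w", "11w"),
                                  n = 60L) {
  trans <- mapply(transitionLabel, stages[-length(stages)], stages[-1])
  do.call(rbind, lapply(trans, function(tr) {
    data.frame(ancestor = c("CM2", "CM3"), descendant = c("CM9", "CM10"),
               transition = tr, n = as.integer(n))
  }))
}

#' Build a simulation configuration
#'
#' Defaults describe the emulated study conditions: 5 stages, ~2000 CM cells
#' per stage (60% of 3333 cells), a MAM program in CM cells whose log-offset
#' peaks at 2w (0, 0.8, 0.5, 0.2, 0) and declines thereafter, declining
#' per-stage offsets for Mfn1 and Hspa9, and CM2->CM9 / CM3->CM10 conversions
#' planted at every transition.
#'
#' @param nGenes,nCellsPerStage universe and per-stage cohort size.
#' @param stages ordered stage labels.
#' @param subtypeSchedule see [defaultSubtypeSchedule()].
#' @param mamGenes a [GeneSet-class]; default [mamGeneSet()].
#' @param mamOffsetByStage named numeric stage -> log-mean offset on MAM genes
#'   in CM cells.
#' @param geneTrendOffsets named list gene -> (stage -> offset); replaces the
#'   MAM offset for those genes.
#' @param conversionPlan see [defaultConversionPlan()].
#' @param baselineMean,dispersion negative-binomial baseline mean scale and
#'   dispersion (size = 1/dispersion).
#' @param librarySizeRange target counts per cell, sampled uniformly.
#' @param ancestorWeight convex weight of the ancestor's log-mean profile in a
#'   converting descendant.
#' @param cellNoiseSd per-cell log-mean jitter sd.
#' @param majorEffect,subtypeEffect marker-gene log elevations.
#' @param mamBaseCM stage-independent MAM elevation in CM cells.
#' @param assignMode "rounding" (largest remainder, deterministic) or
#'   "multinomial".
#' @param seed RNG seed.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nGenes = 1200L, nCellsPerStage = 3333L,
                      stages = c("0w", "2w", "5w", "8w", "11w"),
                      subtypeSchedule = NULL, mamGenes = mamGeneSet(),
                      mamOffsetByStage = NULL, geneTrendOffsets = NULL,
                      conversionPlan = NULL, baselineMean = 1,
                      dispersion = 0.3, librarySizeRange = c(2000, 8000),
                      ancestorWeight = 0.7, cellNoiseSd = 0.35,
                      majorEffect = 1.5, subtypeEffect = 2, mamBaseCM = 1,
                      assignMode = "rounding", seed = 1L) {
  if (is.null(subtypeSchedule)) subtypeSchedule <- defaultSubtypeSchedule(stages)
  if (is.null(mamOffsetByStage)) {
    mamOffsetByStage <- if (length(stages) == 5L) {
      stats::setNames(c(0, 0.8, 0.5, 0.2, 0), stages)
    } else stats::setNames(rep(0, length(stages)), stages)
  }
  if (is.null(geneTrendOffsets)) {
    decl <- stats::setNames(seq(1, 0, length.out = length(stages)), stages)
    geneTrendOffsets <- list(Mfn1 = decl, Hspa9 = 0.75 * decl + 0.25 * decl[1])
  }
  if (is.null(conversionPlan)) {
    conversionPlan <- if (length(stages) == 5L) defaultConversionPlan(stages)
      else data.frame(ancestor = character(), descendant = character(),
                      transition = character(), n = integer())
  }
  new("SimConfig", nGenes = as.integer(nGenes),
      nCellsPerStage = as.integer(nCellsPerStage), stages = stages,
      subtypeSchedule = subtypeSchedule, mamGenes = mamGenes,
      mamOffsetByStage = mamOffsetByStage, geneTrendOffsets = geneTrendOffsets,
      conversionPlan = conversionPlan, baselineMean = baselineMean,
      dispersion = dispersion, librarySizeRange = as.numeric(librarySizeRange),
      ancestorWeight = ancestorWeight, cellNoiseSd = cellNoiseSd,
      majorEffect = majorEffect, subtypeEffect = subtypeEffect,
      mamBaseCM = mamBaseCM, assignMode = assignMode, seed = as.integer(seed))
}

# Plain-list view of a config (for hashing and JSON manifests).
configAsList <- function(config) {
  list(nGenes = config@nGenes, nCellsPerStage = config@nCellsPerStage,
       stages = config@stages,
       subtypeSchedule = lapply(config@subtypeSchedule, as.list),
       mamGenes = setGenes(config@mamGenes),
       mamOffsetByStage = as.list(config@mamOffsetByStage),
       geneTrendOffsets = lapply(config@geneTrendOffsets, as.list),
       conversionPlan = config@conversionPlan,
       baselineMean = config@baselineMean, dispersion = config@dispersion,
       librarySizeRange = config@librarySizeRange,
       ancestorWeight = config@ancestorWeight,
       cellNoiseSd = config@cellNoiseSd, majorEffect = config@majorEffect,
       subtypeEffect = config@subtypeEffect, mamBaseCM = config@mamBaseCM,
       assignMode = config@assignMode, seed = config@seed)
}

# Disjoint marker blocks for major types and subtypes, never from MAM genes.
assignMarkers <- function(geneIds, mamGenes, majors, subtypes) {
  bg <- setdiff(geneIds, mamGenes)
  nGroups <- length(majors) + length(subtypes)
  perMajor <- min(40L, max(1L, floor(length(bg) * 0.8 / nGroups)))
  perSub <- min(40L, max(1L, floor(length(bg) * 0.8 / nGroups)))
  need <- perMajor * length(majors) + perSub * length(subtypes)
  if (need > length(bg)) stop("nGenes too small to assign marker blocks")
  pool <- sample(bg, need)
  i <- 0L
  majorMarkers <- lapply(stats::setNames(majors, majors), function(m) {
    out <- pool[(i + 1L):(i + perMajor)]; i <<- i + perMajor; out
  })
  subMarkers <- lapply(stats::setNames(subtypes, subtypes), function(s) {
    out <- pool[(i + 1L):(i + perSub)]; i <<- i + perSub; out
  })
  list(major = majorMarkers, subtype = subMarkers)
}

#' Simulate a stage-labelled single-cell cohort with planted ground truth
#'
#' Draws counts from a gamma-Poisson model: per-gene baseline log-means,
#' major-type and subtype marker elevations, a CM-restricted MAM program with
#' per-stage offsets, per-cell log jitter, and uniform library-size targets.
#' Cells listed in the conversion plan are generated as convex mixtures of
#' their assigned ancestor cell's latent log-mean profile and their own
#' subtype baseline, so ancestor inference is recoverable from the counts.
#' Deterministic under a fixed seed.
#'
#' @param config a [SimConfig-class] from [simConfig()].
#' @return list with `sce` (a
#'   [SingleCellExperiment::SingleCellExperiment] with a `counts` assay and
#'   colData columns cell_id, stage, major_type, subtype, n_genes_detected,
#'   total_counts) and `truth` (a [GroundTruth-class]).
#' @examples
#' cohort <- simulateCohort(simConfig(nGenes = 80, nCellsPerStage = 60, seed = 7))
#' cohort$sce
#' @export
simulateCohort <- function(config) {
  methods::validObject(config)
  withLocalSeed(config@seed, {
    G <- config@nGenes
    stages <- config@stages
    mam <- setGenes(config@mamGenes)
    extra <- setdiff(names(config@geneTrendOffsets), mam)
    nBg <- G - length(mam) - length(extra)
    if (nBg < 0) stop("nGenes smaller than the MAM/trend gene sets")
    geneIds <- c(mam, extra, sprintf("G%04d", seq_len(nBg)))

    subtypes <- sort(unique(unlist(lapply(config@subtypeSchedule, names))))
    majors <- unique(majorTypeOf(subtypes))
    markers <- assignMarkers(geneIds, mam, majors, subtypes)

    b <- stats::setNames(log(config@baselineMean) + rnorm(G, 0, 1), geneIds)
    typeEff <- matrix(0, G, length(majors), dimnames = list(geneIds, majors))
    for (m in majors) typeEff[markers$major[[m]], m] <- config@majorEffect
    subEff <- matrix(0, G, length(subtypes), dimnames = list(geneIds, subtypes))
    for (s in subtypes) subEff[markers$subtype[[s]], s] <- config@subtypeEffect

    trendGenes <- names(config@geneTrendOffsets)
    pureMam <- setdiff(mam, trendGenes)

    countsList <- vector("list", length(stages))
    cellsList <- vector("list", length(stages))
    convRows <- list()
    prevEta <- NULL; prevStage <- NULL; prevSub <- NULL

    for (si in seq_along(stages)) {
      st <- stages[si]
      p <- config@subtypeSchedule[[st]]
      p <- p[p > 0]
      nBySub <- if (config@assignMode == "rounding") {
        largestRemainder(p, config@nCellsPerStage)
      } else {
        stats::setNames(as.integer(rmultinom(1, config@nCellsPerStage, p)), names(p))
      }
      subVec <- rep(names(nBySub), nBySub)
      n <- length(subVec)
      cellIds <- sprintf("%s_c%05d", st, seq_len(n))
      major <- majorTypeOf(subVec)
      isCM <- major == "CM"

      mamVec <- stats::setNames(numeric(G), geneIds)
      mamVec[pureMam] <- config@mamBaseCM + config@mamOffsetByStage[[st]]
      for (g in trendGenes) {
        mamVec[g] <- config@mamBaseCM + config@geneTrendOffsets[[g]][[st]]
      }

      eta <- typeEff[, major, drop = FALSE] + subEff[, subVec, drop = FALSE] + b
      if (any(isCM)) eta[, isCM] <- eta[, isCM] + mamVec
      eta <- eta + matrix(rnorm(G * n, 0, config@cellNoiseSd), G, n)
      colnames(eta) <- cellIds

      if (!is.null(prevStage)) {
        tr <- transitionLabel(prevStage, st)
        plan <- config@conversionPlan[config@conversionPlan$transition == tr, ,
                                      drop = FALSE]
        if (nrow(plan)) {
          for (i in seq_len(nrow(plan))) {
            descCand <- which(subVec == plan$descendant[i])
            ancCand <- colnames(prevEta)[prevSub == plan$ancestor[i]]
            if (length(descCand) < plan$n[i] || length(ancCand) < plan$n[i]) {
              stop(sprintf("conversion plan %s->%s at %s needs %d cells; only %d/%d available",
                           plan$ancestor[i], plan$descendant[i], tr, plan$n[i],
                           length(ancCand), length(descCand)))
            }
            desc <- sort(sample(descCand, plan$n[i]))
            anc <- sample(ancCand, plan$n[i])
            w <- config@ancestorWeight
            eta[, desc] <- w * prevEta[, anc, drop = FALSE] +
              (1 - w) * eta[, desc, drop = FALSE]
            convRows[[length(convRows) + 1L]] <- data.frame(
              descendant = cellIds[desc], ancestor = anc, transition = tr,
              ancestorSubtype = plan$ancestor[i],
              descendantSubtype = plan$descendant[i])
          }
        }
      }

      L <- runif(n, config@librarySizeRange[1], config@librarySizeRange[2])
      mu <- exp(eta)
      mu <- sweep(mu, 2, L / colSums(mu), `*`)
      cnt <- matrix(rnbinom(G * n, mu = as.vector(mu),
                            size = 1 / config@dispersion), G, n,
                    dimnames = list(geneIds, cellIds))
      storage.mode(cnt) <- "integer"
      countsList[[si]] <- cnt
      cellsList[[si]] <- data.frame(cell_id = cellIds, stage = st,
                                    major_type = major, subtype = subVec)
      prevEta <- eta; prevStage <- st; prevSub <- subVec
    }

    counts <- do.call(cbind, countsList)
    cells <- do.call(rbind, cellsList)
    cells$n_genes_detected <- as.integer(colSums(counts > 0))
    cells$total_counts <- as.integer(colSums(counts))
    rownames(cells) <- cells$cell_id

    sce <- SingleCellExperiment::SingleCellExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(cells))
    S4Vectors::metadata(sce)$stages <- stages
    S4Vectors::metadata(sce)$simSeed <- config@seed
    S4Vectors::metadata(sce)$configHash <- hashObject(configAsList(config))

    conv <- if (length(convRows)) do.call(rbind, convRows) else
      data.frame(descendant = character(), ancestor = character(),
                 transition = character(), ancestorSubtype = character(),
                 descendantSubtype = character())
    trueProps <- do.call(rbind, lapply(stages, function(st) {
      p <- config@subtypeSchedule[[st]]
      data.frame(stage = st, subtype = names(p), proportion = unname(p))
    }))
    pe <- config@conversionPlan
    truth <- new("GroundTruth", conversions = conv, trueProportions = trueProps,
                 trueMamOffsets = config@mamOffsetByStage,
                 plantedEdges = pe[, c("ancestor", "descendant", "transition", "n")])
    list(sce = sce, truth = truth)
  })
}

#' Write a simulated cohort to plain-text fixture files
#'
#' Writes matrix.mtx (Matrix Market), genes.tsv, barcodes.tsv, cells.tsv,
#' truth.json and manifest.json (seed + config hash) into `dir`. A read with
#' [readCohortFixture()] reproduces the counts exactly.
#'
#' @param sce,truth output of [simulateCohort()].
#' @param dir output directory.
#' @param config the [SimConfig-class] used (recorded in the manifest).
#' @param overwrite allow writing into an existing non-empty directory.
#' @return the manifest, invisibly.
#' @export
writeCohortFixture <- function(sce, truth, dir, config = NULL,
                               overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) && !overwrite) {
    stop("refusing to write into non-empty directory '", dir,
         "' without overwrite = TRUE")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cnt <- SummarizedExperiment::assay(sce, "counts")
  Matrix::writeMM(methods::as(Matrix::Matrix(cnt, sparse = TRUE), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(sce), file.path(dir, "genes.tsv"))
  writeLines(colnames(sce), file.path(dir, "barcodes.tsv"))
  write.table(as.data.frame(SummarizedExperiment::colData(sce)),
              file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truthList <- list(conversions = truth@conversions,
                    trueProportions = truth@trueProportions,
                    trueMamOffsets = as.list(truth@trueMamOffsets),
                    plantedEdges = truth@plantedEdges)
  jsonlite::write_json(truthList, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  manifest <- list(
    seed = S4Vectors::metadata(sce)$simSeed,
    configHash = S4Vectors::metadata(sce)$configHash,
    stages = S4Vectors::metadata(sce)$stages,
    nGenes = nrow(sce), nCells = ncol(sce),
    config = if (!is.null(config)) configAsList(config) else NULL,
    package = as.character(packageVersion("mamshift")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a cohort fixture written by [writeCohortFixture()]
#'
#' @param dir directory containing matrix.mtx, genes.tsv, barcodes.tsv,
#'   cells.tsv and (optionally) truth.json / manifest.json.
#' @return list(sce, truth, manifest); `truth`/`manifest` are NULL when the
#'   files are absent.
#' @export
readCohortFixture <- function(dir) {
  cnt <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(cnt) <- "integer"
  rownames(cnt) <- readLines(file.path(dir, "genes.tsv"))
  colnames(cnt) <- readLines(file.path(dir, "barcodes.tsv"))
  cells <- read.table(file.path(dir, "cells.tsv"), sep = "\t", header = TRUE,
                      colClasses = "character")
  cells$n_genes_detected <- as.integer(cells$n_genes_detected)
  cells$total_counts <- as.integer(cells$total_counts)
  rownames(cells) <- cells$cell_id
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = cnt[, cells$cell_id, drop = FALSE]),
    colData = S4Vectors::DataFrame(cells))
  manifest <- truth <- NULL
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
    S4Vectors::metadata(sce)$stages <- manifest$stages
    S4Vectors::metadata(sce)$simSeed <- manifest$seed
    S4Vectors::metadata(sce)$configHash <- manifest$configHash
  }
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    tl <- jsonlite::read_json(tf, simplifyVector = TRUE)
    emptyConv <- data.frame(descendant = character(), ancestor = character(),
                            transition = character(),
                            ancestorSubtype = character(),
                            descendantSubtype = character())
    emptyEdges <- data.frame(ancestor = character(), descendant = character(),
                             transition = character(), n = integer())
    truth <- new("GroundTruth",
                 conversions = if (length(tl$conversions)) as.data.frame(tl$conversions) else emptyConv,
                 trueProportions = as.data.frame(tl$trueProportions),
                 trueMamOffsets = unlist(tl$trueMamOffsets),
                 plantedEdges = if (length(tl$plantedEdges)) as.data.frame(tl$plantedEdges) else emptyEdges)
  }
  list(sce = sce, truth = truth, manifest = manifest)
}
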