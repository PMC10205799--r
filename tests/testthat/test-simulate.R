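test_that("simulation is bit-identical under a fixed seed and counts are valid", {
  cfg <- smallSimConfig(seed = 7)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  ca <- SummarizedExperiment::assay(a$sce, "counts")
  expect_identical(ca, SummarizedExperiment::assay(b$sce, "counts"))
  expect_identical(a$truth@conversions, b$truth@conversions)
  expect_true(all(ca >= 0))
  expect_true(is.integer(ca))
  expect_false(anyDuplicated(rownames(ca)) > 0)
  expect_false(anyDuplicated(colnames(ca)) > 0)
  expect_true(methods::validObject(a$truth))
})

test_that("realized subtype composition matches the schedule", {
  # largest-remainder assignment: per-subtype counts within 1 of exact
  cfg <- smallSimConfig(seed = 2)
  co <- simulateCohort(cfg)
  cd <- as.data.frame(SummarizedExperiment::colData(co$sce))
  for (st in cfg@stages) {
    p <- cfg@subtypeSchedule[[st]]
    obs <- table(factor(cd$subtype[cd$stage == st], levels = names(p)))
    expect_true(all(abs(as.numeric(obs) - p * cfg@nCellsPerStage) <= 1))
  }
  # multinomial mode converges more loosely
  cfgM <- simConfig(nGenes = 120, nCellsPerStage = 2000,
                    conversionPlan = defaultConversionPlan(n = 5),
                    assignMode = "multinomial", seed = 5)
  coM <- simulateCohort(cfgM)
  cdM <- as.data.frame(SummarizedExperiment::colData(coM$sce))
  for (st in cfgM@stages) {
    p <- cfgM@subtypeSchedule[[st]]
    obs <- table(factor(cdM$subtype[cdM$stage == st], levels = names(p)))
    expect_true(all(abs(as.numeric(obs) / sum(obs) - p) < 0.03))
  }
})

test_that("converting cells resemble their assigned ancestor", {
  # planted pairs: Spearman to the true ancestor beats the median correlation
  # to non-ancestors for >= 90% of pairs at default noise
  for (s in 1:3) {
    co <- simulateCohort(smallSimConfig(seed = s))
    sce <- logNormalize(qcFilter(co$sce, minGenes = 5))
    m <- SummarizedExperiment::assay(sce, "logcounts")
    conv <- co$truth@conversions
    good <- 0L
    for (i in seq_len(nrow(conv))) {
      d <- conv$descendant[i]; anc <- conv$ancestor[i]
      from <- strsplit(conv$transition[i], "->", fixed = TRUE)[[1]][1]
      prev <- m[, sce$stage == from, drop = FALSE]
      hv <- selectHVGs(cbind(prev, m[, d, drop = FALSE]), 150)
      rho <- spearmanToPrevious(m[, d], prev, genes = hv)
      if (rho[anc] > stats::median(rho[setdiff(names(rho), anc)])) good <- good + 1L
    }
    expect_gte(good / nrow(conv), 0.9)
  }
})

test_that("zero-offset, composition-stable configuration yields flat stage scores", {
  stages <- c("0w", "2w", "5w", "8w", "11w")
  sched <- defaultSubtypeSchedule()
  for (st in stages) sched[[st]] <- sched[["0w"]]
  cfg <- simConfig(
    nGenes = 400, nCellsPerStage = 667, subtypeSchedule = sched,
    mamOffsetByStage = stats::setNames(rep(0, 5), stages),
    geneTrendOffsets = list(Mfn1 = stats::setNames(rep(0, 5), stages)),
    mamBaseCM = 0,
    conversionPlan = data.frame(ancestor = character(),
                                descendant = character(),
                                transition = character(), n = integer()),
    seed = 9)
  co <- simulateCohort(cfg)
  sce <- logNormalize(qcFilter(co$sce, minGenes = 10))
  res <- suppressWarnings(moduleScore(sce, mamGeneSet(), seed = 0))
  ss <- stageScoreSummary(res, sce, restrictType = "CM")
  z <- abs(ss$mean - mean(ss$mean)) / (ss$sd / sqrt(ss$n))
  expect_true(all(z < 3))
})

test_that("planted 2w-peaked offsets produce the expected stage-mean rank order", {
  # Monte-Carlo over 5 seeds at ~400 CM cells/stage
  for (s in 1:5) {
    co <- simulateCohort(simConfig(nGenes = 400, nCellsPerStage = 667,
                                   conversionPlan = defaultConversionPlan(n = 10),
                                   seed = s))
    sce <- logNormalize(qcFilter(co$sce, minGenes = 10))
    res <- suppressWarnings(moduleScore(sce, mamGeneSet(), seed = 0))
    ss <- stageScoreSummary(res, sce, restrictType = "CM")
    m <- stats::setNames(ss$mean, ss$stage)
    expect_gt(m[["2w"]], m[["5w"]])
    expect_gt(m[["5w"]], m[["8w"]])
    expect_gte(m[["8w"]], max(m[["0w"]], m[["11w"]]))
  }
})

test_that("fixture round trip is exact and the manifest hash tracks the config", {
  cfg <- smallSimConfig(seed = 4, nCellsPerStage = 60L, convN = 1L)
  co <- simulateCohort(cfg)
  dir <- file.path(tempfile("fixture"), "out")
  manifest <- writeCohortFixture(co$sce, co$truth, dir, config = cfg)
  back <- readCohortFixture(dir)
  expect_identical(SummarizedExperiment::assay(back$sce, "counts"),
                   SummarizedExperiment::assay(co$sce, "counts"))
  expect_identical(back$truth@conversions$descendant,
                   co$truth@conversions$descendant)
  expect_identical(back$manifest$configHash, manifest$configHash)
  # refuses to clobber a non-empty directory
  expect_error(writeCohortFixture(co$sce, co$truth, dir), "non-empty")
  expect_silent(writeCohortFixture(co$sce, co$truth, dir, overwrite = TRUE))
  # hash changes when any config field changes
  cfg2 <- smallSimConfig(seed = 4, nCellsPerStage = 61L, convN = 1L)
  expect_false(identical(mamshift:::hashObject(mamshift:::configAsList(cfg)),
                         mamshift:::hashObject(mamshift:::configAsList(cfg2))))
})

test_that("empty conversion plan yields an empty planted-edge ledger", {
  cfg <- simConfig(nGenes = 120, nCellsPerStage = 40,
                   conversionPlan = data.frame(ancestor = character(),
                                               descendant = character(),
                                               transition = character(),
                                               n = integer()),
                   seed = 3)
  co <- simulateCohort(cfg)
  expect_identical(nrow(plantedEdges(co$truth)), 0L)
  expect_identical(nrow(co$truth@conversions), 0L)
  dir <- tempfile("empty")
  writeCohortFixture(co$sce, co$truth, dir)
  tl <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_length(tl$plantedEdges, 0)
})

test_that("infeasible configurations are rejected", {
  # proportions not summing to 1
  sched <- defaultSubtypeSchedule()
  sched[["2w"]][1] <- sched[["2w"]][1] + 0.1
  expect_error(simConfig(subtypeSchedule = sched), "sum")
  # conversion plan larger than the available cells
  cfg <- smallSimConfig(seed = 1, convN = 500L)
  expect_error(simulateCohort(cfg), "available")
  # conversion between non-adjacent stages
  plan <- data.frame(ancestor = "CM2", descendant = "CM9",
                     transition = "0w->5w", n = 2L)
  expect_error(simConfig(conversionPlan = plan), "adjacent")
})
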