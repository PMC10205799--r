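# Two-stage SCE with explicit logcounts for ancestry unit tests.
twoStageSCE <- function(m, stageOf, subtypeOf) {
  cnt <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
  sce <- makeSCE(cnt, stage = stageOf, subtype = subtypeOf,
                 stages = unique(stageOf))
  SummarizedExperiment::assay(sce, "logcounts") <- m
  sce
}

test_that("Spearman correlation to the previous stage matches closed forms", {
  g <- sprintf("g%d", 1:6)
  prev <- cbind(p1 = c(1, 2, 3, 4, 5, 6), p2 = c(6, 5, 4, 3, 2, 1),
                p3 = c(2, 1, 4, 3, 6, 5))
  rownames(prev) <- g
  q <- stats::setNames(c(1, 2, 3, 4, 5, 6), g)
  rho <- spearmanToPrevious(q, prev)
  expect_equal(rho[["p1"]], 1)            # identical ordering
  expect_equal(rho[["p2"]], -1)           # rank reversal
  expect_equal(rho[["p3"]], 29 / 35)      # hand rank computation
  # monotone transform of the query leaves rho unchanged
  expect_equal(spearmanToPrevious(exp(q), prev), rho)
  # degenerate inputs
  expect_error(spearmanToPrevious(q[1:2], prev[1:2, ]), "3 shared genes")
  expect_error(spearmanToPrevious(stats::setNames(rep(1, 6), g), prev),
               "zero expression variance")
  # zero-variance previous cell -> NaN for that cell only
  prev2 <- cbind(prev, p4 = rep(3, 6))
  rho2 <- spearmanToPrevious(q, prev2)
  expect_true(is.nan(rho2[["p4"]]))
  expect_equal(rho2[1:3], rho)
})

test_that("top-k selection is deterministic under ties and degenerate sizes", {
  rho <- stats::setNames(c(.9, .8, .8, .7, .7, .7, .1),
                         c("e", "d", "b", "g", "a", "f", "c"))
  top <- topKAncestors(rho, k = 5)
  # oracle: sort by (-rho, id): e(.9), b(.8), d(.8), then .7 ties a, f, g
  expect_identical(top$cells, c("e", "b", "d", "a", "f"))
  expect_identical(top$rho, c(.9, .8, .8, .7, .7))
  # identical across repeated calls
  expect_identical(topKAncestors(rho, k = 5), top)
  # fewer cells than k: all returned with a warning
  expect_warning(small <- topKAncestors(rho[1:3], k = 5), "only 3")
  expect_identical(length(small$cells), 3L)
  # k = 1 is the argmax
  expect_identical(topKAncestors(rho, k = 1)$cells, "e")
  # all-NaN is an error
  expect_error(topKAncestors(stats::setNames(rep(NaN, 3), c("a", "b", "c"))),
               "NaN")
})

test_that("subtype voting applies plurality with summed-rho then lexicographic ties", {
  labs <- stats::setNames(c("A", "A", "A", "B", "C"), paste0("p", 1:5))
  topk <- list(cells = paste0("p", 1:5), rho = c(.9, .8, .7, .6, .5))
  v <- voteAncestorSubtype(topk, labs)
  expect_identical(v$subtype, "A")
  expect_identical(v$tally, 3L)
  expect_equal(v$voteFraction, 3 / 5)
  # 2-2 tie: A has summed rho 1.7, B has 1.5 -> A
  labs2 <- stats::setNames(c("A", "A", "B", "B", "C"), paste0("p", 1:5))
  topk2 <- list(cells = paste0("p", 1:5), rho = c(.9, .8, .8, .7, .5))
  expect_identical(voteAncestorSubtype(topk2, labs2)$subtype, "A")
  # equal summed rho -> lexicographic
  topk3 <- list(cells = paste0("p", 1:5), rho = c(.8, .7, .8, .7, .5))
  expect_identical(voteAncestorSubtype(topk3, labs2)$subtype, "A")
  # k = 1
  expect_identical(
    voteAncestorSubtype(list(cells = "p4", rho = .6), labs2)$subtype, "B")
  # unlabeled ancestors are an error
  expect_error(voteAncestorSubtype(topk, labs[1:4]), "unlabeled")
})

test_that("conversion edges conserve support and vote only one ancestor when forced", {
  set.seed(31)
  g <- sprintf("g%02d", 1:20)
  nPrev <- 12; nCur <- 9
  m <- matrix(abs(rnorm(20 * (nPrev + nCur), mean = 2)), 20,
              dimnames = list(g, c(sprintf("a%02d", 1:nPrev),
                                   sprintf("b%02d", 1:nCur))))
  sce <- twoStageSCE(m, rep(c("0w", "2w"), c(nPrev, nCur)),
                     rep(c("CM1", "CM2"), c(nPrev, nCur)))
  graph <- conversionMatrix(sce, "0w", "2w", genes = "all")
  e <- edges(graph)
  expect_true(all(e$ancestor == "CM1"))
  expect_identical(sum(e$support), as.integer(nCur))
  # determinism
  graph2 <- conversionMatrix(sce, "0w", "2w", genes = "all")
  expect_identical(edges(graph2), e)
  expect_identical(graph2@assignments, graph@assignments)
  # non-adjacent transitions are rejected
  expect_error(conversionMatrix(sce, "2w", "0w"), "adjacent")
})

test_that("planted noisy-copy lineages are recovered at high support", {
  # all stage-2 cells of subtype B are noisy copies of stage-1 A cells
  for (s in 1:5) {
    set.seed(s)
    g <- sprintf("g%03d", 1:120)
    base <- rnorm(120, mean = 3)
    profA <- base + c(rep(2, 30), rep(0, 90))
    profC <- base + c(rep(0, 90), rep(2, 30))
    mk <- function(prof, n, sd = 0.4) {
      matrix(rnorm(120 * n, mean = prof, sd = sd), 120, n)
    }
    prevA <- mk(profA, 25); prevC <- mk(profC, 25)
    ancIdx <- sample(25, 20, replace = TRUE)
    curB <- prevA[, ancIdx] + matrix(rnorm(120 * 20, sd = 0.3), 120, 20)
    curC <- mk(profC, 15)
    m <- cbind(prevA, prevC, curB, curC)
    dimnames(m) <- list(g, sprintf("c%03d", seq_len(ncol(m))))
    sce <- twoStageSCE(m, rep(c("0w", "2w"), c(50, 35)),
                       rep(c("CMA", "CMC", "CMB", "CMC"), c(25, 25, 20, 15)))
    e <- edges(conversionMatrix(sce, "0w", "2w", genes = "all"))
    supAB <- e$support[e$ancestor == "CMA" & e$descendant == "CMB"]
    expect_gte(sum(supAB), 0.9 * 20)
  }
})

test_that("the vectorised pipeline equals the brute-force reference exactly", {
  # low integer counts force heavy rank ties; duplicated cells force exact
  # correlation ties at the cutoff
  for (s in 1:3) {
    set.seed(100 + s)
    g <- sprintf("g%02d", 1:25)
    nPrev <- 40; nCur <- 25
    cnt <- matrix(rpois(25 * (nPrev + nCur), lambda = 1.2), 25,
                  dimnames = list(g, sprintf("c%03d", seq_len(nPrev + nCur))))
    cnt[, 3] <- cnt[, 1]; cnt[, 7] <- cnt[, 1]        # duplicated prev cells
    cnt[, nPrev + 2] <- cnt[, nPrev + 1]              # duplicated query
    cnt <- cnt + 0.0
    sub <- c(sample(c("CM1", "CM2", "CM3"), nPrev, replace = TRUE),
             sample(c("CM4", "CM5"), nCur, replace = TRUE))
    sce <- twoStageSCE(cnt, rep(c("0w", "2w"), c(nPrev, nCur)), sub)
    graph <- conversionMatrix(sce, "0w", "2w", genes = g)
    cellTable <- as.data.frame(SummarizedExperiment::colData(sce))
    ref <- refConversionEdges(cnt, cellTable, "0w", "2w", k = 5, genes = g)
    got <- edges(graph)[, c("ancestor", "descendant", "support")]
    expect_equal(got$ancestor, ref$ancestor)
    expect_equal(got$descendant, ref$descendant)
    expect_equal(got$support, ref$support)
  }
})

test_that("selection rules enforce their boundaries and audit every exclusion", {
  edgesDf <- data.frame(
    ancestor = c("CM2", "CM2", "CM9", "CM7", "CM2"),
    descendant = c("CM9", "CM9", "CM2", "CM9", "CM7"),
    transition = c("0w->2w", "2w->5w", "0w->2w", "0w->2w", "0w->2w"),
    support = c(10L, 9L, 50L, 40L, 12L),
    voteFraction = c(.8, .7, .9, .8, .6))
  graph <- new("ConversionGraph", edges = edgesDf,
               assignments = data.frame(),
               params = list(k = 5L, stages = c("0w", "2w", "5w")))
  props <- rbind(
    data.frame(stage = "0w", subtype = c("CM2", "CM9", "CM7"),
               fraction = c(0.55, 0.05, 0.10)),
    data.frame(stage = "2w", subtype = c("CM2", "CM9", "CM7"),
               fraction = c(0.35, 0.25, 0.10)),
    data.frame(stage = "5w", subtype = c("CM2", "CM9", "CM7"),
               fraction = c(0.15, 0.45, 0.10)))
  sel <- selectTrajectorySubclusters(graph, props)
  ann <- sel$edges
  # CM7 sits at exactly 10% at every stage: excluded by the strict rule 1
  expect_false("CM7" %in% sel$subtypes)
  expect_match(ann$reason[ann$ancestor == "CM7"], "rule1_min_fraction")
  expect_match(ann$reason[ann$descendant == "CM7"], "rule1_min_fraction")
  # support 10 retained, support 9 excluded by rule 2
  expect_true(ann$retained[1])
  expect_false(ann$retained[2])
  expect_match(ann$reason[2], "rule2_min_support")
  # reverse edge CM9 -> CM2 conflicts with the proportion change (rule 3)
  expect_false(ann$retained[3])
  expect_match(ann$reason[3], "rule3_proportion_conflict")
  expect_false(ann$consistent[3])
  # strict variant also requires the descendant fraction to be non-decreasing
  selS <- selectTrajectorySubclusters(graph, props, consistency = "strict")
  expect_false(selS$edges$consistent[3])
  expect_true(selS$edges$consistent[1])
  # empty retained set is an explicit error
  expect_error(selectTrajectorySubclusters(graph, props, minFrac = 0.9),
               "empty")
})

test_that("planted conversion fixtures pass rule 3 in the planted direction only", {
  edgesDf <- data.frame(ancestor = c("CM2", "CM9"), descendant = c("CM9", "CM2"),
                        transition = "0w->2w", support = c(60L, 20L),
                        voteFraction = c(.8, .6))
  graph <- new("ConversionGraph", edges = edgesDf, assignments = data.frame(),
               params = list(k = 5L, stages = c("0w", "2w")))
  props <- rbind(
    data.frame(stage = "0w", subtype = c("CM2", "CM9"), fraction = c(0.30, 0.02)),
    data.frame(stage = "2w", subtype = c("CM2", "CM9"), fraction = c(0.05, 0.25)))
  sel <- selectTrajectorySubclusters(graph, props)
  expect_true(sel$edges$retained[1])
  expect_false(sel$edges$retained[2])
})

test_that("stage ordering layers the conversion DAG and reports cycles", {
  mk <- function(a, d, tr) data.frame(ancestor = a, descendant = d,
                                      transition = tr)
  expect_identical(
    stageOrderGraph(mk(c("CM2", "CM3"), c("CM9", "CM10"), "0w->2w")),
    list(c("CM2", "CM3"), c("CM10", "CM9")))
  expect_identical(stageOrderGraph(mk(character(0), character(0), character(0))),
                   list())
  expect_identical(
    stageOrderGraph(mk(c("CM2", "CM9"), c("CM9", "CM11"),
                       c("0w->2w", "2w->5w"))),
    list("CM2", "CM9", "CM11"))
  # self edges (persistence) are ignored, distinct-node cycles are fatal
  expect_identical(stageOrderGraph(mk("CM2", "CM2", "0w->2w")), list())
  expect_error(
    stageOrderGraph(mk(c("CM2", "CM9"), c("CM9", "CM2"), c("0w->2w", "2w->5w"))),
    "cycle")
})

test_that("edges are invariant to strictly increasing transforms of expression", {
  co <- simulateCohort(smallSimConfig(seed = 12, nCellsPerStage = 120L,
                                      convN = 2L))
  sce <- logNormalize(qcFilter(co$sce, minGenes = 5))
  hv <- selectHVGs(sce, 100)
  e1 <- edges(conversionMatrix(sce, "0w", "2w", genes = hv))
  warped <- sce
  SummarizedExperiment::assay(warped, "logcounts") <-
    exp(SummarizedExperiment::assay(sce, "logcounts")) * 2 + 1
  e2 <- edges(conversionMatrix(warped, "0w", "2w", genes = hv))
  expect_identical(e1, e2)
})

test_that("support conservation holds across the full graph", {
  co <- simulateCohort(smallSimConfig(seed = 13))
  sce <- logNormalize(qcFilter(co$sce, minGenes = 5))
  graph <- ancestryGraph(sce, nHVG = 150)
  e <- edges(graph)
  a <- graph@assignments
  for (tr in unique(e$transition)) {
    expect_identical(sum(e$support[e$transition == tr]),
                     sum(a$transition == tr))
  }
  # every voted cell is a CM cell of the current stage
  expect_true(all(a$cellId %in% colnames(sce)[sce$major_type == "CM"]))
})
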