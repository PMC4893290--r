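randomAssignment <- function(ids, id = "p") {
  SubtypeAssignment(ids, sample(subtypeLevels(), length(ids), replace = TRUE),
                    id)
}

test_that("consensus retains exactly the concordant samples", {
  ids <- sprintf("s%d", 1:4)
  a <- SubtypeAssignment(ids, c("BASAL", "HER2", "LUMA", "LUMB"), "p1")
  b <- SubtypeAssignment(ids, c("BASAL", "HER2", "LUMA", "LUMA"), "p2")
  cs <- buildConsensus(list(a, b), "T")
  expect_identical(sampleIds(cs), ids[1:3])
  expect_equal(retainedFraction(cs), 0.75)
  expect_equal(sum(perSubtypeCounts(cs)), 3L)

  # two identical assignments keep everything
  cs2 <- buildConsensus(list(a, a))
  expect_equal(retainedFraction(cs2), 1)
  expect_identical(as.character(subtypes(cs2)), as.character(subtypes(a)))
})

test_that("consensus is permutation invariant, monotone, and duplicate-proof", {
  set.seed(100)
  ids <- sprintf("s%03d", 1:300)
  panel <- lapply(1:4, function(i) randomAssignment(ids, paste0("p", i)))
  cs1 <- buildConsensus(panel)
  cs2 <- buildConsensus(rev(panel))
  expect_identical(sampleIds(cs1), sampleIds(cs2))
  expect_identical(subtypes(cs1), subtypes(cs2))
  # adding a predictor can only shrink or preserve the consensus
  for (k in 3:4) {
    prev <- buildConsensus(panel[seq_len(k - 1)])
    expect_true(all(sampleIds(buildConsensus(panel[seq_len(k)])) %in%
                    sampleIds(prev)))
  }
  # a duplicated predictor changes nothing
  cs3 <- buildConsensus(c(panel, panel[1]))
  expect_identical(sampleIds(cs3), sampleIds(cs1))
})

test_that("five independent uniform predictors retain about 4^-4 of samples", {
  set.seed(2024)
  ids <- sprintf("s%05d", seq_len(10000))
  panel <- lapply(1:5, function(i) randomAssignment(ids, paste0("p", i)))
  cs <- buildConsensus(panel)
  p <- 4^-4  # P(5-way agreement) = 4 * (1/4)^5
  sdBin <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(retainedFraction(cs) - p), 4 * sdBin)
})

test_that("mismatched sample universes are rejected with the difference", {
  a <- randomAssignment(sprintf("s%d", 1:5), "p1")
  b <- randomAssignment(sprintf("s%d", 2:6), "p2")
  expect_error(buildConsensus(list(a, b)), "symmetric difference.*s1")
})

test_that("the default panel yields five concordant predictors on clean data", {
  fx <- sharedSim()
  T1 <- fx$sim$datasets$D1
  ref <- trainSSP(applyRobustScaling(fx$sim$datasets$D3), fx$sim$truth$D3,
                  fx$gl$igls$P)
  panel <- defaultPanel(T1, ref, fx$gl$mgls, seed = 1,
                        pgrModule = fx$gl$pgrModule)
  expect_length(panel, 5L)
  ids <- vapply(panel, predictorId, "")
  expect_identical(anyDuplicated(ids), 0L)
  for (i in 1:4)
    for (j in (i + 1):5)
      expect_gt(kappaValue(cohensKappa(panel[[i]], panel[[j]])), 0.6)
  cs <- buildConsensus(panel, "D1")
  expect_gt(retainedFraction(cs), 0.5)
  expect_true(all(perSubtypeCounts(cs) > 0))
})

test_that("a reference model over absent genes fails the panel", {
  fx <- sharedSim()
  T1 <- fx$sim$datasets$D1
  centroids <- matrix(0, 4, 2, dimnames = list(sprintf("none%d", 1:4),
                                               c("BASAL", "LUMA")))
  badRef <- new("SSPModel", iglId = "bad", geneIds = rownames(centroids),
                centroids = centroids, metric = "spearman",
                trainingSetId = "x")
  expect_error(defaultPanel(T1, badRef, fx$gl$mgls, seed = 1,
                            pgrModule = fx$gl$pgrModule),
               "absent from the data")
})

test_that("the consensus suite reproduces its own consensus labels", {
  fx <- sharedSim()
  T1 <- fx$sim$datasets$D1
  ref <- trainSSP(applyRobustScaling(fx$sim$datasets$D3), fx$sim$truth$D3,
                  fx$gl$igls$P)
  cs <- buildConsensus(defaultPanel(T1, ref, fx$gl$mgls, seed = 1,
                                    pgrModule = fx$gl$pgrModule), "D1")
  suite <- trainCSSuite(cs, T1, fx$gl$igls, fx$gl$mgls, seed = 1,
                        pgrModule = fx$gl$pgrModule)
  expect_named(suite, c("ssp", "scm", "stg"))
  expect_length(suite$ssp, 3L)
  csTruth <- SubtypeAssignment(sampleIds(cs), subtypes(cs), "cs")
  scaledCS <- applyRobustScaling(T1)
  scaledCS <- SubtypeConcord:::.subsetExpr(scaledCS, samples = sampleIds(cs))
  for (model in suite$ssp) {
    k <- cohensKappa(predictSSP(model, scaledCS), csTruth)
    expect_gt(kappaValue(k), 0.9)
  }
  for (lid in names(suite$scm)) {
    sc <- scoreMatrix(T1, fx$gl$mgls[[lid]], pgrModule = fx$gl$pgrModule)
    csScores <- ModuleScores(moduleScores(sc)[sampleIds(cs), ],
                             mglId = lid, scaled = TRUE,
                             coverage = moduleCoverage(sc), datasetId = "D1")
    expect_gt(kappaValue(cohensKappa(predictSCM(suite$scm[[lid]], csScores),
                                     csTruth)), 0.9)
    expect_gt(kappaValue(cohensKappa(predictSTG(suite$stg[[lid]], csScores),
                                     csTruth)), 0.85)
  }
})

test_that("a consensus set missing a subtype cannot train the suite", {
  fx <- sharedSim()
  ids <- sprintf("s%d", 1:40)
  labels <- rep(c("BASAL", "LUMA"), 20)
  cs <- new("ConsensusSet", sourceDatasetId = "T", sampleIds = ids,
            labels = factor(labels, levels = subtypeLevels()),
            perSubtypeCounts = c(BASAL = 20L, HER2 = 0L, LUMA = 20L,
                                 LUMB = 0L),
            retainedFraction = 0.5)
  expect_error(trainCSSuite(cs, fx$sim$datasets$D1, fx$gl$igls, fx$gl$mgls),
               "below the minimum size")
})
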