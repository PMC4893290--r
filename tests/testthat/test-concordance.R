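test_that("kappa matches the hand-derived 2x2 example", {
  # counts [[20, 5], [10, 15]]: p_o = 0.7, p_e = 0.5, kappa = 0.4
  la <- c(rep("BASAL", 25), rep("HER2", 25))
  lb <- c(rep("BASAL", 20), rep("HER2", 5), rep("BASAL", 10), rep("HER2", 15))
  ids <- sprintf("s%d", 1:50)
  k <- cohensKappa(SubtypeAssignment(ids, la, "a"),
                   SubtypeAssignment(ids, lb, "b"))
  expect_equal(kappaValue(k), 0.4, tolerance = 1e-12)
  expect_equal(concordantPercent(k), 70)
  expect_identical(k@band, "fair")
  expect_identical(k@n, 50L)
})

test_that("perfect agreement gives kappa 1 and cc 100", {
  ids <- sprintf("s%d", 1:30)
  a <- SubtypeAssignment(ids, rep(subtypeLevels(), length.out = 30), "a")
  k <- cohensKappa(a, SubtypeAssignment(ids, subtypes(a), "b"))
  expect_equal(kappaValue(k), 1)
  expect_equal(concordantPercent(k), 100)
  expect_false(isDegenerate(k))
})

test_that("kappa agrees with the brute-force oracle on random pairs", {
  set.seed(500)
  for (i in 1:60) {
    n <- sample(5:200, 1)
    pair <- randomAssignmentPair(n, sample(2:4, 1))
    k <- cohensKappa(pair$a, pair$b)
    ref <- oracleKappa(subtypes(pair$a), subtypes(pair$b))
    if (is.na(ref)) {
      expect_true(isDegenerate(k))
    } else {
      expect_equal(kappaValue(k), ref, tolerance = 1e-12)
    }
    s <- sample(subtypeLevels(), 1)
    refs <- oracleSubtypeKappa(as.character(subtypes(pair$a)),
                               as.character(subtypes(pair$b)), s)
    got <- subtypeKappa(pair$a, pair$b, s)
    if (is.na(refs)) expect_true(is.na(got))
    else expect_equal(got, refs, tolerance = 1e-12)
  }
})

test_that("kappa is symmetric and invariant under label permutation", {
  set.seed(77)
  pair <- randomAssignmentPair(150, 4)
  k1 <- cohensKappa(pair$a, pair$b)
  k2 <- cohensKappa(pair$b, pair$a)
  expect_equal(kappaValue(k1), kappaValue(k2), tolerance = 1e-12)
  expect_lte(kappaValue(k1), 1)
  perm <- c(BASAL = "LUMB", HER2 = "LUMA", LUMA = "HER2", LUMB = "BASAL")
  pa <- SubtypeAssignment(sampleIds(pair$a),
                          perm[as.character(subtypes(pair$a))], "a")
  pb <- SubtypeAssignment(sampleIds(pair$b),
                          perm[as.character(subtypes(pair$b))], "b")
  k3 <- cohensKappa(pa, pb)
  expect_equal(kappaValue(k3), kappaValue(k1), tolerance = 1e-12)
  expect_equal(concordantPercent(k3), concordantPercent(k1))
})

test_that("degenerate agreement is flagged rather than forced to a number", {
  ids <- sprintf("s%d", 1:10)
  a <- SubtypeAssignment(ids, rep("LUMA", 10), "a")
  k <- cohensKappa(a, SubtypeAssignment(ids, rep("LUMA", 10), "b"))
  expect_true(isDegenerate(k))
  expect_true(is.na(kappaValue(k)))
  expect_equal(concordantPercent(k), 100)
  # a subtype absent from both assignments has undefined one-vs-rest kappa
  expect_true(is.na(subtypeKappa(a, a, "BASAL")))
  # binarized identical assignments with both classes present give 1
  b <- SubtypeAssignment(ids, rep(c("LUMA", "BASAL"), 5), "b")
  expect_equal(subtypeKappa(b, b, "BASAL"), 1)
})

test_that("qualitative bands follow the printed intervals", {
  expect_identical(kappaBand(0.467), "moderate")
  expect_identical(kappaBand(c(-0.3, 0.2, 0.21, 0.4, 0.45, 0.6, 0.7, 0.8,
                               0.81, 1)),
                   c("slight", "slight", "fair", "fair", "moderate",
                     "moderate", "substantial", "substantial",
                     "almost_perfect", "almost_perfect"))
})

test_that("sample universe mismatches are rejected", {
  a <- SubtypeAssignment(c("s1", "s2"), c("BASAL", "HER2"), "a")
  b <- SubtypeAssignment(c("s2", "s3"), c("BASAL", "HER2"), "b")
  expect_error(cohensKappa(a, b), "different samples")
})

test_that("aggregation partitions groups, excludes overlap and degenerates", {
  mk <- function(kappa, cc = 90, degen = FALSE)
    new("KappaResult", table = matrix(1L), kappa = kappa, cc = cc,
        perSubtypeKappa = stats::setNames(rep(kappa, 4), subtypeLevels()),
        band = "moderate", n = 10L, degenerate = degen)
  designs <- data.frame(
    type_a = c("SSP", "SSP", "SSP", "SSP", "SCM", "SSP"),
    type_b = c("SSP", "SSP", "SSP", "SSP", "SSP", "SSP"),
    gene_list_a = c("S", "S", "S", "S", "D", "S"),
    gene_list_b = c("H", "H", "S", "H", "S", "H"),
    cs_a = c("T1", "T1", "T1", "T1", "T1", "T1"),
    cs_b = c("T2", "T1", "T2", "T2", "T2", "T2"),
    validation_dataset = c("V1", "V1", "V1", "T1", "V1", "V1"))
  results <- list(mk(0.2), mk(0.9), mk(0.5), mk(0.99), mk(0.7),
                  mk(NA_real_, degen = TRUE))
  agg <- aggregateConcordance(designs, results)
  expect_equal(agg$n_excluded_overlap, 1)
  expect_equal(agg$n_excluded_degenerate, 1)
  s <- agg$summary
  both <- s[s$group == "both_differ" & s$subtype == "ALL", ]
  expect_equal(both$n, 1L)
  expect_equal(both$median_kappa, 0.2)
  expect_equal(s[s$group == "gene_list_differs" & s$subtype == "ALL",
                 "median_kappa"], 0.9)
  expect_equal(s[s$group == "cs_differs" & s$subtype == "ALL",
                 "median_kappa"], 0.5)
  expect_equal(s[s$group == "inter_type" & s$subtype == "ALL",
                 "median_kappa"], 0.7)

  # odd-count median over three results in one group
  d3 <- designs[c(1, 1, 1), ]
  agg3 <- aggregateConcordance(d3, list(mk(0.2), mk(0.9), mk(0.5)))
  expect_equal(agg3$summary[agg3$summary$subtype == "ALL", "median_kappa"],
               0.5)

  # everything excluded errors
  expect_error(aggregateConcordance(designs[4, , drop = FALSE],
                                    list(mk(0.9))),
               "all comparisons excluded")
})
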