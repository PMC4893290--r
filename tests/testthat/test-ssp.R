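makeLabeled <- function(nPer = 6, nGenes = 12, seed = 21) {
  set.seed(seed)
  labs <- rep(subtypeLevels(), each = nPer)
  n <- length(labs)
  shift <- matrix(rnorm(4 * nGenes, sd = 2), 4, nGenes,
                  dimnames = list(subtypeLevels(), NULL))
  v <- t(shift[labs, ]) + matrix(rnorm(nGenes * n, sd = 0.3), nGenes, n)
  dimnames(v) <- list(sprintf("g%02d", seq_len(nGenes)),
                      sprintf("s%02d", seq_len(n)))
  list(m = SubtypeExpression(v, scaled = TRUE),
       labels = SubtypeAssignment(colnames(v), labs))
}

test_that("centroids are per-subtype gene means over the training set", {
  fx <- makeLabeled()
  igl <- IGL("X", rownames(fx$m))
  model <- trainSSP(fx$m, fx$labels, igl, minClassSize = 2)
  v <- exprValues(fx$m)
  labs <- subtypes(fx$labels)
  for (s in subtypeLevels()) {
    manual <- numeric(nrow(v))
    cols <- which(labs == s)
    for (i in seq_len(nrow(v))) manual[i] <- sum(v[i, cols]) / length(cols)
    expect_equal(unname(model@centroids[, s]), manual, tolerance = 1e-12)
  }

  # duplicating every training sample leaves centroids unchanged
  v2 <- cbind(v, v)
  colnames(v2) <- sprintf("s%02d", seq_len(ncol(v2)))
  fx2m <- SubtypeExpression(v2, scaled = TRUE)
  lab2 <- SubtypeAssignment(colnames(v2), rep(as.character(labs), 2))
  model2 <- trainSSP(fx2m, lab2, igl, minClassSize = 2)
  expect_equal(model2@centroids, model@centroids, tolerance = 1e-12)
})

test_that("training enforces class sizes and gene overlap", {
  fx <- makeLabeled(nPer = 3)
  igl <- IGL("X", rownames(fx$m))
  expect_error(trainSSP(fx$m, fx$labels, igl, minClassSize = 5),
               "below the minimum class size")
  expect_error(trainSSP(fx$m, fx$labels, IGL("Y", c("none1", "none2")),
                        minClassSize = 2),
               "empty intersection")
})

test_that("prediction assigns the nearest centroid under each metric", {
  # 2-gene toy: centroids B=(1,0), H=(0,1); sample (0.9, 0.2) is closer to B
  centroids <- matrix(c(1, 0, 0, 1), 2, 2,
                      dimnames = list(c("g1", "g2"), c("BASAL", "HER2")))
  model <- new("SSPModel", iglId = "toy", geneIds = c("g1", "g2"),
               centroids = centroids, metric = "euclidean",
               trainingSetId = "toy")
  m <- SubtypeExpression(matrix(c(0.9, 0.2), 2, 1,
                                dimnames = list(c("g1", "g2"), "s1")),
                         scaled = TRUE)
  out <- predictSSP(model, m)
  expect_identical(as.character(subtypes(out)), "BASAL")
  d <- attr(out, "distances")
  expect_equal(unname(d[1, ]), c(sqrt(0.01 + 0.04), sqrt(0.81 + 0.64)),
               tolerance = 1e-12)

  # a sample identical to a centroid has distance 0 under any metric
  fx <- makeLabeled()
  igl <- IGL("X", rownames(fx$m))
  for (metric in c("spearman", "pearson", "euclidean")) {
    mod <- trainSSP(fx$m, fx$labels, igl, metric = metric, minClassSize = 2)
    self <- SubtypeExpression(mod@centroids[, "LUMA", drop = FALSE],
                              scaled = TRUE)
    colnames(self) <- "x"
    out <- predictSSP(mod, self)
    expect_identical(as.character(subtypes(out)), "LUMA")
    expect_equal(min(attr(out, "distances")), 0, tolerance = 1e-10)
  }
})

test_that("spearman predictions are invariant to monotone transforms", {
  fx <- makeLabeled(seed = 33)
  igl <- IGL("X", rownames(fx$m))
  model <- trainSSP(fx$m, fx$labels, igl, metric = "spearman",
                    minClassSize = 2)
  p1 <- predictSSP(model, fx$m)
  warped <- SubtypeExpression(exp(0.8 * exprValues(fx$m)) + 2, scaled = TRUE)
  p2 <- predictSSP(model, warped)
  expect_identical(subtypes(p1), subtypes(p2))

  # affine transform of a centroid still matches it
  aff <- SubtypeExpression(
    2 * model@centroids[, "BASAL", drop = FALSE] + 5, scaled = TRUE)
  colnames(aff) <- "x"
  expect_identical(as.character(subtypes(predictSSP(model, aff))), "BASAL")
})

test_that("prediction agrees with a brute-force nearest-centroid oracle", {
  fx <- makeLabeled(nPer = 8, nGenes = 15, seed = 77)
  igl <- IGL("X", rownames(fx$m))
  model <- trainSSP(fx$m, fx$labels, igl, metric = "euclidean",
                    minClassSize = 2)
  test <- makeToyExpression(nGenes = 15, nSamples = 30, seed = 99)
  test <- SubtypeExpression(exprValues(test) - 7, scaled = TRUE)
  out <- predictSSP(model, test)
  v <- exprValues(test)
  for (j in seq_len(ncol(v))) {
    dist <- vapply(colnames(model@centroids), function(s)
      sqrt(sum((v[, j] - model@centroids[, s])^2)), numeric(1))
    expect_identical(as.character(subtypes(out))[j],
                     names(dist)[which.min(dist)])
  }
})

test_that("missing model genes error unless intersect mode is allowed", {
  fx <- makeLabeled()
  igl <- IGL("X", rownames(fx$m))
  model <- trainSSP(fx$m, fx$labels, igl, minClassSize = 2)
  sub <- SubtypeExpression(exprValues(fx$m)[-1, , drop = FALSE], scaled = TRUE)
  expect_error(predictSSP(model, sub), "absent from the data")
  out <- predictSSP(model, sub, intersect = TRUE)
  expect_identical(attr(out, "genes_used"), nrow(fx$m) - 1L)
  tiny <- SubtypeExpression(exprValues(fx$m)[1:2, , drop = FALSE],
                            scaled = TRUE)
  expect_error(predictSSP(model, tiny, intersect = TRUE),
               "fewer than 3 model genes")
})
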