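test_that("probeset collapsing keeps the most variable probeset per gene", {
  v <- rbind(p1 = c(0, 2, 4, 6),    # variance 20/3
             p2 = c(3, 3.5, 3, 3.5),
             p3 = c(1, 1, 2, 2))
  colnames(v) <- sprintf("s%d", 1:4)
  m <- SubtypeExpression(v, level = "probeset")
  map <- GeneMapping(c("p1", "p2", "p3"), c("G", "G", "H"))
  out <- collapseProbesets(m, map)
  expect_identical(exprLevel(out), "gene")
  expect_setequal(rownames(out), c("G", "H"))
  expect_equal(exprValues(out)["G", ], v["p1", ])
  prov <- S4Vectors::metadata(out)$collapse_map
  expect_identical(prov$probeset_id[prov$gene_id == "G"], "p1")
})

test_that("collapsing is identity-like for distinct genes and idempotent", {
  m <- makeToyExpression(level = "probeset", prefix = "p")
  genes <- sprintf("G%02d", seq_len(nrow(m)))
  map <- GeneMapping(rownames(m), genes)
  out <- collapseProbesets(m, map)
  expect_equal(unname(exprValues(out)[order(rownames(out)), ]),
               unname(exprValues(m)[order(genes), ]))
  expect_identical(collapseProbesets(out, map), out)  # gene level: no-op
})

test_that("exact variance ties are broken by lexicographic probeset id", {
  # verified against exhaustive enumeration of both 2-probeset orders
  v <- rbind(pB = c(1, 2, 3), pA = c(3, 2, 1))
  colnames(v) <- sprintf("s%d", 1:3)
  for (ord in list(c(1, 2), c(2, 1))) {
    m <- SubtypeExpression(v[ord, ], level = "probeset")
    out <- collapseProbesets(m, GeneMapping(c("pA", "pB"), c("G", "G")))
    expect_equal(exprValues(out)["G", ], v["pA", ])
  }
})

test_that("unmappable input raises while partial mapping drops probesets", {
  m <- makeToyExpression(level = "probeset", prefix = "p")
  expect_error(collapseProbesets(m, GeneMapping("zzz", "G")),
               "no features mappable")
  out <- collapseProbesets(m, GeneMapping(rownames(m)[1:3],
                                          c("G1", "G2", "G3")))
  expect_identical(nrow(out), 3L)
})

test_that("percentile fitting matches the hand interpolation rule", {
  # 41 evenly spaced points on [0, 1]
  v <- matrix(seq(0, 1, length.out = 41), 1, 41,
              dimnames = list("f", sprintf("s%d", 1:41)))
  p <- fitRobustScaling(SubtypeExpression(v))
  expect_equal(p@qLow, 0.025, tolerance = 1e-12)
  expect_equal(p@qHigh, 0.975, tolerance = 1e-12)

  # two samples: interpolation between the order statistics
  v2 <- matrix(c(0, 10), 1, 2, dimnames = list("f", c("s1", "s2")))
  p2 <- fitRobustScaling(SubtypeExpression(v2))
  expect_equal(p2@qLow, 0.25, tolerance = 1e-12)
  expect_equal(p2@qHigh, 9.75, tolerance = 1e-12)

  # constant feature
  v3 <- matrix(5, 1, 5, dimnames = list("f", sprintf("s%d", 1:5)))
  p3 <- fitRobustScaling(SubtypeExpression(v3))
  expect_equal(p3@qLow, 5)
  expect_equal(p3@qHigh, 5)

  # random data against the brute-force oracle
  set.seed(11)
  m <- makeToyExpression(nGenes = 6, nSamples = 37, seed = 11)
  p4 <- fitRobustScaling(m)
  for (i in seq_len(6)) {
    expect_equal(p4@qLow[i], oracleQuantile(exprValues(m)[i, ], 0.025),
                 tolerance = 1e-12)
    expect_equal(p4@qHigh[i], oracleQuantile(exprValues(m)[i, ], 0.975),
                 tolerance = 1e-12)
  }

  expect_error(fitRobustScaling(SubtypeExpression(
    matrix(1, 2, 1, dimnames = list(c("a", "b"), "s1")))),
    "single-sample")
})

test_that("scaling maps the anchor percentiles to -1/+1 without clipping", {
  p <- ScalingParams("f", 2, 6)
  v <- matrix(c(2, 6, 4, 5, 8), 1, 5,
              dimnames = list("f", sprintf("s%d", 1:5)))
  out <- exprValues(applyRobustScaling(SubtypeExpression(v), p))
  expect_equal(unname(out[1, ]), c(-1, 1, 0, 0.5, 2))  # x=8 maps beyond +1

  # constant features map to zero
  pc <- ScalingParams("f", 5, 5)
  outc <- exprValues(applyRobustScaling(SubtypeExpression(
    matrix(c(5, 7), 1, 2, dimnames = list("f", c("s1", "s2")))), pc))
  expect_equal(unname(outc[1, ]), c(0, 0))

  expect_error(applyRobustScaling(SubtypeExpression(v), ScalingParams("g", 0, 1)),
               "no scaling parameters for feature")
})

test_that("scaled features hit -1/+1 at their empirical anchor percentiles", {
  m <- makeToyExpression(nGenes = 8, nSamples = 81, seed = 3)
  s <- applyRobustScaling(m)
  expect_true(isScaled(s))
  q <- apply(exprValues(s), 1, quantile, probs = c(0.025, 0.975), type = 7)
  expect_equal(unname(q[1, ]), rep(-1, 8), tolerance = 1e-10)
  expect_equal(unname(q[2, ]), rep(1, 8), tolerance = 1e-10)
})

test_that("scaling is equivariant under positive affine transforms", {
  m <- makeToyExpression(nGenes = 5, nSamples = 40, seed = 9)
  s1 <- exprValues(applyRobustScaling(m))
  v2 <- 3.7 * exprValues(m) - 11
  s2 <- exprValues(applyRobustScaling(SubtypeExpression(v2)))
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("pooled scaling fits on the concatenation and applies to the target", {
  fx <- sharedSim()
  target <- fx$sim$datasets$D1
  anchor <- fx$sim$datasets$D2
  out <- pooledScale(target, anchor)
  expect_identical(colnames(out), colnames(target))
  # direct recomputation: scale the concatenated matrix, keep target columns
  pooled <- SubtypeExpression(cbind(exprValues(target), exprValues(anchor)),
                              datasetId = "pool")
  ref <- exprValues(applyRobustScaling(pooled))[, colnames(target)]
  expect_equal(exprValues(out), ref, tolerance = 1e-12)

  # empty anchor reduces to plain within-dataset scaling
  empty <- SubtypeExpression(
    exprValues(anchor)[, 0, drop = FALSE], datasetId = "empty")
  expect_equal(exprValues(pooledScale(target, empty)),
               exprValues(applyRobustScaling(target)), tolerance = 1e-12)

  # disjoint features error
  other <- makeToyExpression(prefix = "zz")
  expect_error(pooledScale(target, other), "feature spaces disagree")
})
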