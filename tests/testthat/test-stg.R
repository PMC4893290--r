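makeMarkerScores <- function(x, scaled = TRUE) {
  ModuleScores(x, mglId = "toy", scaled = scaled,
               coverage = stats::setNames(rep(1, ncol(x)), colnames(x)),
               datasetId = "toy")
}

test_that("the rule table is total, consistent and covers all subtypes", {
  rt <- stgRuleTable()
  key <- paste(rt$ER, rt$HER2, rt$PGR, rt$PROLIF)
  expect_identical(nrow(rt), 16L)
  expect_identical(anyDuplicated(key), 0L)
  expect_setequal(unique(rt$subtype), subtypeLevels())
  expect_true(all(rt$subtype[rt$HER2 == "+"] == "HER2"))
  hrPos <- rt$HER2 == "-" & (rt$ER == "+" | rt$PGR == "+")
  expect_true(all(rt$subtype[hrPos & rt$PROLIF == "-"] == "LUMA"))
  expect_true(all(rt$subtype[hrPos & rt$PROLIF == "+"] == "LUMB"))
  expect_true(all(rt$subtype[rt$HER2 == "-" & rt$ER == "-" & rt$PGR == "-"]
                  == "BASAL"))
})

test_that("worked marker profiles map to the expected subtypes", {
  rt <- stgRuleTable()
  pick <- function(er, her2, pgr, prolif)
    rt$subtype[rt$ER == er & rt$HER2 == her2 & rt$PGR == pgr &
               rt$PROLIF == prolif]
  expect_identical(pick("+", "-", "+", "-"), "LUMA")
  expect_identical(pick("-", "-", "-", "+"), "BASAL")
  # every HER2+ profile, regardless of the other markers
  expect_identical(unique(rt$subtype[rt$HER2 == "+"]), "HER2")
})

test_that("mixture cutpoints solve the equal-posterior equation", {
  set.seed(61)
  n <- 600
  sym <- ifelse(runif(n) < 0.5, rnorm(n, -1, 0.4), rnorm(n, 1, 0.4))
  x <- cbind(ER = sym,
             HER2 = ifelse(runif(n) < 0.3, rnorm(n, 1, 0.4),
                           rnorm(n, -1, 0.4)),
             PROLIF = ifelse(runif(n) < 0.5, rnorm(n, -1, 0.4),
                             rnorm(n, 1, 0.4)),
             PGR = ifelse(runif(n) < 0.5, rnorm(n, -0.9, 0.35),
                          rnorm(n, 0.9, 0.35)))
  rownames(x) <- sprintf("s%03d", seq_len(n))
  model <- fitSTG(makeMarkerScores(x), seed = 1)
  # balanced symmetric mixture: cutpoint near 0
  expect_lt(abs(model@cutpoints["ER"]), 0.2)
  # every cutpoint is an equal-posterior root: refit the marker mixture and
  # check the posterior balance numerically via the closed-form equal-variance
  # approximation direction (lighter component pulls the cutpoint toward it)
  expect_gt(model@cutpoints["HER2"], 0)  # 30/70 mixture favours the heavier low mode
})

test_that("equal-variance unequal-weight cutpoint matches the closed form", {
  split <- list(pi = 0.3, muLow = -1, muHigh = 1, sdLow = 0.5, sdHigh = 0.5)
  cp <- SubtypeConcord:::.equalPosteriorCutpoint(split)
  # closed form: midpoint + sigma^2 log(pi1/pi2) / (mu2 - mu1)
  ref <- 0 + 0.25 * log(0.3 / 0.7) / 2
  expect_equal(cp, ref, tolerance = 1e-8)

  sym <- list(pi = 0.5, muLow = -1, muHigh = 1, sdLow = 0.5, sdHigh = 0.5)
  expect_equal(SubtypeConcord:::.equalPosteriorCutpoint(sym), 0,
               tolerance = 1e-8)
})

test_that("threshold mode fixes all cutpoints at zero", {
  set.seed(9)
  x <- matrix(rnorm(200), 50, 4,
              dimnames = list(sprintf("s%d", 1:50), moduleLevels()))
  model <- fitSTG(makeMarkerScores(x), mode = "threshold")
  expect_equal(unname(model@cutpoints), rep(0, 4))
})

test_that("prediction dichotomizes at the cutpoint with ties under", {
  model <- new("STGModel", mglId = "toy",
               cutpoints = stats::setNames(rep(0, 4), moduleLevels()),
               ruleTable = stgRuleTable(), trainingSetId = "toy")
  x <- rbind(luma = c(ER = 1, HER2 = -1, PROLIF = -1, PGR = 1),
             lumb = c(ER = 1, HER2 = -1, PROLIF = 1, PGR = -1),
             basal = c(ER = -1, HER2 = -1, PROLIF = 1, PGR = -1),
             her2 = c(ER = 1, HER2 = 1, PROLIF = 1, PGR = 1),
             atCut = c(ER = 0, HER2 = 0, PROLIF = 0, PGR = 0))
  out <- predictSTG(model, makeMarkerScores(x))
  expect_identical(as.character(subtypes(out)),
                   c("LUMA", "LUMB", "BASAL", "HER2", "BASAL"))
  prof <- attr(out, "profiles")
  expect_identical(unname(prof["atCut", ]), rep("-", 4))  # ties underexpress
})

test_that("prediction is invariant to joint monotone transforms", {
  set.seed(3)
  x <- matrix(rnorm(200), 50, 4,
              dimnames = list(sprintf("s%d", 1:50), moduleLevels()))
  cut1 <- stats::setNames(c(0.1, -0.2, 0.3, 0), moduleLevels())
  m1 <- new("STGModel", mglId = "toy", cutpoints = cut1,
            ruleTable = stgRuleTable(), trainingSetId = "toy")
  f <- function(z) z^3 + 2 * z  # strictly increasing
  m2 <- new("STGModel", mglId = "toy", cutpoints = f(cut1),
            ruleTable = stgRuleTable(), trainingSetId = "toy")
  p1 <- predictSTG(m1, makeMarkerScores(x))
  p2 <- predictSTG(m2, makeMarkerScores(f(x)))
  expect_identical(subtypes(p1), subtypes(p2))
})

test_that("degenerate marker mixtures advise threshold mode", {
  set.seed(8)
  x <- matrix(rnorm(160, sd = 1e-4), 40, 4,
              dimnames = list(sprintf("s%d", 1:40), moduleLevels()))
  expect_error(fitSTG(makeMarkerScores(x), separationFloor = 0.5),
               "threshold")
})
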