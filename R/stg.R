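# Rule-based STG predictor following the St. Gallen surrogate intrinsic
# subtype definitions. Each of the four marker scores (ER, HER2, PGR,
# proliferation) is dichotomized at a per-marker cutpoint; the resulting
# 2^4 = 16 over/underexpression profiles map to the four subtypes through an
# explicit rule table. The original five-subtype surrogate taxonomy is folded
# to four subtypes by mapping luminal B/HER2+ to HER2 and luminal B/HER2- to
# luminal B; hormone-receptor-positive profiles (ER+ or PGR+) with low
# proliferation are luminal A, with high proliferation luminal B; triple
# negative profiles are basal.

#' The canonical 16-row St. Gallen surrogate rule table
#'
#' @return data.frame with columns `ER`, `HER2`, `PGR`, `PROLIF` (each `"+"`
#'   or `"-"`) and `subtype`, covering all 16 marker profiles.
#' @export
#' @examples
#' stgRuleTable()
stgRuleTable <- function() {
  pm <- c("-", "+")
  rt <- expand.grid(ER = pm, HER2 = pm, PGR = pm, PROLIF = pm,
                    stringsAsFactors = FALSE)
  sub <- character(nrow(rt))
  her2 <- rt$HER2 == "+"
  hr <- rt$ER == "+" | rt$PGR == "+"
  sub[her2] <- "HER2"
  sub[!her2 & hr & rt$PROLIF == "-"] <- "LUMA"
  sub[!her2 & hr & rt$PROLIF == "+"] <- "LUMB"
  sub[!her2 & !hr] <- "BASAL"
  rt$subtype <- sub
  rt
}

# Equal-posterior point of a univariate 2-component mixture. With equal
# component variances the posterior is strictly monotone in the score, so a
# unique crossing exists and has a closed form (it can lie outside the
# inter-mean interval when the mixing weights are lopsided). With unequal
# variances the relevant root is searched between the two means; NA when no
# crossing lies there.
.equalPosteriorCutpoint <- function(split) {
  if (abs(split$sdLow - split$sdHigh) < 1e-10) {
    s2 <- split$sdLow^2
    d <- split$muHigh - split$muLow
    return((split$muLow + split$muHigh) / 2 +
             s2 * log(split$pi / (1 - split$pi)) / d)
  }
  f <- function(x)
    log(split$pi) + dnorm(x, split$muLow, split$sdLow, log = TRUE) -
      log(1 - split$pi) - dnorm(x, split$muHigh, split$sdHigh, log = TRUE)
  lo <- split$muLow
  hi <- split$muHigh
  if (f(lo) <= 0 || f(hi) >= 0)
    return(NA_real_)  # no sign change between the means
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Fit an STG predictor
#'
#' For every marker a univariate 2-component Gaussian mixture is fitted to
#' the scaled scores; the cutpoint is the equal-posterior point between the
#' two component means. With `mode = "threshold"` the cutpoints are fixed at
#' 0 instead (the midpoint of the robustly scaled axis).
#'
#' @param scores a scaled [ModuleScores-class] with all four marker columns.
#' @param seed integer seed recorded for provenance; fitting is deterministic.
#' @param mode `"mixture"` (default) or `"threshold"`.
#' @param minSamples minimum number of samples (default 30).
#' @param separationFloor minimum distance between the two component means on
#'   the scaled axis; below it the fit is considered degenerate.
#' @return An [STGModel-class].
#' @export
fitSTG <- function(scores, seed = NULL, mode = c("mixture", "threshold"),
                   minSamples = 30L, separationFloor = 0.1) {
  mode <- match.arg(mode)
  stopifnot(is(scores, "ModuleScores"))
  if (!isScaled(scores))
    stop("STG fitting requires robustly scaled module scores")
  sc <- moduleScores(scores)
  if (!all(moduleLevels() %in% colnames(sc)))
    stop("missing marker column(s): ",
         paste(setdiff(moduleLevels(), colnames(sc)), collapse = ", "))
  if (nrow(sc) < minSamples)
    stop("at least ", minSamples, " samples required to fit an STG")
  if (!is.null(seed)) set.seed(seed)
  cutpoints <- stats::setNames(numeric(4L), moduleLevels())
  if (identical(mode, "mixture")) {
    for (mk in moduleLevels()) {
      # equal-variance components: the posterior is monotone in the score, so
      # a unique equal-posterior cutpoint exists whenever the mixture is
      # informative
      split <- .fitUnivariateMixture(sc[, mk], what = paste0(mk, " marker"),
                                     modelNames = "E")
      if (split$muHigh - split$muLow < separationFloor)
        stop(sprintf(
          "degenerate %s marker mixture (component means %.3f and %.3f); consider mode = 'threshold'",
          mk, split$muLow, split$muHigh))
      cp <- .equalPosteriorCutpoint(split)
      if (is.na(cp))
        stop(sprintf(
          "no equal-posterior point between the %s component means; consider mode = 'threshold'",
          mk))
      cutpoints[mk] <- cp
    }
  }
  new("STGModel", mglId = scores@mglId, cutpoints = cutpoints,
      ruleTable = stgRuleTable(), trainingSetId = datasetId(scores))
}

#' Predict subtypes with an STG predictor
#'
#' A marker is called overexpressed (`"+"`) when its score exceeds the
#' cutpoint strictly; a score exactly at the cutpoint is underexpressed. The
#' 4-marker profile indexes the model's rule table.
#'
#' @param model an [STGModel-class].
#' @param scores a scaled [ModuleScores-class] with all four marker columns.
#' @return A [SubtypeAssignment-class]; the per-sample status profile is
#'   attached as attribute `"profiles"` (character matrix of `"+"`/`"-"`).
#' @export
predictSTG <- function(model, scores) {
  stopifnot(is(model, "STGModel"), is(scores, "ModuleScores"))
  sc <- moduleScores(scores)
  if (!all(moduleLevels() %in% colnames(sc)))
    stop("missing marker column(s): ",
         paste(setdiff(moduleLevels(), colnames(sc)), collapse = ", "))
  if (anyNA(sc[, moduleLevels()]))
    stop("missing marker scores")
  status <- vapply(moduleLevels(), function(mk)
    ifelse(sc[, mk] > model@cutpoints[mk], "+", "-"),
    character(nrow(sc)))
  status <- matrix(status, nrow = nrow(sc),
                   dimnames = list(rownames(sc), moduleLevels()))
  rt <- model@ruleTable
  key <- paste(rt$ER, rt$HER2, rt$PGR, rt$PROLIF)
  prof <- paste(status[, "ER"], status[, "HER2"], status[, "PGR"],
                status[, "PROLIF"])
  label <- rt$subtype[match(prof, key)]
  out <- SubtypeAssignment(rownames(sc), label,
                           predictorId = paste0("STG.", model@mglId, ".",
                                                model@trainingSetId))
  attr(out, "profiles") <- status
  out
}
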