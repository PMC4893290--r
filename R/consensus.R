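# Consensus sets: the samples of a training cohort on which every predictor
# of a panel agrees. The default panel mirrors the semi-supervised scheme:
# one reference nearest-centroid predictor (applied to robustly scaled
# expression) plus three SCMs and one STG fitted unsupervised on the cohort's
# scaled module scores. Consensus samples and their agreed labels then serve
# as a supervised training set for a full suite of predictors.

#' Build a consensus set from a panel of assignments
#'
#' Retains exactly the samples for which all assignments agree; the agreed
#' label becomes the consensus label.
#'
#' @param assignments list of at least two [SubtypeAssignment-class] objects
#'   over identical sample universes.
#' @param sourceDatasetId label of the cohort the assignments came from;
#'   defaults to `"T"`.
#' @return A [ConsensusSet-class].
#' @export
buildConsensus <- function(assignments, sourceDatasetId = "T") {
  stopifnot(is.list(assignments), length(assignments) >= 2L)
  ids <- sampleIds(assignments[[1L]])
  for (a in assignments[-1L]) {
    if (!setequal(ids, sampleIds(a))) {
      d <- union(setdiff(ids, sampleIds(a)), setdiff(sampleIds(a), ids))
      stop("assignments cover different samples; symmetric difference: ",
           paste(head(d, 10L), collapse = ", "),
           if (length(d) > 10L) ", ...")
    }
  }
  lab <- vapply(assignments, function(a)
    as.character(subtypes(a))[match(ids, sampleIds(a))],
    character(length(ids)))
  lab <- matrix(lab, nrow = length(ids))
  agree <- rowSums(lab == lab[, 1L]) == ncol(lab)
  labels <- .canonicalSubtypes(lab[agree, 1L])
  counts <- table(labels)
  new("ConsensusSet", sourceDatasetId = as.character(sourceDatasetId),
      sampleIds = ids[agree], labels = labels,
      perSubtypeCounts = stats::setNames(as.integer(counts), names(counts)),
      retainedFraction = sum(agree) / length(ids))
}

#' The default five-predictor consensus panel
#'
#' Applies (i) a reference nearest-centroid model to the robustly scaled
#' cohort, fits (ii) three SCMs on the cohort's scaled module scores (one per
#' MGL) and (iii) one STG on the first MGL's markers, and returns the five
#' resulting subtype assignments on the cohort.
#'
#' @param T a gene-level, unscaled [SubtypeExpression-class] training cohort.
#' @param referenceSSP an [SSPModel-class] serving as the fixed reference
#'   predictor (e.g. a published centroid model loaded from file).
#' @param mgls list of three [GeneListSet-class] MGLs.
#' @param seed integer seed forwarded to the mixture fits.
#' @param pgrModule optional single-gene PGR module forwarded to
#'   [scoreMatrix()].
#' @param stgMGL index of the MGL whose modules feed the STG (default 1).
#' @return List of five [SubtypeAssignment-class] objects.
#' @export
defaultPanel <- function(T, referenceSSP, mgls, seed = NULL,
                         pgrModule = NULL, stgMGL = 1L) {
  stopifnot(is(T, "SubtypeExpression"), is(referenceSSP, "SSPModel"),
            length(mgls) == 3L)
  scaled <- applyRobustScaling(T)
  out <- list(predictSSP(referenceSSP, scaled))
  scoresList <- lapply(mgls, scoreMatrix, m = T, scale = TRUE,
                       pgrModule = pgrModule)
  for (sc in scoresList)
    out[[length(out) + 1L]] <- predictSCM(fitSCM(sc, seed = seed), sc)
  scSTG <- scoresList[[stgMGL]]
  out[[length(out) + 1L]] <- predictSTG(fitSTG(scSTG, seed = seed), scSTG)
  out
}

#' Train the consensus-set predictor suite
#'
#' Trains, on the consensus samples only, three nearest-centroid predictors
#' (one per IGL, supervised by the consensus labels), three SCMs and three
#' STGs (one per MGL, fitted on the consensus samples' scaled module scores).
#'
#' @param cs a [ConsensusSet-class].
#' @param T the gene-level, unscaled [SubtypeExpression-class] cohort the
#'   consensus set came from.
#' @param igls list of three IGL [GeneListSet-class] objects.
#' @param mgls list of three MGL [GeneListSet-class] objects.
#' @param seed integer seed forwarded to the mixture fits.
#' @param pgrModule optional single-gene PGR module for [scoreMatrix()].
#' @param metric distance metric for the nearest-centroid models.
#' @param minClassSize minimum consensus samples per subtype (default 5).
#' @return List with elements `ssp`, `scm`, `stg`, each a list of three
#'   fitted models named by gene list id.
#' @export
trainCSSuite <- function(cs, T, igls, mgls, seed = NULL, pgrModule = NULL,
                         metric = "spearman", minClassSize = 5L) {
  stopifnot(is(cs, "ConsensusSet"), is(T, "SubtypeExpression"),
            length(igls) == 3L, length(mgls) == 3L)
  counts <- table(factor(subtypes(cs), levels = subtypeLevels()))
  missing <- names(counts)[counts < minClassSize]
  if (length(missing) > 0L)
    stop("consensus set class(es) below the minimum size of ", minClassSize,
         ": ", paste(missing, collapse = ", "))
  csLabels <- SubtypeAssignment(sampleIds(cs), subtypes(cs),
                                predictorId = paste0("CS.",
                                                     cs@sourceDatasetId))
  scaled <- applyRobustScaling(T)  # scaling uses the full cohort
  scaledCS <- .subsetExpr(scaled, samples = sampleIds(cs))
  ssp <- lapply(igls, function(igl)
    trainSSP(scaledCS, csLabels, igl, metric = metric,
             minClassSize = minClassSize))
  names(ssp) <- vapply(igls, function(x) x@listId, "")

  scm <- list()
  stg <- list()
  for (mgl in mgls) {
    sc <- scoreMatrix(T, mgl, scale = TRUE, pgrModule = pgrModule)
    csScores <- ModuleScores(
      moduleScores(sc)[sampleIds(cs), , drop = FALSE],
      mglId = sc@mglId, scaled = TRUE, coverage = moduleCoverage(sc),
      datasetId = datasetId(sc))
    scm[[mgl@listId]] <- fitSCM(csScores, seed = seed)
    stg[[mgl@listId]] <- fitSTG(csScores, seed = seed)
  }
  list(ssp = ssp, scm = scm, stg = stg)
}
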