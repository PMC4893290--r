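# End-to-end concordance experiment on synthetic data, mirroring the
# consensus-set evaluation protocol: a reference nearest-centroid model is
# trained on a held-out cohort; for each training cohort a five-predictor
# panel yields a consensus set on which a suite of predictors is trained (one
# per gene list and type); all suites are applied to separate validation
# cohorts; and every pair of predictors is compared by Cohen's kappa, with
# pairwise results partitioned by what differs between the two predictors
# (gene list, consensus set, both, or the predictor type).

#' Run the full synthetic concordance experiment
#'
#' Simulates a compendium with known subtypes, builds one consensus set per
#' training cohort, trains predictor suites on the consensus sets, predicts
#' every validation cohort with every suite, and aggregates all pairwise
#' kappa statistics by comparison group.
#'
#' @param nTrain number of training cohorts (consensus sets).
#' @param nValidation number of validation cohorts.
#' @param samplesPerDataset samples per cohort.
#' @param overlap per-module overlap fraction between the synthetic gene
#'   lists.
#' @param separation generator separation multiplier.
#' @param types predictor types to evaluate, a subset of
#'   `c("ssp", "scm", "stg")`.
#' @param seed integer seed fixing the simulated compendium, the gene lists
#'   and the model fits.
#' @return A list with `aggregate` (see [aggregateConcordance()]), `designs`,
#'   `results`, `consensusSets`, and `predictions`.
#' @export
concordanceExperiment <- function(nTrain = 5L, nValidation = 6L,
                                  samplesPerDataset = 180L, overlap = 0.7,
                                  separation = 2,
                                  types = c("ssp", "scm"), seed = 1L) {
  types <- match.arg(types, c("ssp", "scm", "stg"), several.ok = TRUE)
  nData <- nTrain + nValidation + 1L
  cfg <- simulationConfig(nDatasets = nData,
                          samplesPerDataset = samplesPerDataset,
                          separation = separation, seed = seed)
  sim <- simulateCompendium(cfg)
  gl <- makeGeneLists(sim$genes, overlap = overlap, seed = seed)
  trainIds <- names(sim$datasets)[seq_len(nTrain)]
  valIds <- names(sim$datasets)[nTrain + seq_len(nValidation)]
  refId <- names(sim$datasets)[nData]

  reference <- trainSSP(applyRobustScaling(sim$datasets[[refId]]),
                        sim$truth[[refId]], gl$igls$P)

  consensusSets <- list()
  suites <- list()
  for (tid in trainIds) {
    T <- sim$datasets[[tid]]
    panel <- defaultPanel(T, reference, gl$mgls, seed = seed,
                          pgrModule = gl$pgrModule)
    cs <- buildConsensus(panel, sourceDatasetId = tid)
    consensusSets[[tid]] <- cs
    suites[[tid]] <- trainCSSuite(cs, T, gl$igls, gl$mgls, seed = seed,
                                  pgrModule = gl$pgrModule)
  }

  # model catalogue: one predictor per (type, gene list, consensus set)
  catalogue <- list()
  for (tid in trainIds) {
    if ("ssp" %in% types)
      for (lid in names(suites[[tid]]$ssp))
        catalogue[[paste("ssp", lid, tid, sep = ".")]] <-
          list(type = "ssp", gl = lid, cs = tid,
               model = suites[[tid]]$ssp[[lid]])
    if ("scm" %in% types)
      for (lid in names(suites[[tid]]$scm))
        catalogue[[paste("scm", lid, tid, sep = ".")]] <-
          list(type = "scm", gl = lid, cs = tid,
               model = suites[[tid]]$scm[[lid]])
    if ("stg" %in% types)
      for (lid in names(suites[[tid]]$stg))
        catalogue[[paste("stg", lid, tid, sep = ".")]] <-
          list(type = "stg", gl = lid, cs = tid,
               model = suites[[tid]]$stg[[lid]])
  }

  predictions <- list()
  for (vid in valIds) {
    V <- sim$datasets[[vid]]
    scaled <- applyRobustScaling(V)
    scores <- lapply(gl$mgls, scoreMatrix, m = V, scale = TRUE,
                     pgrModule = gl$pgrModule)
    predictions[[vid]] <- lapply(catalogue, function(entry) {
      switch(entry$type,
             ssp = predictSSP(entry$model, scaled),
             scm = predictSCM(entry$model, scores[[entry$gl]]),
             stg = predictSTG(entry$model, scores[[entry$gl]]))
    })
  }

  ids <- names(catalogue)
  designRows <- list()
  results <- list()
  for (vid in valIds) {
    for (i in seq_along(ids)) {
      for (j in seq_along(ids)) {
        if (j <= i) next
        a <- catalogue[[ids[i]]]
        b <- catalogue[[ids[j]]]
        designRows[[length(designRows) + 1L]] <- data.frame(
          type_a = a$type, type_b = b$type, gene_list_a = a$gl,
          gene_list_b = b$gl, cs_a = a$cs, cs_b = b$cs,
          validation_dataset = vid)
        results[[length(results) + 1L]] <-
          cohensKappa(predictions[[vid]][[ids[i]]],
                      predictions[[vid]][[ids[j]]])
      }
    }
  }
  designs <- do.call(rbind, designRows)
  list(aggregate = aggregateConcordance(designs, results),
       designs = designs, results = results,
       consensusSets = consensusSets, predictions = predictions)
}
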