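# Signed-average module scores. A module score summarizes a phenotype (ER
# signalling, HER2 signalling, proliferation, PGR) as
#   score(s) = sum_i w_i x_is / sum_i |w_i|
# over the module genes present in the data; genes absent from the data are
# dropped and the denominator renormalized. Scores are always computed on
# unscaled expression; scaling, when requested, is applied to the score
# columns afterwards via the same robust percentile map.

#' Compute a single module score
#'
#' @param m a gene-level, unscaled [SubtypeExpression-class] object.
#' @param module data.frame with columns `gene_id` and signed `weight`.
#' @param coverageFloor minimum fraction of module genes that must be present
#'   in the data (default 0.5).
#' @return Named numeric vector, one score per sample. The coverage achieved
#'   is attached as attribute `"coverage"`.
#' @export
#' @examples
#' m <- SubtypeExpression(matrix(c(2, 1), 2, 1,
#'        dimnames = list(c("A", "B"), "s1")))
#' computeModuleScore(m, data.frame(gene_id = c("A", "B"), weight = c(1, -1)))
computeModuleScore <- function(m, module, coverageFloor = 0.5) {
  stopifnot(is(m, "SubtypeExpression"))
  module <- module[!duplicated(module$gene_id), , drop = FALSE]
  present <- module$gene_id %in% rownames(m)
  coverage <- mean(present)
  if (coverage < coverageFloor)
    stop(sprintf("module coverage %.3f below floor %.3f (%d of %d genes present)",
                 coverage, coverageFloor, sum(present), nrow(module)))
  mod <- module[present, , drop = FALSE]
  v <- exprValues(m)[mod$gene_id, , drop = FALSE]
  if (anyNA(v))
    stop("missing expression values in module genes")
  score <- drop(crossprod(v, mod$weight)) / sum(abs(mod$weight))
  score <- stats::setNames(as.numeric(score), colnames(m))
  attr(score, "coverage") <- coverage
  score
}

#' Compute the module score matrix for an MGL
#'
#' Computes the ER, HER2, PROLIF (and PGR) module scores for every sample of
#' a dataset. Scores are computed on unscaled gene-level expression; with
#' `scale = TRUE` each score column is subsequently robustly scaled within the
#' dataset (2.5th/97.5th percentiles to -1/+1). When the MGL lacks a PGR
#' module, the single-gene PGR module must be supplied via `pgrModule`.
#'
#' @param m a gene-level, unscaled [SubtypeExpression-class] object.
#' @param mgl a [GeneListSet-class] of kind `"MGL"`.
#' @param scale robustly scale the score columns (default `TRUE`).
#' @param pgrModule optional single-gene PGR module (data.frame with
#'   `gene_id`, `weight`) used when `mgl` has no PGR module.
#' @param coverageFloor minimum per-module gene coverage.
#' @return A [ModuleScores-class] object.
#' @export
scoreMatrix <- function(m, mgl, scale = TRUE, pgrModule = NULL,
                        coverageFloor = 0.5) {
  stopifnot(is(m, "SubtypeExpression"), is(mgl, "GeneListSet"),
            identical(mgl@kind, "MGL"))
  if (!identical(exprLevel(m), "gene"))
    stop("module scores require gene-level expression")
  if (isScaled(m))
    stop("module scores must be computed on unscaled expression")
  modules <- mgl@modules
  if (!"PGR" %in% names(modules) && !is.null(pgrModule))
    modules$PGR <- pgrModule
  modules <- modules[intersect(moduleLevels(), names(modules))]
  scores <- matrix(NA_real_, ncol(m), length(modules),
                   dimnames = list(colnames(m), names(modules)))
  coverage <- stats::setNames(numeric(length(modules)), names(modules))
  for (mid in names(modules)) {
    s <- computeModuleScore(m, modules[[mid]], coverageFloor = coverageFloor)
    scores[, mid] <- s
    coverage[mid] <- attr(s, "coverage")
  }
  ms <- ModuleScores(scores, mglId = mgl@listId, scaled = FALSE,
                     coverage = coverage, datasetId = datasetId(m))
  if (scale) applyRobustScaling(ms) else ms
}
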