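# Probeset collapsing and robust percentile scaling. Scaling maps the 2.5th
# and 97.5th percentile of each feature, within a dataset, to -1 and +1; no
# clipping is applied outside that range. Percentiles use linear interpolation
# between order statistics (quantile type 7).

#' Collapse probesets to genes
#'
#' Maps a probeset-level matrix to gene level. When several probesets map to
#' the same gene, the probeset with the largest sample variance across the
#' dataset is retained; exact variance ties are broken in favour of the
#' lexicographically smaller probeset id. Unmapped probesets are dropped. The
#' probeset chosen for each gene is recorded in the metadata of the result
#' (`metadata(x)$collapse_map`).
#'
#' @param m a probeset-level [SubtypeExpression-class] object.
#' @param mapping a [GeneMapping-class] object.
#' @return A gene-level [SubtypeExpression-class] object.
#' @export
collapseProbesets <- function(m, mapping) {
  stopifnot(is(m, "SubtypeExpression"), is(mapping, "GeneMapping"))
  if (identical(exprLevel(m), "gene"))
    return(m)  # idempotent on gene-level input
  map <- .mappingVector(mapping)
  probes <- intersect(rownames(m), names(map))
  if (length(probes) == 0L)
    stop("no features mappable: the mapping covers none of the probesets")
  v <- exprValues(m)[probes, , drop = FALSE]
  genes <- map[probes]
  vars <- apply(v, 1L, var)
  # order so that within a gene the winning probeset comes first:
  # decreasing variance, ties by increasing probeset id
  ord <- order(genes, -vars, probes, method = "radix")
  keep <- ord[!duplicated(genes[ord])]
  chosen <- probes[keep]
  out <- v[chosen, , drop = FALSE]
  rownames(out) <- unname(genes[chosen])
  res <- SubtypeExpression(out, datasetId = datasetId(m), level = "gene",
                           scaled = isScaled(m))
  S4Vectors::metadata(res)$collapse_map <-
    data.frame(gene_id = rownames(out), probeset_id = chosen,
               row.names = NULL)
  res
}

.robustQuantiles <- function(v) {
  if (anyNA(v))
    stop("missing values present; robust scaling requires complete data")
  q <- apply(v, 1L, quantile, probs = c(0.025, 0.975), names = FALSE,
             type = 7L)
  list(qLow = q[1L, ], qHigh = q[2L, ])
}

#' Fit robust scaling parameters
#'
#' Computes, per feature, the 2.5th and 97.5th percentiles of expression
#' across the samples of a dataset (linear interpolation between order
#' statistics).
#'
#' @param m a [SubtypeExpression-class] object with at least two samples, or a
#'   [ModuleScores-class] object (score columns are treated as features).
#' @return A [ScalingParams-class] object.
#' @export
fitRobustScaling <- function(m) {
  if (is(m, "ModuleScores")) {
    v <- t(moduleScores(m))
  } else {
    stopifnot(is(m, "SubtypeExpression"))
    v <- exprValues(m)
  }
  if (ncol(v) < 2L)
    stop("cannot estimate percentiles from a single-sample dataset")
  q <- .robustQuantiles(v)
  ScalingParams(rownames(v), q$qLow, q$qHigh)
}

.applyScalingToValues <- function(v, p) {
  missing <- setdiff(rownames(v), p@featureIds)
  if (length(missing) > 0L)
    stop("no scaling parameters for feature(s): ",
         paste(missing, collapse = ", "))
  idx <- match(rownames(v), p@featureIds)
  lo <- p@qLow[idx]
  hi <- p@qHigh[idx]
  span <- hi - lo
  out <- 2 * (v - lo) / span - 1
  out[span == 0, ] <- 0  # constant features map to 0
  out
}

#' Apply robust scaling
#'
#' Affine map per feature: `x' = 2 * (x - q_low) / (q_high - q_low) - 1`, so
#' that the fitted 2.5th/97.5th percentiles land on -1/+1. Values outside the
#' percentile window map outside \[-1, +1\] (no clipping). Constant features
#' (`q_low == q_high`) map to 0.
#'
#' @param m a [SubtypeExpression-class] or [ModuleScores-class] object.
#' @param p a [ScalingParams-class] covering every feature of `m`; fitted on
#'   `m` itself when omitted.
#' @return Object of the same class as `m` with `scaled = TRUE`.
#' @export
applyRobustScaling <- function(m, p = fitRobustScaling(m)) {
  if (is(m, "ModuleScores")) {
    out <- t(.applyScalingToValues(t(moduleScores(m)), p))
    return(ModuleScores(out, mglId = m@mglId, scaled = TRUE,
                        coverage = m@coverage, datasetId = m@datasetId))
  }
  stopifnot(is(m, "SubtypeExpression"))
  SubtypeExpression(.applyScalingToValues(exprValues(m), p),
                    datasetId = datasetId(m), level = exprLevel(m),
                    scaled = TRUE)
}

#' Pooled robust scaling for skewed cohorts
#'
#' A cohort whose subtype composition is highly skewed (e.g. an ER+-only
#' dataset) would be distorted by within-dataset scaling. Instead, its columns
#' are concatenated with an anchor cohort of balanced composition, scaling
#' parameters are fitted on the pooled matrix, applied to the target columns
#' only, and the anchor is discarded.
#'
#' @param target the [SubtypeExpression-class] to scale.
#' @param anchor a [SubtypeExpression-class] over the same feature space (may
#'   have zero samples, in which case pooling reduces to within-dataset
#'   scaling).
#' @return The scaled target.
#' @export
pooledScale <- function(target, anchor) {
  stopifnot(is(target, "SubtypeExpression"), is(anchor, "SubtypeExpression"))
  if (!setequal(rownames(target), rownames(anchor))) {
    d1 <- setdiff(rownames(target), rownames(anchor))
    d2 <- setdiff(rownames(anchor), rownames(target))
    stop("feature spaces disagree; target-only: {",
         paste(head(d1, 10L), collapse = ", "), "}, anchor-only: {",
         paste(head(d2, 10L), collapse = ", "), "}")
  }
  tv <- exprValues(target)
  av <- exprValues(anchor)[rownames(tv), , drop = FALSE]
  pooled <- cbind(tv, av)
  q <- .robustQuantiles(pooled)
  p <- ScalingParams(rownames(tv), q$qLow, q$qHigh)
  SubtypeExpression(.applyScalingToValues(tv, p), datasetId = datasetId(target),
                    level = exprLevel(target), scaled = TRUE)
}
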