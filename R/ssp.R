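# Nearest-centroid single sample predictor (SSP). Centroids are per-subtype
# mean vectors of robustly scaled expression over an intrinsic gene list; a
# new case is assigned to the subtype whose centroid is nearest. The default
# distance is 1 - Spearman correlation (the PAM50 convention); Pearson and
# Euclidean are available. Distance ties are broken by canonical subtype
# order.

#' Train a nearest-centroid subtype predictor
#'
#' @param m a robustly scaled [SubtypeExpression-class] training matrix.
#' @param labels a [SubtypeAssignment-class] covering the training samples.
#' @param igl a [GeneListSet-class] of kind `"IGL"` defining the feature
#'   space; the intersection with the genes of `m` is used.
#' @param metric distance metric: `"spearman"` (default), `"pearson"` or
#'   `"euclidean"`.
#' @param minClassSize minimum training samples per subtype (default 5).
#' @return An [SSPModel-class].
#' @export
trainSSP <- function(m, labels, igl, metric = c("spearman", "pearson",
                                                "euclidean"),
                     minClassSize = 5L) {
  metric <- match.arg(metric)
  stopifnot(is(m, "SubtypeExpression"), is(labels, "SubtypeAssignment"),
            is(igl, "GeneListSet"), identical(igl@kind, "IGL"))
  if (!all(sampleIds(labels) %in% colnames(m)))
    stop("training labels refer to samples absent from the expression matrix")
  genes <- intersect(igl@genes, rownames(m))
  if (length(genes) == 0L)
    stop("empty intersection between IGL '", igl@listId,
         "' and the expression features")
  lab <- subtypes(labels)
  counts <- table(lab)
  present <- names(counts)[counts > 0]
  small <- present[counts[present] < minClassSize]
  if (length(small) > 0L)
    stop("subtype(s) below the minimum class size of ", minClassSize, ": ",
         paste(small, collapse = ", "))
  v <- exprValues(m)[genes, sampleIds(labels), drop = FALSE]
  if (anyNA(v))
    stop("missing expression values in IGL genes")
  centroids <- vapply(present, function(s)
    rowMeans(v[, lab == s, drop = FALSE]), numeric(length(genes)))
  dimnames(centroids) <- list(genes, present)
  new("SSPModel", iglId = igl@listId, geneIds = genes, centroids = centroids,
      metric = metric, trainingSetId = datasetId(m))
}

.centroidDistances <- function(v, centroids, metric) {
  # v: genes x samples over exactly the centroid genes
  switch(metric,
    spearman = 1 - cor(v, centroids, method = "spearman"),
    pearson = 1 - cor(v, centroids, method = "pearson"),
    euclidean = {
      d <- matrix(NA_real_, ncol(v), ncol(centroids))
      for (k in seq_len(ncol(centroids)))
        d[, k] <- sqrt(colSums((v - centroids[, k])^2))
      d
    })
}

#' Predict subtypes with a nearest-centroid model
#'
#' Computes, per sample, the distance to every centroid under the model's
#' metric (correlation metrics use distance = 1 - correlation) and assigns the
#' subtype of the nearest centroid. Exact distance ties are broken by
#' canonical subtype order. By default every model gene must be present in the
#' data; with `intersect = TRUE` prediction proceeds on the shared genes
#' (at least 3), and the reduced gene count is recorded as an attribute.
#'
#' @param model an [SSPModel-class].
#' @param m a robustly scaled [SubtypeExpression-class].
#' @param intersect allow prediction on the gene intersection.
#' @return A [SubtypeAssignment-class]; the distance matrix is attached as
#'   attribute `"distances"`.
#' @export
predictSSP <- function(model, m, intersect = FALSE) {
  stopifnot(is(model, "SSPModel"), is(m, "SubtypeExpression"))
  genes <- model@geneIds
  missing <- setdiff(genes, rownames(m))
  if (length(missing) > 0L) {
    if (!intersect)
      stop("model gene(s) absent from the data: ",
           paste(head(missing, 10L), collapse = ", "),
           if (length(missing) > 10L) ", ...")
    genes <- setdiff(genes, missing)
    if (length(genes) < 3L)
      stop("fewer than 3 model genes present in the data")
  }
  centroids <- model@centroids[genes, , drop = FALSE]
  # canonical column order so which.min tie-breaks canonically
  centroids <- centroids[, intersect(subtypeLevels(), colnames(centroids)),
                         drop = FALSE]
  v <- exprValues(m)[genes, , drop = FALSE]
  if (anyNA(v))
    stop("missing expression values in model genes")
  d <- .centroidDistances(v, centroids, model@metric)
  dimnames(d) <- list(colnames(m), colnames(centroids))
  lab <- colnames(d)[apply(d, 1L, which.min)]
  out <- SubtypeAssignment(colnames(m), lab,
                           predictorId = paste0("SSP.", model@iglId, ".",
                                                model@trainingSetId))
  attr(out, "distances") <- d
  attr(out, "genes_used") <- length(genes)
  out
}
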