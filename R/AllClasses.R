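#' @import methods
#' @importFrom stats cor dnorm median quantile rbinom rlnorm rnorm runif var
#' @importFrom utils read.delim write.table head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay
#' @importFrom S4Vectors metadata "metadata<-"
#' @importFrom mclust Mclust mclustBIC meVVV unmap
NULL

#' Canonical intrinsic subtype vocabulary
#'
#' The four intrinsic breast cancer subtypes handled by all predictors in this
#' package, in their fixed canonical order. The order is used for every
#' tie-break and for the layout of contingency tables, so it must be stable
#' across runs.
#'
#' @return Character vector `c("BASAL", "HER2", "LUMA", "LUMB")`.
#' @export
#' @examples
#' subtypeLevels()
subtypeLevels <- function() c("BASAL", "HER2", "LUMA", "LUMB")

#' Module vocabulary for module-score based predictors
#'
#' @return Character vector of the four marker modules: estrogen receptor
#'   signalling, HER2 signalling, proliferation and progesterone receptor.
#' @export
moduleLevels <- function() c("ER", "HER2", "PROLIF", "PGR")

.canonicalSubtypes <- function(x, what = "subtype") {
  x <- as.character(x)
  bad <- setdiff(unique(x), subtypeLevels())
  if (length(bad) > 0L)
    stop("unknown ", what, " label(s): ", paste(bad, collapse = ", "))
  factor(x, levels = subtypeLevels())
}

# ---------------------------------------------------------------------------
# SubtypeExpression: the expression container
# ---------------------------------------------------------------------------

#' Expression matrix container for subtyping
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying a single
#' `exprs` assay of log2 expression values (features x samples), together with
#' the dataset identifier, the feature level (`"probeset"` or `"gene"`) and a
#' flag recording whether robust scaling has been applied. Feature and sample
#' identifiers must be unique; values must be finite or `NA`.
#'
#' @slot datasetId single dataset label, used for per-dataset scaling.
#' @slot exprLevel `"probeset"` or `"gene"`.
#' @slot scaled `TRUE` once robust scaling has been applied.
#' @export
setClass("SubtypeExpression",
  contains = "SummarizedExperiment",
  representation(datasetId = "character", exprLevel = "character",
                 scaled = "logical"))

.matrixViolations <- function(values, featureIds, sampleIds) {
  out <- character(0)
  dup <- unique(featureIds[duplicated(featureIds)])
  if (length(dup) > 0L)
    out <- c(out, paste0("duplicate feature_id: ", dup))
  dup <- unique(sampleIds[duplicated(sampleIds)])
  if (length(dup) > 0L)
    out <- c(out, paste0("duplicate sample_id: ", dup))
  if (nrow(values) != length(featureIds) || ncol(values) != length(sampleIds))
    out <- c(out, sprintf(
      "dimension mismatch: values are %d x %d but %d feature_ids and %d sample_ids given",
      nrow(values), ncol(values), length(featureIds), length(sampleIds)))
  if (any(is.infinite(values)))
    out <- c(out, "non-finite (infinite) expression values present")
  out
}

setValidity("SubtypeExpression", function(object) {
  v <- .matrixViolations(SummarizedExperiment::assay(object, withDimnames = FALSE),
                         rownames(object), colnames(object))
  if (length(object@datasetId) != 1L)
    v <- c(v, "datasetId must be a single string")
  if (length(object@exprLevel) != 1L ||
      !object@exprLevel %in% c("probeset", "gene"))
    v <- c(v, "exprLevel must be 'probeset' or 'gene'")
  if (length(object@scaled) != 1L || is.na(object@scaled))
    v <- c(v, "scaled must be TRUE or FALSE")
  if (length(v) == 0L) TRUE else v
})

#' Construct a SubtypeExpression object
#'
#' @param values numeric matrix of log2 expression, features in rows, samples
#'   in columns; must carry rownames and colnames.
#' @param datasetId dataset label.
#' @param level feature level, `"gene"` (default) or `"probeset"`.
#' @param scaled whether the values are already robustly scaled.
#' @return A [SubtypeExpression-class] object.
#' @export
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' SubtypeExpression(m, datasetId = "demo")
SubtypeExpression <- function(values, datasetId = "dataset",
                              level = c("gene", "probeset"), scaled = FALSE) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (is.null(rownames(values)) && nrow(values) > 0L ||
      is.null(colnames(values)) && ncol(values) > 0L)
    stop("values must have rownames (feature ids) and colnames (sample ids)")
  if (is.null(rownames(values))) rownames(values) <- character(0)
  if (is.null(colnames(values))) colnames(values) <- character(0)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values))
  new("SubtypeExpression", se, datasetId = as.character(datasetId),
      exprLevel = level, scaled = scaled)
}

# ---------------------------------------------------------------------------
# GeneMapping
# ---------------------------------------------------------------------------

#' Probeset-to-gene mapping
#'
#' Many-to-one map from probeset identifiers to gene identifiers. Gene
#' identifiers are opaque strings; Entrez semantics are a convention, not
#' enforced, so synthetic identifiers work equally well.
#'
#' @slot probesetIds probeset identifiers (unique).
#' @slot geneIds gene identifier per probeset.
#' @export
setClass("GeneMapping",
  representation(probesetIds = "character", geneIds = "character"))

setValidity("GeneMapping", function(object) {
  v <- character(0)
  if (length(object@probesetIds) != length(object@geneIds))
    v <- c(v, "probesetIds and geneIds must have equal length")
  dup <- unique(object@probesetIds[duplicated(object@probesetIds)])
  if (length(dup) > 0L)
    v <- c(v, paste0("duplicate probeset in mapping: ", dup))
  if (length(v) == 0L) TRUE else v
})

#' @param probesetIds probeset identifiers.
#' @param geneIds gene identifier per probeset.
#' @rdname GeneMapping-class
#' @export
GeneMapping <- function(probesetIds, geneIds) {
  new("GeneMapping", probesetIds = as.character(probesetIds),
      geneIds = as.character(geneIds))
}

# ---------------------------------------------------------------------------
# SubtypeAssignment
# ---------------------------------------------------------------------------

#' Subtype assignment vector
#'
#' One subtype label per sample, produced by a named predictor.
#'
#' @slot sampleIds ordered sample identifiers.
#' @slot labels factor of subtype labels over [subtypeLevels()].
#' @slot predictorId label of the predictor that produced the assignment.
#' @export
setClass("SubtypeAssignment",
  representation(sampleIds = "character", labels = "factor",
                 predictorId = "character"))

setValidity("SubtypeAssignment", function(object) {
  v <- character(0)
  if (length(object@sampleIds) != length(object@labels))
    v <- c(v, "one label per sample required")
  if (!identical(levels(object@labels), subtypeLevels()))
    v <- c(v, "labels must use the canonical subtype levels")
  if (anyNA(object@labels))
    v <- c(v, "missing subtype labels are not allowed")
  dup <- unique(object@sampleIds[duplicated(object@sampleIds)])
  if (length(dup) > 0L)
    v <- c(v, paste0("duplicate sample_id: ", dup))
  if (length(object@predictorId) != 1L)
    v <- c(v, "predictorId must be a single string")
  if (length(v) == 0L) TRUE else v
})

#' @param sampleIds sample identifiers.
#' @param labels subtype labels (character or factor over [subtypeLevels()]).
#' @param predictorId predictor label.
#' @rdname SubtypeAssignment-class
#' @export
SubtypeAssignment <- function(sampleIds, labels, predictorId = "predictor") {
  new("SubtypeAssignment", sampleIds = as.character(sampleIds),
      labels = .canonicalSubtypes(labels),
      predictorId = as.character(predictorId))
}

# ---------------------------------------------------------------------------
# GeneListSet
# ---------------------------------------------------------------------------

#' Intrinsic gene list (IGL) or module gene list (MGL)
#'
#' An IGL is a plain gene list defining the feature space of a nearest-centroid
#' predictor. An MGL holds, per module, signed gene weights used to compute
#' module scores. An MGL must contain at least the ER, HER2 and PROLIF
#' modules; when the PGR module is absent from a published list it is supplied
#' as a single-gene module.
#'
#' @slot listId list label (e.g. `"S"`, `"H"`, `"P"` for IGLs; `"D"`, `"W"`,
#'   `"HK"` for MGLs).
#' @slot kind `"IGL"` or `"MGL"`.
#' @slot genes gene identifiers (IGL only).
#' @slot modules named list (MGL only): module id -> data.frame with columns
#'   `gene_id`, `weight`.
#' @export
setClass("GeneListSet",
  representation(listId = "character", kind = "character",
                 genes = "character", modules = "list"))

setValidity("GeneListSet", function(object) {
  v <- character(0)
  if (!object@kind %in% c("IGL", "MGL"))
    v <- c(v, "kind must be 'IGL' or 'MGL'")
  if (identical(object@kind, "IGL")) {
    if (length(object@genes) == 0L)
      v <- c(v, "IGL must contain at least one gene")
  } else if (identical(object@kind, "MGL")) {
    need <- c("ER", "HER2", "PROLIF")
    if (!all(need %in% names(object@modules)))
      v <- c(v, paste0("MGL must contain modules ",
                       paste(setdiff(need, names(object@modules)),
                             collapse = ", ")))
    bad <- setdiff(names(object@modules), moduleLevels())
    if (length(bad) > 0L)
      v <- c(v, paste0("unknown module id: ", bad))
    for (mid in names(object@modules)) {
      mod <- object@modules[[mid]]
      if (!is.data.frame(mod) || !all(c("gene_id", "weight") %in% names(mod)))
        v <- c(v, paste0("module ", mid,
                         " must be a data.frame with gene_id and weight"))
      else if (any(mod$weight == 0) || anyNA(mod$weight))
        v <- c(v, paste0("module ", mid, " has zero or missing weights"))
    }
  }
  if (length(v) == 0L) TRUE else v
})

#' @param listId list label.
#' @param genes gene identifiers.
#' @rdname GeneListSet-class
#' @export
IGL <- function(listId, genes) {
  new("GeneListSet", listId = as.character(listId), kind = "IGL",
      genes = as.character(genes), modules = list())
}

#' @param modules named list of data.frames with columns `gene_id`, `weight`.
#' @rdname GeneListSet-class
#' @export
MGL <- function(listId, modules) {
  modules <- lapply(modules, function(m) {
    m <- as.data.frame(m)
    m$gene_id <- as.character(m$gene_id)
    m$weight <- as.numeric(m$weight)
    m[, c("gene_id", "weight")]
  })
  new("GeneListSet", listId = as.character(listId), kind = "MGL",
      genes = character(0), modules = modules)
}

# ---------------------------------------------------------------------------
# ScalingParams
# ---------------------------------------------------------------------------

#' Robust scaling parameters
#'
#' Per-feature 2.5th and 97.5th percentiles; robust scaling maps them to -1
#' and +1 respectively.
#'
#' @slot featureIds feature identifiers.
#' @slot qLow 2.5th percentile per feature.
#' @slot qHigh 97.5th percentile per feature.
#' @export
setClass("ScalingParams",
  representation(featureIds = "character", qLow = "numeric",
                 qHigh = "numeric"))

setValidity("ScalingParams", function(object) {
  v <- character(0)
  n <- length(object@featureIds)
  if (length(object@qLow) != n || length(object@qHigh) != n)
    v <- c(v, "qLow/qHigh must match featureIds in length")
  bad <- which(object@qLow > object@qHigh)
  if (length(bad) > 0L)
    v <- c(v, paste0("qLow > qHigh for feature ", object@featureIds[bad]))
  if (length(v) == 0L) TRUE else v
})

#' @param featureIds feature identifiers.
#' @param qLow,qHigh percentile values per feature.
#' @rdname ScalingParams-class
#' @export
ScalingParams <- function(featureIds, qLow, qHigh) {
  new("ScalingParams", featureIds = as.character(featureIds),
      qLow = as.numeric(qLow), qHigh = as.numeric(qHigh))
}

# ---------------------------------------------------------------------------
# ModuleScores
# ---------------------------------------------------------------------------

#' Module score matrix
#'
#' Per-sample signed-average module scores (samples x modules) computed from a
#' module gene list, with per-module coverage (the fraction of list genes found
#' in the data). Modules falling below the coverage floor are absent from the
#' matrix, never silently zero.
#'
#' @slot scores numeric matrix, samples x modules.
#' @slot mglId the MGL the scores were computed from.
#' @slot scaled whether the score columns were robustly scaled.
#' @slot coverage named numeric, per-module coverage in \[0, 1\].
#' @slot datasetId dataset label of the underlying expression data.
#' @export
setClass("ModuleScores",
  representation(scores = "matrix", mglId = "character", scaled = "logical",
                 coverage = "numeric", datasetId = "character"))

setValidity("ModuleScores", function(object) {
  v <- character(0)
  if (is.null(colnames(object@scores)) ||
      !all(colnames(object@scores) %in% moduleLevels()))
    v <- c(v, "score columns must be named with module ids")
  if (!all(colnames(object@scores) %in% names(object@coverage)))
    v <- c(v, "coverage must be given for every module column")
  cov <- object@coverage
  if (any(cov < 0 | cov > 1))
    v <- c(v, "coverage must lie in [0, 1]")
  if (is.null(rownames(object@scores)))
    v <- c(v, "score rows must be named with sample ids")
  if (length(v) == 0L) TRUE else v
})

ModuleScores <- function(scores, mglId, scaled, coverage, datasetId) {
  new("ModuleScores", scores = scores, mglId = as.character(mglId),
      scaled = scaled, coverage = coverage, datasetId = as.character(datasetId))
}

# ---------------------------------------------------------------------------
# Predictor models
# ---------------------------------------------------------------------------

#' Nearest-centroid single sample predictor
#'
#' One centroid per subtype: the per-gene mean of robustly scaled expression
#' over the training samples of that subtype, restricted to an intrinsic gene
#' list. New cases are assigned to the subtype of the nearest centroid.
#'
#' @slot iglId gene list label.
#' @slot geneIds ordered genes shared by all centroids.
#' @slot centroids numeric matrix, genes x subtypes.
#' @slot metric `"spearman"`, `"pearson"` or `"euclidean"`.
#' @slot trainingSetId label of the training cohort.
#' @export
setClass("SSPModel",
  representation(iglId = "character", geneIds = "character",
                 centroids = "matrix", metric = "character",
                 trainingSetId = "character"))

setValidity("SSPModel", function(object) {
  v <- character(0)
  if (!identical(rownames(object@centroids), object@geneIds))
    v <- c(v, "centroid rows must equal geneIds")
  if (!all(colnames(object@centroids) %in% subtypeLevels()))
    v <- c(v, "centroid columns must be subtype labels")
  if (!object@metric %in% c("spearman", "pearson", "euclidean"))
    v <- c(v, "metric must be spearman, pearson or euclidean")
  if (length(v) == 0L) TRUE else v
})

#' Subtype classification model (Gaussian mixture on module scores)
#'
#' A three-component bivariate Gaussian mixture over scaled (ER, HER2) module
#' scores separates basal, HER2 and luminal samples; a two-component univariate
#' mixture over the proliferation score of luminal samples splits luminal A
#' (low proliferation) from luminal B (high proliferation).
#'
#' @slot mglId module gene list label.
#' @slot weights mixing proportions of the three components.
#' @slot means 2 x 3 matrix of component means (rows ER, HER2).
#' @slot covariances list of three 2 x 2 covariance matrices.
#' @slot compMap component -> `"BASAL"`, `"HER2"` or `"LUMINAL"`.
#' @slot prolifSplit list with elements `pi` (weight of the low component),
#'   `muLow`, `muHigh`, `sdLow`, `sdHigh`.
#' @slot trainingSetId label of the training cohort.
#' @export
setClass("SCMModel",
  representation(mglId = "character", weights = "numeric", means = "matrix",
                 covariances = "list", compMap = "character",
                 prolifSplit = "list", trainingSetId = "character"))

setValidity("SCMModel", function(object) {
  v <- character(0)
  if (length(object@weights) != 3L ||
      abs(sum(object@weights) - 1) > 1e-8)
    v <- c(v, "three mixing weights summing to 1 required")
  if (!identical(dim(object@means), c(2L, 3L)))
    v <- c(v, "means must be a 2 x 3 matrix")
  if (length(object@covariances) != 3L)
    v <- c(v, "three covariance matrices required")
  for (S in object@covariances) {
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) v <- c(v, "covariances must be positive definite")
  }
  if (!setequal(object@compMap, c("BASAL", "HER2", "LUMINAL")) ||
      length(object@compMap) != 3L)
    v <- c(v, "compMap must be a bijection onto BASAL/HER2/LUMINAL")
  ps <- object@prolifSplit
  need <- c("pi", "muLow", "muHigh", "sdLow", "sdHigh")
  if (!all(need %in% names(ps)))
    v <- c(v, "prolifSplit must contain pi, muLow, muHigh, sdLow, sdHigh")
  else if (ps$muLow > ps$muHigh)
    v <- c(v, "prolifSplit means must satisfy muLow <= muHigh")
  if (length(v) == 0L) TRUE else v
})

#' Rule-based St. Gallen surrogate subtype predictor
#'
#' Dichotomizes the four marker scores (ER, HER2, PGR, proliferation) at
#' per-marker cutpoints and maps each of the 16 over/underexpression profiles
#' to a subtype via an explicit rule table following the St. Gallen surrogate
#' intrinsic subtype definitions, with the luminal B/HER2+ surrogate mapped to
#' the HER2 subtype.
#'
#' @slot mglId module gene list label.
#' @slot cutpoints named numeric cutpoint per marker on the scaled score axis.
#' @slot ruleTable data.frame with columns `ER`, `HER2`, `PGR`, `PROLIF`
#'   (each `"+"` or `"-"`) and `subtype`; exactly 16 rows.
#' @slot trainingSetId label of the training cohort.
#' @export
setClass("STGModel",
  representation(mglId = "character", cutpoints = "numeric",
                 ruleTable = "data.frame", trainingSetId = "character"))

setValidity("STGModel", function(object) {
  v <- character(0)
  if (!setequal(names(object@cutpoints), moduleLevels()))
    v <- c(v, "cutpoints must be named ER, HER2, PROLIF, PGR")
  rt <- object@ruleTable
  if (!all(c("ER", "HER2", "PGR", "PROLIF", "subtype") %in% names(rt)))
    v <- c(v, "ruleTable must have marker columns and subtype")
  else {
    key <- do.call(paste, c(rt[, c("ER", "HER2", "PGR", "PROLIF")], sep = ""))
    if (nrow(rt) != 16L || anyDuplicated(key))
      v <- c(v, "ruleTable must cover all 16 profiles exactly once")
    if (!all(rt$subtype %in% subtypeLevels()))
      v <- c(v, "ruleTable subtypes must be canonical labels")
    her2pos <- rt$HER2 == "+"
    if (!all(rt$subtype[her2pos] == "HER2"))
      v <- c(v, "rule violation: HER2+ profiles must map to HER2")
    lum <- !her2pos & (rt$ER == "+" | rt$PGR == "+")
    if (!all(rt$subtype[lum & rt$PROLIF == "-"] == "LUMA"))
      v <- c(v, "rule violation: HER2-, hormone-receptor+, low-proliferation profiles must map to LUMA")
    if (!all(rt$subtype[lum & rt$PROLIF == "+"] == "LUMB"))
      v <- c(v, "rule violation: HER2-, hormone-receptor+, high-proliferation profiles must map to LUMB")
    tn <- !her2pos & rt$ER == "-" & rt$PGR == "-"
    if (!all(rt$subtype[tn] == "BASAL"))
      v <- c(v, "rule violation: triple-negative profiles must map to BASAL")
  }
  if (length(v) == 0L) TRUE else v
})

# ---------------------------------------------------------------------------
# ConsensusSet
# ---------------------------------------------------------------------------

#' Consensus set
#'
#' The samples of a training cohort concordantly subtyped by every predictor
#' in a panel, together with the agreed labels, per-subtype counts and the
#' fraction of the cohort retained.
#'
#' @slot sourceDatasetId cohort the consensus set was derived from.
#' @slot sampleIds retained (concordant) samples.
#' @slot labels agreed subtype per retained sample.
#' @slot perSubtypeCounts named integer counts over [subtypeLevels()].
#' @slot retainedFraction retained / total samples in the cohort.
#' @export
setClass("ConsensusSet",
  representation(sourceDatasetId = "character", sampleIds = "character",
                 labels = "factor", perSubtypeCounts = "integer",
                 retainedFraction = "numeric"))

setValidity("ConsensusSet", function(object) {
  v <- character(0)
  if (length(object@sampleIds) != length(object@labels))
    v <- c(v, "one label per retained sample required")
  if (sum(object@perSubtypeCounts) != length(object@sampleIds))
    v <- c(v, "perSubtypeCounts must sum to the number of retained samples")
  if (object@retainedFraction < 0 || object@retainedFraction > 1)
    v <- c(v, "retainedFraction must lie in [0, 1]")
  if (length(v) == 0L) TRUE else v
})

# ---------------------------------------------------------------------------
# KappaResult
# ---------------------------------------------------------------------------

#' Cohen's kappa concordance result
#'
#' Contingency table between two subtype assignments, the percentage of
#' concordant samples, overall and subtype-specific kappa, and the qualitative
#' agreement band. When the expected agreement equals 1 (both assignments
#' constant and identical) kappa is undefined; the result is then flagged
#' degenerate with `kappa = NA` and `cc = 100`.
#'
#' @slot table square contingency counts in canonical label order.
#' @slot kappa overall Cohen's kappa (`NA` when degenerate).
#' @slot cc percentage of concordant samples, `100 * trace / n`.
#' @slot perSubtypeKappa named numeric, one-vs-rest kappa per subtype.
#' @slot band `"slight"`, `"fair"`, `"moderate"`, `"substantial"` or
#'   `"almost_perfect"`.
#' @slot n number of samples compared.
#' @slot degenerate `TRUE` when kappa is undefined.
#' @export
setClass("KappaResult",
  representation(table = "matrix", kappa = "numeric", cc = "numeric",
                 perSubtypeKappa = "numeric", band = "character",
                 n = "integer", degenerate = "logical"))

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "SubtypeExpression", function(object) {
  cat(sprintf("SubtypeExpression '%s': %d %s features x %d samples (%s)\n",
              object@datasetId, nrow(object), object@exprLevel, ncol(object),
              if (object@scaled) "robustly scaled" else "unscaled"))
})

setMethod("show", "SubtypeAssignment", function(object) {
  cat(sprintf("SubtypeAssignment by '%s' for %d samples\n",
              object@predictorId, length(object@sampleIds)))
  print(table(object@labels))
})

setMethod("show", "GeneListSet", function(object) {
  if (identical(object@kind, "IGL"))
    cat(sprintf("IGL '%s': %d genes\n", object@listId, length(object@genes)))
  else
    cat(sprintf("MGL '%s': modules %s (sizes %s)\n", object@listId,
                paste(names(object@modules), collapse = "/"),
                paste(vapply(object@modules, nrow, 1L), collapse = "/")))
})

setMethod("show", "SSPModel", function(object) {
  cat(sprintf("SSPModel (IGL %s, %s distance): %d genes, centroids %s; trained on %s\n",
              object@iglId, object@metric, length(object@geneIds),
              paste(colnames(object@centroids), collapse = "/"),
              object@trainingSetId))
})

setMethod("show", "SCMModel", function(object) {
  cat(sprintf("SCMModel (MGL %s): 3-component ER/HER2 mixture (%s), luminal split at PROLIF means %.2f/%.2f; trained on %s\n",
              object@mglId, paste(object@compMap, collapse = "/"),
              object@prolifSplit$muLow, object@prolifSplit$muHigh,
              object@trainingSetId))
})

setMethod("show", "STGModel", function(object) {
  cat(sprintf("STGModel (MGL %s): cutpoints %s; trained on %s\n",
              object@mglId,
              paste(sprintf("%s=%.3f", names(object@cutpoints),
                            object@cutpoints), collapse = ", "),
              object@trainingSetId))
})

setMethod("show", "ConsensusSet", function(object) {
  cat(sprintf("ConsensusSet from '%s': %d samples (%.1f%% retained)\n",
              object@sourceDatasetId, length(object@sampleIds),
              100 * object@retainedFraction))
  print(object@perSubtypeCounts)
})

setMethod("show", "KappaResult", function(object) {
  if (object@degenerate)
    cat(sprintf("KappaResult (degenerate): cc = %.2f%%, n = %d\n",
                object@cc, object@n))
  else
    cat(sprintf("KappaResult: kappa = %.3f (%s), cc = %.2f%%, n = %d\n",
                object@kappa, object@band, object@cc, object@n))
})
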