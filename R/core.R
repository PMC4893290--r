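# Accessors and structural validation (core domain plumbing).

#' @rdname SubtypeExpression-class
#' @param x,object a package object.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname SubtypeExpression-class
#' @export
setMethod("exprValues", "SubtypeExpression", function(x)
  SummarizedExperiment::assay(x, "exprs"))

#' @rdname SubtypeExpression-class
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @rdname SubtypeExpression-class
#' @export
setMethod("datasetId", "SubtypeExpression", function(x) x@datasetId)

#' @rdname SubtypeExpression-class
#' @export
setMethod("datasetId", "ModuleScores", function(x) x@datasetId)

#' @rdname SubtypeExpression-class
#' @export
setGeneric("exprLevel", function(x) standardGeneric("exprLevel"))

#' @rdname SubtypeExpression-class
#' @export
setMethod("exprLevel", "SubtypeExpression", function(x) x@exprLevel)

#' @rdname SubtypeExpression-class
#' @export
setGeneric("isScaled", function(x) standardGeneric("isScaled"))

#' @rdname SubtypeExpression-class
#' @export
setMethod("isScaled", "SubtypeExpression", function(x) x@scaled)

#' @rdname SubtypeExpression-class
#' @export
setMethod("isScaled", "ModuleScores", function(x) x@scaled)

#' @rdname SubtypeAssignment-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname SubtypeAssignment-class
#' @export
setMethod("sampleIds", "SubtypeExpression", function(x) colnames(x))

#' @rdname SubtypeAssignment-class
#' @export
setMethod("sampleIds", "SubtypeAssignment", function(x) x@sampleIds)

#' @rdname SubtypeAssignment-class
#' @export
setMethod("sampleIds", "ModuleScores", function(x) rownames(x@scores))

#' @rdname SubtypeAssignment-class
#' @export
setMethod("sampleIds", "ConsensusSet", function(x) x@sampleIds)

#' @rdname SubtypeAssignment-class
#' @export
setGeneric("subtypes", function(x) standardGeneric("subtypes"))

#' @rdname SubtypeAssignment-class
#' @export
setMethod("subtypes", "SubtypeAssignment", function(x) x@labels)

#' @rdname SubtypeAssignment-class
#' @export
setMethod("subtypes", "ConsensusSet", function(x) x@labels)

#' @rdname SubtypeAssignment-class
#' @export
setGeneric("predictorId", function(x) standardGeneric("predictorId"))

#' @rdname SubtypeAssignment-class
#' @export
setMethod("predictorId", "SubtypeAssignment", function(x) x@predictorId)

#' @rdname ModuleScores-class
#' @param x a [ModuleScores-class] object.
#' @export
setGeneric("moduleScores", function(x) standardGeneric("moduleScores"))

#' @rdname ModuleScores-class
#' @export
setMethod("moduleScores", "ModuleScores", function(x) x@scores)

#' @rdname ModuleScores-class
#' @export
setGeneric("moduleCoverage", function(x) standardGeneric("moduleCoverage"))

#' @rdname ModuleScores-class
#' @export
setMethod("moduleCoverage", "ModuleScores", function(x) x@coverage)

#' @rdname KappaResult-class
#' @param x a [KappaResult-class] object.
#' @export
kappaValue <- function(x) x@kappa

#' @rdname KappaResult-class
#' @export
concordantPercent <- function(x) x@cc

#' @rdname KappaResult-class
#' @export
kappaTable <- function(x) x@table

#' @rdname KappaResult-class
#' @export
perSubtypeKappa <- function(x) x@perSubtypeKappa

#' @rdname KappaResult-class
#' @export
isDegenerate <- function(x) x@degenerate

#' @rdname ConsensusSet-class
#' @param x a [ConsensusSet-class] object.
#' @export
retainedFraction <- function(x) x@retainedFraction

#' @rdname ConsensusSet-class
#' @export
perSubtypeCounts <- function(x) x@perSubtypeCounts

#' Validate an expression matrix structurally
#'
#' Checks the structural invariants of an expression matrix (unique feature
#' and sample identifiers, matching dimensions, finite-or-missing values) and
#' returns a description of every violation. Validation never raises; a
#' well-formed input yields `character(0)`.
#'
#' @param values numeric matrix, or a [SubtypeExpression-class] object.
#' @param featureIds,sampleIds identifiers to validate `values` against;
#'   default to the dimnames of `values`.
#' @return Character vector of violation descriptions (empty when valid).
#' @export
#' @examples
#' m <- matrix(0, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s1")))
#' validateMatrix(m)
validateMatrix <- function(values, featureIds = NULL, sampleIds = NULL) {
  if (is(values, "SubtypeExpression")) {
    featureIds <- rownames(values)
    sampleIds <- colnames(values)
    values <- exprValues(values)
  } else {
    if (is.null(featureIds)) featureIds <- rownames(values)
    if (is.null(sampleIds)) sampleIds <- colnames(values)
  }
  .matrixViolations(values, featureIds, sampleIds)
}

# Map probeset -> gene as a named character vector.
.mappingVector <- function(mapping) {
  stats::setNames(mapping@geneIds, mapping@probesetIds)
}

# Subset a SubtypeExpression by features and/or samples, keeping metadata.
.subsetExpr <- function(m, features = NULL, samples = NULL) {
  v <- exprValues(m)
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  SubtypeExpression(v, datasetId = datasetId(m), level = exprLevel(m),
                    scaled = isScaled(m))
}
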