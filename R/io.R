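# Tab-delimited and JSON serialization. Expression matrices are TSV with the
# feature id in the first column and a '#' metadata header carrying dataset id,
# feature level and scaling status, so a write/read round trip restores the
# full object.

#' Write / read an expression matrix
#'
#' Tab-delimited text: a `#`-prefixed metadata line, then a header row of
#' sample identifiers and one row per feature (first column the feature id).
#'
#' @param m a [SubtypeExpression-class] object.
#' @param path file path.
#' @return `readExprMatrix` returns a [SubtypeExpression-class] object;
#'   `writeExprMatrix` returns `path` invisibly.
#' @export
writeExprMatrix <- function(m, path) {
  stopifnot(is(m, "SubtypeExpression"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dataset=%s level=%s scaled=%s",
                     datasetId(m), exprLevel(m), isScaled(m)), con)
  df <- data.frame(feature_id = rownames(m), exprValues(m),
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeExprMatrix
#' @export
readExprMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- list(dataset = "dataset", level = "gene", scaled = "FALSE")
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    for (kv in strsplit(trimws(sub("^#\\s*", "", first)), "\\s+")[[1]]) {
      p <- strsplit(kv, "=", fixed = TRUE)[[1]]
      if (length(p) == 2L) meta[[p[1]]] <- p[2]
    }
  }
  df <- read.delim(path, skip = skip, check.names = FALSE,
                   stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  SubtypeExpression(v, datasetId = meta$dataset, level = meta$level,
                    scaled = as.logical(meta$scaled))
}

#' Write / read a probeset-to-gene mapping
#'
#' Tab-delimited with columns `probeset_id`, `gene_id`.
#'
#' @param mapping a [GeneMapping-class] object.
#' @param path file path.
#' @export
writeGeneMapping <- function(mapping, path) {
  write.table(data.frame(probeset_id = mapping@probesetIds,
                         gene_id = mapping@geneIds),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneMapping
#' @export
readGeneMapping <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  GeneMapping(df$probeset_id, df$gene_id)
}

#' Write / read gene list sets
#'
#' Tab-delimited with columns `list_id`, `kind`, `module_id` (empty for IGLs),
#' `gene_id`, `weight` (empty for IGLs). A file may hold several lists.
#'
#' @param lists a single [GeneListSet-class] or a list of them.
#' @param path file path.
#' @return `readGeneListSets` returns a named list of
#'   [GeneListSet-class] objects.
#' @export
writeGeneListSets <- function(lists, path) {
  if (is(lists, "GeneListSet")) lists <- list(lists)
  rows <- lapply(lists, function(gl) {
    if (identical(gl@kind, "IGL"))
      data.frame(list_id = gl@listId, kind = "IGL", module_id = "",
                 gene_id = gl@genes, weight = NA_real_)
    else
      do.call(rbind, lapply(names(gl@modules), function(mid)
        data.frame(list_id = gl@listId, kind = "MGL", module_id = mid,
                   gene_id = gl@modules[[mid]]$gene_id,
                   weight = gl@modules[[mid]]$weight)))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeGeneListSets
#' @export
readGeneListSets <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(module_id = "character"))
  out <- list()
  for (lid in unique(df$list_id)) {
    d <- df[df$list_id == lid, , drop = FALSE]
    kind <- unique(d$kind)
    if (length(kind) != 1L)
      stop("list ", lid, " has inconsistent kind entries")
    if (identical(kind, "IGL")) {
      out[[as.character(lid)]] <- IGL(lid, d$gene_id)
    } else {
      mods <- split(d[, c("gene_id", "weight")], d$module_id)
      out[[as.character(lid)]] <- MGL(lid, mods)
    }
  }
  out
}

#' Write / read subtype assignments
#'
#' Tab-delimited with columns `sample_id`, `predictor_id`, `subtype`. A file
#' may hold assignments from several predictors.
#'
#' @param assignments a single [SubtypeAssignment-class] or a list of them.
#' @param path file path.
#' @return `readAssignments` returns a named list of
#'   [SubtypeAssignment-class] objects (one per predictor).
#' @export
writeAssignments <- function(assignments, path) {
  if (is(assignments, "SubtypeAssignment")) assignments <- list(assignments)
  rows <- lapply(assignments, function(a)
    data.frame(sample_id = sampleIds(a), predictor_id = predictorId(a),
               subtype = as.character(subtypes(a))))
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeAssignments
#' @export
readAssignments <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(split(df, df$predictor_id), function(d)
    SubtypeAssignment(d$sample_id, d$subtype, unique(d$predictor_id)))
  out[unique(df$predictor_id)]
}

#' Write / read robust scaling parameters
#'
#' Tab-delimited with columns `feature_id`, `q_low`, `q_high`.
#'
#' @param p a [ScalingParams-class] object.
#' @param path file path.
#' @export
writeScalingParams <- function(p, path) {
  write.table(data.frame(feature_id = p@featureIds, q_low = p@qLow,
                         q_high = p@qHigh),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeScalingParams
#' @export
readScalingParams <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  ScalingParams(df$feature_id, df$q_low, df$q_high)
}

#' Write / read a consensus set
#'
#' Tab-delimited with columns `sample_id`, `subtype`, preceded by `#` header
#' lines carrying the source dataset, the retained fraction and the
#' per-subtype counts.
#'
#' @param cs a [ConsensusSet-class] object.
#' @param path file path.
#' @export
writeConsensusSet <- function(cs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# source=%s retained_fraction=%.10g",
                       cs@sourceDatasetId, cs@retainedFraction),
               sprintf("# counts %s", paste(names(cs@perSubtypeCounts),
                                            cs@perSubtypeCounts,
                                            sep = "=", collapse = " "))),
             con)
  write.table(data.frame(sample_id = cs@sampleIds,
                         subtype = as.character(cs@labels)),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConsensusSet
#' @export
readConsensusSet <- function(path) {
  lines <- readLines(path, n = 2L)
  meta <- strsplit(trimws(sub("^#\\s*", "", lines[1])), "\\s+")[[1]]
  kv <- strsplit(meta, "=", fixed = TRUE)
  kv <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  df <- read.delim(path, skip = 2L, stringsAsFactors = FALSE)
  labels <- .canonicalSubtypes(df$subtype)
  counts <- table(labels)
  new("ConsensusSet", sourceDatasetId = unname(kv[["source"]]),
      sampleIds = df$sample_id, labels = labels,
      perSubtypeCounts = stats::setNames(as.integer(counts), names(counts)),
      retainedFraction = as.numeric(kv[["retained_fraction"]]))
}

#' Write / read fitted predictor models as JSON
#'
#' A single JSON document with a `type` field (`"SSP"`, `"SCM"` or `"STG"`)
#' and the model parameters; `readModel` restores the matching S4 class. The
#' STG rule table is stored explicitly (all 16 rows), so alternative
#' profile-to-subtype mappings can be loaded from file.
#'
#' @param model an [SSPModel-class], [SCMModel-class] or [STGModel-class].
#' @param path file path.
#' @export
writeModel <- function(model, path) {
  obj <- if (is(model, "SSPModel")) {
    list(type = "SSP", igl_id = model@iglId, metric = model@metric,
         training_set_id = model@trainingSetId, gene_ids = model@geneIds,
         centroids = as.data.frame(model@centroids))
  } else if (is(model, "SCMModel")) {
    list(type = "SCM", mgl_id = model@mglId,
         training_set_id = model@trainingSetId,
         weights = model@weights, means = model@means,
         covariances = model@covariances, comp_map = model@compMap,
         prolif_split = model@prolifSplit)
  } else if (is(model, "STGModel")) {
    list(type = "STG", mgl_id = model@mglId,
         training_set_id = model@trainingSetId,
         cutpoints = as.list(model@cutpoints),
         rule_table = model@ruleTable)
  } else stop("unsupported model class: ", class(model))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  switch(obj$type,
    SSP = {
      centroids <- as.matrix(obj$centroids)
      rownames(centroids) <- obj$gene_ids
      new("SSPModel", iglId = obj$igl_id, geneIds = obj$gene_ids,
          centroids = centroids, metric = obj$metric,
          trainingSetId = obj$training_set_id)
    },
    SCM = {
      cv <- obj$covariances
      covs <- if (is.array(cv) && length(dim(cv)) == 3L) {
        lapply(seq_len(3L), function(k) matrix(cv[k, , ], 2L, 2L))
      } else {
        lapply(seq_len(3L), function(k) {
          x <- cv[[k]]
          if (is.matrix(x)) x else matrix(unlist(x), 2L, 2L, byrow = TRUE)
        })
      }
      new("SCMModel", mglId = obj$mgl_id, weights = as.numeric(obj$weights),
          means = matrix(as.numeric(obj$means), 2L, 3L,
                         dimnames = list(c("ER", "HER2"), NULL)),
          covariances = covs, compMap = as.character(obj$comp_map),
          prolifSplit = lapply(obj$prolif_split, as.numeric),
          trainingSetId = obj$training_set_id)
    },
    STG = {
      rt <- as.data.frame(obj$rule_table, stringsAsFactors = FALSE)
      new("STGModel", mglId = obj$mgl_id,
          cutpoints = unlist(obj$cutpoints)[moduleLevels()],
          ruleTable = rt, trainingSetId = obj$training_set_id)
    },
    stop("unknown model type: ", obj$type))
}

#' Write / read a module score matrix
#'
#' Tab-delimited sample x module table with a `#` metadata header.
#'
#' @param ms a [ModuleScores-class] object.
#' @param path file path.
#' @export
writeModuleScores <- function(ms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# mgl=%s dataset=%s scaled=%s", ms@mglId,
                       ms@datasetId, ms@scaled),
               sprintf("# coverage %s",
                       paste(names(ms@coverage),
                             format(ms@coverage, digits = 10),
                             sep = "=", collapse = " "))),
             con)
  df <- data.frame(sample_id = rownames(ms@scores), ms@scores,
                   check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeModuleScores
#' @export
readModuleScores <- function(path) {
  lines <- readLines(path, n = 2L)
  kv <- strsplit(trimws(sub("^#\\s*", "", lines[1])), "\\s+")[[1]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  cv <- strsplit(trimws(sub("^#\\s*coverage\\s*", "", lines[2])), "\\s+")[[1]]
  cv <- strsplit(cv, "=", fixed = TRUE)
  coverage <- stats::setNames(as.numeric(vapply(cv, `[`, "", 2L)),
                              vapply(cv, `[`, "", 1L))
  df <- read.delim(path, skip = 2L, check.names = FALSE,
                   stringsAsFactors = FALSE)
  scores <- as.matrix(df[, -1, drop = FALSE])
  rownames(scores) <- df[[1]]
  ModuleScores(scores, mglId = meta[["mgl"]],
               scaled = as.logical(meta[["scaled"]]), coverage = coverage,
               datasetId = meta[["dataset"]])
}
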