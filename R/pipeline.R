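# Manifest-driven pipeline runner. A manifest is a list of steps, each with a
# command, named input/output file paths, parameters and (for stochastic
# steps) an explicit seed. Steps execute in order; referencing a later step's
# output as an input is a validation error, any step failure aborts the run
# with the step name, and a provenance record (input checksums, seeds,
# package version) is written next to the outputs so identical manifests
# reproduce identical artifacts.

.pipelineCommands <- c("simulate", "scale", "score", "train-ssp", "train-scm",
                       "train-stg", "consensus", "train-suite", "predict",
                       "concord", "concord-batch")

#' Read a pipeline manifest from JSON or YAML
#'
#' @param path path to a `.json` or `.yaml`/`.yml` manifest with a `steps`
#'   list.
#' @return Manifest list.
#' @export
readManifest <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML manifests")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                        simplifyMatrix = FALSE)
  }
}

.validateManifest <- function(manifest) {
  steps <- manifest$steps
  if (is.null(steps) || length(steps) == 0L)
    stop("manifest has no steps")
  produced <- character(0)
  allOutputs <- unlist(lapply(steps, function(s) unlist(s$outputs)))
  for (i in seq_along(steps)) {
    s <- steps[[i]]
    if (is.null(s$command) || !s$command %in% .pipelineCommands)
      stop("step ", i, ": unknown command '", s$command, "'")
    if (identical(s$command, "simulate") && is.null(s$seed))
      stop("step ", i, " (simulate): stochastic steps require an explicit seed")
    ins <- unlist(s$inputs)
    late <- ins[ins %in% setdiff(allOutputs, produced)]
    if (length(late) > 0L)
      stop("step ", i, " (", s$command,
           "): input produced by a later step (cyclic manifest): ",
           paste(late, collapse = ", "))
    produced <- c(produced, unlist(s$outputs))
  }
  invisible(TRUE)
}

.loadScoresOrExpr <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("^# mgl=", first)) readModuleScores(path) else readExprMatrix(path)
}

.runStep <- function(s) {
  ins <- s$inputs
  outs <- s$outputs
  p <- s$params
  getp <- function(name, default = NULL)
    if (!is.null(p[[name]])) p[[name]] else default
  switch(s$command,
    "simulate" = {
      args <- p[intersect(names(p), names(formals(simulationConfig)))]
      args$seed <- s$seed
      cfg <- do.call(simulationConfig, args)
      sim <- simulateCompendium(cfg)
      dir.create(outs$dir, showWarnings = FALSE, recursive = TRUE)
      for (did in names(sim$datasets)) {
        writeExprMatrix(sim$datasets[[did]],
                        file.path(outs$dir, paste0(did, ".tsv")))
        writeAssignments(sim$truth[[did]],
                         file.path(outs$dir, paste0(did, "_truth.tsv")))
      }
      gl <- makeGeneLists(sim$genes, overlap = getp("overlap", 0.7),
                          seed = s$seed)
      writeGeneListSets(c(gl$igls, gl$mgls),
                        file.path(outs$dir, "genelists.tsv"))
      write.table(gl$pgrModule, file.path(outs$dir, "pgr_module.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    },
    "scale" = {
      m <- readExprMatrix(ins$input)
      if (!is.null(ins$pooled_anchor)) {
        scaled <- pooledScale(m, readExprMatrix(ins$pooled_anchor))
      } else {
        params <- fitRobustScaling(m)
        if (!is.null(outs$params)) writeScalingParams(params, outs$params)
        scaled <- applyRobustScaling(m, params)
      }
      writeExprMatrix(scaled, outs$output)
    },
    "score" = {
      m <- readExprMatrix(ins$input)
      mgl <- readGeneListSets(ins$mgl)[[getp("mgl_id", 1L)]]
      pgr <- if (!is.null(ins$pgr)) read.delim(ins$pgr) else NULL
      sc <- scoreMatrix(m, mgl, scale = isTRUE(getp("scaled", TRUE)),
                        pgrModule = pgr)
      writeModuleScores(sc, outs$output)
    },
    "train-ssp" = {
      m <- readExprMatrix(ins$input)
      labels <- readAssignments(ins$labels)[[1L]]
      igl <- readGeneListSets(ins$igl)[[getp("igl_id", 1L)]]
      writeModel(trainSSP(m, labels, igl,
                          metric = getp("metric", "spearman")), outs$model)
    },
    "train-scm" = {
      writeModel(fitSCM(readModuleScores(ins$scores), seed = s$seed),
                 outs$model)
    },
    "train-stg" = {
      writeModel(fitSTG(readModuleScores(ins$scores), seed = s$seed,
                        mode = getp("mode", "mixture")), outs$model)
    },
    "predict" = {
      model <- readModel(ins$model)
      a <- if (is(model, "SSPModel")) {
        predictSSP(model, readExprMatrix(ins$input))
      } else if (is(model, "SCMModel")) {
        predictSCM(model, readModuleScores(ins$scores))
      } else {
        predictSTG(model, readModuleScores(ins$scores))
      }
      writeAssignments(a, outs$output)
    },
    "consensus" = {
      files <- unlist(ins)
      assignments <- unlist(lapply(files, readAssignments), recursive = FALSE)
      cs <- buildConsensus(assignments,
                           sourceDatasetId = getp("source", "T"))
      writeConsensusSet(cs, outs$output)
    },
    "train-suite" = {
      cs <- readConsensusSet(ins$consensus)
      m <- readExprMatrix(ins$input)
      lists <- readGeneListSets(ins$gene_lists)
      igls <- Filter(function(x) identical(x@kind, "IGL"), lists)
      mgls <- Filter(function(x) identical(x@kind, "MGL"), lists)
      pgr <- if (!is.null(ins$pgr)) read.delim(ins$pgr) else NULL
      suite <- trainCSSuite(cs, m, igls, mgls, seed = s$seed, pgrModule = pgr)
      dir.create(outs$dir, showWarnings = FALSE, recursive = TRUE)
      for (type in names(suite))
        for (lid in names(suite[[type]]))
          writeModel(suite[[type]][[lid]],
                     file.path(outs$dir, sprintf("%s_%s.json", type, lid)))
    },
    "concord" = {
      a <- readAssignments(ins$a)[[1L]]
      b <- readAssignments(ins$b)[[1L]]
      k <- cohensKappa(a, b)
      jsonlite::write_json(
        list(kappa = k@kappa, cc = k@cc, band = k@band, n = k@n,
             degenerate = k@degenerate,
             per_subtype_kappa = as.list(k@perSubtypeKappa),
             table = as.data.frame(k@table)),
        outs$output, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    },
    "concord-batch" = {
      man <- read.delim(ins$manifest, stringsAsFactors = FALSE)
      results <- lapply(seq_len(nrow(man)), function(i)
        cohensKappa(readAssignments(man$file_a[i])[[1L]],
                    readAssignments(man$file_b[i])[[1L]]))
      agg <- aggregateConcordance(man, results)
      write.table(agg$summary, outs$output, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    },
    stop("unknown command: ", s$command))
  invisible(TRUE)
}

#' Run a pipeline manifest
#'
#' Validates the manifest (known commands, no forward/cyclic artifact
#' references, explicit seeds on stochastic steps), executes the steps in
#' order and writes a provenance record (`provenance.json` next to
#' `provenanceDir`) with the package version and per-step input checksums and
#' seeds. Any step failure aborts with the step name and cause.
#'
#' @param manifest manifest list (see [readManifest()]) or a path to one.
#' @param provenanceDir directory for `provenance.json` (default the current
#'   directory); `NULL` suppresses the record.
#' @return Invisibly, the provenance list.
#' @export
runPipeline <- function(manifest, provenanceDir = ".") {
  if (is.character(manifest)) manifest <- readManifest(manifest)
  .validateManifest(manifest)
  prov <- list(package = "SubtypeConcord",
               version = as.character(utils::packageVersion("SubtypeConcord")),
               steps = list())
  for (i in seq_along(manifest$steps)) {
    s <- manifest$steps[[i]]
    ins <- unlist(s$inputs)
    ok <- tryCatch({.runStep(s); TRUE}, error = function(e) e)
    if (!isTRUE(ok))
      stop("pipeline step ", i, " ('", s$command, "') failed: ",
           conditionMessage(ok))
    sums <- if (length(ins) > 0L) as.list(tools::md5sum(ins)) else list()
    prov$steps[[i]] <- list(command = s$command, seed = s$seed,
                            input_md5 = sums,
                            outputs = as.list(unlist(s$outputs)))
  }
  if (!is.null(provenanceDir))
    jsonlite::write_json(prov, file.path(provenanceDir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prov)
}
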