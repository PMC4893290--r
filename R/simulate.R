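# Synthetic expression compendium with known 4-subtype ground truth. Each
# sample carries a latent per-module activity drawn around its subtype's
# module mean (effect * separation); every gene of a module expresses
# baseline + loading * activity + independent measurement noise, so module
# scores show the within-subtype continuum seen in real cohorts (bimodal but
# overlapping marker distributions) rather than collapsing to the subtype
# means. Gene loadings (drawn once per compendium) emulate the heterogeneous
# effect sizes of real signature genes: weakly loaded genes are dominated by
# batch shifts unless robust scaling re-equalizes the per-gene ranges.
# Background genes carry no subtype signal. Per dataset and per gene, an
# additive location shift and a multiplicative scale jitter emulate residual
# batch heterogeneity between cohorts, which robust scaling is designed to
# remove. Replicate pairs are two measurements of the same underlying sample:
# they share its module activities and differ only in measurement noise.

# subtype x module effect pattern (log2 units, before the separation
# multiplier): basal is ER-/HER2-/high-proliferation, the HER2 subtype is
# HER2-high with intermediate ER, luminal A is ER+/PGR+/low-proliferation and
# luminal B is ER+/high-proliferation.
.defaultEffects <- function() {
  matrix(c(
    # ER   HER2 PROLIF  PGR
    -1.0, -1.0,  1.0, -1.0,   # BASAL
     0.0,  1.0,  0.5, -0.5,   # HER2
     1.0, -1.0, -1.0,  1.0,   # LUMA
     1.0, -1.0,  1.0, -0.5),  # LUMB
    nrow = 4L, byrow = TRUE,
    dimnames = list(subtypeLevels(), moduleLevels()))
}

#' Configuration of the synthetic compendium generator
#'
#' @param nDatasets number of datasets to generate.
#' @param samplesPerDataset samples per dataset (recycled to `nDatasets`).
#' @param proportions subtype proportions, either a single numeric vector of
#'   length 4 (summing to 1) used for all datasets, or a `nDatasets` x 4
#'   matrix. The default (0.29, 0.11, 0.31, 0.29) follows the typical
#'   composition of consensus-subtyped breast cancer cohorts.
#' @param geneCounts named list of gene counts for the ER, HER2, PROLIF and
#'   PGR modules and the subtype-independent background.
#' @param effects subtype x module effect matrix (log2 units); defaults to
#'   the canonical intrinsic-subtype pattern.
#' @param baseline baseline log2 expression.
#' @param separation multiplier on the module effects (0 removes all label
#'   information).
#' @param sdModule within-subtype standard deviation of the latent per-sample
#'   module activity (log2 units), shared by all genes of a module.
#' @param loadingRange range of the per-gene loading on its module activity,
#'   drawn uniformly once per compendium; emulates the heterogeneous effect
#'   sizes of signature genes.
#' @param sdGeneSubtype standard deviation (log2 units per unit of
#'   separation) of the per-gene, per-subtype idiosyncratic expression offset
#'   of module genes, drawn once per compendium, shared across datasets and
#'   scaled by `separation` like all subtype-dependent signal. It makes gene
#'   identity matter: two gene lists that sample different module genes
#'   measure genuinely different signatures, not merely noisier copies of
#'   the same one.
#' @param sdWithin per-gene measurement noise standard deviation (log2
#'   units).
#' @param sigmaBatch standard deviation of the additive batch location shift;
#'   applied as a dataset-wide intensity offset plus independent per-gene
#'   shifts, both with this standard deviation.
#' @param scaleJitterSd standard deviation (log scale) of the per-dataset,
#'   per-gene multiplicative jitter.
#' @param replicatePairs number of replicate array pairs per dataset: each
#'   pair is two independent noisy measurements of one underlying sample.
#' @param heavyTails if `TRUE`, within-subtype noise is drawn from a
#'   t-distribution (df 4) instead of a Gaussian.
#' @param seed integer seed fixing the full output.
#' @return A list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nDatasets = 2L, samplesPerDataset = 200L,
                             proportions = c(BASAL = 0.29, HER2 = 0.11,
                                             LUMA = 0.31, LUMB = 0.29),
                             geneCounts = list(ER = 30L, HER2 = 20L,
                                               PROLIF = 30L, PGR = 5L,
                                               background = 120L),
                             effects = .defaultEffects(), baseline = 7,
                             separation = 2, sdModule = 1, sdWithin = 1,
                             loadingRange = c(0.3, 1), sdGeneSubtype = 0.25,
                             sigmaBatch = 0.5,
                             scaleJitterSd = 0.05, replicatePairs = 0L,
                             heavyTails = FALSE, seed = 1L) {
  if (is.matrix(proportions)) {
    props <- proportions
  } else {
    props <- matrix(proportions, nDatasets, 4L, byrow = TRUE)
  }
  colnames(props) <- subtypeLevels()
  if (any(abs(rowSums(props) - 1) > 1e-8) || any(props < 0))
    stop("subtype proportions must be non-negative and sum to 1 per dataset")
  if (any(unlist(geneCounts) <= 0L))
    stop("all gene counts must be positive")
  cfg <- list(nDatasets = as.integer(nDatasets),
              samplesPerDataset = rep_len(as.integer(samplesPerDataset),
                                          nDatasets),
              proportions = props, geneCounts = geneCounts,
              effects = effects, baseline = baseline,
              separation = separation, sdModule = sdModule,
              sdWithin = sdWithin, loadingRange = loadingRange,
              sdGeneSubtype = sdGeneSubtype,
              sigmaBatch = sigmaBatch, scaleJitterSd = scaleJitterSd,
              replicatePairs = as.integer(replicatePairs),
              heavyTails = isTRUE(heavyTails), seed = as.integer(seed))
  class(cfg) <- "SimulationConfig"
  cfg
}

.syntheticGeneUniverse <- function(geneCounts) {
  mods <- lapply(moduleLevels(), function(mid)
    sprintf("g%s%03d", mid, seq_len(geneCounts[[mid]])))
  names(mods) <- moduleLevels()
  list(modules = mods,
       background = sprintf("gBG%03d", seq_len(geneCounts$background)))
}

#' Simulate a multi-dataset expression compendium with known subtypes
#'
#' @param cfg a [simulationConfig()] object.
#' @return List with elements `datasets` (list of gene-level, unscaled
#'   [SubtypeExpression-class] objects), `truth` (list of parallel
#'   [SubtypeAssignment-class] ground-truth labels), `genes` (the gene
#'   universe: per-module gene ids and background ids) and `replicates`
#'   (per dataset, a data.frame pairing replicate sample ids, or `NULL`).
#' @export
simulateCompendium <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  uni <- .syntheticGeneUniverse(cfg$geneCounts)
  genes <- c(unlist(uni$modules, use.names = FALSE), uni$background)
  nGenes <- length(genes)
  geneModule <- rep(c(moduleLevels(), "BG"),
                    times = c(vapply(uni$modules, length, 1L),
                              length(uni$background)))
  # fixed biology, shared across datasets: per-gene loadings and per-gene,
  # per-subtype idiosyncratic offsets of the module genes
  loading <- runif(nGenes, cfg$loadingRange[1], cfg$loadingRange[2])
  idio <- matrix(0, nGenes, 4L, dimnames = list(genes, subtypeLevels()))
  isModGene <- geneModule != "BG"
  idio[isModGene, ] <- rnorm(sum(isModGene) * 4L,
                             sd = cfg$sdGeneSubtype * cfg$separation)
  datasets <- list()
  truth <- list()
  replicates <- list()
  noise <- function(n) {
    if (cfg$heavyTails) stats::rt(n, df = 4) * cfg$sdWithin / sqrt(2)
    else rnorm(n, sd = cfg$sdWithin)
  }
  for (d in seq_len(cfg$nDatasets)) {
    did <- sprintf("D%d", d)
    n <- cfg$samplesPerDataset[d]
    labels <- sample(subtypeLevels(), n, replace = TRUE,
                     prob = cfg$proportions[d, ])
    sids <- sprintf("%s_s%03d", did, seq_len(n))
    # latent per-sample module activity around the subtype's module mean
    activity <- cfg$effects[labels, , drop = FALSE] * cfg$separation +
      matrix(rnorm(n * 4L, sd = cfg$sdModule), n, 4L)
    colnames(activity) <- moduleLevels()
    # per-sample per-gene mean: baseline + loading * module activity +
    # the gene's idiosyncratic subtype offset
    eff <- matrix(0, nGenes, n)
    modRows <- geneModule != "BG"
    eff[modRows, ] <- loading[modRows] *
      t(activity[, geneModule[modRows], drop = FALSE])
    mu <- cfg$baseline + eff + idio[, labels, drop = FALSE]
    v <- mu + matrix(noise(nGenes * n), nGenes, n)
    repPairs <- NULL
    if (cfg$replicatePairs > 0L) {
      k <- min(cfg$replicatePairs, n)
      origin <- sample(seq_len(n), k)
      repIds <- sprintf("%s_rep", sids[origin])
      vrep <- mu[, origin, drop = FALSE] +
        matrix(noise(nGenes * k), nGenes, k)
      v <- cbind(v, vrep)
      labels <- c(labels, labels[origin])
      repPairs <- data.frame(sample_id = sids[origin], replicate_id = repIds)
      sids <- c(sids, repIds)
    }
    # batch structure: a dataset-wide intensity offset plus per-gene additive
    # shifts, and per-gene multiplicative jitter
    shift <- rnorm(1L, sd = cfg$sigmaBatch) + rnorm(nGenes, sd = cfg$sigmaBatch)
    jitter <- rlnorm(nGenes, sdlog = cfg$scaleJitterSd)
    v <- (v - cfg$baseline) * jitter + cfg$baseline + shift
    dimnames(v) <- list(genes, sids)
    datasets[[did]] <- SubtypeExpression(v, datasetId = did, level = "gene",
                                         scaled = FALSE)
    truth[[did]] <- SubtypeAssignment(sids, labels, predictorId = "truth")
    replicates[[did]] <- repPairs
  }
  list(datasets = datasets, truth = truth, genes = uni,
       replicates = replicates)
}

#' Synthetic gene lists over the simulated gene universe
#'
#' Builds three overlapping IGLs (subsets of the module and background genes)
#' and three MGLs with +/-1 weights over the true module genes, with a
#' controlled per-module overlap fraction so that "different gene list"
#' comparisons are meaningful. Background genes in an IGL carry no subtype
#' signal and give each list its own idiosyncratic noise, as in real
#' signature lists. The PGR module is always the same single-gene module
#' across all three MGLs and is returned separately (mirroring the convention
#' that module-score predictors measure PGR by one fixed probeset).
#'
#' @param genes gene universe as returned by [simulateCompendium()] (`$genes`).
#' @param overlap fraction of genes shared between any two lists, per module
#'   (1 yields identical lists).
#' @param bgFraction background genes per IGL, as a fraction of its module
#'   genes (default 0.5).
#' @param seed integer seed for the gene draws.
#' @return List with `igls` (three [GeneListSet-class] IGLs named S, H, P),
#'   `mgls` (three MGLs named D, W, HK with ER/HER2/PROLIF modules) and
#'   `pgrModule` (single-gene data.frame usable as the shared PGR module).
#' @export
makeGeneLists <- function(genes, overlap = 0.7, bgFraction = 0.5, seed = 1L) {
  stopifnot(overlap >= 0, overlap <= 1, bgFraction >= 0)
  set.seed(seed)
  pickThree <- function(pool, k = NULL) {
    # three subsets of equal size k with a shared core of round(overlap * k)
    n <- length(pool)
    if (is.null(k)) k <- max(1L, floor(n / (3 - 2 * overlap)))
    core <- round(overlap * k)
    k <- max(k, core)
    stopifnot(core + 3 * (k - core) <= n)
    pool <- sample(pool)
    shared <- pool[seq_len(core)]
    rest <- pool[-seq_len(core)]
    lapply(0:2, function(i) {
      uniq <- rest[seq_len(k - core) + i * (k - core)]
      c(shared, uniq)
    })
  }
  moduleNames <- c("ER", "HER2", "PROLIF")
  perModule <- lapply(moduleNames, function(mid) pickThree(genes$modules[[mid]]))
  names(perModule) <- moduleNames
  mglIds <- c("D", "W", "HK")
  mgls <- lapply(1:3, function(i) {
    mods <- lapply(moduleNames, function(mid)
      data.frame(gene_id = perModule[[mid]][[i]], weight = 1))
    names(mods) <- moduleNames
    MGL(mglIds[i], mods)
  })
  names(mgls) <- mglIds
  iglIds <- c("S", "H", "P")
  perModuleIGL <- c(perModule, list(PGR = pickThree(genes$modules$PGR)))
  modSets <- lapply(1:3, function(i)
    unlist(lapply(perModuleIGL, `[[`, i), use.names = FALSE))
  nBg <- round(bgFraction * length(modSets[[1L]]))
  bgSets <- if (nBg > 0L) {
    kMax <- floor(length(genes$background) / (3 - 2 * overlap))
    pickThree(genes$background, k = min(nBg, kMax))
  } else list(character(0), character(0), character(0))
  igls <- lapply(1:3, function(i)
    IGL(iglIds[i], c(modSets[[i]], bgSets[[i]])))
  names(igls) <- iglIds
  list(igls = igls, mgls = mgls,
       pgrModule = data.frame(gene_id = genes$modules$PGR[1L], weight = 1))
}
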