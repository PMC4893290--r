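# Shared synthetic fixtures, generated once per test run.

makeToyExpression <- function(nGenes = 10, nSamples = 5, seed = 42,
                              level = "gene", prefix = "g") {
  set.seed(seed)
  v <- matrix(rnorm(nGenes * nSamples, mean = 7), nGenes, nSamples,
              dimnames = list(sprintf("%s%02d", prefix, seq_len(nGenes)),
                              sprintf("s%02d", seq_len(nSamples))))
  SubtypeExpression(v, datasetId = "toy", level = level)
}

# A small shared compendium under the default generative law.
sharedSim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulationConfig(nDatasets = 3, samplesPerDataset = 150,
                              seed = 424242)
      sim <- simulateCompendium(cfg)
      cache <<- list(sim = sim,
                     gl = makeGeneLists(sim$genes, overlap = 0.7,
                                        seed = 424242))
    }
    cache
  }
})
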