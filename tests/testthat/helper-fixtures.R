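# Shared fixtures, built in code. The full-size default fixture run is
# expensive, so it is computed once per session and cached.

.fixtureCache <- new.env(parent = emptyenv())

# one full default-fixture pipeline run (2,000 cells), cached
fullRunFixture <- function(seed = 42L) {
    key <- paste0("run", seed)
    if (is.null(.fixtureCache[[key]])) {
        oe <- simulateDroplets(defaultSimConfig(), seed = seed)
        .fixtureCache[[key]] <- runPipeline(oe, seed = seed)
    }
    .fixtureCache[[key]]
}

# small simulation for cheap module tests: 5 populations, 300 cells
smallSim <- function(seed = 1L, ...) {
    simulateDroplets(defaultSimConfig(
        nCellsPerPop = c(80L, 60L, 60L, 60L, 40L), ...), seed = seed)
}

# reduced two-population config for contamination-diagnostic runs
contaminationSimConfig <- function(labelingGFP = 0.6, ambient = 0) {
    pops <- list(
        simPopulation("N1", 150, "neuronal", 1:3, 4,
            labeling = c(tg = labelingGFP)),
        simPopulation("G1", 50, "non_neuronal", 4:6, 4))
    simConfig(pops, nGenes = 20, nMito = 2, doubletRate = 0,
        ambientRate = c(tg = ambient))
}

# tiny dense OverlayExperiment from an explicit matrix
toyExperiment <- function(counts, classes, ...) {
    OverlayExperiment(
        methods::as(Matrix::Matrix(counts, sparse = TRUE),
            "CsparseMatrix"),
        featureClass = classes, ...)
}
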