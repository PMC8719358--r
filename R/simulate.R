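#' Specify one simulated cell population
#'
#' @param name Population name.
#' @param nCells Number of cells (>= 1).
#' @param compartment `"neuronal"` or `"non_neuronal"`.
#' @param markerGenes Integer indices of this population's marker genes
#'   (into the endogenous gene vector).
#' @param markerFold Fold enrichment (> 1) of marker genes over their
#'   baseline mean; scalar or one value per marker.
#' @param labeling Named numeric vector of per-transgene retrograde
#'   labeling probabilities in \[0, 1\] (e.g. `c(GFP = 0.6)`). Unnamed
#'   transgenes default to probability 0.
#'
#' @return A validated `SimPopulation` list.
#' @seealso [simConfig()], [simulateDroplets()]
#' @export
simPopulation <- function(name, nCells, compartment = c("neuronal",
                          "non_neuronal"), markerGenes = integer(0),
                          markerFold = 6, labeling = numeric(0)) {
    compartment <- match.arg(compartment)
    stopifnot(nzchar(name), nCells >= 1)
    markerFold <- rep_len(markerFold, length(markerGenes))
    if (length(markerGenes) && any(markerFold <= 1))
        stop("marker fold enrichment must exceed 1")
    if (length(labeling) &&
        (is.null(names(labeling)) || any(labeling < 0 | labeling > 1)))
        stop("labeling must be a named vector of probabilities in [0, 1]")
    structure(list(name = name, nCells = as.integer(nCells),
        compartment = compartment,
        markerGenes = as.integer(markerGenes), markerFold = markerFold,
        labeling = labeling), class = "SimPopulation")
}

#' Configure the droplet simulator
#'
#' Defines the generative model for synthetic droplet data: endogenous
#' counts are negative binomial with per-cell library-size factors and
#' per-population marker fold changes; a labeled cell receives negative
#' binomial transgene counts; every cell additionally receives Poisson
#' ambient transgene counts; mitochondrial features are generated to hit
#' a Beta-drawn per-cell mitochondrial fraction in expectation; doublets
#' are sums of two uniformly drawn singlet profiles.
#'
#' The negative binomial is parameterized by (mean, dispersion) with
#' variance `mean + dispersion * mean^2`.
#'
#' @param populations List of [simPopulation()] specs.
#' @param nGenes Number of endogenous genes (must cover the largest
#'   marker index).
#' @param nMito Number of mitochondrial features.
#' @param baselineMeanlog,baselineSdlog Log-normal parameters of the
#'   per-gene baseline mean expression.
#' @param libsizeMeanlog,libsizeSdlog Log-normal parameters of the
#'   per-cell library-size factor.
#' @param dispersion Negative-binomial dispersion (>= 0).
#' @param transgeneMean Expected transgene counts in a labeled cell with
#'   unit size factor.
#' @param ambientRate Named numeric vector: expected ambient counts per
#'   cell (unit size factor) for each transgene. Transgenes appearing
#'   only here are ambient-only barcodes.
#' @param mitoShape Two Beta shape parameters for the per-cell
#'   mitochondrial fraction.
#' @param doubletRate Fraction of cells in \[0, 1) turned into doublets.
#'
#' @return A validated `SimConfig` list.
#' @export
simConfig <- function(populations, nGenes = 1500L, nMito = 10L,
                      baselineMeanlog = -0.7, baselineSdlog = 1,
                      libsizeMeanlog = 0, libsizeSdlog = 0.3,
                      dispersion = 0.4, transgeneMean = 5,
                      ambientRate = numeric(0), mitoShape = c(2, 80),
                      doubletRate = 0.05) {
    if (length(populations) == 0L)
        stop("at least one population is required")
    stopifnot(all(vapply(populations, inherits, logical(1), "SimPopulation")))
    maxIdx <- max(c(0L, unlist(lapply(populations, `[[`, "markerGenes"))))
    if (nGenes < maxIdx)
        stop(sprintf("nGenes (%d) smaller than largest marker index (%d)",
            nGenes, maxIdx))
    if (dispersion < 0 || transgeneMean < 0 || any(ambientRate < 0))
        stop("rates must be nonnegative")
    if (doubletRate < 0 || doubletRate >= 1)
        stop("doubletRate must lie in [0, 1)")
    tg <- unique(c(unlist(lapply(populations, function(p) names(p$labeling))),
        names(ambientRate)))
    amb <- stats::setNames(rep(0, length(tg)), tg)
    amb[names(ambientRate)] <- ambientRate
    structure(list(populations = populations, nGenes = as.integer(nGenes),
        nMito = as.integer(nMito), baselineMeanlog = baselineMeanlog,
        baselineSdlog = baselineSdlog, libsizeMeanlog = libsizeMeanlog,
        libsizeSdlog = libsizeSdlog, dispersion = dispersion,
        transgeneMean = transgeneMean, ambientRate = amb,
        transgenes = tg, mitoShape = mitoShape,
        doubletRate = doubletRate), class = "SimConfig")
}

#' Default synthetic fixture configuration
#'
#' Five populations (two excitatory-like and one inhibitory-like
#' neuronal, two glial non-neuronal), 2,000 cells, 1,500 endogenous
#' genes, and three transgenes: `GFP` retrogradely labels the first
#' excitatory population, `Cre` the second, and `tdTomato` is an
#' ambient-only barcode (labeling probability 0 everywhere, uniform
#' ambient leakage) emulating contamination from an injection site
#' included in the dissection.
#'
#' @param nCellsPerPop Cell counts per population; a scalar is recycled,
#'   the default is `c(500, 400, 400, 400, 300)`.
#' @param ambientTdTomato Ambient rate of the tdTomato barcode.
#' @param ... Overrides passed to [simConfig()].
#' @return A `SimConfig`.
#' @export
defaultSimConfig <- function(nCellsPerPop = c(500L, 400L, 400L, 400L, 300L),
                             ambientTdTomato = 0.15, ...) {
    n <- rep_len(as.integer(nCellsPerPop), 5L)
    mk <- function(i) ((i - 1L) * 25L + 1L):(i * 25L)
    pops <- list(
        simPopulation("Exc1", n[1], "neuronal", mk(1), 20,
            labeling = c(GFP = 0.6)),
        simPopulation("Exc2", n[2], "neuronal", mk(2), 20,
            labeling = c(Cre = 0.5)),
        simPopulation("Inh1", n[3], "neuronal", mk(3), 20),
        simPopulation("Astro", n[4], "non_neuronal", mk(4), 20),
        simPopulation("Oligo", n[5], "non_neuronal", mk(5), 20))
    simConfig(pops, ambientRate = c(tdTomato = ambientTdTomato), ...)
}

#' Simulate a droplet count matrix with ground truth
#'
#' Draws a features x cells count matrix under the model described in
#' [simConfig()] and records per-cell ground truth (population,
#' compartment, per-transgene labeled flags, doublet flag) in `colData`.
#' The same seed yields byte-identical output.
#'
#' @param config A `SimConfig`.
#' @param seed Integer seed fixing the full output.
#'
#' @return An [OverlayExperiment-class] whose `colData` carries the
#'   simulation truth and whose `metadata` stores the config and seed.
#' @examples
#' oe <- simulateDroplets(defaultSimConfig(nCellsPerPop = 30), seed = 1)
#' table(oe$population, oe$compartment)
#' @export
simulateDroplets <- function(config, seed = 1L) {
    stopifnot(inherits(config, "SimConfig"))
    set.seed(as.integer(seed))
    pops <- config$populations
    nPop <- length(pops)
    nCells <- sum(vapply(pops, `[[`, integer(1), "nCells"))
    popIdx <- rep(seq_len(nPop), vapply(pops, `[[`, integer(1), "nCells"))
    popName <- vapply(pops, `[[`, character(1), "name")[popIdx]
    compartment <- vapply(pops, `[[`, character(1), "compartment")[popIdx]

    gmean <- stats::rlnorm(config$nGenes, config$baselineMeanlog,
        config$baselineSdlog)
    # marker genes are reliably detectable in their population: floor
    # their baseline so fold enrichment translates into expression
    markerIdx <- unique(unlist(lapply(pops, `[[`, "markerGenes")))
    if (length(markerIdx))
        gmean[markerIdx] <- pmax(gmean[markerIdx], 0.1)
    fold <- matrix(1, config$nGenes, nPop)
    for (p in seq_len(nPop))
        fold[pops[[p]]$markerGenes, p] <- pops[[p]]$markerFold
    sf <- stats::rlnorm(nCells, config$libsizeMeanlog, config$libsizeSdlog)
    size <- if (config$dispersion > 0) 1 / config$dispersion else Inf

    rnb <- function(mu) {
        if (is.finite(size)) stats::rnbinom(length(mu), mu = mu, size = size)
        else stats::rpois(length(mu), mu)
    }

    endo <- matrix(0L, config$nGenes, nCells)
    for (p in seq_len(nPop)) {
        cols <- which(popIdx == p)
        mu <- outer(gmean * fold[, p], sf[cols])
        endo[, cols] <- rnb(mu)
    }

    # mitochondrial features: expected total per cell hits the drawn
    # Beta fraction of the cell's expected endogenous total
    mitoFrac <- stats::rbeta(nCells, config$mitoShape[1], config$mitoShape[2])
    expectedEndo <- sf * colSums(gmean * fold)[popIdx]
    mitoTotal <- mitoFrac / (1 - mitoFrac) * expectedEndo
    w <- stats::rlnorm(config$nMito, 0, 0.5)
    w <- w / sum(w)
    mito <- matrix(stats::rpois(config$nMito * nCells,
        outer(w, mitoTotal)), config$nMito, nCells)

    tg <- config$transgenes
    nTg <- length(tg)
    tgCounts <- matrix(0L, nTg, nCells)
    labeled <- matrix(FALSE, nCells, nTg, dimnames = list(NULL, tg))
    labProb <- matrix(0, nPop, nTg, dimnames = list(NULL, tg))
    for (p in seq_len(nPop))
        labProb[p, names(pops[[p]]$labeling)] <- pops[[p]]$labeling
    for (t in seq_len(nTg)) {
        lab <- stats::rbinom(nCells, 1L, labProb[popIdx, t]) == 1L
        labeled[, t] <- lab
        cnt <- integer(nCells)
        if (any(lab))
            cnt[lab] <- rnb(sf[lab] * config$transgeneMean)
        amb <- config$ambientRate[[t]]
        if (amb > 0)
            cnt <- cnt + stats::rpois(nCells, amb * sf)
        tgCounts[t, ] <- cnt
    }

    counts <- rbind(endo, mito, tgCounts)
    rownames(counts) <- c(sprintf("gene%04d", seq_len(config$nGenes)),
        if (config$nMito) sprintf("mt-%02d", seq_len(config$nMito)), tg)
    colnames(counts) <- sprintf("cell%05d", seq_len(nCells))
    fclass <- c(rep("endogenous", config$nGenes),
        rep("mito", config$nMito), rep("transgene", nTg))

    doublet <- rep(FALSE, nCells)
    population2 <- rep(NA_character_, nCells)
    nDoub <- floor(config$doubletRate * nCells)
    if (nDoub > 0) {
        hosts <- sample.int(nCells, nDoub)
        for (h in hosts) {
            partner <- sample.int(nCells - 1L, 1L)
            if (partner >= h) partner <- partner + 1L
            hostTotal <- sum(counts[, h])
            partnerTotal <- sum(counts[, partner])
            counts[, h] <- counts[, h] + counts[, partner]
            doublet[h] <- TRUE
            population2[h] <- popName[partner]
            labeled[h, ] <- labeled[h, ] | labeled[partner, ]
            # doublet inherits the compartment (and primary population)
            # of the larger parent; ties keep the host parent
            if (partnerTotal > hostTotal) {
                population2[h] <- popName[h]
                compartment[h] <- compartment[partner]
                popName[h] <- popName[partner]
            }
        }
    }

    cd <- DataFrame(population = popName, compartment = compartment,
        doublet = doublet, population2 = population2,
        sizeFactor = sf)
    for (t in tg) cd[[paste0("labeled_", t)]] <- labeled[, t]
    oe <- OverlayExperiment(
        methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
        featureClass = fclass, colData = cd)
    metadata(oe)$simConfig <- config
    metadata(oe)$seed <- as.integer(seed)
    oe
}
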