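mkToy <- function() {
    # 4 features (2 endo, 1 mito, 1 transgene) x 5 cells
    m <- matrix(c(
        5, 0, 2, 0, 0,
        3, 0, 0, 1, 0,
        0, 4, 1, 0, 0,
        1, 0, 0, 2, 0), 4, 5, byrow = TRUE,
        dimnames = list(c("g1", "g2", "mt1", "tg"),
            paste0("c", 1:5)))
    toyExperiment(m, c("endogenous", "endogenous", "mito", "transgene"))
}

test_that("QC metrics match a dense hand computation", {
    oe <- suppressWarnings(computeQCMetrics(mkToy()))
    m <- as.matrix(SummarizedExperiment::assay(oe, "counts"))
    expect_identical(oe$total_counts, as.integer(colSums(m)))
    expect_identical(oe$genes_detected,
        as.integer(colSums(m[c("g1", "g2", "tg"), ] > 0)))
    expect_equal(oe$mito_fraction[1:4], unname(m["mt1", 1:4] /
        colSums(m)[1:4]))
    # mito-only cell
    expect_equal(oe$mito_fraction[2], 1)
    # all-zero cell: flagged, fraction defined as 0
    expect_true(oe$qc_zero_total[5])
    expect_equal(oe$mito_fraction[5], 0)
})

test_that("QC filter retains exactly the cells satisfying every bound", {
    # 9 cells crafted so that exactly one cell fails each rule
    genes <- c(500, 500, 50, 300, 6500, 5000, 500, 500, 500)
    counts <- c(2000, 2000, 2000, 400, 20000, 40000, 2000, 2000, 2000)
    mito <- c(0.01, 0.2, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01)
    doublet <- c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
        FALSE, FALSE)
    nGenes <- 9500
    m <- matrix(0L, nGenes + 1, 9)
    for (i in 1:9) {
        nz <- seq_len(genes[i])
        m[nz, i] <- 1L
        m[1, i] <- m[1, i] + as.integer(round(counts[i] * (1 - mito[i]))) -
            length(nz) + 1L
        m[nGenes + 1, i] <- as.integer(round(counts[i] * mito[i]))
    }
    rownames(m) <- c(sprintf("g%d", seq_len(nGenes)), "mt1")
    oe <- toyExperiment(m, c(rep("endogenous", nGenes), "mito"),
        colData = S4Vectors::DataFrame(doublet = doublet))
    kept <- qcFilter(oe, qcBounds(200, 6000, 750, 30000, 0.05))
    expect_identical(colnames(kept), paste0("cell", c(1, 8, 9)))
    rep <- qcReport(kept)
    expect_equal(unname(rep$removed_per_criterion[c("high_mito",
        "low_genes", "low_counts", "high_genes", "high_counts",
        "doublet")]), c(1, 1, 1, 1, 1, 1))
    expect_equal(rep$n_input, 9)
    expect_equal(rep$n_retained, 3)

    # identity bounds pass everything non-doublet
    all9 <- qcFilter(oe, qcBounds(0, Inf, 0, Inf, 1),
        doublets = rep(FALSE, 9))
    expect_identical(ncol(all9), 9L)

    # filtering is idempotent
    again <- qcFilter(kept, qcBounds(200, 6000, 750, 30000, 0.05))
    expect_identical(colnames(again), colnames(kept))

    expect_error(qcFilter(oe, doublets = rep(TRUE, 9)), "all cells")
})

test_that("dataset QC presets carry the documented bounds", {
    v1 <- qcBoundsPreset("v1")
    expect_equal(unlist(v1[1:4]), c(minGenes = 200, maxGenes = 6000,
        minCounts = 750, maxCounts = 30000))
    sc <- qcBoundsPreset("sc")
    expect_equal(unlist(sc[1:4]), c(minGenes = 300, maxGenes = 9000,
        minCounts = 750, maxCounts = 50000))
    vm <- qcBoundsPreset("vm")
    expect_equal(unlist(vm[1:4]), c(minGenes = 300, maxGenes = 5000,
        minCounts = 500, maxCounts = 20000))
    expect_equal(v1$maxMitoFraction, 0.05)
})

test_that("log normalization matches the dense formula and preserves ranking", {
    oe <- mkToy()[, 1:4]
    oe <- normalizeLog(oe, scale = 1e4)
    m <- as.matrix(SummarizedExperiment::assay(oe, "counts"))
    ln <- as.matrix(SummarizedExperiment::assay(oe, "logcounts"))
    oracle <- log1p(1e4 * sweep(m, 2, colSums(m), "/"))
    expect_equal(ln, oracle)
    expect_equal(ln[m == 0], rep(0, sum(m == 0)))
    # single-feature cell: ln(1 + 1e4)
    solo <- toyExperiment(matrix(7, 1, 1, dimnames = list("g", "c")),
        "endogenous")
    expect_equal(as.numeric(SummarizedExperiment::assay(
        normalizeLog(solo), "logcounts")), log(1 + 1e4))
    # within-cell ranking is preserved
    for (j in seq_len(ncol(m)))
        expect_identical(order(m[, j]), order(ln[, j]))
    # zero-total cell is a hard error
    expect_error(normalizeLog(mkToy()), "zero total")
})

test_that("TF-IDF weighting matches the dense oracle and its zero structure", {
    set.seed(4)
    m <- matrix(rpois(12, 2), 4, 3,
        dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
    m[1, ] <- c(3, 1, 2)  # present in all cells -> weight 0
    m[2, ] <- c(5, 0, 0)  # single cell: weight 5 * ln(3)
    oe <- tfidf(toyExperiment(m, rep("endogenous", 4)))
    w <- as.matrix(SummarizedExperiment::assay(oe, "tfidf"))
    expect_equal(w, tfidfOracle(m))
    expect_equal(w[1, ], c(c1 = 0, c2 = 0, c3 = 0))
    expect_equal(w[2, 1], 5 * log(3), ignore_attr = TRUE)
    # weight is 0 iff TF = 0 or the gene appears in every cell
    ng <- rowSums(m > 0)
    expect_identical(w == 0, m == 0 | ng == ncol(m))
})

test_that("HVG selection ranks dispersion spikes first and breaks ties by index", {
    n <- 60
    m <- matrix(2, 50, n, dimnames = list(sprintf("g%02d", 1:50),
        sprintf("c%02d", 1:n)))
    m[, seq(1, n, 2)] <- 3  # identical distribution for every gene
    oe <- normalizeLog(toyExperiment(m, rep("endogenous", 50)))
    sel <- suppressWarnings(selectHVG(oe, nTop = 10))
    expect_identical(sel, sprintf("g%02d", 1:10))  # tie-break by index

    m2 <- m
    m2[30, ] <- c(rep(0, n / 2), rep(40, n / 2))  # dispersion spike
    oe2 <- normalizeLog(toyExperiment(m2, rep("endogenous", 50)))
    sel2 <- suppressWarnings(selectHVG(oe2, nTop = 5))
    expect_identical(sel2[1], "g30")

    expect_warning(selectHVG(oe, nTop = 100), "only 50")
    expect_length(suppressWarnings(selectHVG(oe, nTop = 100)), 50)
})

test_that("HVG ranking never sees transgene features", {
    oe <- normalizeLog(qcFilter(smallSim(seed = 2),
        qcBounds(0, Inf, 1, Inf, 1)))
    sel <- suppressWarnings(selectHVG(oe, nTop = 2000))
    expect_length(intersect(sel, transgeneNames(oe)), 0)
})

test_that("unit scaling yields zero mean, unit variance, and zero rows for constants", {
    m <- matrix(c(rep(c(0, 2), each = 3),
                  rep(5, 6),
                  rnorm(6, 10)), 3, 6, byrow = TRUE,
        dimnames = list(c("g1", "g2", "g3"), paste0("c", 1:6)))
    oe <- toyExperiment(round(m), rep("endogenous", 3))
    SummarizedExperiment::assay(oe, "logcounts") <-
        Matrix::Matrix(m, sparse = TRUE)
    s <- scaleUnit(oe)
    expect_equal(unname(s["g1", ]), rep(c(-1, 1), each = 3))
    expect_equal(unname(s["g2", ]), rep(0, 6))
    expect_equal(rowMeans(s), c(g1 = 0, g2 = 0, g3 = 0))
    # unit population variance for non-constant genes
    expect_equal(rowMeans(s^2)[c("g1", "g3")], c(g1 = 1, g3 = 1))
    expect_error(scaleUnit(oe, "nope"), "unknown")
})
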