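test_that("transgene-positive calling applies the read threshold", {
    m <- matrix(c(3, 0, 0, 0,
                  0, 0, 0, 0,
                  2, 1, 0, 0), 3, 4, byrow = TRUE,
        dimnames = list(c("g1", "tgA", "tgB"), paste0("c", 1:4)))
    oe <- toyExperiment(m, c("endogenous", "transgene", "transgene"))
    calls <- callPositive(oe, theta = 1)
    expect_equal(sum(calls[, "tgA"]), 0)
    expect_equal(unname(which(calls[, "tgB"])), c(1L, 2L))
    calls2 <- callPositive(oe, theta = 2)
    expect_equal(unname(which(calls2[, "tgB"])), 1L)
    expect_equal(attr(calls, "summary"), c(tgA = 0, tgB = 2))
    noTg <- toyExperiment(m[1, , drop = FALSE], "endogenous")
    expect_error(callPositive(noTg), "no transgene")
})

test_that("with no ambient leakage, positives are a subset of truly labeled cells", {
    cfg <- defaultSimConfig(nCellsPerPop = 60L, ambientTdTomato = 0,
        doubletRate = 0)
    oe <- simulateDroplets(cfg, seed = 31)
    calls <- callPositive(oe)
    expect_true(all(oe$labeled_GFP[calls[, "GFP"]]))
    expect_true(all(oe$labeled_Cre[calls[, "Cre"]]))
    expect_equal(sum(calls[, "tdTomato"]), 0)
})

test_that("cluster enrichment matches exhaustive placement enumeration on a 20-cell toy", {
    # 20 cells, 2 clusters (12 + 8), 4 positives, 3 of them in cluster 1
    labels <- rep(c(0, 1), c(12, 8))
    calls <- matrix(FALSE, 20, 1, dimnames = list(NULL, "tg"))
    calls[c(1, 13, 14, 15), "tg"] <- TRUE
    en <- clusterEnrichment(calls, labels)
    # oracle enumerates all C(20, 4) placements; cluster 1 has n = 8
    pOracle <- hyperEnumOracle(N = 20, K = 4, n = 8, k = 3)
    got <- en$p[en$cluster == 1]
    expect_equal(got, pOracle, tolerance = 1e-9)
    p0 <- hyperEnumOracle(N = 20, K = 4, n = 12, k = 1)
    expect_equal(en$p[en$cluster == 0], p0, tolerance = 1e-9)
})

test_that("enrichment assigns concentrated transgenes and not uniform ones", {
    labels <- rep(0:3, each = 50)
    calls <- matrix(FALSE, 200, 1, dimnames = list(NULL, "tg"))
    calls[which(labels == 2)[1:30], 1] <- TRUE
    en <- clusterEnrichment(calls, labels)
    expect_true(en$assigned[en$cluster == 2])
    expect_equal(which.min(en$p), which(en$cluster == 2))
    expect_false(any(en$assigned[en$cluster != 2]))

    # uniform placement: no assignment across 10 simulated draws
    set.seed(35)
    anyAssigned <- vapply(1:10, function(i) {
        calls <- matrix(FALSE, 200, 1, dimnames = list(NULL, "tg"))
        calls[sample(200, 20), 1] <- TRUE
        any(clusterEnrichment(calls, labels)$assigned)
    }, logical(1))
    expect_lte(mean(anyAssigned), 0.2)
})

test_that("compartment table reproduces the published nuclei cross-tabulation", {
    # 54,267 total nuclei, 797 non-neuronal; 11,377 positives of which
    # 153 non-neuronal
    compart <- rep(c("non_neuronal", "neuronal"), c(797, 54267 - 797))
    pos <- logical(54267)
    pos[1:153] <- TRUE                      # non-neuronal positives
    pos[798:(798 + 11224 - 1)] <- TRUE      # neuronal positives
    calls <- matrix(pos, ncol = 1, dimnames = list(NULL, "tdTomato"))
    tab <- compartmentTable(calls, compart, "tdTomato",
        reference = "versus_negative")
    expect_equal(unname(tab@counts),
        matrix(c(153, 11224, 644, 42246), 2, byrow = TRUE))
    # percentages as published: 1.34% of positives, 1.47% of all nuclei
    expect_equal(fractionPercent(153, 11377, 2), 1.34)
    expect_equal(fractionPercent(797, 54267, 2), 1.47)

    tabT <- compartmentTable(calls, compart, "tdTomato",
        reference = "versus_total")
    expect_equal(unname(tabT@counts[2, ]), c(797, 54267 - 797))

    none <- matrix(FALSE, 10, 1, dimnames = list(NULL, "tg"))
    expect_warning(
        tab0 <- compartmentTable(none, rep(c("neuronal", "non_neuronal"),
            5), "tg"), "degenerate")
    expect_true(tab0@degenerate)
    expect_error(compartmentTable(calls, compart[-1], "tdTomato"),
        "every cell")
})

test_that("compartment table on the synthetic fixture matches a truth recount", {
    oe <- smallSim(seed = 37)
    calls <- callPositive(oe)
    tab <- compartmentTable(calls, oe$compartment, "GFP")
    nn <- oe$compartment == "non_neuronal"
    pos <- calls[, "GFP"]
    expect_equal(unname(tab@counts), matrix(c(
        sum(pos & nn), sum(pos & !nn),
        sum(!pos & nn), sum(!pos & !nn)), 2, byrow = TRUE))
})

test_that("chi-square of a 2x2 table matches the closed form and stats oracles", {
    # equal proportions: chi2 = 0, p = 1
    flat <- chisq2x2(matrix(c(10, 20, 30, 60), 2, byrow = TRUE))
    expect_equal(flat$chi2, 0)
    expect_equal(flat$p, 1)

    set.seed(39)
    for (i in 1:20) {
        t <- matrix(rpois(4, 20) + 1, 2)
        a <- t[1, 1]; b <- t[1, 2]; c <- t[2, 1]; d <- t[2, 2]
        N <- sum(t)
        closed <- N * (a * d - b * c)^2 /
            ((a + b) * (c + d) * (a + c) * (b + d))
        got <- chisq2x2(t, "none")
        expect_equal(got$chi2, closed, tolerance = 1e-9)
        ref <- suppressWarnings(chisq.test(t, correct = FALSE))
        expect_equal(got$chi2, unname(ref$statistic), tolerance = 1e-9)
        expect_equal(got$p, ref$p.value, tolerance = 1e-9)
        # z^2 of the two-proportion test equals chi2
        z <- suppressWarnings(prop.test(t, correct = FALSE))
        expect_equal(got$chi2, unname(z$statistic), tolerance = 1e-9)
        # Yates agrees with chisq.test(correct = TRUE)
        refY <- suppressWarnings(chisq.test(t, correct = TRUE))
        expect_equal(chisq2x2(t, "yates")$chi2,
            unname(refY$statistic), tolerance = 1e-9)
    }
    expect_error(chisq2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
        "margin")
})

test_that("contamination verdicts separate retrograde labeling from ambient leakage", {
    retro <- vapply(1:20, function(s) {
        oe <- simulateDroplets(contaminationSimConfig(0.6, 0),
            seed = 400 + s)
        calls <- callPositive(oe)
        verdict(contaminationVerdict(calls, oe$compartment,
            as.integer(factor(oe$population)) - 1L, "tg"))
    }, character(1))
    expect_gte(mean(retro == "retrograde_consistent"), 0.95)

    amb <- vapply(1:20, function(s) {
        oe <- simulateDroplets(contaminationSimConfig(0, 0.5),
            seed = 600 + s)
        calls <- callPositive(oe)
        verdict(contaminationVerdict(calls, oe$compartment,
            as.integer(factor(oe$population)) - 1L, "tg"))
    }, character(1))
    expect_gte(mean(amb == "ambient_suspect"), 0.95)

    # zero positives
    oe <- simulateDroplets(contaminationSimConfig(0, 0), seed = 1)
    calls <- callPositive(oe)
    v <- contaminationVerdict(calls, oe$compartment,
        rep(0L, ncol(oe)), "tg")
    expect_identical(verdict(v), "undetected")
    expect_error(contaminationVerdict(calls,
        rep("neuronal", ncol(oe)), rep(0L, ncol(oe)), "tg"),
        "single-compartment")
})

test_that("perturbation check is calibrated under the null and detects a spike", {
    oe <- smallSim(seed = 41, doubletRate = 0)
    oe <- normalizeLog(oe)
    labels <- as.integer(factor(oe$population)) - 1L
    excLab <- labels[match("Exc1", oe$population)]
    calls <- callPositive(oe)

    # permuted calls within the cluster: a null with no real signal
    set.seed(42)
    zeros <- vapply(1:20, function(i) {
        permCalls <- calls
        idx <- which(labels == excLab)
        permCalls[idx, "GFP"] <- sample(calls[idx, "GFP"])
        res <- perturbationCheck(oe, labels, permCalls, excLab, "GFP")
        res$n_significant == 0L
    }, logical(1))
    expect_gte(mean(zeros), 0.9)

    # a real 4-fold shift in positives is detected
    oe2 <- oe
    cnt <- SummarizedExperiment::assay(oe2, "counts")
    idx <- which(labels == excLab & calls[, "GFP"])
    cnt["gene0200", idx] <- cnt["gene0200", idx] + 8
    SummarizedExperiment::assay(oe2, "counts") <- cnt
    oe2 <- normalizeLog(oe2)
    res <- perturbationCheck(oe2, labels, calls, excLab, "GFP")
    expect_identical(res$status, "ok")
    expect_true("gene0200" %in% res$significant_genes)

    # too few positives: explicit insufficient-data result
    few <- calls; few[, "GFP"] <- FALSE; few[idx[1:5], "GFP"] <- TRUE
    res2 <- perturbationCheck(oe, labels, few, excLab, "GFP")
    expect_identical(res2$status, "insufficient_data")
    expect_identical(res2$n_significant, 0L)
})

test_that("co-expression percentages use half-up integer rounding", {
    expect_identical(coexpressionRate(145, 120), 83L)
    expect_identical(coexpressionRate(353, 307), 87L)
    expect_identical(coexpressionRate(8, 1), 13L)  # 12.5 rounds up
    expect_identical(coexpressionRate(100, 0), 0L)
    expect_error(coexpressionRate(0, 0), "at least one")
    expect_error(coexpressionRate(10, 11), "nDoublePos")
})

test_that("breadth counts the clusters containing positives", {
    labels <- rep(0:4, each = 10)
    calls <- matrix(FALSE, 50, 1, dimnames = list(NULL, "tg"))
    expect_equal(breadth(calls, labels, "tg"), 0)
    calls[c(1, 11, 21), 1] <- TRUE
    expect_equal(breadth(calls, labels, "tg"), 0.6)
    calls[c(31, 41), 1] <- TRUE
    expect_equal(breadth(calls, labels, "tg"), 1)
})
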