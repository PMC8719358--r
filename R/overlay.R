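#' Call transgene-positive cells
#'
#' A cell is positive for a transgene when its raw transgene count is at
#' least `theta` reads (default 1: any aligned transgene read marks the
#' cell, matching per-cell read accounting for retrograde barcodes;
#' raise `theta` for noisy data).
#'
#' @param x An [OverlayExperiment-class] containing transgene features.
#' @param theta Read threshold (>= 1).
#' @return Logical cells x transgenes matrix with attributes `theta` and
#'   `summary` (positives per transgene).
#' @export
callPositive <- function(x, theta = 1L) {
    stopifnot(is(x, "OverlayExperiment"), theta >= 1)
    tg <- transgeneNames(x)
    if (length(tg) == 0L)
        stop("no transgene features in this experiment")
    m <- SummarizedExperiment::assay(x, "counts")[tg, , drop = FALSE]
    calls <- t(as.matrix(m >= theta))
    dimnames(calls) <- list(colnames(x), tg)
    attr(calls, "theta") <- theta
    attr(calls, "summary") <- colSums(calls)
    calls
}

#' Hypergeometric enrichment of transgene-positive cells per cluster
#'
#' For each cluster and transgene, computes the upper-tail
#' hypergeometric probability of observing at least the cluster's
#' number of positive cells if the global positives were placed at
#' random, applies Benjamini-Hochberg correction across clusters within
#' each transgene, and flags a cluster as assigned to the transgene's
#' projection target when `q < alpha` and its positive fraction exceeds
#' the global fraction.
#'
#' @param calls Cells x transgenes logical matrix from [callPositive()].
#' @param labels Per-cell cluster labels covering all called cells.
#' @param alpha Assignment significance level on BH-adjusted q (default
#'   0.05).
#' @return A [S4Vectors::DataFrame]: `cluster`, `transgene`, `n_cells`,
#'   `n_pos`, `fraction`, `global_fraction`, `p`, `q`, `assigned`.
#' @export
clusterEnrichment <- function(calls, labels, alpha = 0.05) {
    labels <- as.vector(labels)
    stopifnot(nrow(calls) == length(labels))
    lev <- sort(unique(labels))
    N <- nrow(calls)
    empty <- vapply(lev, function(l) sum(labels == l) == 0, logical(1))
    if (any(empty)) warning("empty cluster(s) skipped")
    rows <- lapply(colnames(calls), function(t) {
        K <- sum(calls[, t])
        res <- lapply(lev[!empty], function(l) {
            idx <- labels == l
            n <- sum(idx); k <- sum(calls[idx, t])
            p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
            DataFrame(cluster = l, transgene = t, n_cells = n,
                n_pos = k, fraction = k / n, global_fraction = K / N,
                p = p)
        })
        df <- do.call(rbind, res)
        df$q <- stats::p.adjust(df$p, method = "BH")
        df$assigned <- df$q < alpha & df$fraction > df$global_fraction
        df
    })
    do.call(rbind, rows)
}

#' Construct a 2x2 contingency table with its chi-square statistic
#'
#' @param a,b,c,d Nonnegative integer cell counts, rows = groups,
#'   columns = outcome (`(a, b)` is the first row).
#' @param correction `"none"` (default) or `"yates"` continuity
#'   correction.
#' @param rowNames,colNames Optional dimnames.
#' @return A [ContingencyTable-class]. Degenerate tables (a zero
#'   margin) carry `NA` statistics and `degenerate = TRUE`.
#' @export
contingencyTable <- function(a, b, c, d, correction = c("none", "yates"),
                             rowNames = c("group1", "group2"),
                             colNames = c("positive", "negative")) {
    correction <- match.arg(correction)
    ct <- matrix(as.numeric(c(a, b, c, d)), 2, 2, byrow = TRUE,
        dimnames = list(rowNames, colNames))
    margins <- c(rowSums(ct), colSums(ct))
    degenerate <- any(margins == 0)
    if (degenerate) {
        chi2 <- NA_real_; p <- NA_real_
    } else {
        st <- chisq2x2(ct, correction = correction)
        chi2 <- st$chi2; p <- st$p
    }
    new("ContingencyTable", counts = ct, correction = correction,
        chi2 = chi2, p = p, degenerate = degenerate)
}

#' Pearson chi-square test for a 2x2 table
#'
#' With `correction = "none"` the statistic is the closed form
#' `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with df = 1; `"yates"`
#' shrinks `|ad - bc|` by `N/2` (floored at 0). The p-value is the
#' upper tail of the chi-square distribution with one degree of
#' freedom.
#'
#' @param table A 2x2 numeric matrix or [ContingencyTable-class].
#' @param correction `"none"` or `"yates"`.
#' @return List with `chi2` and `p`. Errors on a zero margin (an exact
#'   test is advised there).
#' @examples
#' chisq2x2(matrix(c(56, 157, 1, 28), 2, byrow = TRUE))  # p = 0.0065
#' @export
chisq2x2 <- function(table, correction = c("none", "yates")) {
    correction <- match.arg(correction)
    if (is(table, "ContingencyTable")) table <- table@counts
    stopifnot(all(dim(table) == c(2, 2)))
    a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
    N <- a + b + c + d
    margins <- c(a + b, c + d, a + c, b + d)
    if (any(margins == 0))
        stop("zero margin: chi-square undefined, use an exact test")
    num <- abs(a * d - b * c)
    if (correction == "yates") num <- max(0, num - N / 2)
    chi2 <- N * num^2 / prod(margins)
    list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Compartment contingency table for one transgene
#'
#' Cross-tabulates transgene positivity against the neuronal /
#' non-neuronal compartment. With `reference = "versus_negative"`
#' (independent rows, the default) the rows are transgene-positive and
#' transgene-negative cells; with `"versus_total"` the second row is all
#' cells, mirroring reporting of positives against dataset totals.
#' Columns are non-neuronal, neuronal.
#'
#' @param calls Calls matrix from [callPositive()].
#' @param compartments Per-cell `"neuronal"` / `"non_neuronal"` labels.
#' @param transgene Transgene name.
#' @param reference `"versus_negative"` or `"versus_total"`.
#' @param correction Passed to [contingencyTable()].
#' @return A [ContingencyTable-class] (degenerate, with a warning, when
#'   there are no positives).
#' @export
compartmentTable <- function(calls, compartments, transgene,
                             reference = c("versus_negative",
                                           "versus_total"),
                             correction = "none") {
    reference <- match.arg(reference)
    stopifnot(transgene %in% colnames(calls))
    compartments <- as.vector(compartments)
    if (length(compartments) != nrow(calls) || anyNA(compartments))
        stop("a compartment label is required for every cell")
    if (!all(compartments %in% c("neuronal", "non_neuronal")))
        stop("compartments must be 'neuronal' or 'non_neuronal'")
    pos <- calls[, transgene]
    nn <- compartments == "non_neuronal"
    a <- sum(pos & nn); b <- sum(pos & !nn)
    if (reference == "versus_negative") {
        cc <- sum(!pos & nn); dd <- sum(!pos & !nn)
        rn <- c("positive", "negative")
    } else {
        cc <- sum(nn); dd <- sum(!nn)
        rn <- c("positive", "total")
    }
    tab <- contingencyTable(a, b, cc, dd, correction = correction,
        rowNames = rn, colNames = c("non_neuronal", "neuronal"))
    if (sum(pos) == 0)
        warning(sprintf("no positive cells for '%s': degenerate table",
            transgene))
    tab
}

#' Fraction of clusters containing a transgene-positive cell
#'
#' A genuinely retrograde barcode should appear in the handful of
#' clusters corresponding to its projection population; an ambient
#' barcode appears in virtually every cluster.
#'
#' @param calls Calls matrix from [callPositive()].
#' @param labels Per-cell cluster labels.
#' @param transgene Transgene name.
#' @return Fraction in \[0, 1\].
#' @export
breadth <- function(calls, labels, transgene) {
    labels <- as.vector(labels)
    stopifnot(nrow(calls) == length(labels),
        transgene %in% colnames(calls))
    lev <- unique(labels)
    mean(vapply(lev, function(l)
        any(calls[labels == l, transgene]), logical(1)))
}

#' Ambient-contamination verdict for a transgene
#'
#' Diagnoses whether a transgene's distribution across cells is
#' consistent with retrograde neuronal labeling or with ambient RNA
#' leakage. Retrograde labeling of neurons depletes the transgene-
#' positive set of non-neuronal cells; ambient RNA is compartment
#' neutral. The one-sided test compares the non-neuronal proportion
#' among positives against negatives with a two-proportion z-test
#' (`z^2` equals the Pearson chi-square of the versus-negative table).
#'
#' Verdicts: `"retrograde_consistent"` when positives are depleted of
#' the non-neuronal compartment at level `alpha`;
#' `"ambient_suspect"` when not depleted and the transgene appears in
#' at least `breadthCut` of clusters; `"undetected"` with zero
#' positives; `"inconclusive"` otherwise (not depleted but narrow).
#'
#' @param calls Calls matrix from [callPositive()].
#' @param compartments Per-cell compartment labels.
#' @param labels Per-cell cluster labels.
#' @param transgene Transgene name.
#' @param alpha One-sided significance level (default 0.05).
#' @param breadthCut Cluster-breadth cutoff for the ambient verdict
#'   (default 0.9).
#' @return A [ContaminationVerdict-class].
#' @export
contaminationVerdict <- function(calls, compartments, labels, transgene,
                                 alpha = 0.05, breadthCut = 0.9) {
    compartments <- as.vector(compartments)
    if (length(unique(compartments)) < 2L)
        stop("diagnostic undefined for a single-compartment dataset")
    tab <- suppressWarnings(compartmentTable(calls, compartments,
        transgene, reference = "versus_negative"))
    br <- breadth(calls, labels, transgene)
    nPos <- sum(calls[, transgene])
    if (nPos == 0) {
        return(new("ContaminationVerdict", transgene = transgene,
            breadth = br, table = tab, pOneSided = NA_real_,
            verdict = "undetected"))
    }
    ct <- tab@counts
    n1 <- sum(ct[1, ]); n2 <- sum(ct[2, ])
    p1 <- ct[1, 1] / n1; p2 <- ct[2, 1] / n2
    pPool <- (ct[1, 1] + ct[2, 1]) / (n1 + n2)
    se <- sqrt(pPool * (1 - pPool) * (1 / n1 + 1 / n2))
    pOne <- if (se == 0) 1 else stats::pnorm((p1 - p2) / se)
    v <- if (!is.na(pOne) && pOne < alpha) "retrograde_consistent"
         else if (br >= breadthCut) "ambient_suspect"
         else "inconclusive"
    new("ContaminationVerdict", transgene = transgene, breadth = br,
        table = tab, pOneSided = pOne, verdict = v)
}

#' Ground-state perturbation check
#'
#' Tests whether viral infection skewed endogenous expression by
#' comparing transgene-positive and transgene-negative cells within one
#' cluster, gene by gene (Mann-Whitney U on log-normalized expression),
#' with Benjamini-Hochberg correction across the tested genes. When
#' infection preserves the transcriptional ground state, no gene should
#' be significant.
#'
#' @param x An [OverlayExperiment-class] with `logcounts`.
#' @param labels Per-cell cluster labels.
#' @param calls Calls matrix from [callPositive()].
#' @param cluster Cluster label to test within.
#' @param transgene Transgene name.
#' @param qCut Significance cutoff on q (default 0.05).
#' @param minPos Minimum positive and negative cells (default 10).
#' @return List with `status` (`"ok"` or `"insufficient_data"`),
#'   `n_pos`, `n_neg`, `n_tested`, `n_significant`, and
#'   `significant_genes`.
#' @export
perturbationCheck <- function(x, labels, calls, cluster, transgene,
                              qCut = 0.05, minPos = 10L) {
    stopifnot(is(x, "OverlayExperiment"))
    labels <- as.vector(labels)
    idx <- labels == cluster
    pos <- calls[, transgene] & idx
    neg <- !calls[, transgene] & idx
    if (sum(pos) < minPos || sum(neg) < minPos) {
        return(list(status = "insufficient_data",
            n_pos = sum(pos), n_neg = sum(neg),
            n_tested = 0L, n_significant = 0L,
            significant_genes = character(0)))
    }
    genes <- endogenousNames(x)
    sub <- as.matrix(SummarizedExperiment::assay(x, "logcounts")[genes,
        idx, drop = FALSE])
    grp <- ifelse(pos[idx], "pos", "neg")
    st <- .mwuOneVsRest(sub, grp)
    p <- st[[which(vapply(st, `[[`, character(1), "cluster") == "pos")]]$p
    q <- stats::p.adjust(p, method = "BH")
    sig <- genes[q < qCut]
    list(status = "ok", n_pos = sum(pos), n_neg = sum(neg),
        n_tested = length(genes), n_significant = length(sig),
        significant_genes = sig)
}

#' Co-expression percentage of a marker among probe-positive cells
#'
#' The FISH-style validation statistic: of `nProbePos` cells positive
#' for the retrograde probe, the percentage also positive for a
#' candidate marker, rounded half-up to the nearest integer.
#'
#' @param nProbePos Number of probe-positive cells (>= 1).
#' @param nDoublePos Number of those also marker-positive
#'   (<= `nProbePos`).
#' @return Integer percent.
#' @examples
#' coexpressionRate(145, 120)  # 83
#' @export
coexpressionRate <- function(nProbePos, nDoublePos) {
    if (nProbePos < 1)
        stop("at least one probe-positive cell is required")
    if (nDoublePos > nProbePos || nDoublePos < 0)
        stop("nDoublePos must lie in [0, nProbePos]")
    as.integer(roundHalfUp(100 * nDoublePos / nProbePos))
}
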