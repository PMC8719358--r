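#' Mann-Whitney U test for one gene
#'
#' Two-sided rank-sum comparison of two samples. For samples of at most
#' 10 per side without ties the exact U distribution is used; otherwise
#' the normal approximation with tie correction (and continuity
#' correction for the p-value). The reported `z` is the standardized,
#' tie-corrected U statistic used for marker ranking; its sign is
#' positive when the first sample tends larger.
#'
#' @param a,b Numeric samples (first sample = in-group).
#' @param exact Force (`TRUE`) or forbid (`FALSE`) the exact path;
#'   default `NULL` chooses automatically.
#' @return List with `U` (first-sample statistic), `z`, `p`, and
#'   `method`.
#' @export
mannWhitneyTest <- function(a, b, exact = NULL) {
    n1 <- length(a); n2 <- length(b); N <- n1 + n2
    stopifnot(n1 >= 1, n2 >= 1)
    r <- rank(c(a, b))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    hasTies <- anyDuplicated(c(a, b)) > 0
    if (is.null(exact)) exact <- n1 <= 10 && n2 <= 10 && !hasTies
    if (exact && hasTies)
        stop("exact Mann-Whitney path is undefined with ties")
    mu <- n1 * n2 / 2
    if (exact) {
        p <- if (U > mu)
            2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
        else 2 * stats::pwilcox(U, n1, n2)
        p <- min(1, p)
        sigma <- sqrt(n1 * n2 * (N + 1) / 12)
        z <- (U - mu) / sigma
        method <- "exact"
    } else {
        tab <- table(c(a, b))
        tieTerm <- sum(tab^3 - tab)
        sigma2 <- n1 * n2 / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
        if (sigma2 <= 0) return(list(U = U, z = 0, p = 1,
            method = "normal"))
        sigma <- sqrt(sigma2)
        z <- (U - mu) / sigma
        zc <- (U - mu - sign(U - mu) * 0.5) / sigma
        p <- min(1, 2 * stats::pnorm(-abs(zc)))
        method <- "normal"
    }
    list(U = U, z = z, p = p, method = method)
}

# vectorized one-vs-rest Mann-Whitney over genes (rows of a dense
# matrix); ranks and tie terms are computed once per matrix since the
# rest group is the complement of each cluster
.mwuOneVsRest <- function(m, groups) {
    N <- ncol(m)
    R <- matrix(0, nrow(m), N)
    tieTerm <- numeric(nrow(m))
    for (g in seq_len(nrow(m))) {
        v <- m[g, ]
        R[g, ] <- rank(v)
        tab <- tabulate(match(v, unique(v)))
        tieTerm[g] <- sum(tab^3 - tab)
    }
    lev <- sort(unique(groups))
    res <- lapply(lev, function(l) {
        idx <- groups == l
        n1 <- sum(idx); n2 <- N - n1
        R1 <- rowSums(R[, idx, drop = FALSE])
        U <- R1 - n1 * (n1 + 1) / 2
        mu <- n1 * n2 / 2
        sigma2 <- n1 * n2 / 12 * ((N + 1) - tieTerm / (N * (N - 1)))
        z <- ifelse(sigma2 > 0, (U - mu) / sqrt(sigma2), 0)
        zc <- ifelse(sigma2 > 0,
            (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2), 0)
        p <- pmin(1, 2 * stats::pnorm(-abs(zc)))
        p[sigma2 <= 0] <- 1
        list(cluster = l, U = U, z = z, p = p)
    })
    res
}

#' Rank cluster marker genes by one-vs-rest Mann-Whitney U
#'
#' For every cluster, compares each endogenous gene's log-normalized
#' expression in the cluster against all other cells with the
#' Mann-Whitney U test, applies Benjamini-Hochberg correction across
#' genes within the cluster's comparison, and keeps the top `nTop`
#' genes by descending standardized U (`z`), ties broken by gene index.
#' Clusters with fewer than `minCells` cells are excluded with a
#' warning.
#'
#' @param x An [OverlayExperiment-class] with a `logcounts` assay.
#' @param labels Per-cell cluster labels.
#' @param nTop Markers kept per cluster (default 50).
#' @param minCells Minimum cluster size (default 3).
#' @return A [S4Vectors::DataFrame] with columns `gene`, `cluster`, `z`,
#'   `p`, `q`, `frac_in`, `frac_out`, `log_fold`, ordered by cluster
#'   then rank.
#' @export
rankMarkers <- function(x, labels, nTop = 50L, minCells = 3L) {
    stopifnot(is(x, "OverlayExperiment"))
    labels <- as.vector(labels)
    stopifnot(length(labels) == ncol(x))
    lev <- sort(unique(labels))
    if (length(lev) < 2L)
        stop("marker ranking requires at least two clusters")
    sizes <- table(labels)
    small <- names(sizes)[sizes < minCells]
    if (length(small)) {
        warning(sprintf("excluding cluster(s) below %d cells: %s",
            minCells, paste(small, collapse = ", ")))
        keep <- !(labels %in% small)
        x <- x[, keep]; labels <- labels[keep]
        if (length(unique(labels)) < 2L)
            stop("fewer than two clusters remain after size filtering")
    }
    genes <- endogenousNames(x)
    m <- as.matrix(SummarizedExperiment::assay(x, "logcounts")[genes, ,
        drop = FALSE])
    expr <- expm1(m)
    stats <- .mwuOneVsRest(m, labels)
    rows <- lapply(stats, function(s) {
        idx <- labels == s$cluster
        q <- stats::p.adjust(s$p, method = "BH")
        fracIn <- rowMeans(m[, idx, drop = FALSE] > 0)
        fracOut <- rowMeans(m[, !idx, drop = FALSE] > 0)
        lf <- log((rowMeans(expr[, idx, drop = FALSE]) + 1e-9) /
                  (rowMeans(expr[, !idx, drop = FALSE]) + 1e-9))
        ord <- order(-s$z, seq_along(s$z))[seq_len(min(nTop, length(genes)))]
        DataFrame(gene = genes[ord], cluster = s$cluster,
            z = s$z[ord], p = s$p[ord], q = q[ord],
            frac_in = fracIn[ord], frac_out = fracOut[ord],
            log_fold = lf[ord])
    })
    do.call(rbind, rows)
}

#' Jaccard similarity of per-cluster top marker sets
#'
#' @param markerTable Output of [rankMarkers()].
#' @param method `"jaccard"` (default): `|A∩B| / |A∪B|`; `"overlap"`:
#'   `|A∩B| / max(|A|, |B|)`, i.e. the cutoff applies to the raw
#'   mutual-presence fraction of the top sets rather than to the
#'   Jaccard score.
#' @return Symmetric similarity matrix with unit diagonal, one
#'   row/column per cluster.
#' @export
jaccardTopsets <- function(markerTable, method = c("jaccard", "overlap")) {
    method <- match.arg(method)
    sets <- split(markerTable$gene, markerTable$cluster)
    k <- length(sets)
    J <- matrix(1, k, k, dimnames = list(names(sets), names(sets)))
    if (k >= 2) for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        inter <- length(intersect(sets[[i]], sets[[j]]))
        J[i, j] <- J[j, i] <- switch(method,
            jaccard = inter / length(union(sets[[i]], sets[[j]])),
            overlap = inter / max(length(sets[[i]]), length(sets[[j]]))
        )
    }
    J
}

#' Merge clusters whose top marker sets overlap
#'
#' Clusters joined by pairwise similarity at or above the threshold
#' (default 0.8, the 80% cutoff on mutual presence of top-50 marker
#' sets) are merged; merging is the transitive closure of
#' above-threshold pairs (connected components). Merged labels are
#' renumbered contiguously by the smallest member label.
#'
#' @param similarity Square symmetric matrix from [jaccardTopsets()].
#' @param threshold Merge threshold in (0, 1].
#' @return A `MergeMap` list: `map` (named old label -> merged 0-based
#'   label), `similarity`, `threshold`.
#' @seealso [applyMergeMap()]
#' @export
mergeByJaccard <- function(similarity, threshold = 0.8) {
    if (threshold <= 0 || threshold > 1)
        stop("threshold must lie in (0, 1]")
    stopifnot(is.matrix(similarity), nrow(similarity) == ncol(similarity),
        isTRUE(all.equal(similarity, t(similarity))))
    adj <- (similarity >= threshold) * 1
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
        diag = FALSE)
    comp <- igraph::components(g)$membership
    # renumber components by their smallest member (input order)
    first <- match(unique(comp), comp)
    newLab <- match(comp, comp[sort(first)]) - 1L
    structure(list(
        map = stats::setNames(newLab, rownames(similarity)),
        similarity = similarity, threshold = threshold),
        class = "MergeMap")
}

#' @rdname mergeByJaccard
#' @param labels Per-cell labels to translate.
#' @param mergeMap A `MergeMap`.
#' @return `applyMergeMap` returns the per-cell merged labels.
#' @export
applyMergeMap <- function(labels, mergeMap) {
    stopifnot(inherits(mergeMap, "MergeMap"))
    out <- mergeMap$map[as.character(as.vector(labels))]
    if (anyNA(out))
        stop("labels contain clusters absent from the merge map")
    stats::setNames(as.integer(out), names(labels))
}

#' Final marker selection after cluster merging
#'
#' Keeps ranked markers that are expressed in the majority of their
#' cluster (`frac_in >= minFracIn`), rare outside it
#' (`frac_out <= maxFracOut`), and unique — a gene surviving the
#' expression filters in more than one cluster's list is dropped from
#' all of them.
#'
#' @param markerTable Output of [rankMarkers()] computed on merged
#'   labels.
#' @param minFracIn Minimum in-cluster expressing fraction (default
#'   0.5).
#' @param maxFracOut Maximum out-of-cluster expressing fraction (default
#'   0.2).
#' @return A [S4Vectors::DataFrame] subset of `markerTable`, ranked by
#'   `z` within cluster; empty (with a warning) when nothing survives.
#' @export
selectFinalMarkers <- function(markerTable, minFracIn = 0.5,
                               maxFracOut = 0.2) {
    keep <- markerTable$frac_in >= minFracIn &
        markerTable$frac_out <= maxFracOut
    tab <- markerTable[keep, , drop = FALSE]
    dup <- unique(tab$gene[duplicated(tab$gene)])
    tab <- tab[!tab$gene %in% dup, , drop = FALSE]
    if (nrow(tab) == 0L)
        warning("no marker passed the final selection filters")
    tab[order(tab$cluster, -tab$z), , drop = FALSE]
}
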