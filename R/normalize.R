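#' Library-size and log normalization
#'
#' Scales every cell's counts to a common total (default `1e4`) and
#' applies the natural-log transform `ln(1 + scale * count / total)`,
#' stored as the `logcounts` assay. Zero counts map to zero, so sparsity
#' is preserved; within a cell, the transform preserves count ranking.
#'
#' @param x An [OverlayExperiment-class] with no zero-total cells
#'   (run [qcFilter()] first).
#' @param scale Target total per cell.
#' @return `x` with a `logcounts` assay.
#' @export
normalizeLog <- function(x, scale = 1e4) {
    stopifnot(is(x, "OverlayExperiment"))
    m <- SummarizedExperiment::assay(x, "counts")
    total <- Matrix::colSums(m)
    if (any(total == 0))
        stop(sprintf("%d cell(s) with zero total counts; filter them first",
            sum(total == 0)))
    ln <- m %*% Matrix::Diagonal(x = scale / total)
    ln@x <- log1p(ln@x)
    dimnames(ln) <- dimnames(m)
    SummarizedExperiment::assay(x, "logcounts") <- ln
    x
}

#' TF-IDF gene weighting
#'
#' Weights each gene's count by the log inverse of its cell frequency:
#' `weight(g, c) = TF(g, c) * ln(N / n_g)`, where `TF` is the raw count
#' of gene `g` in cell `c`, `N` the number of cells, and `n_g` the
#' number of cells in which the gene appears (count > 0). Genes present
#' in every cell get weight 0 everywhere (as do genes present in none),
#' so the weighting emphasizes genes that vary across the population
#' rather than genes that are uniformly abundant. Stored as the `tfidf`
#' assay; an optional exploratory transform off the main pipeline path.
#'
#' @param x An [OverlayExperiment-class].
#' @return `x` with a `tfidf` assay.
#' @export
tfidf <- function(x) {
    stopifnot(is(x, "OverlayExperiment"))
    m <- SummarizedExperiment::assay(x, "counts")
    N <- ncol(m)
    ng <- Matrix::rowSums(m > 0)
    idf <- ifelse(ng == 0, 0, log(N / pmax(ng, 1)))
    w <- Matrix::Diagonal(x = idf) %*% m
    dimnames(w) <- dimnames(m)
    SummarizedExperiment::assay(x, "tfidf") <- methods::as(w, "CsparseMatrix")
    x
}

#' Select highly variable genes
#'
#' Ranks genes by normalized dispersion of their log-normalized
#' expression: per-gene dispersion (variance over mean) is z-scored
#' within 20 equal-frequency bins of the gene means, ranked descending,
#' with ties broken by gene index. Transgene features are always
#' excluded from the ranking input; mitochondrial features are eligible.
#'
#' @param x An [OverlayExperiment-class] with a `logcounts` assay.
#' @param nTop Number of genes to select (default 2000). When fewer
#'   genes are available, all are returned with a warning.
#' @param nBins Number of mean bins.
#' @return Character vector of selected gene names, most variable first.
#' @export
selectHVG <- function(x, nTop = 2000L, nBins = 20L) {
    stopifnot(is(x, "OverlayExperiment"))
    m <- SummarizedExperiment::assay(x, "logcounts")
    keep <- featureClass(x) != "transgene"
    m <- m[keep, , drop = FALSE]
    mu <- Matrix::rowMeans(m)
    v <- Matrix::rowMeans(m^2) - mu^2
    v <- v * ncol(m) / max(1, ncol(m) - 1)
    disp <- ifelse(mu > 0, v / mu, 0)
    br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = nBins + 1)))
    bin <- cut(mu, breaks = br, include.lowest = TRUE)
    bm <- tapply(disp, bin, mean)
    bs <- tapply(disp, bin, stats::sd)
    normDisp <- (disp - bm[bin]) / ifelse(is.na(bs[bin]) | bs[bin] == 0,
        1, bs[bin])
    ord <- order(-normDisp, seq_along(normDisp))
    if (nTop > length(ord)) {
        warning(sprintf("requested %d genes but only %d available",
            nTop, length(ord)))
        nTop <- length(ord)
    }
    rownames(m)[ord[seq_len(nTop)]]
}

#' Scale genes to zero mean and unit variance
#'
#' Returns a dense genes x cells matrix of the selected features with
#' each gene centered to mean 0 and scaled to variance 1
#' (zero-variance genes map to all zeros). The feature classes travel
#' with the matrix (attribute `featureClass`) so that downstream
#' embedding can enforce the endogenous-genes-only contract.
#'
#' @param x An [OverlayExperiment-class] with a `logcounts` assay.
#' @param features Feature names (typically from [selectHVG()]);
#'   defaults to all non-transgene features.
#' @return A dense numeric matrix with attribute `featureClass`.
#' @export
scaleUnit <- function(x, features = NULL) {
    stopifnot(is(x, "OverlayExperiment"))
    if (is.null(features))
        features <- rownames(x)[featureClass(x) != "transgene"]
    missing <- setdiff(features, rownames(x))
    if (length(missing))
        stop(sprintf("unknown feature(s): %s",
            paste(utils::head(missing, 5), collapse = ", ")))
    m <- as.matrix(SummarizedExperiment::assay(x, "logcounts")[features, ,
        drop = FALSE])
    mu <- rowMeans(m)
    sdev <- sqrt(rowMeans((m - mu)^2))  # population variance (1/n)
    s <- (m - mu) / ifelse(sdev == 0, 1, sdev)
    s[sdev == 0, ] <- 0
    attr(s, "featureClass") <-
        featureClass(x)[match(features, rownames(x))]
    s
}
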