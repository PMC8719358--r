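#' Per-cell QC metrics
#'
#' Adds `genes_detected` (endogenous + transgene features with count
#' > 0), `total_counts` (all features), and `mito_fraction`
#' (mitochondrial counts over total counts) to `colData`. A cell with
#' zero total counts gets `mito_fraction = 0` and is flagged in
#' `qc_zero_total`.
#'
#' @param x An [OverlayExperiment-class].
#' @return `x` with QC columns added to `colData`.
#' @export
computeQCMetrics <- function(x) {
    stopifnot(is(x, "OverlayExperiment"))
    m <- SummarizedExperiment::assay(x, "counts")
    fc <- featureClass(x)
    total <- Matrix::colSums(m)
    genes <- Matrix::colSums(m[fc != "mito", , drop = FALSE] > 0)
    mito <- Matrix::colSums(m[fc == "mito", , drop = FALSE])
    zero <- total == 0
    x$genes_detected <- as.integer(genes)
    x$total_counts <- as.integer(total)
    x$mito_fraction <- unname(ifelse(zero, 0, mito / pmax(total, 1)))
    x$qc_zero_total <- unname(zero)
    if (any(zero))
        warning(sprintf("%d cell(s) with zero total counts flagged",
            sum(zero)))
    x
}

#' QC bounds on genes, counts, and mitochondrial fraction
#'
#' `qcBounds` builds an explicit bounds object; `qcBoundsPreset` returns
#' the bounds used for the three tissue datasets the method was
#' developed on: `"v1"` (visual cortex cells: 200-6,000 genes,
#' 750-30,000 counts), `"sc"` (superior colliculus nuclei: 300-9,000
#' genes, 750-50,000 counts), and `"vm"` (ventral midbrain nuclei:
#' 300-5,000 genes, 500-20,000 counts), each with a 5% mitochondrial
#' cap.
#'
#' @param minGenes,maxGenes,minCounts,maxCounts Integer bounds
#'   (inclusive).
#' @param maxMitoFraction Maximum mitochondrial fraction in \[0, 1\].
#' @param preset One of `"v1"`, `"sc"`, `"vm"`.
#' @return A `QCBounds` list.
#' @export
qcBounds <- function(minGenes = 0L, maxGenes = Inf, minCounts = 0L,
                     maxCounts = Inf, maxMitoFraction = 0.05) {
    if (minGenes > maxGenes || minCounts > maxCounts)
        stop("lower bounds must not exceed upper bounds")
    if (maxMitoFraction < 0 || maxMitoFraction > 1)
        stop("maxMitoFraction must lie in [0, 1]")
    structure(list(minGenes = minGenes, maxGenes = maxGenes,
        minCounts = minCounts, maxCounts = maxCounts,
        maxMitoFraction = maxMitoFraction), class = "QCBounds")
}

#' @rdname qcBounds
#' @export
qcBoundsPreset <- function(preset = c("v1", "sc", "vm")) {
    switch(match.arg(preset),
        v1 = qcBounds(200L, 6000L, 750L, 30000L, 0.05),
        sc = qcBounds(300L, 9000L, 750L, 50000L, 0.05),
        vm = qcBounds(300L, 5000L, 500L, 20000L, 0.05))
}

#' Filter cells on QC bounds and doublet flags
#'
#' Retains cells satisfying all bounds (inclusive) whose doublet flag is
#' `FALSE`. Doublet detection itself is out of scope: flags are
#' precomputed inputs, taken from `colData(x)$doublet` when present or
#' supplied explicitly. The removal report (cells failing each
#' criterion; criteria overlap) is stored in `metadata(x)$qcReport` and
#' available via [qcReport()].
#'
#' @param x An [OverlayExperiment-class]; [computeQCMetrics()] is applied
#'   if its columns are missing.
#' @param bounds A [qcBounds()] object or preset name.
#' @param doublets Optional logical per-cell vector overriding
#'   `colData(x)$doublet`.
#' @return The filtered `OverlayExperiment`. Errors (with the report in
#'   the condition message) if no cell survives.
#' @export
qcFilter <- function(x, bounds = qcBounds(), doublets = NULL) {
    stopifnot(is(x, "OverlayExperiment"))
    if (is.character(bounds)) bounds <- qcBoundsPreset(bounds)
    if (!"genes_detected" %in% colnames(SummarizedExperiment::colData(x)))
        x <- computeQCMetrics(x)
    if (is.null(doublets))
        doublets <- if ("doublet" %in%
            colnames(SummarizedExperiment::colData(x))) x$doublet
            else rep(FALSE, ncol(x))
    stopifnot(length(doublets) == ncol(x))
    fail <- list(
        low_genes = x$genes_detected < bounds$minGenes,
        high_genes = x$genes_detected > bounds$maxGenes,
        low_counts = x$total_counts < bounds$minCounts,
        high_counts = x$total_counts > bounds$maxCounts,
        high_mito = x$mito_fraction > bounds$maxMitoFraction,
        doublet = as.logical(doublets))
    keep <- !Reduce(`|`, fail)
    report <- list(bounds = bounds,
        n_input = ncol(x), n_retained = sum(keep),
        n_removed = sum(!keep),
        removed_per_criterion = vapply(fail, sum, numeric(1)))
    if (!any(keep))
        stop(paste0("QC removed all cells; removals per criterion: ",
            paste(names(fail), vapply(fail, sum, numeric(1)),
                sep = "=", collapse = ", ")))
    out <- x[, keep]
    metadata(out)$qcReport <- report
    out
}

#' @rdname qcFilter
#' @param object A filtered `OverlayExperiment`.
#' @return `qcReport` returns the stored removal report.
#' @export
qcReport <- function(object) metadata(object)$qcReport
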