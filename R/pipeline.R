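#' Pipeline configuration
#'
#' Collects the stage parameters of the full overlay pipeline. Unknown
#' keys are rejected; the fully resolved configuration is echoed into
#' every run report so any output can be reproduced.
#'
#' @param bounds QC bounds: a [qcBounds()] object or preset name
#'   (`"v1"`, `"sc"`, `"vm"`).
#' @param useTfidf Apply [tfidf()] as an additional exploratory assay
#'   (off the main path; default `FALSE`).
#' @param scale Library-size normalization target.
#' @param nHvg Highly variable genes to keep.
#' @param nPcs Principal components.
#' @param k Nearest neighbors for the graph.
#' @param resolution Leiden resolution.
#' @param nTopMarkers Top markers per cluster.
#' @param mergeThreshold Marker-set similarity cutoff for cluster
#'   merging.
#' @param mergeMethod `"jaccard"` or `"overlap"` (see
#'   [jaccardTopsets()]).
#' @param theta Transgene-positive read threshold.
#' @param alpha Significance level for enrichment assignment and the
#'   contamination diagnostic.
#' @param breadthCut Cluster-breadth cutoff for the ambient verdict.
#' @param minFracIn,maxFracOut Final marker selection fractions.
#' @return A validated `PipelineConfig` list.
#' @export
pipelineConfig <- function(bounds = "v1", useTfidf = FALSE, scale = 1e4,
                           nHvg = 2000L, nPcs = 50L, k = 15L,
                           resolution = 0.6, nTopMarkers = 50L,
                           mergeThreshold = 0.8,
                           mergeMethod = c("jaccard", "overlap"),
                           theta = 1L, alpha = 0.05, breadthCut = 0.9,
                           minFracIn = 0.5, maxFracOut = 0.2) {
    structure(list(bounds = bounds, useTfidf = useTfidf, scale = scale,
        nHvg = nHvg, nPcs = nPcs, k = k, resolution = resolution,
        nTopMarkers = nTopMarkers, mergeThreshold = mergeThreshold,
        mergeMethod = match.arg(mergeMethod), theta = theta,
        alpha = alpha, breadthCut = breadthCut, minFracIn = minFracIn,
        maxFracOut = maxFracOut), class = "PipelineConfig")
}

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("pipeline stage '%s' failed: %s", name,
            conditionMessage(e)), call. = FALSE))
}

#' Run the full overlay pipeline
#'
#' Chains QC filtering, normalization, highly-variable-gene selection,
#' scaling, PCA, kNN graph construction, Leiden clustering
#' (endogenous genes only), marker ranking, Jaccard cluster merging,
#' transgene-positive calling, hypergeometric projection assignment,
#' and, when compartment labels are available, the ambient-
#' contamination diagnostic. All randomness derives from `seed`;
#' rerunning with the same seed reproduces byte-identical outputs.
#'
#' @param input An [OverlayExperiment-class] or a counts directory path
#'   readable by [readCountsDir()].
#' @param config A [pipelineConfig()].
#' @param seed Integer master seed.
#' @param outDir Optional directory; when given, cluster labels, marker
#'   tables, the overlay report, the dendrogram, and a JSON run report
#'   are written there.
#' @return A list of class `OverlayRun`: the processed experiment,
#'   `coords`, `labels` (merged) and `labelsUnmerged`, `markers`,
#'   `mergeMap`, `finalMarkers`, `enrichment`, `verdicts`,
#'   `dendrogram`, `report`, `config`.
#' @export
runPipeline <- function(input, config = pipelineConfig(), seed = 1L,
                        outDir = NULL) {
    stopifnot(inherits(config, "PipelineConfig"))
    x <- if (is.character(input)) .stage("read", readCountsDir(input))
         else input
    stopifnot(is(x, "OverlayExperiment"))
    report <- list(config = unclass(config), seed = as.integer(seed),
        n_cells_input = ncol(x), n_features = nrow(x))

    x <- .stage("qc_metrics", computeQCMetrics(x))
    x <- .stage("qc_filter", qcFilter(x, bounds = config$bounds))
    report$qc <- qcReport(x)
    report$qc$bounds <- unclass(report$qc$bounds)
    x <- .stage("normalize", normalizeLog(x, scale = config$scale))
    if (isTRUE(config$useTfidf)) x <- .stage("tfidf", tfidf(x))
    hvg <- .stage("hvg", suppressWarnings(selectHVG(x, nTop = config$nHvg)))
    scaled <- .stage("scale", scaleUnit(x, hvg))
    coords <- .stage("pca", pcaEmbed(scaled, nPcs = config$nPcs,
        transgenes = transgeneNames(x)))
    g <- .stage("knn", knnGraph(coords, k = config$k))
    labels0 <- .stage("cluster", communityCluster(g,
        resolution = config$resolution, seed = seed))
    report$n_clusters_initial <- length(unique(labels0))

    markers0 <- .stage("markers", suppressWarnings(
        rankMarkers(x, labels0, nTop = config$nTopMarkers)))
    J <- jaccardTopsets(markers0, method = config$mergeMethod)
    mm <- mergeByJaccard(J, threshold = config$mergeThreshold)
    labels <- applyMergeMap(labels0, mm)
    merged <- length(unique(labels)) < length(unique(labels0))
    markers <- if (merged) .stage("markers_merged", suppressWarnings(
        rankMarkers(x, labels, nTop = config$nTopMarkers))) else markers0
    finalMarkers <- suppressWarnings(selectFinalMarkers(markers,
        minFracIn = config$minFracIn, maxFracOut = config$maxFracOut))
    report$n_clusters_merged <- length(unique(labels))

    calls <- .stage("overlay", callPositive(x, theta = config$theta))
    enrichment <- .stage("enrichment", suppressWarnings(
        clusterEnrichment(calls, labels, alpha = config$alpha)))
    verdicts <- list()
    cd <- SummarizedExperiment::colData(x)
    if ("compartment" %in% colnames(cd) &&
        length(unique(cd$compartment)) > 1L) {
        verdicts <- lapply(colnames(calls), function(t)
            .stage("contamination", contaminationVerdict(calls,
                cd$compartment, labels, t, alpha = config$alpha,
                breadthCut = config$breadthCut)))
        names(verdicts) <- colnames(calls)
    }
    dendro <- if (length(unique(labels)) >= 2L)
        clusterDendrogram(coords, labels, nPcs = config$nPcs) else NULL

    report$n_cells_retained <- ncol(x)
    report$positives_per_transgene <- as.list(attr(calls, "summary"))
    report$verdicts <- lapply(verdicts, function(v)
        list(transgene = v@transgene, verdict = v@verdict,
            breadth = v@breadth, p_one_sided = v@pOneSided))

    run <- structure(list(experiment = x, hvg = hvg, coords = coords,
        labels = labels, labelsUnmerged = labels0, markers = markers,
        mergeMap = mm, finalMarkers = finalMarkers, calls = calls,
        enrichment = enrichment, verdicts = verdicts,
        dendrogram = dendro, report = report, config = config,
        seed = as.integer(seed)), class = "OverlayRun")
    if (!is.null(outDir)) writeRunOutputs(run, outDir)
    run
}

#' Write the artifacts of a pipeline run
#'
#' Writes `labels.tsv` (barcode, cluster, merged cluster),
#' `markers.tsv`, `final_markers.tsv`, `overlay.tsv` (per cluster x
#' transgene enrichment), `dendrogram.nwk` when available, and
#' `report.json`. Numeric TSV columns use 6 significant digits; output
#' is byte-stable for a fixed seed.
#'
#' @param run An `OverlayRun` from [runPipeline()].
#' @param outDir Output directory (created if needed).
#' @return `outDir`, invisibly.
#' @export
writeRunOutputs <- function(run, outDir) {
    stopifnot(inherits(run, "OverlayRun"))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeReportTsv(data.frame(
        barcode = names(run$labels),
        cluster = as.integer(run$labelsUnmerged),
        cluster_merged = as.integer(run$labels)),
        file.path(outDir, "labels.tsv"))
    writeReportTsv(run$markers, file.path(outDir, "markers.tsv"))
    writeReportTsv(run$finalMarkers,
        file.path(outDir, "final_markers.tsv"))
    writeReportTsv(run$enrichment, file.path(outDir, "overlay.tsv"))
    if (!is.null(run$dendrogram))
        writeNewick(run$dendrogram, file.path(outDir, "dendrogram.nwk"))
    jsonlite::write_json(run$report,
        file.path(outDir, "report.json"),
        auto_unbox = TRUE, digits = 10, pretty = TRUE, na = "null")
    invisible(outDir)
}
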