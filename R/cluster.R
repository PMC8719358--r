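#' PCA embedding of scaled expression
#'
#' Principal component analysis of cells in scaled gene space. Transgene
#' features must not be present in the input — viral barcodes carry the
#' connectivity signal being overlaid and may never influence the
#' clustering — and this is enforced, not optional: if the matrix
#' carries a `featureClass` attribute containing `"transgene"`, or any
#' row name matches `transgenes`, an error is thrown.
#'
#' Component signs are fixed (largest-magnitude loading positive) so the
#' embedding is deterministic.
#'
#' @param scaled Dense genes x cells matrix from [scaleUnit()].
#' @param nPcs Number of principal components (default 50); must be
#'   smaller than both dimensions.
#' @param transgenes Optional transgene names to check row names
#'   against.
#' @return A cells x `nPcs` coordinate matrix with attribute
#'   `varExplained` (non-increasing per-component explained variance).
#' @export
pcaEmbed <- function(scaled, nPcs = 50L, transgenes = NULL) {
    fc <- attr(scaled, "featureClass")
    if (!is.null(fc) && any(fc == "transgene"))
        stop("transgene features must be excluded from the embedding input")
    if (!is.null(transgenes) && any(rownames(scaled) %in% transgenes))
        stop("transgene features must be excluded from the embedding input")
    if (nPcs >= min(dim(scaled)))
        stop(sprintf("nPcs = %d must be < min(genes, cells) = %d",
            nPcs, min(dim(scaled))))
    pc <- stats::prcomp(t(scaled), center = FALSE, scale. = FALSE,
        rank. = nPcs)
    coords <- pc$x
    # deterministic sign convention
    for (j in seq_len(ncol(coords))) {
        i <- which.max(abs(pc$rotation[, j]))
        if (pc$rotation[i, j] < 0) coords[, j] <- -coords[, j]
    }
    attr(coords, "varExplained") <- pc$sdev[seq_len(nPcs)]^2
    coords
}

#' k-nearest-neighbor graph in PC space
#'
#' Each cell is connected to its `k` nearest neighbors by Euclidean
#' distance; directed edges are symmetrized by union into an unweighted
#' undirected graph. Neighbor ties are broken by cell index.
#'
#' @param coords Cells x dims coordinate matrix from [pcaEmbed()].
#' @param k Number of neighbors (default 15); requires at least `k + 1`
#'   cells.
#' @return An [igraph::igraph] graph with one vertex per cell.
#' @export
knnGraph <- function(coords, k = 15L) {
    n <- nrow(coords)
    if (n < k + 1L)
        stop(sprintf("need at least k + 1 = %d cells, got %d", k + 1L, n))
    d <- as.matrix(stats::dist(coords))
    edges <- matrix(0L, n * k, 2L)
    for (i in seq_len(n)) {
        o <- order(d[i, -i], seq_len(n)[-i])[seq_len(k)]
        nb <- seq_len(n)[-i][o]
        edges[((i - 1L) * k + 1L):(i * k), ] <- cbind(i, nb)
    }
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    g <- igraph::simplify(g)
    if (!is.null(rownames(coords)))
        igraph::V(g)$name <- rownames(coords)
    g
}

#' Leiden community clustering
#'
#' Applies Leiden community detection (modularity objective) to the
#' neighborhood graph. Labels are integers contiguous from 0, renumbered
#' by first occurrence along the cell ordering; the result is
#' deterministic for a fixed seed.
#'
#' @param graph Graph from [knnGraph()].
#' @param resolution Resolution parameter (default 0.6).
#' @param seed Integer seed.
#' @param nIterations Leiden refinement iterations.
#' @return Integer vector of 0-based labels, named by cell when the
#'   graph has vertex names, with attributes `resolution` and `seed`.
#' @export
communityCluster <- function(graph, resolution = 0.6, seed = 0L,
                             nIterations = 10L) {
    if (igraph::vcount(graph) == 0L)
        stop("empty graph")
    set.seed(as.integer(seed))
    cl <- igraph::cluster_leiden(graph,
        objective_function = "modularity",
        resolution = resolution, n_iterations = nIterations)
    mem <- igraph::membership(cl)
    labels <- match(mem, unique(mem)) - 1L
    names(labels) <- igraph::V(graph)$name
    attr(labels, "resolution") <- resolution
    attr(labels, "seed") <- as.integer(seed)
    labels
}

#' Subset cells by marker expression
#'
#' Selects the cells whose normalized expression of a gene set is
#' positive (count > 0 per gene) under rule `"any"` or `"all"` — e.g.
#' the excitatory-neuron subset for subclustering.
#'
#' @param x An [OverlayExperiment-class].
#' @param genes Gene names; unknown genes raise an error.
#' @param rule `"any"` (default) or `"all"`.
#' @return Logical per-cell vector, named by barcode, with attribute
#'   `provenance` recording genes and rule.
#' @export
subsetByMarker <- function(x, genes, rule = c("any", "all")) {
    rule <- match.arg(rule)
    stopifnot(is(x, "OverlayExperiment"))
    missing <- setdiff(genes, rownames(x))
    if (length(missing))
        stop(sprintf("unknown gene(s): %s", paste(missing, collapse = ", ")))
    m <- SummarizedExperiment::assay(x, "counts")[genes, , drop = FALSE] > 0
    sel <- if (rule == "any") Matrix::colSums(m) > 0
           else Matrix::colSums(m) == length(genes)
    sel <- stats::setNames(as.logical(sel), colnames(x))
    attr(sel, "provenance") <- list(genes = genes, rule = rule)
    sel
}

#' Cluster dendrogram on PC centroids
#'
#' Complete-linkage hierarchical clustering of cluster centroids in
#' principal-component space, with distance `1 - Pearson r` between
#' centroid PC vectors over the top `nPcs` components. Leaves are the
#' cluster labels.
#'
#' @param coords Cells x PCs matrix from [pcaEmbed()].
#' @param labels Per-cell cluster labels (>= 2 distinct values).
#' @param nPcs Components used (default up to 50).
#' @return An [ape::phylo] tree (serialize with [writeNewick()]).
#' @export
clusterDendrogram <- function(coords, labels, nPcs = 50L) {
    labels <- as.vector(labels)
    stopifnot(nrow(coords) == length(labels))
    lev <- sort(unique(labels))
    if (length(lev) < 2L)
        stop("dendrogram requires at least two clusters")
    nPcs <- min(nPcs, ncol(coords))
    cent <- t(vapply(lev, function(l)
        colMeans(coords[labels == l, seq_len(nPcs), drop = FALSE]),
        numeric(nPcs)))
    rownames(cent) <- as.character(lev)
    d <- 1 - stats::cor(t(cent))
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    ape::as.phylo(hc)
}
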