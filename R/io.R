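#' Round half away from zero
#'
#' Rounding convention used for reported percentages: halves round up
#' (`0.5 -> 1`), unlike base [round()]'s round-half-even.
#'
#' @param x Numeric.
#' @param digits Number of decimal digits.
#' @return Rounded numeric.
#' @examples
#' roundHalfUp(0.5)      # 1
#' roundHalfUp(2.675, 2) # 2.68
#' @export
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage of a count over a total
#'
#' @param n,total Nonnegative counts, `total > 0`.
#' @param digits Decimal digits of the reported percentage.
#' @return `roundHalfUp(100 * n / total, digits)`.
#' @examples
#' fractionPercent(53740, 54537, 2) # 98.54
#' @export
fractionPercent <- function(n, total, digits = 2) {
    stopifnot(total > 0, n >= 0)
    roundHalfUp(100 * n / total, digits)
}

# fixed numeric formatting for TSV outputs: 6 significant digits
.fmtNum <- function(x) {
    if (is.double(x)) formatC(x, digits = 6, format = "g") else x
}

#' Write a tab-separated report with stable numeric formatting
#'
#' Doubles are written at 6 significant digits so that reruns with the
#' same seed produce byte-identical files.
#'
#' @param df A data.frame or DataFrame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeReportTsv <- function(df, path) {
    df <- as.data.frame(df)
    df[] <- lapply(df, .fmtNum)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Write/read a CellRanger-style counts directory
#'
#' The directory holds `matrix.mtx` (Matrix Market integer triplets,
#' 1-based indices, features x cells), `features.tsv`
#' (`id`, `name`, `class` with class in endogenous/mito/transgene),
#' `barcodes.tsv`, and, when the object carries simulation truth,
#' `truth.tsv`. `readCountsDir` of a written directory reproduces the
#' counts and annotations exactly.
#'
#' @param x An [OverlayExperiment-class].
#' @param path Directory (created if needed).
#' @return `writeCountsDir` returns `path` invisibly; `readCountsDir`
#'   returns an [OverlayExperiment-class].
#' @export
writeCountsDir <- function(x, path) {
    stopifnot(is(x, "OverlayExperiment"))
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- methods::as(Matrix::drop0(
        SummarizedExperiment::assay(x, "counts")), "TsparseMatrix")
    con <- file(file.path(path, "matrix.mtx"), "w")
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
        sprintf("%d %d %d", nrow(m), ncol(m), length(m@x))), con)
    o <- order(m@j, m@i)
    writeLines(sprintf("%d %d %d", m@i[o] + 1L, m@j[o] + 1L,
        as.integer(m@x[o])), con)
    close(con)
    utils::write.table(
        data.frame(id = rownames(x), name = rownames(x),
            class = featureClass(x)),
        file.path(path, "features.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    writeLines(colnames(x), file.path(path, "barcodes.tsv"))
    cd <- SummarizedExperiment::colData(x)
    if ("population" %in% colnames(cd)) {
        truth <- data.frame(barcode = colnames(x), check.names = FALSE)
        for (cc in setdiff(colnames(cd), "sizeFactor"))
            truth[[cc]] <- cd[[cc]]
        writeReportTsv(truth, file.path(path, "truth.tsv"))
    }
    invisible(path)
}

.mtxError <- function(line, msg)
    stop(sprintf("malformed matrix.mtx at line %d: %s", line, msg))

#' @rdname writeCountsDir
#' @export
readCountsDir <- function(path) {
    mtx <- file.path(path, "matrix.mtx")
    ftsv <- file.path(path, "features.tsv")
    btsv <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, ftsv, btsv))
        if (!file.exists(f)) stop(sprintf("missing file: %s", f))
    lines <- readLines(mtx)
    if (!grepl("^%%MatrixMarket matrix coordinate (integer|real) general",
        lines[1]))
        .mtxError(1L, "unsupported or missing MatrixMarket header")
    body <- which(!startsWith(lines, "%"))
    dimLine <- body[1]
    dims <- suppressWarnings(as.integer(strsplit(trimws(lines[dimLine]),
        "\\s+")[[1]]))
    if (length(dims) != 3L || anyNA(dims))
        .mtxError(dimLine, "expected 'nrow ncol nnz'")
    entries <- body[-1]
    if (length(entries) != dims[3])
        .mtxError(dimLine, sprintf("declared %d entries, found %d",
            dims[3], length(entries)))
    trip <- matrix(NA_real_, length(entries), 3)
    if (length(entries)) {
        parsed <- strsplit(trimws(lines[entries]), "\\s+")
        bad <- which(lengths(parsed) != 3L)
        if (length(bad))
            .mtxError(entries[bad[1]], "expected 'row col value'")
        trip <- matrix(suppressWarnings(as.numeric(unlist(parsed))),
            ncol = 3, byrow = TRUE)
        if (anyNA(trip))
            .mtxError(entries[which(is.na(rowSums(trip)))[1]],
                "non-numeric entry")
        out <- which(trip[, 1] < 1 | trip[, 1] > dims[1] |
                     trip[, 2] < 1 | trip[, 2] > dims[2])
        if (length(out))
            .mtxError(entries[out[1]], "index out of bounds")
    }
    feat <- utils::read.table(ftsv, sep = "\t", header = FALSE,
        colClasses = "character")
    if (ncol(feat) < 3L)
        stop("features.tsv must have id, name, class columns")
    if (!all(feat[[3]] %in% .FEATURE_CLASSES))
        stop("features.tsv class column must be endogenous/mito/transgene")
    if (nrow(feat) != dims[1])
        stop(sprintf("features.tsv has %d rows, matrix declares %d",
            nrow(feat), dims[1]))
    bc <- readLines(btsv)
    if (length(bc) != dims[2])
        stop(sprintf("barcodes.tsv has %d rows, matrix declares %d",
            length(bc), dims[2]))
    m <- Matrix::sparseMatrix(i = trip[, 1], j = trip[, 2], x = trip[, 3],
        dims = dims[1:2], dimnames = list(feat[[1]], bc))
    cd <- NULL
    ttsv <- file.path(path, "truth.tsv")
    if (file.exists(ttsv)) {
        truth <- utils::read.table(ttsv, sep = "\t", header = TRUE)
        stopifnot(identical(truth$barcode, bc))
        cd <- truth[setdiff(colnames(truth), "barcode")]
    }
    OverlayExperiment(m, featureClass = feat[[3]], colData = cd)
}

#' Serialize a cluster dendrogram to Newick
#'
#' @param tree An [ape::phylo] tree (from [clusterDendrogram()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeNewick <- function(tree, path) {
    ape::write.tree(tree, file = path)
    invisible(path)
}
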