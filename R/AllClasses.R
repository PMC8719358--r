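#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
NULL

.FEATURE_CLASSES <- c("endogenous", "mito", "transgene")

#' Registry of viral transgene barcode sequences
#'
#' A `TransgeneRegistry` holds the nucleotide sequences of virally
#' delivered transgenes (recombinases, fluorophores) together with the
#' projection target each virus was injected into and the virus class.
#' The registry is the input to reference augmentation
#' ([augmentedReference()]) and to barcode discriminability checks
#' ([discriminabilityReport()]).
#'
#' @slot sequences A [Biostrings::DNAStringSet] of transgene sequences;
#'   names are the unique transgene identifiers.
#' @slot projectionTarget Character vector, one free-text label per
#'   transgene (the injected structure), `NA` when unknown.
#' @slot virusClass Character vector, one free-text label per transgene
#'   (e.g. `"retro-AAV"`, `"HSV"`), `NA` when unknown.
#' @slot hasWpre Logical vector; whether the construct carries a 3' WPRE
#'   element (relevant for 5' sequencing detectability), `NA` when unknown.
#'
#' @seealso [parseTransgeneFasta()], [readTransgeneFasta()],
#'   [pairwiseIdentity()]
#' @export
setClass("TransgeneRegistry",
    slots = c(
        sequences = "DNAStringSet",
        projectionTarget = "character",
        virusClass = "character",
        hasWpre = "logical"
    )
)

setValidity("TransgeneRegistry", function(object) {
    n <- length(object@sequences)
    nm <- names(object@sequences)
    msg <- character()
    if (is.null(nm) || any(!nzchar(nm)) || anyNA(nm))
        msg <- c(msg, "all transgenes must have nonempty names")
    else if (anyDuplicated(nm))
        msg <- c(msg, sprintf("duplicate transgene name(s): %s",
            paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    if (n > 0 && any(Biostrings::width(object@sequences) < 1L))
        msg <- c(msg, "all sequences must have length >= 1")
    if (n > 0) {
        freq <- Biostrings::alphabetFrequency(object@sequences)
        bad <- rowSums(freq[, c("A", "C", "G", "T", "N"), drop = FALSE]) !=
            rowSums(freq)
        if (any(bad))
            msg <- c(msg, sprintf(
                "sequence(s) contain letters outside A/C/G/T/N: %s",
                paste(nm[bad], collapse = ", ")))
    }
    for (s in c("projectionTarget", "virusClass", "hasWpre"))
        if (length(slot(object, s)) != n)
            msg <- c(msg, sprintf("'%s' must have one entry per sequence", s))
    if (length(msg)) msg else TRUE
})

#' Construct a TransgeneRegistry
#'
#' @param sequences A named [Biostrings::DNAStringSet] or named character
#'   vector of nucleotide sequences (uppercased on ingest; `N` is accepted
#'   but flagged and never counts as a match in identity computations).
#' @param projectionTarget,virusClass Optional character vectors recycled
#'   to the number of sequences.
#' @param hasWpre Optional logical vector recycled to the number of
#'   sequences.
#'
#' @return A [TransgeneRegistry-class] object.
#' @examples
#' reg <- TransgeneRegistry(c(GFP = "ATGGTGAGCAAG", Cre = "ATGTCCAATTTA"),
#'     projectionTarget = c("PPRF", "LP"))
#' reg
#' @export
TransgeneRegistry <- function(sequences, projectionTarget = NA_character_,
                              virusClass = NA_character_, hasWpre = NA) {
    if (is.character(sequences))
        sequences <- Biostrings::DNAStringSet(toupper(sequences))
    n <- length(sequences)
    nN <- vapply(seq_len(n), function(i)
        Biostrings::countPattern("N",  sequences[[i]]), integer(1))
    if (any(nN > 0))
        warning(sprintf("sequence(s) contain N (flagged, never a match): %s",
            paste(names(sequences)[nN > 0], collapse = ", ")))
    new("TransgeneRegistry",
        sequences = sequences,
        projectionTarget = rep_len(as.character(projectionTarget), n),
        virusClass = rep_len(as.character(virusClass), n),
        hasWpre = rep_len(as.logical(hasWpre), n))
}

#' Single-cell experiment with transgene-aware feature classes
#'
#' An `OverlayExperiment` extends
#' [SingleCellExperiment][SingleCellExperiment::SingleCellExperiment-class]
#' with the requirement that every feature (row) is classified as
#' `endogenous`, `mito`, or `transgene` via the `featureClass` column of
#' `rowData`. The class is enforced at every stage that must distinguish
#' viral barcodes from endogenous genes: clustering input never contains
#' transgene features, QC mitochondrial fractions are computed from the
#' `mito` class, and the overlay stage acts on the `transgene` class.
#'
#' @seealso [featureClass()], [transgeneNames()], [simulateDroplets()],
#'   [readCountsDir()]
#' @export
setClass("OverlayExperiment", contains = "SingleCellExperiment")

setValidity("OverlayExperiment", function(object) {
    rd <- SummarizedExperiment::rowData(object)
    if (!"featureClass" %in% colnames(rd))
        return("rowData must contain a 'featureClass' column")
    fc <- rd$featureClass
    if (!all(fc %in% .FEATURE_CLASSES))
        return(sprintf("featureClass values must be one of: %s",
            paste(.FEATURE_CLASSES, collapse = ", ")))
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        return("features must have unique names")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("an assay named 'counts' is required")
    TRUE
})

#' Construct an OverlayExperiment
#'
#' @param counts Integer (sparse) matrix, features x cells, with unique
#'   row names.
#' @param featureClass Character vector, one of `"endogenous"`, `"mito"`,
#'   `"transgene"` per feature.
#' @param colData Optional per-cell annotation
#'   ([S4Vectors::DataFrame] or data.frame).
#' @param ... Further arguments passed to
#'   [SingleCellExperiment::SingleCellExperiment()].
#'
#' @return An [OverlayExperiment-class].
#' @examples
#' m <- Matrix::Matrix(matrix(rpois(12, 2), 4,
#'     dimnames = list(c("g1", "g2", "mt1", "GFP"), NULL)), sparse = TRUE)
#' oe <- OverlayExperiment(m,
#'     featureClass = c("endogenous", "endogenous", "mito", "transgene"))
#' featureClass(oe)
#' @export
OverlayExperiment <- function(counts, featureClass, colData = NULL, ...) {
    if (is.null(colnames(counts)))
        colnames(counts) <- sprintf("cell%d", seq_len(ncol(counts)))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        rowData = DataFrame(featureClass = as.character(featureClass)),
        ...)
    if (!is.null(colData))
        SummarizedExperiment::colData(sce) <-
            cbind(SummarizedExperiment::colData(sce), DataFrame(colData))
    new("OverlayExperiment", sce)
}

#' Two-by-two contingency table with Pearson chi-square statistic
#'
#' Holds the 2x2 counts used by the ambient-contamination diagnostic and
#' by marker-specificity tests, together with the Pearson chi-square
#' statistic (df = 1) and its two-sided p-value. Rows are groups
#' (e.g. transgene-positive / transgene-negative), columns are outcomes
#' (e.g. non-neuronal / neuronal).
#'
#' @slot counts 2x2 numeric matrix of nonnegative counts `(a, b; c, d)`.
#' @slot correction `"none"` or `"yates"`.
#' @slot chi2,p Statistic and two-sided p-value; `NA` when a margin is
#'   zero (degenerate table).
#' @slot degenerate Logical; `TRUE` when any margin is zero.
#' @seealso [contingencyTable()], [chisq2x2()], [compartmentTable()]
#' @export
setClass("ContingencyTable",
    slots = c(counts = "matrix", correction = "character",
              chi2 = "numeric", p = "numeric", degenerate = "logical"))

setValidity("ContingencyTable", function(object) {
    ct <- object@counts
    if (!all(dim(ct) == c(2L, 2L))) return("counts must be a 2x2 matrix")
    if (any(ct < 0) || any(ct != round(ct)))
        return("counts must be nonnegative integers")
    if (!object@correction %in% c("none", "yates"))
        return("correction must be 'none' or 'yates'")
    TRUE
})

#' Ambient-contamination verdict for one transgene
#'
#' Result of [contaminationVerdict()]: the cluster breadth of the
#' transgene, the compartment contingency table, the one-sided
#' depletion p-value, and the verdict. A transgene delivered by genuine
#' retrograde infection of neurons should be depleted of the
#' non-neuronal compartment; ambient RNA leaks into droplets without
#' regard to compartment.
#'
#' @slot transgene Transgene name.
#' @slot breadth Fraction of clusters containing at least one positive
#'   cell.
#' @slot table The [ContingencyTable-class] (positive vs negative rows,
#'   non-neuronal vs neuronal columns).
#' @slot pOneSided One-sided p-value for depletion of the non-neuronal
#'   compartment among positives.
#' @slot verdict One of `"retrograde_consistent"`, `"ambient_suspect"`,
#'   `"undetected"`, `"inconclusive"`.
#' @export
setClass("ContaminationVerdict",
    slots = c(transgene = "character", breadth = "numeric",
              table = "ContingencyTable", pOneSided = "numeric",
              verdict = "character"))

setValidity("ContaminationVerdict", function(object) {
    ok <- c("retrograde_consistent", "ambient_suspect", "undetected",
            "inconclusive")
    if (!object@verdict %in% ok)
        return(sprintf("verdict must be one of: %s", paste(ok, collapse = ", ")))
    if (object@breadth < 0 || object@breadth > 1)
        return("breadth must lie in [0, 1]")
    TRUE
})
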