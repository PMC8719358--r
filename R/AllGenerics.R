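#' Feature classes of an OverlayExperiment
#'
#' @param x An [OverlayExperiment-class].
#' @return `featureClass` returns the per-feature class vector
#'   (`endogenous`, `mito`, `transgene`); `transgeneNames`,
#'   `endogenousNames`, and `mitoNames` return the feature names of the
#'   corresponding class.
#' @examples
#' oe <- simulateDroplets(defaultSimConfig(nCellsPerPop = 20), seed = 1)
#' table(featureClass(oe))
#' transgeneNames(oe)
#' @export
setGeneric("featureClass", function(x) standardGeneric("featureClass"))

#' @rdname featureClass
#' @export
setGeneric("transgeneNames", function(x) standardGeneric("transgeneNames"))

#' @rdname featureClass
#' @export
setGeneric("endogenousNames", function(x) standardGeneric("endogenousNames"))

#' @rdname featureClass
#' @export
setGeneric("mitoNames", function(x) standardGeneric("mitoNames"))

#' @describeIn featureClass per-feature class vector
#' @export
setMethod("featureClass", "OverlayExperiment", function(x)
    SummarizedExperiment::rowData(x)$featureClass)

#' @describeIn featureClass names of transgene features
#' @export
setMethod("transgeneNames", "OverlayExperiment", function(x)
    rownames(x)[featureClass(x) == "transgene"])

#' @describeIn featureClass names of endogenous features
#' @export
setMethod("endogenousNames", "OverlayExperiment", function(x)
    rownames(x)[featureClass(x) == "endogenous"])

#' @describeIn featureClass names of mitochondrial features
#' @export
setMethod("mitoNames", "OverlayExperiment", function(x)
    rownames(x)[featureClass(x) == "mito"])

#' @export
#' @describeIn TransgeneRegistry number of transgenes
setMethod("length", "TransgeneRegistry", function(x) length(x@sequences))

#' @export
#' @describeIn TransgeneRegistry transgene names
setMethod("names", "TransgeneRegistry", function(x) names(x@sequences))

#' Transgene sequences of a registry
#'
#' @param x A [TransgeneRegistry-class].
#' @return The underlying named [Biostrings::DNAStringSet].
#' @export
setGeneric("transgeneSequences",
    function(x) standardGeneric("transgeneSequences"))

#' @describeIn TransgeneRegistry the underlying DNAStringSet
#' @export
setMethod("transgeneSequences", "TransgeneRegistry", function(x) x@sequences)

#' @export
#' @describeIn TransgeneRegistry subset by name or index
setMethod("[", "TransgeneRegistry", function(x, i, j, ..., drop = TRUE) {
    if (is.character(i)) i <- match(i, names(x@sequences))
    initialize(x, sequences = x@sequences[i],
        projectionTarget = x@projectionTarget[i],
        virusClass = x@virusClass[i], hasWpre = x@hasWpre[i])
})

setMethod("show", "TransgeneRegistry", function(object) {
    cat(sprintf("TransgeneRegistry with %d transgene(s)\n", length(object)))
    if (length(object)) {
        df <- data.frame(
            name = names(object),
            width = Biostrings::width(object@sequences),
            target = object@projectionTarget,
            virus = object@virusClass,
            wpre = object@hasWpre)
        print(df, row.names = FALSE)
    }
    invisible(object)
})

setMethod("show", "ContingencyTable", function(object) {
    cat("2x2 ContingencyTable (rows = groups, cols = outcome)\n")
    print(object@counts)
    if (object@degenerate) {
        cat("degenerate table (zero margin): chi-square undefined\n")
    } else {
        cat(sprintf("chi2 = %.6g, df = 1, p = %.6g (correction: %s)\n",
            object@chi2, object@p, object@correction))
    }
    invisible(object)
})

setMethod("show", "ContaminationVerdict", function(object) {
    cat(sprintf("ContaminationVerdict for '%s': %s\n",
        object@transgene, object@verdict))
    cat(sprintf("  cluster breadth: %.3f\n", object@breadth))
    cat(sprintf("  one-sided depletion p: %.4g\n", object@pOneSided))
    show(object@table)
    invisible(object)
})

#' Accessors for contingency results
#'
#' @param x A [ContingencyTable-class] or [ContaminationVerdict-class].
#' @return `chi2Statistic` and `pValue` return the Pearson statistic and
#'   two-sided p-value of a table; `verdict` returns the verdict string
#'   of a contamination diagnostic.
#' @export
setGeneric("chi2Statistic", function(x) standardGeneric("chi2Statistic"))

#' @rdname chi2Statistic
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname chi2Statistic
#' @export
setGeneric("verdict", function(x) standardGeneric("verdict"))

#' @describeIn chi2Statistic Pearson statistic of a 2x2 table
#' @export
setMethod("chi2Statistic", "ContingencyTable", function(x) x@chi2)

#' @describeIn chi2Statistic two-sided p-value of a 2x2 table
#' @export
setMethod("pValue", "ContingencyTable", function(x) x@p)

#' @describeIn chi2Statistic verdict string of a contamination diagnostic
#' @export
setMethod("verdict", "ContaminationVerdict", function(x) x@verdict)

#' @describeIn chi2Statistic one-sided depletion p of a contamination
#'   diagnostic
#' @export
setMethod("pValue", "ContaminationVerdict", function(x) x@pOneSided)
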