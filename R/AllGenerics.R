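#' @rdname ResponseExperiment-class
#' @param x,object a \code{ResponseExperiment}
#' @export
setGeneric("cellLines", function(x) standardGeneric("cellLines"))

#' @rdname ResponseExperiment-class
#' @export
setGeneric("expressionScale", function(x) standardGeneric("expressionScale"))

#' @rdname ReceptorDesign-class
#' @param x a \code{ReceptorDesign}
#' @export
setGeneric("receptors", function(x) standardGeneric("receptors"))

#' @rdname ReceptorDesign-class
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @rdname ReceptorDesign-class
#' @param receptor single receptor name
#' @export
setGeneric("positiveLines",
           function(x, receptor) standardGeneric("positiveLines"))

#' @rdname ReceptorDesign-class
#' @export
setGeneric("negativeLines",
           function(x, receptor) standardGeneric("negativeLines"))

#' @rdname ResponseCalls-class
#' @param x a \code{ResponseCalls}
#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))

#' @rdname ResponseCalls-class
#' @export
setGeneric("regulationCalls", function(x) standardGeneric("regulationCalls"))

#' @rdname AttributionResult-class
#' @param x an \code{AttributionResult} (or \code{PlantedTruth} for the
#'   annotation accessor)
#' @export
setGeneric("attributedProbeSets",
           function(x) standardGeneric("attributedProbeSets"))

#' @rdname AttributionResult-class
#' @export
setGeneric("attributedGenes", function(x) standardGeneric("attributedGenes"))

#' @rdname PlantedTruth-class
#' @export
setGeneric("plantedGenes",
           function(x, receptor) standardGeneric("plantedGenes"))

#' @rdname PlantedTruth-class
#' @export
setGeneric("truthAnnotation",
           function(x) standardGeneric("truthAnnotation"))

setMethod("cellLines", "ResponseExperiment",
          function(x) unique(as.character(colData(x)$cellLine)))

setMethod("expressionScale", "ResponseExperiment", function(x) {
    sc <- metadata(x)$scale
    if (is.null(sc)) "linear" else sc
})

setMethod("receptors", "ReceptorDesign", function(x) rownames(x@presence))
setMethod("cellLines", "ReceptorDesign", function(x) colnames(x@presence))
setMethod("presenceMatrix", "ReceptorDesign", function(x) x@presence)

setMethod("positiveLines", "ReceptorDesign", function(x, receptor) {
    .checkReceptor(x, receptor)
    colnames(x@presence)[x@presence[receptor, ]]
})

setMethod("negativeLines", "ReceptorDesign", function(x, receptor) {
    .checkReceptor(x, receptor)
    colnames(x@presence)[!x@presence[receptor, ]]
})

.checkReceptor <- function(design, receptor) {
    if (length(receptor) != 1L || !receptor %in% receptors(design))
        stop("receptor '", receptor, "' is not in the design (receptors: ",
             paste(receptors(design), collapse = ", "), ")", call. = FALSE)
    invisible(TRUE)
}

setMethod("foldChanges", "ResponseCalls", function(x) x@fold)
setMethod("regulationCalls", "ResponseCalls", function(x) x@call)

setMethod("attributedProbeSets", "AttributionResult", function(x) x@probeSets)
setMethod("attributedGenes", "AttributionResult", function(x) x@genes)

setMethod("plantedGenes", "PlantedTruth", function(x, receptor) {
    if (missing(receptor)) return(x@receptorGenes)
    if (!receptor %in% names(x@receptorGenes))
        stop("no planted genes recorded for receptor '", receptor, "'")
    x@receptorGenes[[receptor]]
})

setMethod("truthAnnotation", "PlantedTruth", function(x) x@annotation)

setMethod("show", "ReceptorDesign", function(object) {
    p <- object@presence
    cat("ReceptorDesign:", nrow(p), "receptor(s) x", ncol(p),
        "cell line(s)\n")
    print(ifelse(p, "+", "-"), quote = FALSE)
})

setMethod("show", "ResponseCalls", function(object) {
    cat("ResponseCalls:", nrow(object@fold), "probe set(s) x",
        ncol(object@fold), "cell line(s)\n")
    cat("  thresholds: up >", object@upThreshold, "; down <",
        signif(object@downThreshold, 4), "\n")
    n <- ncol(object@fold)
    for (ln in colnames(object@fold)) {
        cl <- object@call[, ln]
        cat(sprintf("  %s: %d up, %d down, %d unchanged\n", ln,
                    sum(cl == "up"), sum(cl == "down"),
                    sum(cl == "unchanged")))
    }
    if (length(object@excluded))
        cat("  excluded (missing values):", length(object@excluded),
            "probe set(s)\n")
})

setMethod("show", "AttributionResult", function(object) {
    cat("AttributionResult for receptor", object@receptor,
        paste0("(", object@direction, "-regulated, ", object@level,
               " level)\n"))
    cat("  positive lines:", paste(object@positiveLines, collapse = ", "),
        "\n")
    cat("  negative lines:", paste(object@negativeLines, collapse = ", "),
        "\n")
    cat("  attributed probe sets:", length(object@probeSets), "\n")
    if (object@level == "gene")
        cat("  distinct genes:", length(object@genes),
            "( unannotated probe sets:", object@nUnannotated, ")\n")
})

setMethod("show", "PlantedTruth", function(object) {
    cat("PlantedTruth:",
        length(unlist(object@receptorGenes)), "planted gene(s) across",
        length(object@receptorGenes), "receptor(s);",
        length(object@annotation), "annotated probe set(s)\n")
})
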