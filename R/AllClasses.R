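#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Ligand-response expression experiment
#'
#' A \linkS4class{SummarizedExperiment} holding one fluorescence matrix
#' (probe sets in rows, hybridized arrays in columns) for a panel of cell
#' lines measured untreated (control) and ligand-stimulated (treated), with
#' one or more replicate arrays per condition.  Column metadata must carry
#' \code{cellLine}, \code{condition} (one of \code{"control"},
#' \code{"treated"}) and \code{replicate}; \code{metadata(x)$scale} records
#' whether values are on the \code{"linear"} or \code{"log2"} scale, which
#' downstream fold-change computation honours.
#'
#' @slot . inherits all slots from \code{SummarizedExperiment}.
#' @seealso [ResponseExperiment()] for the constructor,
#'   [readExpressionTable()], [simulateAttributionDataset()]
#' @export
setClass("ResponseExperiment", contains = "SummarizedExperiment")

.validResponseExperiment <- function(object) {
    msg <- character()
    cd <- colData(object)
    need <- c("cellLine", "condition", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData is missing column(s): ",
                             paste(miss, collapse = ", ")))
    if (!"fluorescence" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'fluorescence' is required")
    if (!length(msg)) {
        if (!all(cd$condition %in% c("control", "treated")))
            msg <- c(msg, "condition must be 'control' or 'treated'")
        ids <- rownames(object)
        if (is.null(ids) || anyDuplicated(ids))
            msg <- c(msg, "probe-set identifiers (rownames) must be unique")
        sc <- expressionScale(object)
        if (!sc %in% c("linear", "log2"))
            msg <- c(msg, "metadata(x)$scale must be 'linear' or 'log2'")
        v <- assay(object, "fluorescence")
        if (identical(sc, "linear") && any(v < 0, na.rm = TRUE))
            msg <- c(msg, "linear-scale fluorescence must be non-negative")
        key <- paste(cd$cellLine, cd$condition)
        lines <- unique(cd$cellLine)
        want <- as.vector(outer(lines, c("control", "treated"), paste))
        absent <- setdiff(want, key)
        if (length(absent))
            msg <- c(msg, paste0("every (cell line, condition) needs >= 1 ",
                                 "replicate; missing: ",
                                 paste(absent, collapse = "; ")))
    }
    if (length(msg)) msg else TRUE
}
setValidity("ResponseExperiment", .validResponseExperiment)

#' Binary receptor-by-cell-line design
#'
#' Records which receptor is expressed ("present") in which cell line.  The
#' presence pattern of a receptor across lines is what makes its response
#' genes attributable: a gene is credited to a receptor only when it responds
#' in every receptor-positive line and in no receptor-negative line, so the
#' design must offer both kinds of lines (see [checkIdentifiability()]).
#'
#' @slot presence logical matrix, receptors in rows, cell lines in columns.
#' @slot thresholds numeric vector of per-line presence thresholds used to
#'   derive the design from fluorescence (NA when supplied directly).
#' @seealso [ReceptorDesign()], [deriveReceptorProfile()]
#' @export
setClass("ReceptorDesign",
    representation(presence = "matrix", thresholds = "numeric"))

.validReceptorDesign <- function(object) {
    msg <- character()
    p <- object@presence
    if (!is.logical(p))
        msg <- c(msg, "presence must be a logical matrix")
    if (nrow(p) < 1L || ncol(p) < 1L)
        msg <- c(msg, "design needs at least one receptor and one cell line")
    if (is.null(rownames(p)) || is.null(colnames(p)) ||
        anyDuplicated(rownames(p)) || anyDuplicated(colnames(p)))
        msg <- c(msg, "receptor and cell-line names must be unique and set")
    if (any(is.na(p)))
        msg <- c(msg, "presence entries must be TRUE/FALSE (binary)")
    if (length(msg)) msg else TRUE
}
setValidity("ReceptorDesign", .validReceptorDesign)

#' Fold changes and regulation calls per probe set and cell line
#'
#' Stores the treated/control fold-change matrix together with the
#' categorical regulation calls (\code{"up"}, \code{"down"},
#' \code{"unchanged"}) made at strict thresholds: up when
#' fold > \code{upThreshold}, down when fold < \code{downThreshold},
#' boundary values are unchanged.
#'
#' @slot fold numeric matrix, probe sets x cell lines, strictly positive.
#' @slot call character matrix of the same shape.
#' @slot upThreshold,downThreshold numeric scalars.
#' @slot excluded character vector of probe sets dropped from calling
#'   because of missing values.
#' @seealso [callRegulation()], [computeFoldChanges()]
#' @export
setClass("ResponseCalls",
    representation(fold = "matrix", call = "matrix",
                   upThreshold = "numeric", downThreshold = "numeric",
                   excluded = "character"))

.validResponseCalls <- function(object) {
    msg <- character()
    if (!identical(dim(object@fold), dim(object@call)))
        msg <- c(msg, "fold and call matrices must have identical shape")
    if (any(object@fold <= 0, na.rm = TRUE))
        msg <- c(msg, "fold changes must be strictly positive")
    if (!all(object@call %in% c("up", "down", "unchanged")))
        msg <- c(msg, "calls must be 'up', 'down' or 'unchanged'")
    if (!(object@downThreshold < 1 && 1 < object@upThreshold))
        msg <- c(msg, "thresholds must satisfy down < 1 < up")
    f <- object@fold
    up <- !is.na(f) & f > object@upThreshold
    dn <- !is.na(f) & f < object@downThreshold
    if (any(up != (object@call == "up")) || any(dn != (object@call == "down")))
        msg <- c(msg, "calls inconsistent with thresholds")
    if (length(msg)) msg else TRUE
}
setValidity("ResponseCalls", .validResponseCalls)

#' Result of attributing up-regulated genes to one receptor
#'
#' Holds the probe sets whose response pattern across cell lines matches a
#' receptor's presence pattern (responding in every receptor-positive line,
#' not responding in any receptor-negative line), and, after
#' [collapseToGenes()], the distinct gene symbols they annotate to.
#'
#' @slot receptor single receptor name.
#' @slot positiveLines,negativeLines cell lines used on each side of the rule.
#' @slot probeSets attributed probe-set identifiers.
#' @slot genes distinct gene symbols (empty until gene-level collapse).
#' @slot nUnannotated number of attributed probe sets without a gene symbol
#'   (NA until collapse).
#' @slot level \code{"probe_set"} or \code{"gene"}.
#' @slot direction \code{"up"} or \code{"down"} (mirror analysis).
#' @export
setClass("AttributionResult",
    representation(receptor = "character", positiveLines = "character",
                   negativeLines = "character", probeSets = "character",
                   genes = "character", nUnannotated = "integer",
                   level = "character", direction = "character"))

.validAttributionResult <- function(object) {
    msg <- character()
    if (length(object@receptor) != 1L)
        msg <- c(msg, "exactly one receptor")
    if (!object@level %in% c("probe_set", "gene"))
        msg <- c(msg, "level must be 'probe_set' or 'gene'")
    if (!object@direction %in% c("up", "down"))
        msg <- c(msg, "direction must be 'up' or 'down'")
    if (length(object@genes) > length(object@probeSets))
        msg <- c(msg, "gene set cannot exceed probe-set count")
    if (length(msg)) msg else TRUE
}
setValidity("AttributionResult", .validAttributionResult)

#' Planted ground truth of a simulated attribution dataset
#'
#' @slot receptorGenes named list: receptor -> planted gene symbols.
#' @slot geneProbeSets named list: gene symbol -> probe-set identifiers.
#' @slot annotation named character vector: probe set -> gene symbol.
#' @export
setClass("PlantedTruth",
    representation(receptorGenes = "list", geneProbeSets = "list",
                   annotation = "character"))

.validPlantedTruth <- function(object) {
    msg <- character()
    g <- unlist(object@receptorGenes, use.names = FALSE)
    if (anyDuplicated(g))
        msg <- c(msg, "planted gene sets must be disjoint across receptors")
    if (!all(g %in% names(object@geneProbeSets)))
        msg <- c(msg, "every planted gene must map to >= 1 probe set")
    if (length(msg)) msg else TRUE
}
setValidity("PlantedTruth", .validPlantedTruth)
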