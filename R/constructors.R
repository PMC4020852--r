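#' Construct a ResponseExperiment
#'
#' @param fluorescence numeric matrix, probe sets x arrays; rownames are
#'   probe-set identifiers.
#' @param cellLine,condition,replicate per-column (per-array) labels;
#'   \code{condition} must be \code{"control"} or \code{"treated"}.
#' @param scale \code{"linear"} (default) or \code{"log2"}; controls how
#'   fold changes are computed downstream.
#' @return a validated [ResponseExperiment-class] object.
#' @examples
#' m <- matrix(c(100, 150, 110, 160), nrow = 1,
#'             dimnames = list("ps1", NULL))
#' re <- ResponseExperiment(m, cellLine = rep("PC3", 4),
#'                          condition = c("control", "treated",
#'                                        "control", "treated"),
#'                          replicate = c(1, 1, 2, 2))
#' @export
ResponseExperiment <- function(fluorescence, cellLine, condition, replicate,
                               scale = c("linear", "log2")) {
    scale <- match.arg(scale)
    fluorescence <- as.matrix(fluorescence)
    cd <- DataFrame(cellLine = as.character(cellLine),
                    condition = as.character(condition),
                    replicate = as.integer(replicate))
    colnames(fluorescence) <-
        paste(cd$cellLine, cd$condition, cd$replicate, sep = "|")
    se <- SummarizedExperiment(
        assays = list(fluorescence = fluorescence),
        colData = cd,
        metadata = list(scale = scale))
    new("ResponseExperiment", se)
}

#' Construct a ReceptorDesign
#'
#' @param presence logical (or 0/1) matrix, receptors in rows, cell lines in
#'   columns, TRUE where the receptor is expressed in that line.
#' @param thresholds optional per-line numeric thresholds recorded when the
#'   design was derived from fluorescence.
#' @return a validated [ReceptorDesign-class] object.
#' @examples
#' ReceptorDesign(rbind(LPA1 = c(TRUE, TRUE, FALSE),
#'                      LPA2 = c(TRUE, TRUE, TRUE)),
#'                cellLines = c("PC3", "MDA-MB-231", "MCF-7"))
#' @param cellLines,receptors optional dimension names when \code{presence}
#'   lacks them.
#' @export
ReceptorDesign <- function(presence, receptors = rownames(presence),
                           cellLines = colnames(presence),
                           thresholds = NULL) {
    presence <- as.matrix(presence)
    if (!is.logical(presence)) {
        if (!all(presence %in% c(0, 1)))
            stop("presence entries must be binary (TRUE/FALSE or 0/1)")
        presence <- presence == 1
    }
    rownames(presence) <- receptors
    colnames(presence) <- cellLines
    if (is.null(thresholds))
        thresholds <- rep(NA_real_, ncol(presence))
    new("ReceptorDesign", presence = presence,
        thresholds = as.numeric(thresholds))
}

#' The three-line, four-receptor design used throughout the examples
#'
#' PC3 expresses LPA1, LPA2, LPA3 and LPA6; MDA-MB-231 expresses LPA1 and
#' LPA2; MCF-7 expresses LPA2 and LPA6.  Under this design only LPA1 and
#' LPA6 are identifiable: LPA1 responses must appear in PC3 and MDA-MB-231
#' (two unrelated cancers, excluding cell-type-specific genes) and not in
#' MCF-7.
#'
#' @return a [ReceptorDesign-class]
#' @examples
#' checkIdentifiability(exampleDesign())
#' @export
exampleDesign <- function() {
    ReceptorDesign(rbind(
        LPA1 = c(TRUE,  TRUE,  FALSE),
        LPA2 = c(TRUE,  TRUE,  TRUE),
        LPA3 = c(TRUE,  FALSE, FALSE),
        LPA6 = c(TRUE,  FALSE, TRUE)),
        cellLines = c("PC3", "MDA-MB-231", "MCF-7"))
}
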