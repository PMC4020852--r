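## Receptor attribution by boolean set logic across cell lines: a probe set
## is credited to a receptor when it is up-regulated in every line that
## expresses the receptor and not up-regulated in any line that lacks it.

#' Derive a receptor presence/absence design from receptor fluorescence
#'
#' Thresholds the fluorescence of the probe sets interrogating each
#' receptor: a receptor is called present in a line when its value strictly
#' exceeds the line's presence threshold.  The threshold can be given as an
#' absolute fluorescence (scalar or one per line) or derived from a
#' background distribution: when \code{background} is supplied, the
#' per-line threshold defaults to \code{backgroundMultiple} times the
#' line's \code{backgroundQuantile} fluorescence quantile (3x the 10th
#' percentile by default).  Thresholds are recorded in the design for
#' auditability.
#'
#' @param receptorFluorescence numeric matrix, receptors x cell lines
#'   (replicate-mean fluorescence); no missing values allowed.
#' @param presenceThreshold absolute threshold(s); overrides
#'   \code{background}.
#' @param background optional probe-fluorescence matrix (probes x the same
#'   cell lines) from which per-line thresholds are derived.
#' @param backgroundMultiple,backgroundQuantile knobs of the derived
#'   threshold.
#' @return a [ReceptorDesign-class] with thresholds recorded.
#' @export
deriveReceptorProfile <- function(receptorFluorescence,
                                  presenceThreshold = NULL,
                                  background = NULL,
                                  backgroundMultiple = 3,
                                  backgroundQuantile = 0.10) {
    m <- as.matrix(receptorFluorescence)
    if (any(is.na(m)))
        stop("missing receptor probe value(s): ",
             paste(rownames(m)[rowSums(is.na(m)) > 0], collapse = ", "))
    if (is.null(presenceThreshold)) {
        if (is.null(background))
            stop("supply presenceThreshold or a background distribution")
        background <- as.matrix(background)
        stopifnot(identical(colnames(background), colnames(m)))
        presenceThreshold <- backgroundMultiple *
            apply(background, 2L, stats::quantile,
                  probs = backgroundQuantile, names = FALSE)
    }
    thr <- rep_len(as.numeric(presenceThreshold), ncol(m))
    presence <- sweep(m, 2L, thr, `>`)
    ReceptorDesign(presence, thresholds = thr)
}

#' Check which receptors a design can attribute genes to
#'
#' A receptor is identifiable when it has at least \code{minPositive}
#' positive lines (default 2 — requiring the response in two unrelated
#' lines excludes cell-type-specific genes), at least \code{minNegative}
#' negative lines (default 1 — without a negative line nothing
#' distinguishes the receptor's responses from ubiquitous ones), and a
#' presence pattern unique among the receptors (two receptors with
#' identical patterns are mutually confounded).
#'
#' @param design a [ReceptorDesign-class].
#' @param minPositive,minNegative line-count requirements.
#' @return a \code{data.frame} with columns \code{receptor},
#'   \code{nPositive}, \code{nNegative} and \code{status} (one of
#'   \code{"identifiable"}, \code{"no_negative_line"},
#'   \code{"insufficient_positive_lines"},
#'   \code{"confounded_with:<receptor>"}).
#' @examples
#' checkIdentifiability(exampleDesign())
#' @export
checkIdentifiability <- function(design, minPositive = 2L,
                                 minNegative = 1L) {
    stopifnot(is(design, "ReceptorDesign"))
    p <- presenceMatrix(design)
    pat <- apply(p, 1L, paste, collapse = ",")
    status <- character(nrow(p))
    for (i in seq_len(nrow(p))) {
        nPos <- sum(p[i, ])
        nNeg <- sum(!p[i, ])
        twin <- setdiff(rownames(p)[pat == pat[i]], rownames(p)[i])
        status[i] <- if (nNeg < minNegative) "no_negative_line"
        else if (nPos < minPositive) "insufficient_positive_lines"
        else if (length(twin))
            paste0("confounded_with:", paste(twin, collapse = ","))
        else "identifiable"
    }
    data.frame(receptor = rownames(p),
               nPositive = as.integer(rowSums(p)),
               nNegative = as.integer(rowSums(!p)),
               status = status, row.names = NULL, stringsAsFactors = FALSE)
}

#' Attribute regulated probe sets to one receptor
#'
#' Probe-set level set logic: a probe set is attributed to the receptor
#' when its call is \code{"up"} in every receptor-positive line and not
#' \code{"up"} in every receptor-negative line (\code{negativeMode =
#' "not_up"}, the default — a probe set that is down-regulated in a
#' negative line still counts as "not responding"; \code{"strict"} requires
#' \code{"unchanged"} there).  \code{direction = "down"} runs the mirror
#' analysis on down calls.  Attribution for a receptor the design cannot
#' identify (see [checkIdentifiability()]) is refused unless
#' \code{force = TRUE}, which proceeds with a warning.
#'
#' @param calls a [ResponseCalls-class].
#' @param design a [ReceptorDesign-class]; its cell lines must all be
#'   present in \code{calls}.
#' @param receptor receptor name to attribute to.
#' @param negativeMode \code{"not_up"} or \code{"strict"}.
#' @param direction \code{"up"} (default) or \code{"down"}.
#' @param force proceed despite a non-identifiable receptor.
#' @param minPositive,minNegative forwarded to [checkIdentifiability()].
#' @return an [AttributionResult-class] at probe-set level.
#' @export
attributeReceptor <- function(calls, design, receptor,
                              negativeMode = c("not_up", "strict"),
                              direction = c("up", "down"),
                              force = FALSE, minPositive = 2L,
                              minNegative = 1L) {
    stopifnot(is(calls, "ResponseCalls"), is(design, "ReceptorDesign"))
    negativeMode <- match.arg(negativeMode)
    direction <- match.arg(direction)
    .checkReceptor(design, receptor)
    rep <- checkIdentifiability(design, minPositive, minNegative)
    st <- rep$status[rep$receptor == receptor]
    if (st != "identifiable") {
        if (!force)
            stop("receptor '", receptor, "' is not identifiable (",
                 st, "); use force = TRUE to attribute anyway")
        warning("attributing to non-identifiable receptor '", receptor,
                "' (", st, ")")
    }
    cl <- regulationCalls(calls)
    pos <- positiveLines(design, receptor)
    neg <- negativeLines(design, receptor)
    missingLines <- setdiff(c(pos, neg), colnames(cl))
    if (length(missingLines))
        stop("calls lack cell line(s): ",
             paste(missingLines, collapse = ", "))
    hitPos <- rowSums(cl[, pos, drop = FALSE] == direction) == length(pos)
    offNeg <- if (negativeMode == "not_up")
        rowSums(cl[, neg, drop = FALSE] != direction) == length(neg)
    else
        rowSums(cl[, neg, drop = FALSE] == "unchanged") == length(neg)
    probeSets <- rownames(cl)[hitPos & offNeg]
    new("AttributionResult", receptor = receptor, positiveLines = pos,
        negativeLines = neg, probeSets = probeSets, genes = character(),
        nUnannotated = NA_integer_, level = "probe_set",
        direction = direction)
}

#' Collapse an attribution to distinct gene symbols
#'
#' Maps attributed probe sets through the annotation and keeps the distinct
#' gene symbols.  Probe sets without an annotation are counted in
#' \code{nUnannotated}, never silently dropped.
#'
#' @param result a probe-set-level [AttributionResult-class].
#' @param annotation named character vector (probe set -> gene), as from
#'   [readAnnotation()] or [truthAnnotation()].
#' @return the [AttributionResult-class] at gene level.
#' @examples
#' ann <- c(ps1 = "HBEGF", ps2 = "HBEGF", ps3 = "IL6")
#' @export
collapseToGenes <- function(result, annotation) {
    stopifnot(is(result, "AttributionResult"))
    ps <- attributedProbeSets(result)
    gene <- annotation[ps]
    annotated <- !is.na(gene) & nzchar(gene)
    result@genes <- unique(unname(gene[annotated]))
    result@nUnannotated <- sum(!annotated)
    result@level <- "gene"
    validObject(result)
    result
}

#' Run the full attribution pipeline on an experiment
#'
#' Convenience composition: replicate aggregation, fold changes, regulation
#' calls, identifiability check, attribution and (when an annotation is
#' given) gene-level collapse.
#'
#' @param exp a [ResponseExperiment-class].
#' @param design a [ReceptorDesign-class].
#' @param receptor receptor to attribute to.
#' @param annotation optional probe-set -> gene map.
#' @param upThreshold,downThreshold,floor forwarded to the component steps.
#' @param ... forwarded to [attributeReceptor()].
#' @return list with \code{calls} (a [ResponseCalls-class]), \code{counts}
#'   (per-line regulation counts), \code{identifiability} and
#'   \code{attribution} (an [AttributionResult-class]).
#' @export
runAttribution <- function(exp, design, receptor, annotation = NULL,
                           upThreshold = 1.3, downThreshold = 1 / 1.3,
                           floor = 1, ...) {
    agg <- aggregateReplicates(exp)
    folds <- computeFoldChanges(agg, floor = floor)
    calls <- callRegulation(folds, upThreshold = upThreshold,
                            downThreshold = downThreshold)
    res <- attributeReceptor(calls, design, receptor, ...)
    if (!is.null(annotation))
        res <- collapseToGenes(res, annotation)
    list(calls = calls, counts = countRegulated(calls)$counts,
         identifiability = checkIdentifiability(design),
         attribution = res)
}
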