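## Differential response by fold-change thresholding: replicate
## aggregation, treated/control fold changes with a background floor, and
## up/down calls at a strict threshold (default > 1.3-fold for "up",
## reciprocal for "down").

#' Average replicate arrays per probe set, cell line and condition
#'
#' Arithmetic mean over replicate arrays; a single replicate passes through
#' unchanged.  Missing values propagate (\code{NA} mean), so probe sets with
#' any missing replicate in a required condition are excluded later by
#' [computeFoldChanges()] rather than silently dropped here.
#'
#' @param exp a [ResponseExperiment-class].
#' @return list with matrices \code{control} and \code{treated} (probe sets
#'   x cell lines) plus the experiment's \code{scale}.
#' @examples
#' m <- matrix(c(100, 200, 300, 330), nrow = 1,
#'             dimnames = list("ps1", NULL))
#' re <- ResponseExperiment(m, cellLine = rep("PC3", 4),
#'                          condition = rep(c("control", "treated"), each = 2),
#'                          replicate = c(1, 2, 1, 2))
#' aggregateReplicates(re)$control     # 150
#' @export
aggregateReplicates <- function(exp) {
    stopifnot(is(exp, "ResponseExperiment"))
    cd <- colData(exp)
    m <- assay(exp, "fluorescence")
    lines <- cellLines(exp)
    agg <- function(cond) {
        out <- matrix(NA_real_, nrow = nrow(m), ncol = length(lines),
                      dimnames = list(rownames(m), lines))
        for (ln in lines) {
            j <- which(cd$cellLine == ln & cd$condition == cond)
            if (!length(j))
                stop("no replicates for (", ln, ", ", cond, ")")
            out[, ln] <- rowMeans(m[, j, drop = FALSE], na.rm = FALSE)
        }
        out
    }
    list(control = agg("control"), treated = agg("treated"),
         scale = expressionScale(exp))
}

#' Treated/control fold changes with a background floor
#'
#' On the linear scale, \code{fold = max(treated, floor) / max(control,
#' floor)}: the floor (a small positive fluorescence, default 1 unit)
#' prevents division by zero on background-level probes and damps ratios
#' driven by values below the detection floor; floored probe sets are
#' reported.  On the log2 scale, \code{fold = 2^(treated - control)} and no
#' floor applies.  Probe sets with a missing mean in either condition are
#' excluded from the result and listed, never silently dropped.
#'
#' @param aggregated output of [aggregateReplicates()].
#' @param floor fluorescence floor (linear scale only; > 0).
#' @return list with \code{fold} (probe sets x lines matrix),
#'   \code{excluded} (probe sets with missing values), \code{floored}
#'   (probe sets where the floor engaged) and \code{scale}.
#' @export
computeFoldChanges <- function(aggregated, floor = 1) {
    ctl <- aggregated$control
    trt <- aggregated$treated
    scale <- if (is.null(aggregated$scale)) "linear" else aggregated$scale
    stopifnot(identical(dim(ctl), dim(trt)))
    bad <- is.na(ctl) | is.na(trt)
    excluded <- rownames(ctl)[rowSums(bad) > 0]
    keep <- !(rownames(ctl) %in% excluded)
    ctl <- ctl[keep, , drop = FALSE]
    trt <- trt[keep, , drop = FALSE]
    if (scale == "log2") {
        fold <- 2^(trt - ctl)
        floored <- character()
    } else {
        if (any(ctl < 0) || any(trt < 0))
            stop("negative mean fluorescence on the linear scale")
        if (floor <= 0) stop("floor must be strictly positive")
        flooredMask <- ctl < floor | trt < floor
        floored <- rownames(ctl)[rowSums(flooredMask) > 0]
        fold <- pmax(trt, floor) / pmax(ctl, floor)
    }
    list(fold = fold, excluded = excluded, floored = floored, scale = scale)
}

#' Call up/down/unchanged regulation at strict fold-change thresholds
#'
#' A probe set is called up-regulated in a line when its fold change there
#' strictly exceeds \code{upThreshold} (default 1.3), down-regulated when
#' strictly below \code{downThreshold} (default the log-symmetric
#' reciprocal 1/1.3), otherwise unchanged; a fold of exactly 1.3 is
#' unchanged.
#'
#' @param folds output of [computeFoldChanges()] (or a bare positive
#'   matrix).
#' @param upThreshold,downThreshold strict thresholds; must satisfy
#'   \code{downThreshold < 1 < upThreshold}.
#' @return a [ResponseCalls-class].
#' @examples
#' f <- matrix(c(1.31, 1.30, 0.5), ncol = 1,
#'             dimnames = list(c("a", "b", "c"), "PC3"))
#' regulationCalls(callRegulation(f))   # up, unchanged, down
#' @export
callRegulation <- function(folds, upThreshold = 1.3,
                           downThreshold = 1 / 1.3) {
    if (is.list(folds)) {
        fold <- folds$fold
        excluded <- folds$excluded
    } else {
        fold <- folds
        excluded <- character()
    }
    if (!(downThreshold < 1 && 1 < upThreshold))
        stop("thresholds must satisfy downThreshold < 1 < upThreshold")
    if (any(fold <= 0, na.rm = TRUE))
        stop("fold changes must be strictly positive")
    call <- matrix("unchanged", nrow = nrow(fold), ncol = ncol(fold),
                   dimnames = dimnames(fold))
    call[fold > upThreshold] <- "up"
    call[fold < downThreshold] <- "down"
    new("ResponseCalls", fold = fold, call = call,
        upThreshold = upThreshold, downThreshold = downThreshold,
        excluded = as.character(excluded))
}

#' Count regulated probe sets per cell line
#'
#' @param calls a [ResponseCalls-class].
#' @return list with \code{counts} (data.frame: cellLine, nUp, nDown,
#'   nUnchanged) and the per-line identifier lists \code{up} and
#'   \code{down}.
#' @export
countRegulated <- function(calls) {
    stopifnot(is(calls, "ResponseCalls"))
    cl <- regulationCalls(calls)
    lines <- colnames(cl)
    up <- lapply(lines, function(ln) rownames(cl)[cl[, ln] == "up"])
    down <- lapply(lines, function(ln) rownames(cl)[cl[, ln] == "down"])
    names(up) <- names(down) <- lines
    counts <- data.frame(
        cellLine = lines,
        nUp = vapply(up, length, integer(1)),
        nDown = vapply(down, length, integer(1)),
        nUnchanged = vapply(lines, function(ln) sum(cl[, ln] == "unchanged"),
                            integer(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    list(counts = counts, up = up, down = down)
}
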