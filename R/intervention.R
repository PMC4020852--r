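## Xenograft-arm computations: caliper tumor volume, percent decrease of a
## treated group mean relative to vehicle, and the unpaired two-sided
## t-test.

#' Tumor volume from caliper length and width
#'
#' \code{TV = L * W^2 / 2} (mm^3), the standard ellipsoid approximation for
#' subcutaneous xenografts measured with a Vernier caliper.  Convention: L
#' is the longer axis; a width exceeding the length is computed normally
#' but warned about.
#'
#' @param L,W length and width in mm (vectorized; >= 0).
#' @return volume(s) in mm^3.
#' @examples
#' tumorVolume(10, 5)   # 125
#' @export
tumorVolume <- function(L, W) {
    if (any(L < 0) || any(W < 0))
        stop("length and width must be non-negative")
    if (any(W > L))
        warning("width exceeds length for some tumors; ",
                "convention is L = longer axis")
    L * W^2 / 2
}

#' Percent decrease of a treated mean relative to the vehicle mean
#'
#' \code{100 * (meanVehicle - meanTreated) / meanVehicle}; negative when
#' the treated mean exceeds the vehicle mean.  Display rounding to the
#' nearest integer is left to the caller; full precision is returned.
#'
#' @param meanTreated,meanVehicle group means; \code{meanVehicle} must be
#'   strictly positive.
#' @return percent decrease (full precision).
#' @examples
#' percentDecrease(25.35, 44.93)   # ~ 43.6, i.e. "44%"
#' @export
percentDecrease <- function(meanTreated, meanVehicle) {
    if (any(meanVehicle <= 0))
        stop("meanVehicle must be strictly positive")
    100 * (meanVehicle - meanTreated) / meanVehicle
}

#' Unpaired two-sided t-test
#'
#' Classical pooled-variance Student t-test on \code{length(a) +
#' length(b) - 2} degrees of freedom (via [stats::t.test()] with
#' \code{var.equal = TRUE}); \code{welch = TRUE} switches to the Welch
#' variant.  Degenerate data (zero variance in both groups) cannot be
#' tested by t: equal means return t = 0, p = 1 by convention, unequal
#' means t = +-Inf with the smallest representable p; both are flagged.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch (unequal-variance) variant.
#' @return list with \code{t}, \code{df}, \code{p.value}, \code{method}
#'   and \code{degenerate} flag.
#' @examples
#' unpairedTTest(c(1, 2, 3), c(101, 102, 103))$p.value
#' @export
unpairedTTest <- function(a, b, welch = FALSE) {
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 observations")
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b)) {
            warning("zero variance and equal means; p = 1 by convention")
            return(list(t = 0, df = length(a) + length(b) - 2L,
                        p.value = 1, method = "Student", degenerate = TRUE))
        }
        warning("zero variance with unequal means; t is infinite")
        return(list(t = sign(mean(a) - mean(b)) * Inf,
                    df = length(a) + length(b) - 2L,
                    p.value = .Machine$double.xmin,
                    method = if (welch) "Welch" else "Student",
                    degenerate = TRUE))
    }
    ht <- stats::t.test(a, b, var.equal = !welch)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p.value = ht$p.value,
         method = if (welch) "Welch" else "Student", degenerate = FALSE)
}

#' Summarize a two-group intervention experiment
#'
#' Per-group n, mean, SD and SEM; percent decrease of the treated group
#' mean relative to vehicle; unpaired two-sided t-test on the raw values.
#'
#' @param table \code{data.frame} with columns \code{group} (levels
#'   \code{"vehicle"}, \code{"treated"}) and \code{measurement}, as from
#'   [simulateIntervention()] or [readInterventionTable()].
#' @param welch forwarded to [unpairedTTest()].
#' @return list with \code{groups} (summary data.frame),
#'   \code{percentDecrease}, \code{t}, \code{df}, \code{p.value} and
#'   \code{method}.
#' @examples
#' tab <- simulateIntervention(8, 44.93, 25.35, cv = 0.25, seed = 2)
#' runInterventionAnalysis(tab)$percentDecrease
#' @export
runInterventionAnalysis <- function(table, welch = FALSE) {
    stopifnot(all(c("group", "measurement") %in% colnames(table)))
    lev <- c("vehicle", "treated")
    miss <- setdiff(lev, unique(table$group))
    if (length(miss))
        stop("missing group(s): ", paste(miss, collapse = ", "))
    g <- split(table$measurement, factor(table$group, levels = lev))
    groups <- data.frame(
        group = lev,
        n = vapply(g, length, integer(1)),
        mean = vapply(g, mean, numeric(1)),
        sd = vapply(g, stats::sd, numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    groups$sem <- groups$sd / sqrt(groups$n)
    pd <- percentDecrease(groups$mean[groups$group == "treated"],
                          groups$mean[groups$group == "vehicle"])
    tt <- unpairedTTest(g$vehicle, g$treated, welch = welch)
    list(groups = groups, percentDecrease = pd, t = tt$t, df = tt$df,
         p.value = tt$p.value, method = tt$method)
}
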