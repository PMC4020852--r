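## Clinical-arm statistics: housekeeping normalization, equal-frequency
## quartile stratification, Kruskal-Wallis with Dunn's post-test, Spearman
## correlation with exact small-sample p-values.

#' Normalize target expression to a housekeeping gene
#'
#' Elementwise ratio target/housekeeping, the standard relative
#' quantification of RT-qPCR measurements against a stably expressed
#' reference gene.
#'
#' @param target,housekeeping numeric vectors of equal length; housekeeping
#'   values must be strictly positive.
#' @param sampleIDs optional names used in error messages.
#' @return numeric vector of normalized values.
#' @examples
#' normalizeToHousekeeping(c(10, 6), c(5, 3))
#' @export
normalizeToHousekeeping <- function(target, housekeeping,
                                    sampleIDs = names(target)) {
    if (length(target) != length(housekeeping))
        stop("target and housekeeping must have the same length")
    bad <- which(!(housekeeping > 0))
    if (length(bad)) {
        lab <- if (!is.null(sampleIDs)) sampleIDs[bad] else bad
        stop("non-positive housekeeping value for sample(s): ",
             paste(lab, collapse = ", "))
    }
    target / housekeeping
}

#' Stratify samples into equal-frequency groups by rank
#'
#' Rank-based split into \code{k} groups of (as near as possible) equal
#' size: with \code{n = kq + r}, the \code{r} extra samples go to the
#' lowest-labeled groups, so sizes never differ by more than 1.  Q1 holds
#' the lowest values, Qk the highest.  Ties are broken by stable input
#' order; when a tied value spans a group boundary a warning is emitted.
#'
#' @param values numeric vector (n >= k).
#' @param k number of groups (default 4, quartiles).
#' @param sampleIDs optional sample identifiers.
#' @return list with \code{labels} (factor Q1..Qk in input order),
#'   \code{sizes} (named integer vector) and \code{boundaries} (upper value
#'   of each group).
#' @examples
#' quartileStratify(c(5, 1, 9, 3, 7, 2, 8, 4))$sizes
#' @export
quartileStratify <- function(values, k = 4L, sampleIDs = NULL) {
    n <- length(values)
    if (n < k) stop("need at least k = ", k, " samples, got ", n)
    if (anyNA(values)) stop("values must not contain NA")
    q <- n %/% k
    r <- n %% k
    sizes <- q + as.integer(seq_len(k) <= r)
    lab <- paste0("Q", seq_len(k))
    ord <- order(values)  # radix sort: stable for ties
    grp <- rep.int(lab, times = sizes)
    labels <- factor(character(n), levels = lab)
    labels[ord] <- grp
    bounds <- tapply(values[ord], grp, max)[lab]
    for (i in seq_len(k - 1L)) {
        lastOfGroup <- values[ord][cumsum(sizes)[i]]
        firstOfNext <- values[ord][cumsum(sizes)[i] + 1L]
        if (lastOfGroup == firstOfNext) {
            warning("tied value ", lastOfGroup, " spans the ", lab[i], "/",
                    lab[i + 1L], " boundary; split by stable input order")
            break
        }
    }
    if (!is.null(sampleIDs)) names(labels) <- sampleIDs
    list(labels = labels, sizes = stats::setNames(sizes, lab),
         boundaries = bounds)
}

#' Kruskal-Wallis omnibus test with Dunn's post-test
#'
#' The omnibus H statistic (tie-corrected, via [stats::kruskal.test()])
#' tests whether any group's distribution is shifted; Dunn's pairwise z
#' statistics compare mean ranks of the pooled sample,
#' \deqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{\left(\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)},}
#' with the tie term computed over the pooled ranks.  Two-sided normal
#' p-values are adjusted across all k(k-1)/2 pairs (Bonferroni by
#' default, matching common statistics-software behaviour).
#'
#' @param groups list of numeric vectors (>= 2 groups, each non-empty,
#'   >= 3 values in total).
#' @param adjust multiplicity adjustment passed to [stats::p.adjust()].
#' @return list with \code{H}, \code{p.value} (omnibus), \code{pairwise}
#'   (data.frame: group1, group2, z, p, p.adj), \code{adjust} and
#'   \code{method}.
#' @examples
#' kruskalWallisDunn(list(Q1 = c(1, 2, 3), Q4 = c(10, 11, 12)))
#' @export
kruskalWallisDunn <- function(groups, adjust = "bonferroni") {
    if (length(groups) < 2L) stop("need at least two groups")
    sizes <- lengths(groups)
    if (any(sizes == 0L))
        stop("group(s) of size zero: ",
             paste(names(groups)[sizes == 0L], collapse = ", "))
    x <- unlist(groups, use.names = FALSE)
    if (length(x) < 3L) stop("need at least three observations in total")
    if (is.null(names(groups)))
        names(groups) <- paste0("G", seq_along(groups))
    g <- factor(rep(names(groups), sizes), levels = names(groups))

    allEqual <- length(unique(x)) == 1L
    if (allEqual) {
        H <- 0; pOmni <- 1
    } else {
        kw <- stats::kruskal.test(x, g)
        H <- unname(kw$statistic)
        pOmni <- kw$p.value
    }

    r <- rank(x)
    N <- length(x)
    Rbar <- tapply(r, g, mean)
    tt <- table(r)
    tieSum <- sum(tt^3 - tt)
    varTerm <- N * (N + 1) / 12 - tieSum / (12 * (N - 1))
    pair <- utils::combn(names(groups), 2L)
    z <- p <- numeric(ncol(pair))
    for (j in seq_len(ncol(pair))) {
        i1 <- pair[1L, j]; i2 <- pair[2L, j]
        se <- sqrt(varTerm * (1 / sizes[[i1]] + 1 / sizes[[i2]]))
        z[j] <- if (se == 0) 0 else (Rbar[[i1]] - Rbar[[i2]]) / se
        p[j] <- 2 * stats::pnorm(-abs(z[j]))
    }
    pairwise <- data.frame(group1 = pair[1L, ], group2 = pair[2L, ],
                           z = z, p = p,
                           p.adj = pmin(stats::p.adjust(p, method = adjust),
                                        1),
                           stringsAsFactors = FALSE)
    list(H = H, p.value = pOmni, pairwise = pairwise, adjust = adjust,
         method = "Kruskal-Wallis with Dunn's post-test")
}

# all permutations of 1..n as an n! x n integer matrix (n <= 10 intended)
.permutations <- function(n) {
    p <- matrix(1L, 1L, 1L)
    if (n == 1L) return(p)
    for (k in 2L:n) {
        np <- nrow(p)
        out <- matrix(0L, np * k, k)
        for (i in seq_len(k)) {
            rows <- ((i - 1L) * np + 1L):(i * np)
            adj <- p
            adj[adj >= i] <- adj[adj >= i] + 1L
            out[rows, 1L] <- i
            out[rows, -1L] <- adj
        }
        p <- out
    }
    p
}

#' Spearman rank correlation with exact or t-approximate p-value
#'
#' Tie-corrected Spearman rho (Pearson correlation of the rank vectors).
#' For \code{n} at most \code{exactNMax} the two-sided p-value is exact:
#' the fraction of all \code{n!} rank permutations with \code{|rho|} at
#' least the observed value.  For larger n the usual t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom is
#' used.
#'
#' @param x,y numeric vectors of equal length, n >= 3, no NAs; neither may
#'   be constant (rho undefined).
#' @param exactNMax largest n for exact enumeration (default 9).
#' @return list with \code{rho}, \code{n}, \code{p.value} and
#'   \code{method} (\code{"exact-permutation"} or
#'   \code{"t-approximation"}).
#' @examples
#' spearmanCorrelation(1:5, c(2, 1, 4, 3, 5))
#' @export
spearmanCorrelation <- function(x, y, exactNMax = 9L) {
    n <- length(x)
    if (length(y) != n) stop("x and y must have the same length")
    if (n < 3L) stop("need at least 3 observations")
    if (anyNA(x) || anyNA(y)) stop("missing values are not allowed")
    if (length(unique(x)) == 1L || length(unique(y)) == 1L)
        stop("rho is undefined for a constant vector")
    rx <- rank(x); ry <- rank(y)
    rho <- stats::cor(rx, ry)
    if (n <= exactNMax) {
        perms <- .permutations(n)
        rxs <- (rx - mean(rx)) / stats::sd(rx)
        rys <- (ry - mean(ry)) / stats::sd(ry)
        rhoAll <- (matrix(rys[perms], nrow = nrow(perms)) %*% rxs) / (n - 1)
        p <- mean(abs(rhoAll) >= abs(rho) - 1e-12)
        method <- "exact-permutation"
    } else {
        tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
        p <- 2 * stats::pt(-abs(tstat), df = n - 2)
        p <- min(max(p, .Machine$double.xmin), 1)
        method <- "t-approximation"
    }
    list(rho = rho, n = n, p.value = p, method = method)
}

#' Validate a biomarker pair on a patient cohort
#'
#' Composition of the clinical-arm statistics: stratify the cohort into
#' quartiles of marker A, compare marker B across the quartiles
#' (Kruskal-Wallis omnibus plus Dunn's post-test, reported both against the
#' top quartile and for all pairs), summarize marker B per quartile (n,
#' mean, SD, median), and correlate the two markers (Spearman).  A linear
#' fit (slope/intercept, no test) is included for plotting convenience.
#'
#' When the table lacks \code{marker_A}/\code{marker_B} columns but has
#' \code{raw_A}/\code{raw_B} and \code{housekeeping}, markers are first
#' normalized to the housekeeping gene.
#'
#' @param cohort \code{data.frame} as from [simulateCohort()] or
#'   [readCohortTable()].
#' @param markerA,markerB column names of the two markers.
#' @param k number of strata (default 4).
#' @param adjust multiplicity adjustment for Dunn's test.
#' @return list with \code{quartiles}, \code{perQuartile},
#'   \code{comparison} (full Dunn output), \code{vsTop} (each lower
#'   quartile against the top one) and \code{correlation}; plus
#'   \code{linearFit}.
#' @examples
#' rep <- runCohortValidation(simulateCohort(60, 0.5, seed = 3))
#' rep$correlation$rho
#' @export
runCohortValidation <- function(cohort, markerA = "marker_A",
                                markerB = "marker_B", k = 4L,
                                adjust = "bonferroni") {
    if (!markerA %in% colnames(cohort) || !markerB %in% colnames(cohort)) {
        need <- c("raw_A", "raw_B", "housekeeping")
        if (all(need %in% colnames(cohort))) {
            cohort[[markerA]] <- normalizeToHousekeeping(
                cohort$raw_A, cohort$housekeeping, cohort$sample_id)
            cohort[[markerB]] <- normalizeToHousekeeping(
                cohort$raw_B, cohort$housekeeping, cohort$sample_id)
        } else {
            stop("cohort lacks marker columns '", markerA, "'/'", markerB,
                 "' and raw_A/raw_B/housekeeping to derive them")
        }
    }
    a <- cohort[[markerA]]
    b <- cohort[[markerB]]
    strat <- quartileStratify(a, k = k, sampleIDs = cohort$sample_id)
    groups <- split(b, strat$labels)
    perQuartile <- data.frame(
        quartile = names(groups),
        n = vapply(groups, length, integer(1)),
        mean = vapply(groups, mean, numeric(1)),
        sd = vapply(groups, stats::sd, numeric(1)),
        median = vapply(groups, stats::median, numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE)
    comparison <- kruskalWallisDunn(groups, adjust = adjust)
    top <- paste0("Q", k)
    pw <- comparison$pairwise
    vsTop <- pw[pw$group1 == top | pw$group2 == top, , drop = FALSE]
    correlation <- spearmanCorrelation(a, b)
    fit <- stats::lm(b ~ a)
    list(quartiles = strat, perQuartile = perQuartile,
         comparison = comparison, vsTop = vsTop,
         correlation = correlation,
         linearFit = c(intercept = unname(stats::coef(fit)[1]),
                       slope = unname(stats::coef(fit)[2])))
}
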