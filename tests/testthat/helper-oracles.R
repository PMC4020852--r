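# Independent oracles and small fixture builders used across the suite.
# These deliberately re-derive results by brute force, without touching the
# package's own code paths.

# build a ResponseCalls object straight from a fold matrix
callsFromFolds <- function(fold, up = 1.3, down = 1 / 1.3) {
    callRegulation(fold, upThreshold = up, downThreshold = down)
}

# all permutations of seq_len(n), one per list element (recursive, naive)
oraclePermutations <- function(n) {
    if (n == 1L) return(list(1L))
    out <- list()
    for (sub in oraclePermutations(n - 1L)) {
        for (pos in seq_len(n)) {
            out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
        }
    }
    out
}

# exact two-sided Spearman p by full enumeration, via stats::cor only
oracleSpearmanExactP <- function(x, y) {
    n <- length(x)
    rx <- rank(x); ry <- rank(y)
    obs <- abs(cor(rx, ry))
    hits <- vapply(oraclePermutations(n),
                   function(p) abs(cor(rx, ry[p])) >= obs - 1e-12,
                   logical(1))
    mean(hits)
}

# Monte-Carlo permutation p for the Kruskal-Wallis H statistic
oracleKWPermutationP <- function(groups, nPerm = 1e4, seed = 99) {
    x <- unlist(groups, use.names = FALSE)
    g <- rep(seq_along(groups), lengths(groups))
    hstat <- function(xx) {
        unname(suppressWarnings(kruskal.test(xx, g))$statistic)
    }
    obs <- hstat(x)
    set.seed(seed)
    perm <- replicate(nPerm, hstat(sample(x)))
    mean(perm >= obs - 1e-12)
}

# Monte-Carlo permutation p for the two-sample mean difference
oracleTPermutationP <- function(a, b, nPerm = 1e5, seed = 17) {
    x <- c(a, b)
    na <- length(a)
    obs <- abs(mean(a) - mean(b))
    set.seed(seed)
    hits <- replicate(nPerm, {
        idx <- sample(length(x), na)
        abs(mean(x[idx]) - mean(x[-idx])) >= obs - 1e-12
    })
    mean(hits)
}

# truth-table attribution: probe attributed iff up in all positive lines
# and not up in any negative line
oracleAttribute <- function(upFlags, posLines, negLines) {
    all(upFlags[posLines]) && !any(upFlags[negLines])
}

# identifiability rules re-applied literally
oracleIdentifiability <- function(presence, minPositive = 2, minNegative = 1) {
    pat <- apply(presence, 1L, paste, collapse = ",")
    vapply(rownames(presence), function(r) {
        nPos <- sum(presence[r, ]); nNeg <- sum(!presence[r, ])
        twin <- setdiff(rownames(presence)[pat == pat[r]], r)
        if (nNeg < minNegative) "no_negative_line"
        else if (nPos < minPositive) "insufficient_positive_lines"
        else if (length(twin)) paste0("confounded_with:",
                                      paste(twin, collapse = ","))
        else "identifiable"
    }, character(1))
}

# tiny deterministic experiment: one line, given replicate values
miniExperiment <- function(control, treated, line = "PC3",
                           probes = sprintf("ps%d", seq_len(nrow(control)))) {
    m <- cbind(control, treated)
    rownames(m) <- probes
    ResponseExperiment(
        m,
        cellLine = rep(line, ncol(m)),
        condition = rep(c("control", "treated"),
                        c(ncol(control), ncol(treated))),
        replicate = c(seq_len(ncol(control)), seq_len(ncol(treated))))
}

# a hand-written GEO Series Matrix fixture (synthetic, 2 lines x 2
# conditions, 1 replicate, 3 probes); returns path
writeSeriesMatrixFixture <- function(path, log2scale = FALSE,
                                     dropEnd = FALSE) {
    vals <- rbind(ps1 = c(100, 200, 100, 100),
                  ps2 = c(50, 50, 80, 120),
                  ps3 = c(10, 10, 10, 10))
    if (log2scale) vals <- log2(vals)
    titles <- c("A_ctl", "A_trt", "B_ctl", "B_trt")
    ln <- c(
        "!Series_title\t\"synthetic ligand response fixture\"",
        if (log2scale)
            "!Sample_data_processing\t\"log2 transformed signal\"\t\"log2 transformed signal\"\t\"log2 transformed signal\"\t\"log2 transformed signal\""
        else
            "!Sample_data_processing\t\"linear signal\"\t\"linear signal\"\t\"linear signal\"\t\"linear signal\"",
        paste0("!Sample_title\t",
               paste(sprintf('"%s"', titles), collapse = "\t")),
        "!series_matrix_table_begin",
        paste(c("\"ID_REF\"", sprintf('"GSM%d"', 1:4)), collapse = "\t"),
        vapply(rownames(vals), function(p)
            paste(c(sprintf('"%s"', p), format(vals[p, ], digits = 12)),
                  collapse = "\t"), character(1)),
        if (!dropEnd) "!series_matrix_table_end")
    writeLines(ln, path)
    path
}

seriesMatrixSampleMap <- function() {
    data.frame(title = c("A_ctl", "A_trt", "B_ctl", "B_trt"),
               cellLine = c("A", "A", "B", "B"),
               condition = c("control", "treated", "control", "treated"),
               replicate = 1L, stringsAsFactors = FALSE)
}
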