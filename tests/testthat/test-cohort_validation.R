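# Housekeeping normalization, quartile stratification, KW + Dunn, Spearman.

test_that("housekeeping normalization is the elementwise ratio", {
    expect_equal(normalizeToHousekeeping(10, 5), 2)
    v <- c(3.2, 5.5, 8)
    expect_equal(normalizeToHousekeeping(v, v), rep(1, 3))
    expect_error(
        normalizeToHousekeeping(c(1, 2), c(1, 0),
                                sampleIDs = c("s1", "s2")),
        "s2")
})

test_that("quartile sizes follow the remainder rule", {
    s <- quartileStratify(rnorm(234))
    expect_equal(unname(s$sizes), c(59L, 59L, 58L, 58L))
    s8 <- quartileStratify(c(5, 1, 9, 3, 7, 2, 8, 4))
    expect_equal(unname(s8$sizes), rep(2L, 4))
    expect_identical(as.character(s8$labels),
                     c("Q3", "Q1", "Q4", "Q2", "Q3", "Q1", "Q4", "Q2"))
    # Q1 lowest, Q4 highest
    x <- rnorm(41)
    s41 <- quartileStratify(x)
    expect_equal(unname(s41$sizes), c(11L, 10L, 10L, 10L))
    expect_lt(max(x[s41$labels == "Q1"]), min(x[s41$labels == "Q4"]))
    expect_error(quartileStratify(1:3, k = 4), "at least")
})

test_that("group sizes never differ by more than one for any n", {
    for (n in 4:60) {
        s <- quartileStratify(rnorm(n))
        expect_lte(diff(range(s$sizes)), 1L)
        expect_equal(sum(s$sizes), n)
    }
})

test_that("tied values split by stable order with a warning", {
    expect_warning(s <- quartileStratify(rep(1, 8)), "spans")
    expect_equal(unname(s$sizes), rep(2L, 4))
    expect_identical(as.character(s$labels),
                     c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3", "Q4", "Q4"))
})

test_that("all-tied groups give H = 0 and omnibus p = 1", {
    res <- kruskalWallisDunn(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
    expect_equal(res$H, 0)
    expect_equal(res$p.value, 1)
    expect_true(all(res$pairwise$p.adj == 1))
    expect_error(kruskalWallisDunn(list(a = 1:3)), "two groups")
    expect_error(kruskalWallisDunn(list(a = 1:3, b = numeric())), "zero")
})

test_that("omnibus p agrees with a permutation oracle", {
    set.seed(5)
    groups <- list(a = rnorm(4), b = rnorm(4), c = rnorm(4) + 2.2)
    res <- kruskalWallisDunn(groups)
    pPerm <- oracleKWPermutationP(groups, nPerm = 1e4)
    # chi-square approximation vs exact permutation: Monte-Carlo + approx slack
    expect_lt(abs(res$p.value - pPerm), 0.02)
    # and a clearly null configuration
    set.seed(6)
    groups0 <- list(a = rnorm(6), b = rnorm(6), c = rnorm(6))
    res0 <- kruskalWallisDunn(groups0)
    p0 <- oracleKWPermutationP(groups0, nPerm = 1e4)
    expect_lt(abs(res0$p.value - p0), 0.05)
})

test_that("two-group Dunn z matches the Wilcoxon normal approximation", {
    set.seed(9)
    a <- rnorm(7); b <- rnorm(9) + 0.8
    res <- kruskalWallisDunn(list(a = a, b = b))
    # normal approximation of the rank-sum test, tie-corrected, no
    # continuity correction (independent derivation)
    x <- c(a, b); r <- rank(x); N <- length(x)
    W <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
    mu <- length(a) * length(b) / 2
    tt <- table(r)
    sig2 <- length(a) * length(b) / 12 *
        (N + 1 - sum(tt^3 - tt) / (N * (N - 1)))
    zW <- (W - mu) / sqrt(sig2)
    pW <- 2 * pnorm(-abs(zW))
    expect_equal(abs(res$pairwise$z), abs(zW), tolerance = 1e-10)
    expect_equal(res$pairwise$p, pW, tolerance = 1e-10)
})

test_that("Spearman rho and exact p match enumeration", {
    expect_equal(spearmanCorrelation(1:6, (1:6)^3)$rho, 1)
    expect_equal(spearmanCorrelation(1:6, -(1:6))$rho, -1)
    set.seed(12)
    for (i in 1:5) {
        x <- rnorm(5); y <- rnorm(5)
        res <- spearmanCorrelation(x, y)
        expect_identical(res$method, "exact-permutation")
        expect_equal(res$p.value, oracleSpearmanExactP(x, y))
        expect_equal(res$rho, cor(x, y, method = "spearman"))
    }
    # ties handled through the rank-based rho
    x <- c(1, 2, 2, 3, 4, 5, 6)
    y <- c(2, 1, 3, 3, 5, 6, 7)
    expect_equal(spearmanCorrelation(x, y)$rho,
                 cor(x, y, method = "spearman"))
    expect_error(spearmanCorrelation(rep(1, 5), rnorm(5)), "constant")
    expect_error(spearmanCorrelation(1:4, 1:5), "length")
})

test_that("large-sample Spearman p uses the t approximation", {
    set.seed(13)
    x <- rnorm(40); y <- x + rnorm(40)
    res <- spearmanCorrelation(x, y)
    expect_identical(res$method, "t-approximation")
    rho <- cor(x, y, method = "spearman")
    tstat <- rho * sqrt((40 - 2) / (1 - rho^2))
    expect_equal(res$p.value, 2 * pt(-abs(tstat), 38))
})

test_that("Spearman type-I error is calibrated under independence", {
    hits <- vapply(1:1000, function(s) {
        co <- simulateCohort(50, rhoTarget = 0, seed = 10000 + s)
        spearmanCorrelation(co$marker_A, co$marker_B)$p.value < 0.05
    }, logical(1))
    # binomial 3-sigma band around 0.05 at 1000 draws: +- 0.021
    expect_lt(abs(mean(hits) - 0.05), 0.025)
})

test_that("module outputs are rank-invariant to monotone transforms", {
    co <- simulateCohort(101, rhoTarget = 0.4, seed = 8)
    a <- co$marker_A; b <- co$marker_B
    s1 <- quartileStratify(a)
    s2 <- quartileStratify(exp(a))
    expect_identical(s1$labels, s2$labels)
    g1 <- split(b, s1$labels); g2 <- split(log(b), s2$labels)
    k1 <- kruskalWallisDunn(g1); k2 <- kruskalWallisDunn(g2)
    expect_equal(k1$H, k2$H)
    expect_equal(k1$pairwise$z, k2$pairwise$z)
    expect_equal(spearmanCorrelation(a, b)$rho,
                 spearmanCorrelation(exp(a), log(b))$rho)
})

test_that("cohort validation orders quartile means under dependence", {
    for (s in c(1, 2, 3)) {
        co <- simulateCohort(234, rhoTarget = 0.25, seed = s)
        rep <- runCohortValidation(co)
        pq <- rep$perQuartile
        expect_gt(pq$mean[pq$quartile == "Q4"],
                  pq$mean[pq$quartile == "Q1"])
        expect_equal(nrow(pq), 4L)
        expect_equal(nrow(rep$vsTop), 3L)
    }
})

test_that("null cohorts rarely flag Q1 vs Q4 after adjustment", {
    hits <- vapply(1:100, function(s) {
        co <- simulateCohort(234, rhoTarget = 0, seed = 500 + s)
        rep <- runCohortValidation(co)
        pw <- rep$comparison$pairwise
        row <- pw$group1 == "Q1" & pw$group2 == "Q4" |
            pw$group1 == "Q4" & pw$group2 == "Q1"
        pw$p.adj[row] <= 0.05
    }, logical(1))
    expect_gte(mean(!hits), 0.90)
})

test_that("strong dependence is detected in every seed", {
    ps <- vapply(1:100, function(s) {
        co <- simulateCohort(234, rhoTarget = 0.9, seed = 900 + s)
        runCohortValidation(co)$comparison$p.value
    }, numeric(1))
    expect_true(all(ps < 0.001))
})

test_that("cohort validation normalizes raw columns when needed", {
    co <- simulateCohort(60, rhoTarget = 0.5, seed = 44)
    raw <- co[, c("sample_id", "raw_A", "raw_B", "housekeeping")]
    rep <- runCohortValidation(raw)
    full <- runCohortValidation(co)
    expect_equal(rep$correlation$rho, full$correlation$rho)
    expect_error(runCohortValidation(co[, "sample_id", drop = FALSE]),
                 "lacks marker")
})
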