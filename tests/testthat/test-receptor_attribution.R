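# Receptor profiles, identifiability rules, boolean attribution and
# gene-level collapse.

test_that("receptor profiles derive from fluorescence thresholding", {
    fl <- rbind(LPA1 = c(500, 400, 10),
                LPA2 = c(600, 500, 700),
                LPA3 = c(300, 20, 15),
                LPA6 = c(450, 30, 350))
    colnames(fl) <- c("PC3", "MDA-MB-231", "MCF-7")
    d <- deriveReceptorProfile(fl, presenceThreshold = 100)
    expect_identical(presenceMatrix(d), presenceMatrix(exampleDesign()))
    expect_equal(d@thresholds, rep(100, 3))
    # threshold 0 with positive values: everything present
    dAll <- deriveReceptorProfile(fl, presenceThreshold = 0)
    expect_true(all(presenceMatrix(dAll)))
    # all values below threshold: empty design, nothing identifiable
    dNone <- deriveReceptorProfile(fl, presenceThreshold = 1e6)
    expect_false(any(presenceMatrix(dNone)))
    expect_true(all(checkIdentifiability(dNone)$status != "identifiable"))
    fl[1, 2] <- NA
    expect_error(deriveReceptorProfile(fl, presenceThreshold = 100),
                 "missing.*LPA1")
})

test_that("background-derived thresholds are 3x the 10th percentile", {
    set.seed(1)
    bg <- matrix(runif(600, 0, 100), 200, 3,
                 dimnames = list(NULL, c("PC3", "MDA-MB-231", "MCF-7")))
    fl <- rbind(LPA1 = c(500, 400, 10))
    colnames(fl) <- colnames(bg)
    d <- deriveReceptorProfile(fl, background = bg)
    expect_equal(d@thresholds,
                 unname(3 * apply(bg, 2, quantile, 0.10)))
})

test_that("identifiability statuses match the brute-force rules", {
    rep <- checkIdentifiability(exampleDesign())
    expect_identical(rep$status[match(c("LPA1", "LPA2", "LPA3", "LPA6"),
                                      rep$receptor)],
                     c("identifiable", "no_negative_line",
                       "insufficient_positive_lines", "identifiable"))
    expect_equal(rep$nPositive[rep$receptor == "LPA1"], 2L)
    expect_equal(rep$nNegative[rep$receptor == "LPA1"], 1L)
    # random designs agree with an independent literal application
    set.seed(21)
    for (i in 1:20) {
        p <- matrix(sample(c(TRUE, FALSE), 12, replace = TRUE), 4, 3,
                    dimnames = list(paste0("R", 1:4), paste0("L", 1:3)))
        d <- ReceptorDesign(p)
        got <- checkIdentifiability(d)
        expect_identical(got$status, unname(oracleIdentifiability(p)))
    }
})

test_that("identical presence patterns are mutually confounded", {
    p <- rbind(R1 = c(TRUE, TRUE, FALSE), R2 = c(TRUE, TRUE, FALSE))
    colnames(p) <- paste0("L", 1:3)
    rep <- checkIdentifiability(ReceptorDesign(p))
    expect_identical(rep$status, c("confounded_with:R2",
                                   "confounded_with:R1"))
})

test_that("a single cell line identifies no receptor", {
    p <- matrix(c(TRUE, FALSE), 2, 1,
                dimnames = list(c("R1", "R2"), "L1"))
    rep <- checkIdentifiability(ReceptorDesign(p))
    expect_true(all(rep$status != "identifiable"))
})

test_that("attribution matches the truth table over all response patterns", {
    design <- exampleDesign()
    lines <- cellLines(design)
    pats <- expand.grid(PC3 = c(TRUE, FALSE), `MDA-MB-231` = c(TRUE, FALSE),
                        `MCF-7` = c(TRUE, FALSE))
    fold <- matrix(1, nrow(pats), 3,
                   dimnames = list(sprintf("pat%d", seq_len(nrow(pats))),
                                   lines))
    for (i in seq_len(nrow(pats)))
        fold[i, ] <- ifelse(unlist(pats[i, ]), 2, 1)
    calls <- callRegulation(fold)
    res <- attributeReceptor(calls, design, "LPA1")
    for (i in seq_len(nrow(pats))) {
        want <- oracleAttribute(setNames(unlist(pats[i, ]), lines),
                                posLines = c("PC3", "MDA-MB-231"),
                                negLines = "MCF-7")
        expect_identical(rownames(fold)[i] %in% attributedProbeSets(res),
                         want)
    }
    # spot checks from the truth table
    up2not1 <- which(pats$PC3 & pats$`MDA-MB-231` & !pats$`MCF-7`)
    expect_identical(attributedProbeSets(res), rownames(fold)[up2not1])
    upAll <- which(pats$PC3 & pats$`MDA-MB-231` & pats$`MCF-7`)
    expect_false(any(rownames(fold)[upAll] %in% attributedProbeSets(res)))
})

test_that("negative-line handling distinguishes not-up from strict modes", {
    fold <- matrix(c(2, 2, 0.5), 1, 3,
                   dimnames = list("ps1", cellLines(exampleDesign())))
    calls <- callRegulation(fold)
    notUp <- attributeReceptor(calls, exampleDesign(), "LPA1")
    expect_identical(attributedProbeSets(notUp), "ps1")
    strict <- attributeReceptor(calls, exampleDesign(), "LPA1",
                                negativeMode = "strict")
    expect_length(attributedProbeSets(strict), 0)
})

test_that("non-identifiable receptors are refused without force", {
    fold <- matrix(2, 2, 3, dimnames = list(c("a", "b"),
                                            cellLines(exampleDesign())))
    calls <- callRegulation(fold)
    expect_error(attributeReceptor(calls, exampleDesign(), "LPA2"),
                 "no_negative_line")
    expect_error(attributeReceptor(calls, exampleDesign(), "LPA3"),
                 "insufficient_positive_lines")
    expect_warning(res <- attributeReceptor(calls, exampleDesign(), "LPA2",
                                            force = TRUE),
                   "non-identifiable")
    expect_length(attributedProbeSets(res), 2)
    expect_error(attributeReceptor(calls, exampleDesign(), "LPA9"),
                 "not in the design")
})

test_that("raising the up-threshold shrinks the positive-line hits", {
    # the set of probes up-called in every receptor-positive line can only
    # shrink as the threshold rises; full attribution is monotone whenever
    # the negative lines stay quiet (the planted-simulation regime), but
    # not for arbitrary data, where raising the threshold can also silence
    # an up call in a negative line and admit a probe
    set.seed(33)
    fold <- matrix(exp(rnorm(300, sd = 0.5)), 100, 3,
                   dimnames = list(sprintf("p%03d", 1:100),
                                   cellLines(exampleDesign())))
    pos <- positiveLines(exampleDesign(), "LPA1")
    prev <- NULL
    for (thr in c(1.1, 1.3, 1.6, 2.0)) {
        cl <- regulationCalls(callRegulation(fold, upThreshold = thr))
        hits <- rownames(fold)[
            rowSums(cl[, pos, drop = FALSE] == "up") == length(pos)]
        if (!is.null(prev)) expect_true(all(hits %in% prev))
        prev <- hits
    }
    # quiet negative lines (single-receptor design, so no decoy genes are
    # ever up in MCF-7): attribution itself is monotone
    soloDesign <- ReceptorDesign(
        rbind(LPA1 = c(TRUE, TRUE, FALSE)),
        cellLines = c("PC3", "MDA-MB-231", "MCF-7"))
    cfg <- SimulationConfig(soloDesign, nGenes = 100,
                            nPlantedPerReceptor = 10, effectSize = 2,
                            noiseCV = 0.05, seed = 3)
    sim <- simulateAttributionDataset(cfg)
    foldsSim <- computeFoldChanges(aggregateReplicates(sim$experiment))
    prev <- NULL
    for (thr in c(1.3, 1.6, 1.9, 2.5)) {
        got <- attributedProbeSets(attributeReceptor(
            callRegulation(foldsSim, upThreshold = thr),
            soloDesign, "LPA1"))
        if (!is.null(prev)) expect_true(all(got %in% prev))
        prev <- got
    }
})

test_that("attribution is invariant to cell-line ordering", {
    set.seed(34)
    lines <- cellLines(exampleDesign())
    fold <- matrix(exp(rnorm(150, sd = 0.5)), 50, 3,
                   dimnames = list(sprintf("p%02d", 1:50), lines))
    base <- attributedProbeSets(
        attributeReceptor(callRegulation(fold), exampleDesign(), "LPA1"))
    perm <- c(3, 1, 2)
    foldP <- fold[, perm]
    designP <- ReceptorDesign(presenceMatrix(exampleDesign())[, perm])
    got <- attributedProbeSets(
        attributeReceptor(callRegulation(foldP), designP, "LPA1"))
    expect_setequal(got, base)
})

test_that("gene collapse keeps distinct symbols and counts unannotated", {
    res <- new("AttributionResult", receptor = "LPA1",
               positiveLines = c("PC3", "MDA-MB-231"),
               negativeLines = "MCF-7",
               probeSets = c("ps1", "ps2", "ps3"), genes = character(),
               nUnannotated = NA_integer_, level = "probe_set",
               direction = "up")
    ann <- c(ps1 = "HBEGF", ps2 = "HBEGF", ps3 = "IL6")
    g <- collapseToGenes(res, ann)
    expect_setequal(attributedGenes(g), c("HBEGF", "IL6"))
    expect_equal(g@nUnannotated, 0L)
    gNone <- collapseToGenes(res, c(zz = "X"))
    expect_length(attributedGenes(gNone), 0)
    expect_equal(gNone@nUnannotated, 3L)
})

test_that("planted signatures are recovered from noisy simulations", {
    design <- exampleDesign()
    for (seed in c(101, 202)) {
        cfg <- SimulationConfig(design, nGenes = 1000,
                                nPlantedPerReceptor = 50, effectSize = 2,
                                noiseCV = 0.05, seed = seed)
        sim <- simulateAttributionDataset(cfg)
        for (r in c("LPA1", "LPA6")) {
            res <- runAttribution(sim$experiment, design, r,
                                  annotation = truthAnnotation(sim$truth))
            got <- attributedGenes(res$attribution)
            planted <- plantedGenes(sim$truth, r)
            sens <- mean(planted %in% got)
            fdp <- if (length(got)) mean(!got %in% planted) else 0
            expect_gte(sens, 0.95)
            expect_lte(fdp, 0.02)
        }
        # mutual exclusivity of LPA1 and LPA6 attributions
        a1 <- runAttribution(sim$experiment, design, "LPA1")$attribution
        a6 <- runAttribution(sim$experiment, design, "LPA6")$attribution
        expect_length(intersect(attributedProbeSets(a1),
                                attributedProbeSets(a6)), 0)
    }
})

test_that("down-regulation mirror analysis uses the same logic", {
    fold <- matrix(c(0.5, 0.5, 1.0,
                     0.5, 0.5, 0.5), 2, 3, byrow = TRUE,
                   dimnames = list(c("a", "b"),
                                   cellLines(exampleDesign())))
    calls <- callRegulation(fold)
    res <- attributeReceptor(calls, exampleDesign(), "LPA1",
                             direction = "down")
    expect_identical(attributedProbeSets(res), "a")
})
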