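## Synthetic-data generators.  Every pipeline input can be produced here
## with planted ground truth, so the whole analysis is testable offline.

# run expr with a private RNG stream; the caller's .Random.seed is untouched
.withSeed <- function(seed, expr) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
    expr
}

# lognormal multiplier with mean 1 and coefficient of variation cv
.noiseFactor <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    s <- sqrt(log1p(cv^2))
    exp(stats::rnorm(n, mean = -s^2 / 2, sd = s))
}

# lognormal draws with a prescribed arithmetic mean and cv
.rlnormMeanCV <- function(n, mean, cv) {
    if (cv == 0) return(rep(mean, n))
    s <- sqrt(log1p(cv^2))
    exp(stats::rnorm(n, mean = log(mean) - s^2 / 2, sd = s))
}

#' Configuration of a simulated ligand-response experiment
#'
#' Bundles the knobs of [simulateAttributionDataset()]: the receptor design,
#' the number of genes on the simulated array, how many response genes are
#' planted per receptor, the multiplicative effect applied to planted genes
#' in receptor-positive lines under treatment, the coefficient of variation
#' of the multiplicative (lognormal) measurement noise, the number of
#' duplicate probe sets interrogating each gene, replicate arrays per
#' condition, and the baseline fluorescence level.
#'
#' @param design a [ReceptorDesign-class].
#' @param nGenes genes on the array (default 1000).
#' @param nPlantedPerReceptor response genes planted for each receptor in the
#'   design; sets are disjoint (default 50).
#' @param effectSize multiplicative fold applied to a planted gene in every
#'   positive line of its receptor, treated condition only (> 0; default 2).
#' @param noiseCV coefficient of variation of the lognormal noise on each
#'   measurement (>= 0; default 0.05).
#' @param nDuplicateProbesets distinct probe sets per gene, each an
#'   independent noisy readout of the same gene-level signal (default 2).
#' @param nReplicates replicate arrays per (line, condition) (default 2).
#' @param baselineMean control-condition fluorescence level (> 0;
#'   default 100).
#' @param nContextSpecific genes up-regulated under treatment in a single
#'   random line irrespective of any receptor, exercising the
#'   minimum-positive-lines guard (default 0).
#' @param seed integer seed; the whole simulation is deterministic given it.
#' @return a \code{SimulationConfig} object.
#' @export
SimulationConfig <- function(design, nGenes = 1000L,
                             nPlantedPerReceptor = 50L,
                             effectSize = 2, noiseCV = 0.05,
                             nDuplicateProbesets = 2L, nReplicates = 2L,
                             baselineMean = 100, nContextSpecific = 0L,
                             seed = 1L) {
    stopifnot(is(design, "ReceptorDesign"))
    if (effectSize <= 0) stop("effectSize must be strictly positive")
    if (baselineMean <= 0) stop("baselineMean must be strictly positive")
    if (noiseCV < 0) stop("noiseCV must be >= 0")
    if (nDuplicateProbesets < 1) stop("nDuplicateProbesets must be >= 1")
    if (nReplicates < 1) stop("nReplicates must be >= 1")
    nPlanted <- nPlantedPerReceptor * length(receptors(design))
    if (nPlanted + nContextSpecific > nGenes)
        stop("cannot plant ", nPlanted, " receptor genes plus ",
             nContextSpecific, " context-specific genes in ", nGenes,
             " genes")
    structure(list(design = design, nGenes = as.integer(nGenes),
                   nPlantedPerReceptor = as.integer(nPlantedPerReceptor),
                   effectSize = effectSize, noiseCV = noiseCV,
                   nDuplicateProbesets = as.integer(nDuplicateProbesets),
                   nReplicates = as.integer(nReplicates),
                   baselineMean = baselineMean,
                   nContextSpecific = as.integer(nContextSpecific),
                   seed = as.integer(seed)),
              class = "SimulationConfig")
}

#' Simulate a ligand-response experiment with planted receptor signatures
#'
#' Generates control and treated fluorescence for every cell line of the
#' design.  Control values are \code{baselineMean} times independent
#' lognormal noise.  For a gene planted for receptor R, treated values in
#' every R-positive line carry an additional \code{effectSize} multiplier;
#' everywhere else the treated multiplier is 1, so unplanted genes have unit
#' fold change in expectation.  Duplicate probe sets are independent noisy
#' readouts of the same gene-level signal and map to the same gene symbol in
#' the returned annotation.
#'
#' @param config a [SimulationConfig()].
#' @return a list with elements \code{experiment}
#'   (a [ResponseExperiment-class]) and \code{truth}
#'   (a [PlantedTruth-class] recording receptor -> planted genes,
#'   gene -> probe sets, and the probe-set annotation map).
#' @examples
#' cfg <- SimulationConfig(exampleDesign(), nGenes = 50,
#'                         nPlantedPerReceptor = 2, noiseCV = 0, seed = 7)
#' sim <- simulateAttributionDataset(cfg)
#' sim$truth
#' @export
simulateAttributionDataset <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    design <- config$design
    lines <- cellLines(design)
    recs <- receptors(design)

    genes <- sprintf("GENE%04d", seq_len(config$nGenes))
    receptorGenes <- list()
    idx <- 0L
    for (r in recs) {
        receptorGenes[[r]] <- genes[idx + seq_len(config$nPlantedPerReceptor)]
        idx <- idx + config$nPlantedPerReceptor
    }
    contextGenes <- if (config$nContextSpecific > 0)
        genes[idx + seq_len(config$nContextSpecific)] else character()

    nDup <- config$nDuplicateProbesets
    probeSets <- sprintf("%s_s%d_at", rep(genes, each = nDup),
                         rep(seq_len(nDup), times = config$nGenes))
    annotation <- stats::setNames(rep(genes, each = nDup), probeSets)
    geneProbeSets <- split(probeSets, rep(genes, each = nDup))[genes]

    # gene x line matrix of treated-condition multipliers
    effect <- matrix(1, nrow = config$nGenes, ncol = length(lines),
                     dimnames = list(genes, lines))
    for (r in recs) {
        pos <- positiveLines(design, r)
        effect[receptorGenes[[r]], pos] <- config$effectSize
    }

    out <- .withSeed(config$seed, {
        for (g in contextGenes)
            effect[g, sample(length(lines), 1L)] <- config$effectSize
        nRep <- config$nReplicates
        cols <- expand.grid(replicate = seq_len(nRep),
                            condition = c("control", "treated"),
                            cellLine = lines, stringsAsFactors = FALSE)
        nP <- length(probeSets)
        m <- matrix(NA_real_, nrow = nP, ncol = nrow(cols),
                    dimnames = list(probeSets, NULL))
        for (j in seq_len(nrow(cols))) {
            mult <- if (cols$condition[j] == "treated")
                effect[, cols$cellLine[j]] else rep(1, config$nGenes)
            m[, j] <- config$baselineMean * rep(mult, each = nDup) *
                .noiseFactor(nP, config$noiseCV)
        }
        list(m = m, cols = cols)
    })

    experiment <- ResponseExperiment(out$m,
                                     cellLine = out$cols$cellLine,
                                     condition = out$cols$condition,
                                     replicate = out$cols$replicate)
    metadata(experiment)$seed <- config$seed
    truth <- new("PlantedTruth", receptorGenes = receptorGenes,
                 geneProbeSets = geneProbeSets, annotation = annotation)
    list(experiment = experiment, truth = truth)
}

#' Simulate a patient cohort with two correlated biomarkers
#'
#' Draws two marker columns from a Gaussian copula with lognormal marginals.
#' The copula's Pearson parameter is chosen as
#' \eqn{\rho_P = 2 \sin(\pi \rho_S / 6)} so that the population Spearman
#' correlation equals \code{rhoTarget}.  A positive housekeeping column and
#' raw (un-normalized) marker columns are included so the housekeeping
#' normalization step can be exercised end to end: raw = marker x
#' housekeeping, and dividing by housekeeping recovers the marker.
#'
#' @param n number of samples (>= 3).
#' @param rhoTarget target population Spearman correlation in [-1, 1].
#' @param marginalMeans,marginalCVs length-2 arithmetic means and
#'   coefficients of variation of the two (normalized) marker marginals.
#' @param housekeepingMean,housekeepingCV marginal of the housekeeping gene.
#' @param seed integer seed.
#' @return a \code{data.frame} with columns \code{sample_id},
#'   \code{marker_A}, \code{marker_B} (normalized expression),
#'   \code{raw_A}, \code{raw_B} and \code{housekeeping}, with the seed in
#'   \code{attr(-, "seed")}.
#' @examples
#' cohort <- simulateCohort(234, rhoTarget = 0.25, seed = 42)
#' cor(cohort$marker_A, cohort$marker_B, method = "spearman")
#' @export
simulateCohort <- function(n, rhoTarget, marginalMeans = c(1, 1),
                           marginalCVs = c(0.6, 0.6),
                           housekeepingMean = 100, housekeepingCV = 0.2,
                           seed = 1L) {
    if (n < 3) stop("n must be >= 3")
    if (abs(rhoTarget) > 1) stop("rhoTarget must be in [-1, 1]")
    rhoP <- 2 * sin(pi * rhoTarget / 6)
    qmarg <- function(z, mean, cv) {
        s <- sqrt(log1p(cv^2))
        exp(log(mean) - s^2 / 2 + s * z)
    }
    .withSeed(seed, {
        z1 <- stats::rnorm(n)
        z2 <- rhoP * z1 + sqrt(1 - rhoP^2) * stats::rnorm(n)
        hk <- .rlnormMeanCV(n, housekeepingMean, housekeepingCV)
        a <- qmarg(z1, marginalMeans[1], marginalCVs[1])
        b <- qmarg(z2, marginalMeans[2], marginalCVs[2])
        out <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                          marker_A = a, marker_B = b,
                          raw_A = a * hk, raw_B = b * hk,
                          housekeeping = hk,
                          stringsAsFactors = FALSE)
        attr(out, "seed") <- as.integer(seed)
        out
    })
}

#' Simulate a two-group intervention experiment
#'
#' Two labeled groups (\code{"vehicle"}, \code{"treated"}) of lognormal
#' measurements with the stated arithmetic means and a common coefficient of
#' variation, emulating e.g. serum biomarker concentrations in drug-treated
#' versus vehicle-treated tumor-bearing animals.
#'
#' @param nPerGroup animals per group (>= 1; default 8).
#' @param meanControl,meanTreated group arithmetic means (> 0).
#' @param cv coefficient of variation shared by both groups (>= 0).
#' @param seed integer seed.
#' @return a \code{data.frame} with columns \code{animal_id}, \code{group}
#'   and \code{measurement}, seed recorded in \code{attr(-, "seed")}.
#' @examples
#' simulateIntervention(4, meanControl = 44.93, meanTreated = 25.35,
#'                      cv = 0, seed = 1)
#' @export
simulateIntervention <- function(nPerGroup = 8L, meanControl, meanTreated,
                                 cv = 0.25, seed = 1L) {
    if (nPerGroup < 1) stop("nPerGroup must be >= 1")
    if (meanControl <= 0 || meanTreated <= 0)
        stop("group means must be strictly positive")
    if (cv < 0) stop("cv must be >= 0")
    .withSeed(seed, {
        veh <- .rlnormMeanCV(nPerGroup, meanControl, cv)
        trt <- .rlnormMeanCV(nPerGroup, meanTreated, cv)
        out <- data.frame(
            animal_id = sprintf("A%02d", seq_len(2L * nPerGroup)),
            group = rep(c("vehicle", "treated"), each = nPerGroup),
            measurement = c(veh, trt), stringsAsFactors = FALSE)
        attr(out, "seed") <- as.integer(seed)
        out
    })
}
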