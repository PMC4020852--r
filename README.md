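# receptorSig

Receptor-specific gene-signature discovery from ligand-response
expression profiles, with the downstream statistics used to qualify a
signature gene as a biomarker of receptor activity.

## The problem

A signaling lipid like lysophosphatidic acid (LPA) acts through six
G-protein-coupled receptors (LPA₁–LPA₆), and tumor cell lines express
overlapping subsets of them, so a ligand-responsive gene cannot by itself
be credited to one receptor. `receptorSig` implements a cross-cell-line
boolean attribution: given a panel of lines with known receptor
presence/absence patterns, a gene is attributed to receptor R when it is
up-regulated by the ligand (fold change strictly > 1.3,
treated/control) in **every** R-positive line and in **no** R-negative
line. With positive lines drawn from unrelated cancers, the intersection
removes cell-type-specific responses; the negative line removes
ubiquitous ones. Formally, for probe set *g* with regulation call
`up(g, l)` in line *l*:

    g ∈ Sig(R)  ⇔  (∀ l ∈ P(R): up(g, l))  ∧  (∀ l ∈ N(R): ¬up(g, l))

where P(R), N(R) are the receptor-positive and -negative lines. The
package also implements the validation arms around such a signature:
quartile stratification of a patient cohort by one marker with
Kruskal–Wallis/Dunn comparison of a second marker across quartiles,
Spearman correlation (exact permutation p for small n, t-approximation
otherwise), and two-group intervention analysis (percent decrease of a
treated group mean versus vehicle, pooled or Welch t-test, caliper tumor
volume L·W²/2).

All inputs can be generated by the built-in simulators with planted
ground truth, so every stage is testable offline; a GEO Series Matrix
loader imports archived expression deposits for re-analysis.

## Worked example

```r
library(receptorSig)

design <- exampleDesign()       # PC3, MDA-MB-231, MCF-7 x LPA1/2/3/6
checkIdentifiability(design)
#>   receptor nPositive nNegative                      status
#> 1     LPA1         2         1                identifiable
#> 2     LPA2         3         0            no_negative_line
#> 3     LPA3         1         2 insufficient_positive_lines
#> 4     LPA6         2         1                identifiable
```

Only LPA1 and LPA6 can be attributed: LPA2 is everywhere (no negative
line), LPA3 is in one line only. Simulate a 1000-gene experiment with 50
genes planted per receptor (2-fold effect, 5% noise), and recover the
LPA1 signature:

```r
cfg <- SimulationConfig(design, nGenes = 1000, nPlantedPerReceptor = 50,
                        effectSize = 2, noiseCV = 0.05, seed = 7)
sim <- simulateAttributionDataset(cfg)
res <- runAttribution(sim$experiment, design, "LPA1",
                      annotation = truthAnnotation(sim$truth))
res$attribution
#> AttributionResult for receptor LPA1 (up-regulated, gene level)
#>   positive lines: PC3, MDA-MB-231
#>   negative lines: MCF-7
#>   attributed probe sets: 100
#>   distinct genes: 50 ( unannotated probe sets: 0 )
```

The 100 attributed probe sets collapse to exactly the 50 planted genes
(two duplicate probe sets per gene): sensitivity 1.000, false-discovery
proportion 0.000 against the planted truth. The per-line up counts in
`res$counts` (400 in PC3, 200 elsewhere) are the planted genes of each
line's expressed receptors.

Validation arms:

```r
percentDecrease(25.35, 44.93)   # treated vs vehicle group means
#> [1] 43.5789                    # reported as a 44% decrease

rep <- runCohortValidation(simulateCohort(234, rhoTarget = 0.25, seed = 7))
rep$quartiles$sizes
#> Q1 Q2 Q3 Q4
#> 59 59 58 58
rep$correlation[c("rho", "p.value")]
#> $rho [1] 0.1827  $p.value [1] 0.00505
```

i.e. a 234-sample cohort splits 59/59/58/58 into equal-frequency
quartiles, and this particular simulated cohort shows a sample Spearman
of 0.18 (population target 0.25) with p ≈ 0.005.

A command-line interface (`inst/scripts/receptorsig`) exposes
`simulate`, `attribute`, `validate-cohort`, `intervention` and
`geo-import` subcommands; every run writes a provenance record with the
config, seed and package version.

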