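---
title: "Receptor-specific gene-signature discovery: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor-specific gene-signature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(receptorSig)
```

# The problem

A ligand such as lysophosphatidic acid (LPA) signals through several
G-protein-coupled receptors at once (LPA~1~–LPA~6~), and most cell lines
express several of them. A gene that responds to ligand stimulation in one
cell line therefore cannot be credited to any single receptor. The idea
this package implements is to turn the *pattern* of receptor expression
across a panel of cell lines into a boolean attribution rule: if receptor R
is expressed in some lines and absent from others, then a gene driven
specifically by R should respond to the ligand in **every** R-positive line
and in **no** R-negative line. Genes passing the rule form an R-specific
response signature, and a secreted member of that signature is a candidate
blood-borne biomarker of R activity — which the downstream modules then
evaluate in patient cohorts (quartile stratification, rank statistics,
correlation) and in intervention experiments (percent decrease under a
receptor antagonist, unpaired t-test).

# The attribution model

The expression data are probe-set level fluorescence matrices, one array
per (cell line, condition, replicate), held in a
`SummarizedExperiment`-derived `ResponseExperiment`. The procedure is:

1. **Replicate aggregation** — arithmetic mean of replicate arrays per
   (probe set, line, condition) (`aggregateReplicates()`).
2. **Fold change** — `fold = max(treated, floor) / max(control, floor)` on
   the linear scale, with a floor of 1 fluorescence unit by default; for
   log2-scaled deposits `fold = 2^(treated − control)`
   (`computeFoldChanges()`).
3. **Regulation calls** — strictly greater than 1.3 is "up", strictly less
   than 1/1.3 is "down", boundary values are "unchanged"
   (`callRegulation()`). The up rule is the published one; the reciprocal
   down threshold is our log-symmetric default and is a parameter.
4. **Attribution** — for a chosen receptor, a probe set is attributed when
   it is called up in every receptor-positive line and not up in every
   receptor-negative line (`attributeReceptor()`), then collapsed to
   distinct gene symbols via the platform annotation
   (`collapseToGenes()`), with unannotated probe sets counted, never
   dropped.

There are no p-values in this stage by design: the discovery rule is a
pure fold-change screen, and its statistical control comes from the
cross-line intersection, not from per-gene tests.

## Identifiability

Attribution is only meaningful when the design permits it.
`checkIdentifiability()` requires at least `minPositive = 2` positive
lines (two *unrelated* cancers, so that cell-type-specific responses are
excluded by the intersection), at least `minNegative = 1` negative line
(otherwise the receptor's genes cannot be separated from ubiquitous
ligand responses), and a presence pattern unique among the receptors.
On the built-in three-line example design
(`exampleDesign()`: PC3 = {LPA1, LPA2, LPA3, LPA6},
MDA-MB-231 = {LPA1, LPA2}, MCF-7 = {LPA2, LPA6}) this classifies LPA1 and
LPA6 identifiable, LPA2 as lacking a negative line, and LPA3 as having a
single positive line; LPA3-like receptors are reported and refused rather
than silently attributed, because a single positive line cannot exclude
cell-type-specific genes.

## A note on threshold monotonicity

Raising the up-threshold shrinks the set of probe sets passing the
positive-line condition, but it can also *silence* an up call in a
negative line, so the full attribution is not globally monotone in the
threshold under the default "not up" negative rule. It is monotone
whenever the negative lines are quiet (folds near 1), which is the regime
the planted simulations produce; the test suite asserts exactly these two
properties rather than a blanket monotonicity.

# What the simulator emulates — and what it does not

`simulateAttributionDataset()` generates the whole discovery input with
planted truth:

- control fluorescence = `baselineMean` (default 100 units, a typical
  mid-range microarray signal) × lognormal noise;
- treated fluorescence adds a multiplicative `effectSize` (default 2) for
  genes planted for receptor R, in R-positive lines only;
- noise is multiplicative lognormal with mean 1, parameterized by its
  coefficient of variation (`noiseCV`, default 0.05 — fluorescence is
  positive and microarray noise is approximately multiplicative; replicate
  variance is a free parameter of the generator, not calibrated to any
  deposited dataset);
- two replicate arrays per condition (matching a two-replicate
  hybridization design) and two duplicate probe sets per gene, each an
  independent noisy readout of the same gene-level signal;
- genes are planted for *every* receptor of the design, in disjoint sets
  (default 50 per receptor out of 1000), so genes belonging to the
  non-target receptors act as decoys that exercise the negative-line
  logic;
- optional "context-specific" genes, up in a single random line, exercise
  the two-positive-lines guard.

Real microarray data differ in ways the generator deliberately ignores:
probe-level effects and normalization artifacts, correlated noise across
probe sets, intensity-dependent variance, and background regulation of
unplanted genes. Passing the recovery tests therefore demonstrates the
*logic* of the pipeline under its stated noise model, not performance on
raw archived arrays. For real deposits, `readGEOSeriesMatrix()` imports a
Series Matrix file (with a user-supplied sample-title mapping and
automatic log2 detection, overridable) so the same pipeline can be run on
an accession downloaded separately.

The cohort generator (`simulateCohort()`) draws two markers from a
Gaussian copula with lognormal marginals; the copula parameter is
$\rho_P = 2\sin(\pi\rho_S/6)$, which makes the *population* Spearman equal
the target exactly, so the comonotone case ($\rho_S = 1$) is exact for any
seed while intermediate targets are hit up to sampling error.
`simulateIntervention()` draws two lognormal groups with prescribed
arithmetic means and CV (default n = 8 per group, a typical xenograft arm
size; group sizes are a free choice of the generator).

# Validation statistics

- **Quartile stratification** (`quartileStratify()`): rank-based split
  into equal-frequency groups; with $n = 4q + r$ the $r$ extra samples go
  to the lowest-labeled groups ($n = 234 \rightarrow 59, 59, 58, 58$),
  and ties are broken by stable input order with a warning when a tied
  value spans a boundary. The rule is fixed so that group sizes are
  exactly reproducible.
- **Kruskal–Wallis + Dunn** (`kruskalWallisDunn()`): tie-corrected omnibus
  H via `stats::kruskal.test`; Dunn's pairwise z on pooled ranks with the
  tie term $\sum_t(t^3-t)/(12(N-1))$, Bonferroni-adjusted across all
  pairs by default (the behaviour of the commercial software most wet
  labs use); the two-group special case coincides with the normal
  approximation of the rank-sum test, which the tests verify. The
  degenerate all-tied input returns H = 0, p = 1.
- **Spearman correlation** (`spearmanCorrelation()`): tie-corrected rho;
  exact two-sided p by full enumeration of rank permutations for
  $n \le 9$, otherwise the $t = \rho\sqrt{(n-2)/(1-\rho^2)}$
  approximation — at cohort scale ($n = 234$) the approximation is the
  operative method, and the exact mode exists mainly as an internal
  oracle. Constant input is an error (rho undefined).
- **Intervention analysis** (`runInterventionAnalysis()`): group
  summaries, percent decrease $100(\bar x_{veh} - \bar x_{trt})/\bar
  x_{veh}$ reported at full precision (display rounding to the nearest
  integer is the caller's choice), and the pooled-variance Student t-test
  by default with a Welch flag, since intervention groups often differ
  visibly in spread. Zero-variance degenerate inputs return p = 1 (equal
  means, by convention) or an infinite t (unequal means), both flagged.

The cohort report intentionally emits both mean ± SD summaries per
quartile and the rank-based tests; neither is privileged. A linear
slope/intercept is included for plotting but carries no test.

# Numerical and design choices

- Fold-change floor 1.0 unit: avoids division by zero at background;
  floored probe sets are listed in the output. Scale invariance holds
  when the floor is scaled with the data.
- Strict inequalities at both call thresholds; an implementation using
  $\ge$ would shift counts at boundary folds, which is why the boundary
  case is pinned in the tests.
- Presence threshold for deriving a receptor design from fluorescence has
  no canonical value; the default is 3× the line's 10th-percentile probe
  fluorescence, always recorded in the resulting object.
- Down-regulated mirror attribution is implemented
  (`direction = "down"`) but not run by default: the discovery analysis
  concerns up-regulated genes.
- Exact Spearman enumeration is limited to $n \le 9$ ($9! = 362{,}880$
  permutations) for memory reasons.
- All simulations take an explicit integer seed and restore the caller's
  RNG state; identical config + seed gives bit-identical output.

Problem sizes used in the shipped tests and acceptance script — 1000-gene
arrays with 50 planted genes per receptor, 234-sample cohorts, 100-seed
calibration loops, $10^4$–$10^5$-resample oracles — were chosen as the
smallest sizes at which the sampling distributions of the checked
quantities are comfortably inside their asserted bands.

# Known limitations

- The discovery stage consumes already-normalized fluorescence; no
  CEL-level processing or normalization is provided.
- The boolean rule has no notion of effect-size uncertainty: a probe at
  fold 1.29 in one positive line is lost regardless of its other lines.
- Attribution quality degrades when receptors share presence patterns
  (confounding) or when `noiseCV` approaches the call threshold's
  log-width; the planted-recovery guarantees in the tests hold for
  `noiseCV` ≤ 0.05 at effect 2.0.
- Secreted-protein filtering of a signature is a curation step outside
  the package's scope; a user-supplied whitelist can be intersected with
  `attributedGenes()` output.
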