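---
title: "mirTarNet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirTarNet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirTarNet)
```

This vignette documents the statistical model behind each pipeline stage,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the analysis recipe left genuine freedom.

## The setting

The pipeline targets bulk small-RNA sequencing of a developmental time
course: four ordered time points (by default postnatal days P01, P04, P09,
P23) with four biological replicates each. The scientific question is
which miRNAs change expression as the tissue matures, which genes they
plausibly repress, and which biological processes those regulatory edges
touch. miRNAs repress their targets, so a *bona fide* regulatory edge
should show anti-correlated differential expression: an upregulated miRNA
with a downregulated predicted target, or vice versa.

## Differential expression model

Counts $K_{fj}$ for feature $f$ in sample $j$ are modelled as negative
binomial with mean $s_j \mu_{fg(j)}$ and variance $\mu + \phi_f \mu^2$,
where $s_j$ is a sample size factor and $g(j)$ the sample's time point.

**Normalization.** Size factors are plain median-of-ratios against the
geometric-mean pseudo-reference, computed over features with strictly
positive counts in every sample. The factors are not rescaled afterwards,
so two samples with a global 2× depth difference get factors
$(1/\sqrt 2, \sqrt 2)$. If no feature is positive everywhere the function
stops and points the user to total-count normalization rather than
silently switching.

**Dispersion.** Per feature, within-group variances of normalized counts
are pooled across groups and converted by the moment identity
$\phi = (v - \mu)/\mu^2$. Features whose variance does not exceed their
mean get the floor ($10^{-8}$). Raw estimates are shrunk toward the
across-feature mean with weight 0.25 — a deliberately simple stand-in for
trend-based empirical-Bayes shrinkage that stabilises the 4-vs-4 design
without adding machinery. With hundreds of samples the shrinkage target is
dominated by the data and moment estimates recover a true $\phi = 0.5$
within ±0.1.

**Test.** The Wald statistic compares log group means of normalized
counts with the delta-method variance
$\mathrm{Var}(\log\hat\mu_g) = n_g^{-2}\sum_{i \in g}(1/(s_i\mu_g)+\phi)$,
referred to the standard normal, two-sided. An independent
likelihood-ratio check (full NB likelihood, fixed $\phi$) agrees with the
Wald p-value on strong effects in the test suite.

**Thresholds.** DE means linear fold change ≥ 1.8 (or reciprocal for
down) *and* BH-adjusted p ≤ 0.01. Both are configurable
(`fcThreshold`, `fdrAlpha`); the inclusive comparisons (≥, ≤) were chosen
so that boundary cases are deterministic, and the threshold is applied to
the raw group-mean ratio (no shrinkage of the fold change). Features whose
mean raw count is below `minMean = 300` at *every* time point are excluded
before testing and before BH; the filter deliberately reads per-time-point
means, so a feature expressed only late in the course is kept. The filter
uses raw counts, as it precedes normalization in the analysis order.

**Numerical choices.** The fold change adds a pseudo-count
$\varepsilon = 0.5$ to both group means to avoid infinities at zeros;
$\varepsilon$ does not enter the test statistic except that a group mean
of exactly zero is floored at $\varepsilon$ there, because the literal
statistic is 0/0 in that case. Features that are all-zero in both groups
are reported as degenerate with FC = 1, p = 1. Result tables are sorted by
FDR, then $|\log_2$FC$|$ descending, then feature id, so output order is
total and reproducible. BH is the standard step-up with running-minimum
enforcement; it matches a definition-based oracle on all permutations of
up to six p-values in the tests.

## Temporal pattern classification

Each miRNA is listed at the *first* adjacent comparison in which it is DE
(long-range comparisons can be allowed to define the first hit via
`firstFromLongRange`, off by default). Persistence is judged on
*cumulative* comparisons: those whose later time point lies beyond the
first hit's and whose baseline is at or before the first hit's baseline.
This reading lets a P09–P04 hit be confirmed by P23–P01, matching how a
transiently downregulated miRNA is recognised by its absence from the
P23–P01 list, and lets an early hit stay "persistent" even if an
intermediate adjacent window alone does not reach the thresholds. A miRNA
DE in no window beyond its first hit is *transient*; a direction reversal
anywhere is *non-monotone* and excluded from persistence (the bookkeeping
offers no precedent for such cases, so they get their own label rather
than a forced call); anything else is *mixed*. V-shaped recovery profiles
(down then back up) therefore fall out as non-monotone or mixed — they are
reported, not forced into a category.

## Target verification and the eligibility gate

Verification is a pure intersection: predicted targets of an up-miRNA ∩
genes down in the same comparison (and vice versa). Per-comparison
matching is the default because miRNA repression should be visible in the
same contrast; pooling mRNA calls across comparisons is available
(`pool = TRUE`) since the alternative reading cannot be excluded. Genes
measured but not predicted contribute nothing. A miRNA absent from the
prediction table is distinct from one with an empty prediction — the
former is flagged `noPrediction`, mirroring how target databases simply
lack entries for some miRNAs. Gene symbols are matched after trimming and
uppercasing (miRNA ids keep their case, which is meaningful in miRNA
nomenclature); the identifier namespace of a real prediction export is
the user's responsibility. Sets with fewer than `minTargets = 40` verified
genes are flagged ineligible for enrichment but never deleted.

## Enrichment

The over-representation p-value is the exact hypergeometric upper tail
$P(X \ge k)$, summed in log space with log-sum-exp, stable for universes
of at least $10^5$ genes; the EASE-style mode decrements the overlap by
one first ($k \le 1$ gives p = 1). The default background is the measured
genes (those in the differential mRNA input) intersected with
collection-annotated genes — the statistically defensible choice when the
query itself is drawn from measured genes; `universePolicy = "annotated"`
uses all annotated genes instead, closer to web-tool defaults. Both exist
because published analyses rarely state their background. Significance is
on the raw p ≤ 0.05 per the convention of DAVID-style reports; a BH column
across sets is emitted for transparency but does not drive the flag.

## Network export

Edges are significant (miRNA, set) pairs weighted by overlap size, the
convention in chord diagrams where a term's section is proportional to the
number of associated target genes. A gene targeted by several miRNAs
counts once per edge; term totals are sums of incident edge weights.
Node order is deterministic (miRNAs by id, terms by total weight then id)
and both exports are byte-stable, so diffing two runs is meaningful.
Sub-networks filter terms by a case-insensitive name pattern (default
keyword `mitochondri` for the mitochondria-associated GO:CC view) and
carry weights over unchanged.

## qPCR quantification

ΔCt subtracts the per-sample mean of the chosen reference assays (two
housekeeping miRNAs by default in the synthetic plates; any number is
accepted), which cancels per-sample offsets exactly. ΔΔCt is relative to
the control group's mean ΔCt, and fold change is $2^{-\Delta\Delta Ct}$
with the amplification base fixed at 2 (no efficiency correction, matching
standard practice when validated assays are used; the base is
configurable). The control group's fold change is exactly 1 by
construction. Group comparisons use the classical equal-variance two-sample
t-test on ΔCt values (Welch optional). Spike-in assays are checked for
presence and across-sample stability but never normalized against — they
monitor the RT/qPCR steps, not the biology. Noise-free groups with equal
means give p = 1, with different means p = 0, so synthetic zero-noise
plates behave sensibly.

## The synthetic-data generator

`generatorConfig()` defaults encode the emulated study design: 4 time
points × 4 replicates, 240 miRNA features, a 3000-gene transcriptome, 15%
of miRNAs planted DE with $|\log_2$FC$| \in [1.5, 2.5]$, NB dispersions
log-normal around 0.05, baseline means log-normal around 1500 with planted
features floored at 500 (above the 300-count filter), per-sample size
factors log-normal (SD 0.1 on the log scale). Trajectories follow four
templates mirroring the phenomenology of postnatal time courses:
`early_down` (repressed from the first window onward), `mid_down` (from
the second), `late_up` (induced in the last window) and `transient` (a dip
in the middle window that half-recovers; its effect size is capped at
$2\log_2 1.8 \approx 1.7$ because a larger dip cannot return to within the
DE band of both endpoints). Template weights default to roughly the
published composition of such a course (≈0.20/0.28/0.47/0.05). Each
planted miRNA gets 60 true repressive edges into the opposite-direction
gene pool (12% of genes per direction) plus an equal number of uniform
decoy predictions, one planted gene set containing 70% of a 50-gene sample
from its true targets, and 60 random background sets (25–80 genes, a few
named with mitochondrial GO:CC terms so the subnetwork filter has
something to find).

What the generator does **not** emulate: mapping/counting artefacts,
GC or length biases, correlated dispersion–mean trends, batch effects,
partially overlapping target sets of miRNA families, and an mRNA side
with its own count noise (the differential gene table is emitted directly,
the way a previously published companion transcriptome is consumed; a
count-level mRNA mode would be a natural extension). Passing the recovery
tests therefore demonstrates correctness of the statistical machinery
under the stated model, not robustness to real-data pathologies.

## Problem sizes in the test suite

The suite favours many small, seeded simulations: the null false-call rate
uses 20 seeds × 500 features at the 4-vs-4 design; sensitivity uses a
10-seed panel at the default generator size; oracle equivalences run over
all hypergeometric margins ≤ 30 and all permutations of ≤ 6 p-values; the
end-to-end determinism check runs the pipeline twice at a reduced size (60
miRNAs, 600 genes). These sizes give stable pass/fail behaviour at
desk-scale runtimes while exercising every code path.

## Known limitations

- The DE module is a documented simplified stand-in for a full GLM-based
  NB framework: no covariates, no trend-fitted empirical-Bayes dispersion,
  no LFC shrinkage, normal (not t) reference for the Wald statistic.
- Persistence semantics depend on which long-range comparisons are in the
  plan; with none, persistence for late hits is vacuous.
- Enrichment treats gene sets as flat lists — no GO-DAG propagation or
  term redundancy trimming.
- Verified targets are correlational: anti-correlated expression plus a
  database prediction is evidence, not proof, of direct repression.
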