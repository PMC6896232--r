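---
title: "Models and methods behind germnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind germnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germnet)
```

`germnet` analyses bulk RNA-seq time courses of pluripotent cells
differentiating towards the three germ layers and infers the
transcription-factor network driving them. This vignette explains the models
the package implements, the parameters that matter, the choices made where
the design was genuinely open, and what the synthetic benchmarks do and do
not establish.

## Normalization

Counts are first converted to reads per million using the total number of
aligned reads per sample (`gross_normalize()`); transcript length is
deliberately not corrected for, because only relative changes across samples
matter downstream. Residual per-sample scale distortions (library
composition, batch) are then removed by `fine_normalize()`: per-gene log2
ratios between a sample and a reference profile are ordered by reference
expression, smoothed with a running median, and the sample is rescaled by
`2^(-median)` of the smoothed ratios — the shift that brings the
median-filtered log expression onto the identity line. The underlying
assumption is that the *median* highly expressed gene is unchanged between
samples; datasets violating this (global amplification, extreme composition
shifts) will be over-corrected.

Three constants here are package decisions, exposed as arguments:

* **Reference profile** — the per-gene geometric mean across samples.
* **High-expression filter** — genes with geometric-mean rpm above 32 enter
  the fit (default window requires at least 101 of them). The geometric
  mean is used rather than a per-sample minimum because it is exactly
  invariant under the correction itself, which makes re-normalization a
  no-op (factors of 1 to machine precision) and the gene set stable under
  the distortions being removed.
* **Centred factors** — log2 fine factors are centred to mean zero, so the
  correction redistributes scale between samples without changing the
  overall level. Without centring, a rerun would reproduce the mean shift
  instead of unity factors.

All log transforms and fold ratios use a pseudocount of 1 rpm (configurable):
bounded behaviour at zero counts, standard practice. Differential genes
require `max rpm > 3` (strict) and `(max+1)/(min+1) >= 4` (inclusive) over a
condition's time course including the shared day-0 baseline; replicates stay
separate samples throughout. Fold boundaries are inclusive so that a gene at
exactly the threshold passes — a deterministic, documented convention.

## Trajectory mapping

Sample clustering is average linkage on correlation distance (1 − Pearson on
log2 expression of the filtered genes); Euclidean distance is available.
Correlation distance is the package default because it ignores per-sample
scale, which is the quantity normalization already fights; a constant
profile makes it undefined and is reported as an error rather than patched.

PCA centres each gene and decomposes the samples-by-genes matrix by SVD;
variance fractions are squared singular values over their sum. No per-gene
scaling is applied — scaling would equalize the contribution of
low-information genes, and the expression filter has already removed flat
genes. External profiles are projected by restricting to shared genes,
centring with the *training* means and multiplying onto the training
loadings: re-centring on the external data would translate the map and
destroy comparability of trajectories. A minimum of 50 % shared genes is
required (configurable); the missing fraction is reported.

Cross-platform inputs are harmonized first: `quantile_match()` replaces each
value by the reference quantile of its within-sample rank (average ranks for
ties), so each column is distributed like the sequencing reference up to tie
granularity, and `center_genes()` removes per-gene means to absorb platform
offsets. Probe-to-gene collapsing, where needed, should keep the probe with
the highest mean intensity — the package operates on gene-level matrices.
The fold-variation presets ship as named filters: 16-fold during any
in vitro differentiation course, optionally conjoined with 8-fold across
external embryo sections.

## Motif activity response analysis

Promoters are the 1 kb window proximal to the transcription start site;
longer input is trimmed to its 3' end. JASPAR PFMs become log2-odds matrices
against a uniform background with a total pseudocount of 0.8 distributed by
background (avoids infinite scores at zero counts, standard magnitude). A
window on either strand is a site when its score reaches `rel_score` (default
0.80) of the maximum achievable score; overlapping hits all count, windows
containing N are skipped. The 0.80 relative-score convention is a package
decision — no universal site-calling threshold exists — and the site matrix
is monotone in it, so stricter values can only remove sites. A consequence
worth knowing: sites *sampled* from a PFM carry binomial mismatches, so at a
fixed relative threshold the scanner's recall of planted sites depends
steeply on the PFM's information content. The recovery benchmarks therefore
use near-consensus motifs (dominant-base fraction 0.97–1.0), where detection
is essentially exact; with soft motifs the site counts are thinned and the
correlation with ground truth drops accordingly.

The activity model treats log2 expression additively per sample:
`log2 e[g,s] = c[s] + Σ_m N[g,m]·A[m,s] + ε[g,s]`, fitted by ordinary least
squares independently per sample. Two exact properties are tested: with zero
noise the fit recovers planted activities and intercepts to machine
precision, and adding a constant to one sample's log expression moves only
that sample's intercept.

Which motifs deserve a place in the model is decided by per-sample forward
selection: at each step the candidate with the largest residual-variance
reduction is scored by the F-statistic of its coefficient and admitted when
its p-value, Bonferroni-corrected for the number of remaining candidates,
falls below `alpha = 0.01`. This is the package's operationalization of
"significant motif activity" in the spirit of reduced regression analysis;
it is deliberately isolated in one function (`motif_significance()`) so a
different significance rule can be substituted. Two consequences of this
design: the familywise false-selection rate is controlled at `alpha` *per
sample* (the union bound holds because the best candidate's corrected p is
compared, not each candidate's), so across S samples the per-dataset rate is
bounded by `S·alpha`; and after selection the activities of all selected
motifs are refit jointly over every sample, so each selected motif carries a
complete activity trajectory rather than gaps in samples where it was not
individually admitted. `alpha = 1` degenerates to selecting all candidates.

TF eligibility requires every constituent gene of a motif (dimers split on
`::`) to exceed 6 rpm somewhere in the chosen samples — conservative for
dimers, which are only as expressed as their weakest subunit.

## Network rules

An edge regulator → target exists iff (i) the regulator has ≥ 1 predicted
site in the target gene's promoter and (ii) the absolute activity–expression
Pearson correlation strictly exceeds 0.8; positive correlation is inductive,
negative inhibitory, and the correlation is the edge weight. Strictness at
the boundary follows the rule's wording ("greater than"); the site condition
uses presence regardless of any binarization of the count matrix. Self-edges
are excluded by default. Dimer motifs have no single transcript to read
expression from, so they are excluded from the *target* role unless an
explicit motif-to-gene mapping names one gene; they remain full regulators.

Feed-forward loops are all ordered triples with edges a→b, b→c, a→c; a loop
is coherent when the indirect sign product equals the direct sign. Dense
overlapping regulons are maximal regulator sets (≥ 2) sharing ≥ 3 common
targets; because intersection is monotone, maximality reduces to "no single
additional regulator keeps the shared set large enough", which the finder
exploits; it is validated against exhaustive subset search. The DOR
thresholds are configurable — there is no formal community definition — and
the defaults are chosen so the benchmark scenario's planted structure is
found uniquely. Exports (SIF, GraphML, TSV) use deterministic ordering:
nodes lexicographic, edges by (regulator, target).

## Enrichment

The empirical enrichment p-value of a gene set against a hit set draws
`resamples` subsets of the pool without replacement and uses the add-one
estimator `p = (1 + #{null ≥ observed})/(resamples + 1)`, which is never
zero and converges to the hypergeometric upper tail (verified within three
Monte-Carlo standard errors at 10^5 resamples). Benjamini–Hochberg
correction is delegated to `stats::p.adjust`.

## The synthetic generator, and what passing means

`simulate_dataset()` draws uniform-ACGT promoters with Poisson-planted,
non-overlapping, strand-symmetric PFM sites; smooth per-condition activity
trajectories (logistic/linear/constant) that share a common day-0 value —
one undifferentiated origin — with a per-motif baseline; expression from the
additive model plus Gaussian noise; and Poisson counts (negative binomial
with an overdispersion option) scaled to the sample depth. Defaults describe
a realistic desk-scale study: three conditions, eight days, two replicates,
1 kb promoters, site rate 0.5, noise SD 0.5 log2 units, 5×10^6 reads per
sample.

The generator emulates exactly the statistical structure the pipeline
assumes — which is the point, and also the caveat. Passing recovery
benchmarks shows the estimators are correct and calibrated *under the
model*: it does not establish robustness to promoter sequence composition
bias, motif similarity within real databases, transcript-length effects,
overdispersion beyond the NB option, or regulation outside the proximal
1 kb. The documented five-edge scenario
(`simulate_grn_scenario()`) additionally holds intercepts constant and keeps
noise low so that it isolates the edge rule; its two regulators have
orthogonal activity trajectories by construction (symmetric vs antisymmetric
across the two conditions), and target promoters contain only their planted
regulator's sites.

## Benchmark problem sizes

The test suite and `scripts/acceptance.R` use: 2,000 genes × 20 motifs × 16
samples at noise SD 0.5 for activity recovery (per-sample r ≥ 0.95); the
five-edge scenario for precision/recall ≥ 0.9 with exact signs; 200 null
datasets (200 genes × 20 candidates × 2 samples) for selection calibration —
two samples keep the per-dataset false-selection bound at 2 % — and 100
planted datasets at amplitude 4× noise for power; 100 random
sequence/motif pairs, 20 random graphs, five 10-node graphs, a 9-sample
clustering fixture and 10^5 resamplings for the oracle equivalences; and a
600-gene flat-expression study for normalization factor recovery within 5 %.
These sizes were chosen as the smallest at which the asymptotic claims are
comfortably displayed.

## Known limitations

Promoter scanning is position-independent and ignores conservation,
chromatin and distal regulation; activities are linear in site counts and
shared across genes; the correlation gate cannot orient causality and will
happily connect a regulator to a target co-driven by a confounder when a
site happens to be present; and reproducing published node/edge counts from
real studies depends on the exact annotation, motif release and thresholds
used there.
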