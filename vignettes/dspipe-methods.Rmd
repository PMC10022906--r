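---
title: "Methods: models, parameters, and design choices in dspipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in dspipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dspipe analyses targeted digital spatial RNA profiling data: probe counts
exported per segmented area of interest (AOI), with several probes per
gene and a set of no-target negative-control probes whose counts estimate
per-AOI background. This vignette records the statistical model behind
each stage, the parameters a user might tune, the choices made where the
design was genuinely open, and what the synthetic benchmark does and does
not establish.

## Quality control

Within one AOI, the **snAUC** is the ROC area separating gene-probe
counts (positives) from negative-probe counts (negatives). It is computed
as the Mann–Whitney U statistic over all (gene, negative) probe pairs
divided by the number of pairs, with ties counting one half — a rank
computation, so it is invariant to any strictly monotone transform
applied to both classes. An AOI with no usable signal scores near 0.5.

The **limit of detection (LOD)** is the 90th percentile of the AOI's own
negative-probe counts. Two conventions needed fixing:

* *Percentile convention.* Linear interpolation between order statistics
  (`stats::quantile` type 7). The choice is visible only through the LOD
  of small negative-probe panels and is asserted against an independent
  interpolation formula in the tests.
* *Per-AOI versus global LOD.* Background level varies with each AOI's
  area and chemistry, so the LOD is computed per AOI from that AOI's 75
  negative probes. A single global LOD would transfer background from
  deep AOIs to shallow ones.

Detection is inclusive at the boundary: a count **strictly below** the
LOD is undetectable; a count equal to the LOD is detected.

AOI filtering requires total counts strictly above 100,000 and snAUC
strictly above 0.65. Probe filtering removes gene probes undetected in
strictly more than 80% of AOIs (negative probes are exempt — they are the
background ruler, not measurements). Gene filtering, applied after
collapsing, retains genes whose collapsed value reaches the AOI LOD in at
least 20% of AOIs (inclusive). Thresholds quoted with ">" are strict and
those quoted with "at least" are inclusive, and a frozen-defaults test
pins every one of them.

## Collapsing and normalization

Each gene's surviving probes are collapsed to one value per AOI by
geometric mean after replacing zeros with 1 — the standard
digital-counting convention; without it a single dropout probe would
annihilate the gene. The generator plants lognormal per-probe biases with
geometric mean 1 within each gene precisely so that the geometric mean is
the natural unbiased collapse.

Normalization is a fixed four-step chain:

1. **Background subtraction**: the geometric mean of the AOI's negative
   probes is subtracted from every gene value, floored at 0.
2. **Library scaling** to counts per million (every column then sums to
   10⁶).
3. **Quantile normalization**: sort each column, average across columns
   at each rank, map back by original ranks. Ties receive the mean of the
   rank-averaged reference values over their tied span, which preserves
   within-column rank order and keeps the operation idempotent. (This
   differs slightly from interpolating at fractional tie ranks, which
   does not keep the column multisets exactly equal for tie spans longer
   than two; the two agree exactly on tie-free data, which the tests
   verify against limma's implementation.)
4. **log2(x + 1)**, so fold changes are natively in log2 units and zero
   maps to zero.

The chain follows the order in which the steps are stated for this assay
type; folding scaling into quantile normalization would change nothing
downstream of step 3 but is not what the procedure describes.

## Differential expression

Per gene, an ordinary least-squares two-group fit on log2 expression.
Residual variances are moderated by the standard empirical-Bayes
construction: variances are modelled as scaled inverse-chi-square draws,
and the prior degrees of freedom d₀ and prior variance s₀² are estimated
by moment matching of log s²_g (digamma/trigamma matching, with a Newton
trigamma inverse). The posterior variance (d₀s₀² + d s²_g)/(d₀ + d)
enters the t statistic, which is referred to a t distribution with d + d₀
degrees of freedom. Two limits anchor the implementation: with d₀ forced
to 0 the fit reduces to ordinary t-tests, and when the observed
log-variances show no excess dispersion the prior is taken as the raw
mean of the variances, so identical gene variances leave the t statistics
exactly unmoderated. Zero-variance genes are excluded from prior fitting
but receive a positive posterior variance through the prior, so no
statistic divides by zero. The fit is cross-checked against limma on
non-degenerate data.

Significance is |log2FC| > 1 (strict) and Benjamini–Hochberg adjusted
P < 0.05, adjusted within each contrast separately (per-analysis
families). Subtype signatures are intersections of the pairwise contrast
up-sets; a gene up in only one of its two comparisons belongs to no
signature. Externally curated gene sets use an *inclusive* fold-change
threshold (|log2FC| ≥ 1), mirroring how public tumour-vs-normal tables
are turned into gene sets; the internal/external asymmetry is
deliberate and tested.

Two modelling simplifications are documented rather than hidden: AOIs are
treated as independent observations (no random effect for slide or
patient), and the HGD-vs-LGD contrast pools subtypes rather than
adjusting for them. Both follow the analysis this pipeline reproduces;
nested designs would need a mixed model this package does not fit.

## Preranked gene-set enrichment

Genes are ranked by log2 fold change. The enrichment score is the
maximum-deviation weighted Kolmogorov–Smirnov running sum with hit
increments proportional to |statistic| (weight exponent 1) and uniform
miss decrements. The null is **gene-subset sampling**: `n_perm` random
same-size subsets of the ranked universe — the correct null for a
preranked analysis, where no sample labels exist to permute. NES divides
ES by the mean |null ES| of matching sign; the p-value is the fraction of
same-sign null scores at least as extreme (with the +1/(n+1) correction
under Monte Carlo sampling). For universes where `choose(n, k)` is small
the null can be enumerated exhaustively, making ES, NES and p exact; the
acceptance tests exploit this. Set-size defaults are min 5 / max 500
after intersection with the universe — conventional bounds, not quoted
values — and genes absent from the measured universe are dropped from
sets before testing, reflecting targeted-panel reality. A tie tolerance
of 1e-9 guards extremum comparisons against float-order effects; an
exact ±tie between two running-sum peaks is resolved toward the first
position.

Cluster over-representation uses the upper-tail hypergeometric
probability P(X ≥ k) with BH adjustment across sets. The universe
defaults to all filtered genes (configurable); restricting it to network
genes would make enrichment conditional on coexpression and is left to
the caller.

## Coexpression network

Spearman correlations (average ranks for ties) are computed for all gene
pairs; constant genes are recorded as missing and excluded. The null
distribution comes from permutations that shuffle each gene's values
across AOIs — breaking all pairwise association while preserving
marginals. **Granularity matters here**: each permutation contributes
⌊genes/2⌋ disjoint random-pair |ρ| values to one pooled null, so the
empirical p-value floor is 1/(n_perm·⌊genes/2⌋ + 1) rather than
1/(n_perm + 1). With one draw per permutation no pair could ever reach
q < 0.01 once hundreds of thousands of pairs are tested; pooling per-pair
draws is also the natural reading of a "null distribution of correlation
coefficients" built from whole-matrix permutations.

Per pair, p = (1 + #{null ≥ |ρ|}) / (1 + #null); q-values use the
positive-FDR estimator with π₀ = mean(p > 0.5)/0.5 (capped at 1, floored
at 1/m) and enforced monotonicity in p. Edges require |ρ| ≥ 0.7
(inclusive) **and** q < 0.01 (strict); weights are ρ⁴, which compresses
moderate correlations while keeping weights in [0, 1]. Communities come
from Leiden clustering with a modularity quality at resolution 0.5,
10 iterations, seeded; clusters under 10 genes are flagged underpowered
but keep their labels. Overlay annotation attaches per-group z-scored
mean expression (z across genes), the HGD-vs-LGD log2FC as a node-size
attribute, and external-set membership flags, for export to GraphML.

## Exploration

PCA treats AOIs as observations with genes centred and, by default,
scaled to unit variance (the underlying procedure does not state a
scaling; unit variance stops the brightest genes from owning the first
component, and the choice is exposed as an argument). Hierarchical
clustering uses Euclidean distance with the ward.D2 criterion — distances
are *not* squared before the Ward update — and heatmap-style calls
z-score rows first, with constant rows flattened to zero under a warning.
The k = 2 cut of the grade-signature clustering yields the high/low-risk
AOI grouping.

## The synthetic-data generator

`simulate_dataset()` draws probe counts from a negative binomial with
shared dispersion (default 0.15) around
2^(baseline_g + effects_ga + offset_a) · bias_p: gene baselines are
normal on the log2 scale (mean 2.9, sd 1.8), probe biases lognormal
(sdlog 0.35, geometric mean 1 per gene), negative probes draw around
2^2 at the reference library size, and AOI library sizes are uniform on
[40,000, 1,000,000] multiplied by subtype factors (PB 1.15, INT 1.35,
GF 1) and a grade factor (HGD 1.25) that recreate the yield-density
confounding normalization must remove. These magnitudes were fixed once
against the cohort-level medians the study design implies (median total
counts around 6×10⁵, roughly half of probes above background, about 70%
of genes retained, median 623 nuclei per AOI) and are not revisited. The
default design carries 98 AOIs over 12 slides — 50 HGD, 48 LGD, with GF
regions always low grade — and plants 30 genes per subtype, 25
HGD-associated genes (log2 effect 2), and three latent-factor modules of
40/30/20 genes at loading 1.5. All randomness derives from one root seed
through named child streams, so identical configurations are
bit-reproducible and individual stages can be re-run.

Planted-effect *recovery* benchmarks (DE sensitivity, signature
intersection, module-to-cluster mapping) instead use a well-expressed
regime (baseline 6, gene sd 1): recovery criteria presuppose that the
planted genes survive detection filtering, which genes parked at the
detection boundary by design would not. The cohort-calibrated defaults
are kept for everything that measures QC, normalization, and
false-positive control.

What the generator does **not** emulate: spatial autocorrelation between
neighbouring AOIs, patient-level random effects, probe-specific
sequence-driven efficiency beyond a static lognormal bias, zero inflation
beyond the negative binomial, and segmentation artefacts. Passing the
benchmark therefore shows the pipeline recovers the structure it assumes,
under confounded library sizes and overdispersed counts — not that it is
robust to spatially structured noise or misannotation.

## Problem sizes and numerical conventions in the test suite

The suite exercises: snAUC against brute-force pair counting on 200
random instances; quantile normalization invariants on 100 random
matrices; BH against a brute-force step-up on 500 random vectors;
hypergeometric p against exhaustive enumeration of all C(10,4) draws;
GSEA against exhaustive subset enumeration on universes of 6–12 genes
plus a 50-seed null calibration; DE recovery with 20 planted genes
(log2FC 2, 10 vs 10 AOIs, 500 genes) over 20 seeds with matched null
simulations; signature recovery with 3×25 planted genes at 90 AOIs over
10 seeds; network null calibration on 900 independent genes at 60 AOIs
over 20 seeds and module recovery (40/30/20 at loading 1.5 among 900
background genes, 80 AOIs) over 10 seeds with 1,000 permutations; and a
byte-identity check of two end-to-end runs. These sizes were chosen so
the whole suite completes in about a minute while keeping binomial
tolerance bands meaningful.

## Known limitations

* No mixed-effects modelling of slides/patients; inference treats AOIs
  as independent.
* The permutation null assumes exchangeability of AOIs per gene; strong
  batch structure would call for a stratified permutation the package
  does not implement.
* The q-value estimator uses a single λ = 0.5 rather than a smoothed
  π₀ path; it is deliberately simple and swappable.
* GSEA p-values are bounded below by the null size; with the default
  1,000 subsets the smallest attainable p is ~1/1001 per sign class.
* The CLI is a thin wrapper; scheduling, caching and resume logic beyond
  per-stage reuse of on-disk intermediates are out of scope.
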