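---
title: "Methods: models, parameters, and design choices in maturekit"
author: "maturekit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters, and design choices in maturekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maturekit)
```

maturekit implements the computational core of a neuronal-maturation
time-course analysis: how gene expression and chromatin accessibility of a
defined neuron population (spinal motor neurons purified by nuclear
tagging) change from neurogenesis to adulthood, how much of that program an
in vitro culture recapitulates, and what cell-type mixture a bulk adult
profile represents. This vignette documents the statistical models, every
tunable parameter that matters, what the synthetic-data generator does and
does not emulate, and the design decisions taken where the procedure was
genuinely open.

## Normalization and the expressed-gene universe

Counts are normalized by **median of ratios**: for each gene with a
nonzero count in every sample, form the ratio of its count to its
geometric mean across samples; a sample's size factor is the median of
those ratios. Genes with any zero count are excluded from the reference
(their geometric mean is zero), the standard convention. Normalized values
satisfy `value * size_factor == count` exactly, so the raw matrix is
always recoverable.

One consequence worth knowing: size factors are only defined relative to
the geometric-mean reference, which itself contains every sample. Scaling
one sample's counts by $c$ multiplies its factor by $c$ *relative to the
other samples*, but shifts all normalized values by the gauge constant
$c^{1/n}$. All downstream statistics (fold changes, calls, PCA) are
invariant to that gauge.

The **expressed-gene filter** keeps genes with CPM $\ge 5$ in *all*
replicates of at least one condition group (timepoint-by-condition by
default). The threshold is inclusive, and raising it can only shrink the
set. One filter is computed over all loaded conditions and reused for
every contrast, mirroring how a full time course is typically loaded at
once; per-pair filtering can be had by passing an explicit `scope`.

## The negative-binomial exact test

Each consecutive-timepoint contrast is tested with a two-group NB exact
test, the classic contract for overdispersed counts with few replicates:

* counts are put on a common scale (median-of-ratios normalization, then
  rounding to integer pseudo-counts — the "equalized effective library
  size" device);
* a single **common dispersion** $\varphi$ (variance $= \mu +
  \varphi\mu^2$) is estimated by method of moments, pooling
  $\sum (n_i-1)(v_g - m_g)$ over $\sum (n_i-1) m_g^2$ across genes and
  groups. Pooling numerator and denominator avoids the upward bias of
  clipping per-gene estimates at zero. Tagwise empirical-Bayes shrinkage
  is deliberately out of scope;
* for each gene the two group sums are compared conditional on their
  total: group sums of $n$ iid NB$(\mu, \varphi)$ counts are
  NB$(n\mu, n/\varphi)$, and the two-sided "double tail" p-value sums the
  probability of every split of the total at most as likely as the
  observed one. $\varphi = 0$ degrades gracefully to the Poisson/binomial
  case. Totals above $5\times10^5$ switch to a normal approximation of the
  conditional law (never reached at the package's default scales);
* the reported log2 fold change is computed on normalized group means with
  a pseudocount of 0.5 normalized units; the p-value always comes from the
  exact test, never from the pseudocounted ratio.

Calls use the conventional thresholds **fold change $\ge 2$ (inclusive)
and $p < 0.001$ (strict)**; genes with zero counts in both groups are
`stable` with $p = 1$. The test is antisymmetric under group swap, and its
type-I error and power are verified by seeded simulation in the test
suite: on a 2000-gene null ($\varphi = 0.05$, 3 vs 3) the rejection rate
at $p < 0.001$ stays within three binomial standard deviations of nominal,
and power for 4-fold effects at mean 200 exceeds 0.9. The power simulation
embeds the effect genes in a majority-null background on purpose: if every
gene changes 4-fold, median-of-ratios normalization absorbs the fold change
itself — a property of the normalization, not of the test.

## Sample PCA

Genes with more than 10 normalized reads in at least one sample are kept,
`log2(x + 1)`-transformed (the base and pseudocount are package choices;
any monotone log works), per-gene centered and scaled to unit variance,
and the samples projected with `prcomp`. Constant genes are dropped before
scaling. Percent variance explained is reported per component.

## Temporal dynamics and effector categories

`percentDynamic()` is purely a tally over existing DE calls restricted to
the expressed universe — it never re-tests. `categorizeEffectors()` applies
case-insensitive substring rules to gene descriptions (channel; receptor
but not nuclear; transcription or nuclear-receptor; histone or chromatin;
kinase) plus a case-sensitive `Col` symbol-prefix rule for collagens
(mouse symbol capitalization). Substring rather than whole-word matching
is a documented choice; the precedence
`transcription_factor > chromatin_regulator > channel > receptor > kinase
> collagen` resolves collisions in single-label mode, and `multiLabel =
TRUE` returns the full membership matrix instead.
`inducedFractionByCategory()` reports, per category, the percent of
expressed members that start below an expression ceiling (default 100
normalized units at the first timepoint) and are called up over the
first-to-last contrast; categories with no expressed members are `NA`, not
zero.

## Two-stage NNLS deconvolution

The reference pipeline consumes an already-labeled cell-by-gene count
matrix (clustering itself is out of scope):

1. **balance**: every cluster is downsampled without replacement to the
   size of the smallest cluster (the seed is a required, logged
   parameter);
2. **profiles**: cells are depth-scaled to the median total count,
   `log1p`-transformed, and averaged within clusters;
3. **merge**: restricted to the 1000 highest-variance genes (variance
   across cluster profiles), clusters are grouped by average-linkage
   hierarchical clustering on correlation distance $1 - r$, cutting the
   tree at height $1 - \texttt{corrThreshold}$. Under average linkage the
   merge height is one minus the mean cross-correlation, so every merged
   class has average within-class correlation at least the threshold. The
   threshold (default **0.8**) has no canonical value and is therefore
   mandatory in every run report;
4. **fit**: the bulk profile is expressed as a non-negative linear
   combination of class profiles by Lawson–Hanson NNLS
   (`pracma::lsqnonneg`). The fit is done in log space, matching the
   mean-log profiles; pass linear-scale bulk and it is `log1p`-ed to
   match (`bulkIsLog = TRUE` skips this). Proportions are weights
   normalized to percent; an all-zero solution is flagged degenerate
   rather than divided by zero.

Stage 2 repeats the identical pipeline on the cholinergic-flagged clusters
only, resolving the bulk signal into cholinergic cell classes; top-variance
genes are recomputed within the stage. Every fit is checked in the test
suite against an exhaustive active-set oracle and the KKT conditions, and
parameter recovery on seeded mixtures (4 classes, 2000 genes, noise up to
5% of signal) achieves mean absolute error below 2 percentage points with
absent classes at essentially zero weight.

## Concordance classification

`buildConcordance()` joins two DE contrasts on their shared genes (inner
join; exclusions counted) and assigns each gene exactly one of eight
categories from its (sign, significance) pair: `shared_up`, `shared_down`,
`opposite`, four one-sided `*_specific_*` categories, and `stable`.
Significance reuses the DE call by default; `mode = "lfc-only"` with a
configurable cut reproduces the quadrant-count variant used for
activity-blockade comparisons. The up-recapitulation percent is
`shared_up / (shared_up + opposite-with-up-in-Y + y_specific_up)`; because
it is debatable whether opposite-regulated genes belong in the
denominator, the variant without them is always reported alongside.
`lfcCorrelation()` is a Pearson correlation with the two-sided p-value of
the linear-model t statistic.

## Peak dynamics

Peak sets are `GRanges` with a significance `score`; files follow the BED
convention (0-based half-open) and are converted at the I/O boundary.
Design decisions, stated once:

* overlap means $\ge 1$ shared base, and subtraction removes whole
  features;
* "most significant" ranks by the score column descending, ties broken by
  (chrom, start) for determinism;
* gained peaks between consecutive timepoints are the top-$n$ (default
  100000) of the later set with no overlap to *any* earlier peak; lost
  symmetric. Percents are relative to the realized top-set size;
* peak-to-TSS distance is measured from the interval midpoint,
  `floor((start + end) / 2)` in 0-based coordinates; proximal means
  distance $\le 2000$ bp, inclusive (2000 is proximal, 2001 distal);
* the gene-association window of `peaksNearGenes()` defaults to 50 kb and
  is deliberately surfaced: no canonical value exists, and the counts
  depend on it materially;
* per-gene gained vs lost counts are compared with a two-sided Welch
  t-test;
* conservation averaging computes length-weighted per-base means under a
  piecewise-constant track (uncovered bases score 0) and compares the
  region mean to 49,896 random 2-kb intervals sampled uniformly from the
  genome with chromosomes weighted by length, under a fixed seed.

## The synthetic-data generator

Every stage is testable without downloads because the generators encode
the study conditions as defaults and return their ground truth:

* **time course**: NB counts (single global dispersion, variance
  $\mu + \varphi\mu^2$) over ordered timepoints; at each transition exactly
  `floor(fraction * nGenes)` genes (seeded sample, split evenly up/down)
  carry a $\pm$`lfcMagnitude` log2 effect; gene means follow the
  cumulative effect; per-sample library factors are log-normal with the
  configured CV (mean 1). Defaults: seven ages, 3 replicates, effect
  magnitude 2 (4-fold), baseline means $2^3$–$2^9$, $\varphi = 0.1$,
  library CV 0.1 — chosen as a defensible bulk-RNA-seq regime since the
  source data's effect-size and dispersion distributions are not published;
* **paired series**: exact counts (not per-gene coin flips) of the first
  series' dynamic genes are assigned shared / opposite / flat, so truth
  counts are deterministic. The demo fixtures use shared-up 0.4 and
  shared-down 0.3, the recapitulation regime the concordance stage is
  designed around;
* **single-cell reference**: cluster log-mean archetypes share a latent
  class component so within-class correlation equals the configured value
  in expectation and between-class correlation is near zero; cells are NB
  with log-normal depth;
* **peak universe**: non-overlapping fixed-width intervals placed by
  rejection sampling with a retry cap (a saturated genome raises a
  generation error); a configured fraction is placed with midpoint within
  2 kb of a TSS and the rest strictly farther, so proximal/distal truth is
  exact; per transition exactly `floor(frac * n)` peaks are removed and
  added, and additions avoid the previous set's footprint so gain/loss
  recovery is exact under whole-feature subtraction;
* **score track**: piecewise-constant segments of geometric random length
  with uniform scores, or a constant score for closed-form checks.

What the generators do **not** emulate: read-level artifacts (no
FASTQ/BAM), GC or length bias, per-gene dispersion trends, single-cell
dropout or ambient RNA beyond plain NB sampling, realistic genome sequence
or peak-width distributions, and correlated replicate structure. Passing
tests therefore demonstrate algorithmic correctness and calibration under
the stated model, not robustness to every artifact of real libraries.

## Problem sizes and determinism

The test suite and the acceptance script run simulations at deliberate
desk scale: 2000-gene null and 1000-gene power simulations for the exact
test, 2000-gene/320-cell references with 100 mixtures for deconvolution,
1200-gene paired fixtures and 400-peak universes for the end-to-end run.
These sizes give Monte-Carlo error comfortably inside the asserted
tolerances while keeping a full run in minutes. Every stochastic step is a
pure function of its arguments plus an explicit seed (generators save and
restore the caller's RNG state), and pipeline reruns with the same config
produce identical outputs. TSV and JSON outputs carry a `#`-prefixed
provenance block (tool version, timestamp, seed); BED files are written
without comment headers to stay maximally interoperable with interval
tools.

## Known limitations

* Common (not tagwise) dispersion can over- or under-state significance
  for genes far from the global mean-variance trend.
* The merge threshold of 0.8 groups clusters correctly when within-class
  correlation clearly exceeds between-class correlation; references with a
  correlation continuum need the threshold chosen with the dendrogram in
  hand.
* Whether reference fitting should happen in log or linear expression
  space is genuinely ambiguous; the package fits mean-log profiles (the
  space the merging operates in) and surfaces the choice rather than
  hiding it.
* Headline numbers from the full-scale study (PC1 variance, percent
  dynamic per age, in vivo/in vitro correlation) require the deposited
  datasets; the package reproduces the *procedures* and validates them on
  synthetic ground truth and printed worked examples.
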