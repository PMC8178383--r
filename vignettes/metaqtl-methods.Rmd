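---
title: "Meta-QTL analysis on a consensus map: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meta-QTL analysis on a consensus map: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaqtl)
```

## Why meta-QTL

A published QTL is a noisy interval estimate: its peak position depends
on the study's map, its confidence interval on the population size and
the fraction of phenotypic variance the locus explains. When dozens of
biparental durum wheat populations report QTL for overlapping traits,
the question is which genomic regions those reports jointly support.
Meta-QTL analysis answers it in three steps — put everything on one map,
cluster what co-locates, and let the pooled evidence shrink the
confidence interval — and `metaqtl` implements the three steps plus the
downstream candidate-gene screen as composable, tibble-in/tibble-out
functions.

## Projection

Transfer between maps is *homothetic*: the affine map fixing the two
flanking markers shared between the study map and the consensus map
(`project_position()`). This is exact whenever the two maps are locally
affine between those markers, and it degrades gracefully — a distorted
local expansion rate changes positions inside the interval by at most
the interval's length. QTL whose flanking markers are absent from the
consensus map, or sit on different consensus chromosomes, are not
projected; `project_qtl()` returns them in a rejection table with
reasons rather than silently dropping them.

The projected 95% CI comes from the empirical population-size formula
`CI95 = k / (N R²)` with `k` = 163 (RIL), 287 (DH), 530 (F2, BC). Two
population types in the source material have no stated constant:
backcross inbred lines (BIL) default here to the backcross constant 530
(they are backcross-derived), and populations labelled simply
"biparental" (BP) default to the RIL constant 163 (the BP-labelled
populations in the reference study's own table are populations typed RIL
in their original publications). Both are explicit, overridable
assumptions (`guo_constants(BP = ..., BIL = ...)`). When `N` or `R²` is
missing the CI falls back to the consensus-map distance between the
projected flanking markers — the same convention the reference study
states for unreported CIs.

The peak standard deviation used by the mixture model is
`sd = CI95 / 3.92`, i.e. the CI is read as a two-sided normal 95%
interval (2 × 1.96). The source does not state this conversion; it is
the standard one in the meta-QTL literature and is applied before any
clamping, so a CI that runs past a chromosome end still contributes its
full variance (clamped bounds are kept separately for reporting).
Flanking intervals wider than a third of the chromosome are projected
but flagged `low_confidence`; the flag is informational only.

## The mixture model and EM

Per chromosome, projected peaks follow

$$x_i \sim \sum_{j=1}^{K} \pi_j \, \mathcal N(\mu_j, s_i^2),$$

with the per-QTL variances $s_i^2$ treated as known data. This is the
classical meta-QTL model: the only free parameters are the $K$ component
means and $K-1$ mixing proportions, so $p = 2K - 1$. `fit_mixture()`
maximizes the likelihood by EM; the M-step mean update is the
responsibility- and inverse-variance-weighted average

$$\mu_j = \frac{\sum_i r_{ij} x_i / s_i^2}{\sum_i r_{ij} / s_i^2}.$$

Numerical choices:

* **Convergence** — stop when the log-likelihood improves by `< 1e-8`,
  or after 1000 iterations. The log-likelihood trace is stored and
  asserted non-decreasing in the tests.
* **Initialization** — `restarts = 10` deterministic starts: the first
  places initial means on evenly spaced empirical quantiles of the
  positions, the rest on seeded random quantiles. All seeding goes
  through a helper that restores the caller's RNG state, so fits do not
  perturb user code.
* **Degeneracy** — coincident initial means are nudged apart by 0.1% of
  the data range; a converged fit whose means come within `1e-6` cM is
  recorded as non-identifiable for that `K` and excluded from model
  choice. A component whose responsibility mass vanishes keeps its mean
  instead of producing NaN.
* **Underflow** — all mixture arithmetic is in log space with
  log-sum-exp.

$K$ ranges over `1 .. min(n, 10)` per chromosome (`kmax = 10`; the
densest chromosome in the reference catalogue carries 9 MQTL). The
chosen $K$ minimizes at least three of AIC, AICc, BIC and AWE, with
`AWE = -2 lnL + 2p(3/2 + ln n)` — the form used in the mixture
model-choice literature; "AWE" has variants, so the formula is part of
the package contract (`information_criteria()`). When no $K$ collects
three votes the smallest $K$ among the most-voted wins (parsimony), and
a four-way scatter falls back to the BIC winner. The reference study
does not define behaviour for split votes; this tie-break is our
decision and is documented rather than hidden.

## From components to MQTL

Members are assigned by maximum responsibility. Components with one
member are not MQTL — they route into the grouped/single/unassigned
classification. For a component with $m \ge 2$ members the MQTL peak is
the inverse-variance-weighted member mean and its CI width is
$3.92\,(\sum_i s_i^{-2})^{-1/2}$, which is never wider than any member
CI (pooled-variance inequality, asserted in tests). Flanking markers
are the consensus markers nearest *outside* the CI bounds (terminal
markers when the CI runs off the map), and the physical span is the
distance between their bp anchors; a missing bp anchor makes the span
undefined, which the physical filter treats as a failure with an audited
reason.

Classification uses closed intervals (touching endpoints overlap —
"overlapped" in the source carries no further qualification, so the
conservative reading is used): a QTL is **grouped** when it belongs to
exactly one MQTL, its peak lies inside that MQTL's CI and its CI
overlaps no other MQTL; **unassigned** when its CI overlaps two or more
MQTL or its peak escapes every MQTL CI; **single** when it forms a
lone-member component overlapping nothing. With wide per-QTL CIs and
narrow pooled MQTL CIs the unassigned class is naturally large — the
pooled CI shrinks like $1/\sqrt m$ while member peaks scatter like
$s_i$, so strict peak-inside-CI membership is a demanding criterion.

## Selection thresholds

`selection_config()` defaults: at least 5 member QTL, CI width no larger
than the *current run's mean* MQTL CI (4.9 cM happened to be the
reference study's realized mean; hard-coding it would bake one dataset
into the method), member mean R² at least 0.10 — all inclusive
comparisons, mirroring the "equal to or greater/lower than" wording —
and a *strict* `< 5 Mb` physical span for candidate-gene analysis.
`loffler_select()` and `physical_filter()` both attach a complete audit
table (every comparison, every reason), because the reference study's
own counts ("17 selected" vs 10 rows in its selected table) cannot be
reconciled without seeing which filter removed what.

## Candidate genes

Gene models overlapping the MQTL's flanking-marker interval count under
closed any-overlap semantics (a gene partially inside counts);
transposable elements are excluded by feature type or description
keyword. Expression screens: stress/control fold change is computed per
tissue and stage (so tissue-specific induction is not diluted), with the
control floored at `epsilon = 0.01` tpm and reported folds capped at
1000; the threshold defaults to 2-fold — the source states no number, so
a conventional DEG threshold is used and everything is configurable.
Tissue expression is a strict `tpm > 1` (grain: `> 2`) cut.

## The synthetic scenario

No per-study QTL database is publicly deposited, so the generator
(`sim_config()`, `simulate_metaqtl_study()`) is a first-class module
producing inputs with the structure the pipeline assumes, plus planted
ground truth. Defaults (chosen once, as study conditions, not tuned):

* 3 chromosomes of 160 cM / 600 Mb with 200 markers each (~0.8 cM
  spacing — coarse against a real 30k-marker consensus map but local
  enough that flank intervals are tight);
* 3 clusters per chromosome at 20/50/80% of its length, 8–12 QTL each,
  echoing the reference scale of 11–40 QTL per chromosome;
* populations drawn 70% RIL / 15% DH / 10% BC / 5% BIL with sizes
  85–249, and PVE uniform on (0.05, 0.40) — the spectrum of the
  reference study's population table;
* positional noise `Normal(0, s²)` with `s` implied by the drawn
  population's empirical CI — the exact noise model the mixture assumes;
* study maps that distort every consensus interval by a random factor in
  (0.7, 1.3), making homothetic projection exact by construction, so any
  projection error isolates flank-assignment bugs;
* genes placed uniformly with a 20% TE fraction; planted responsive
  genes at 4-fold induction while background genes fluctuate within
  (0.7, 1.4)× — below any 2-fold screen by construction.

Cluster separation (~48 cM) is far above 8 pooled standard deviations
(~3.5 cM at 10 members), so correct-K recovery is the expected outcome;
the acceptance script measures it at 100 seeded replicates. What passing
these tests does *not* show: robustness to clusters closer than a few
member SDs, to non-normal positional error, to map-order violations
between study and consensus maps, or to the marker-density heterogeneity
of real consensus maps.

## Reference tables and their discrepancies

The packaged transcriptions of the reference study's summary tables
(`reference_mqtl()` and friends) are the ground for the reproduction
tests. Known internal inconsistencies of the source are preserved and
flagged, never corrected: the catalogue contains 27 two-member MQTL and
311 member QTL while the source prose says 26 and implies 318; the durum
gene-count column sums to 456 against a printed total of 436; the
prose's CI-reduction figure (80%) differs from the value recomputed from
its own printed means (80.8%). `summarize_run()` reports recomputed
values. Marker/bp concatenations in the catalogue's rendering were split
using marker-family naming conventions, calibrated so the flanking
distances of all ten selected MQTL reproduce the published Mb values.

## Problem sizes

The default test and acceptance runs use the scales above: ~85–90 QTL
per simulated scenario, $K \le 10$, 10 EM restarts, 100 recovery
replicates — a deliberate scale-down of the reference study's 368-QTL,
14-chromosome dataset that keeps every code path exercised while a full
run of the suite stays in the minutes range on one CPU.

## Limitations

Two-flank homothetic transfer only (no spline or multi-anchor map
integration); one genome at a time for candidate genes (no
durum/bread-wheat homolog linking); no favourable-allele tracking or
GWAS co-location; the mixture is per-chromosome and single-trait-pool —
joint multi-trait models are out of scope.
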