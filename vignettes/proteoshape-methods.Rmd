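---
title: "proteoshape: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{proteoshape: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoshape)
```

This vignette documents the statistical models behind `proteoshape`, the
conventions that make its numbers reproducible to the bit, and the design
decisions taken where more than one reasonable implementation exists.

## The setting

A nitrogen-starvation time course measures the same cells under a deplete
(N−) and a replete (N+) condition at a handful of timepoints (3, 6, 12, 24,
48 h and 10 days in the motivating design), with three biological replicates
each. The proteome arrives as MaxQuant LFQ intensities, the transcriptome as
FPKM. Both layers are reduced to per-gene log2 fold-change trajectories,
log2(N−/N+) per timepoint — *LogetP* for protein, *LogetT* for transcript —
and the scientific questions are (i) what temporal structure the proteome
response has, and (ii) where protein trajectories genuinely diverge from
their transcripts once a plain temporal delay is discounted.

## Preprocessing model

**Missingness.** An LFQ intensity of 0 is MaxQuant's code for "not
quantified in this run", not a measured zero; readers convert zeros to
missing before anything is counted. Missingness in LFQ data is
left-censored: low-abundance proteins drop out first (MNAR).

**Filter.** Proteins quantified too sparsely to compare are removed before
imputation. Two counting semantics exist because the two natural readings of
"quantified in at least half" differ: per *sample* (default: at least
⌈f·n⌉ non-missing samples within each condition, f = 0.5) and per
*timepoint* (a timepoint counts once any replicate is present). Both are
implemented behind `mode =`; the sample-level rule is the default because it
is the stricter and more common Perseus workflow. The filter is monotone in
`min_fraction`, which the test suite checks as a property.

**Imputation.** Missing cells in column *j* are drawn from
N(mean_j − `down_shift`·sd_j, (`width`·sd_j)²) computed over the column's
*present* values — the down-shifted normal model that mimics values at the
detection limit. Defaults `width = 0.3` and `down_shift = 1.8` (both in
column-SD units) are the Perseus defaults. Choices worth making explicit:

* statistics are per sample column, not matrix-wide (each LC–MS run has its
  own depth);
* the column SD uses the sample (n−1) convention;
* one RNG stream, seeded from `seed`, is consumed column-by-column in sample
  order, so imputation is bit-reproducible and independent of row order and
  of which other columns contain missing values;
* a column with fewer than two present values is an error, not a silent
  fallback — its SD is undefined.

**Fold changes and testing.** Replicate means are taken on the log2 scale
(mean of logs, not log of means), then differenced between conditions.
Differential calls use Welch's unequal-variance t per entity per timepoint —
the paper-style "two sample t test" leaves the variance assumption open, and
Welch is the robust default with the pooled form available via
`var_equal = TRUE` — followed by Benjamini–Hochberg adjustment across
entities within each timepoint. BH is used for FDR control because a
permutation-based FDR is not reproducible without the exact permutation
scheme; the q-values are checked against a brute-force step-up oracle in the
tests. Degenerate groups follow a fixed convention: zero variance in both
groups gives p = 1 when the means are equal and p = 0 otherwise, logged when
it happens.

## The shape-based distance

Both series are z-normalized with the population (1/m) variance convention,
so a normalized series of length m has squared norm m and the worked
examples are exact. The coefficient-normalized cross-correlation at shift w
divides the sliding dot product (zero-padded) by the product of the two
norms, which bounds every coefficient in [−1, 1]; SBD is one minus the
maximum coefficient over w ∈ [−(m−1), m−1]. It is computed via FFT and
cross-checked in the tests against a direct O(m²) sliding-dot-product
oracle at 1e−9.

Conventions fixed here:

* **Time axis.** SBD operates on index positions; the unevenly spaced hours
  (3, 6, 12, 24, 48) are treated as equally spaced ranks. Five- or six-point
  series cannot support continuous-time alignment, and the shape-extraction
  algebra is defined on integer shifts.
* **Shift sign.** Positive `best_shift` means the *second* series lags the
  first, so `sbd(transcript, protein)` returns a positive shift for a
  protein trailing its transcript.
* **Ties** at the maximum coefficient resolve to the smallest |shift|, then
  the negative one — so an undelayed pair reports shift 0, never an
  arbitrary ±w.
* **Degenerate (constant) series** carry no shape: distance 0 between two
  constants, and the uninformative midpoint 1 against anything else. This
  avoids NaN propagation while ranking flat-vs-flat as identical.
* Numerical noise is clamped: coefficients are truncated into [−1, 1] and
  ties detected at 1e−12.

**Concordance classes.** The per-gene transcript/protein SBDs are classified
against the 25th/75th percentiles (linear-interpolation quantile, type 7) of
a reference SBD set — by default *all* paired genes, so per-category
fractions are read off subsets against global thresholds; a subset reference
is available via the `reference` argument. Strict inequalities are used at
both thresholds, so tied SBDs fall into the middle class.

**k-shape clustering.** Starting from a seeded random assignment, the
algorithm alternates shape extraction — members aligned to the current
centroid at their optimal SBD shift, new centroid the principal eigenvector
of Q·S·Q with S the aligned scatter matrix and Q the centering matrix, sign
fixed toward the aligned-member mean, then z-normalized — with reassignment
of every profile to its nearest centroid by SBD. Emptied clusters are
reseeded with the profile farthest from its current centroid. The objective
(sum of member SBDs) is recorded per iteration and the tests assert it never
increases; with 40 profiles of length 10 convergence takes 2–3 iterations.

## Hierarchical structure discovery

Row (gene) clustering uses 1 − Spearman correlation between fold-change
profiles — invariant under monotone transforms, in [0, 2], average ranks for
ties, constant profiles pinned at distance 1 and flagged. Column (timepoint)
grouping uses Euclidean distances. Linkage is average by default (the common
heatmap default; complete/ward are accepted) and the cluster count k = 8 is
a given of the analysis design, exposed as a parameter rather than selected
automatically. Sample PCA centers features but does not scale them to unit
variance: log-scale LFQ magnitudes are comparable across proteins and carry
signal.

Category summaries report frequencies, not enrichment tests: counts per
cluster ranked descending (alphabetical tie-break), top five flagged. The
per-category LogetT − LogetP matrix aggregates by mean (median available)
over each layer's own detected genes, because the two layers detect
different subsets — an intersection mode exists for strict same-set
comparisons. Localization consensus is a strict plurality over per-tool
calls with ties reported as `ambiguous`; no precedence order between tools
is assumed, and a manual `override` column wins where present.

## The synthetic generator: what it emulates, and what not

`generate_paired_series()` emulates the delayed-response regime: a base
trajectory per gene (cumulative sum of Gaussian steps — a smooth random
walk, matching the irregular monotone/zigzag profiles real fold-change
clusters show, without committing to a parametric family), and for a chosen
fraction of genes a protein trajectory that is the transcript shifted by
0–2 timepoint indices, edge-padded with its first value (biological
trajectories have no natural zero at the boundary), rescaled by a positive
factor, plus i.i.d. Gaussian noise (default SD 0.2 log2 units, a typical
replicate-level scatter). Independent genes get a fresh walk.
`generate_lfq_matrix()` emulates the LFQ layer: log-normal intensities
around per-entity condition/timepoint means (baseline log2 abundance
N(25, 2²), replicate SD 0.3) and logistic-in-log-intensity dropout,
p_miss = plogis(intercept − slope·log2 intensity), slope ≥ 0 so that low
intensities are the ones lost.

What the generator does *not* model: replicate correlation structure,
intensity-dependent variance, shared regulation across genes, or any real
biology of the starvation response. Passing tests on synthetic data
therefore demonstrate that the algorithms recover planted structure under
the stated noise model — not that real transcript/protein discordance is
fully captured by a delay-plus-noise model.

**Shift identifiability.** A genuinely useful caveat surfaced by the
property tests: exact recovery of a planted delay requires shapes whose
autocorrelation decays with lag and whose content survives the shift.
Smooth random walks on 5-point windows are strongly lag-1 autocorrelated,
so an undelayed alignment of a delayed walk pair often scores as well as
the true shift, and a two-index shift erases 40% of a 5-point window
outright. The shift-recovery tests therefore use interior unimodal (bump)
shapes, where recovery is exact across all tested lengths and delays; for
walk pairs the suite asserts the attainable statement — delayed pairs rank
closer in shape than independent pairs (rank-sum separation), with the
recovered shifts concentrated on {0, delay}. For the same reason the
delayed-vs-independent separation on 5-point walks with delays up to 2 is
real but partial; fully reliable truth recovery needs longer series or
delays confined to one index.

## Problem sizes and reproducibility

The test suite runs on fixture sizes chosen to exercise every code path
while keeping the default run under half a minute: 10⁴ random pairs for the
coefficient bound, 10³ pairs (m ≤ 64) for the FFT-vs-oracle check, 10⁵
draws for the imputation-moment check, 400 paired trajectories for the
end-to-end concordance run, 40 profiles for planted k-shape recovery, and a
60-gene two-layer pipeline run. All randomness flows through explicit
integer seeds into private RNG streams (the global `.Random.seed` is never
touched by package code), and the pipeline manifest records every seed,
parameter and per-stage count needed to re-execute a run bit-identically.

## Known limitations

* SBD's index-rank time axis ignores the actual spacing of the hours; a
  one-index delay means "one sampling interval", which is 3 h early in the
  course and ~8 days at the end.
* The quartile classification is relative by construction: a quarter of the
  reference set is always "highly similar", whatever the absolute
  concordance level.
* k-shape with k far from the truth converges but the objective plateaus
  are not compared across k; no automatic model selection is provided.
* The Welch/BH pipeline treats timepoints independently; no longitudinal
  model (splines, mixed effects) is fitted.
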