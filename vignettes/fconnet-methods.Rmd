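---
title: "Methods: from regional BOLD signals to group differences in network topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from regional BOLD signals to group differences in network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fconnet)
```

## Overview

`fconnet` implements a complete resting-state functional-connectivity
analysis for a two-arm (treatment vs. manual placebo), three-session
(baseline T0, post-treatment T1, follow-up T2) repeated-measures design:

1. **Confound removal** — RETROICOR-style Fourier regression of cardiac and
   respiratory artifacts, frame-wise displacement (FWD) regression, then
   demeaning, detrending, de-spiking and band-pass filtering;
2. **Connectome construction** — atlas parcellation (AAL, 116 regions),
   squared-correlation similarity, percolation (connectedness-preserving)
   thresholding, and four node metrics: strength, eigenvector centrality,
   weighted betweenness and weighted clustering;
3. **Group inference** — per-node mixed-design repeated-measures ANOVA with
   the group-by-time interaction, a baseline-controlled change-score
   contrast, Benjamini–Hochberg FDR correction, dysfunction-count
   correlations, Mann–Whitney, summary-statistic t and chi-square tests,
   and a noncentral-t power analysis for paired designs;
4. **Synthesis** — a generator of cohorts with known covariance structure
   and planted group-by-time network effects, so that every downstream
   stage can be validated end to end without access to subject data.

The trial this design emulates deposited no imaging data, so all empirical
claims the package makes about itself are claims about its behaviour on
synthetic cohorts; the generator is therefore first-class, tested code, and
its assumptions are spelled out below.

## The synthetic signal model

Regional BOLD signals are modelled as a stationary Gaussian vector AR(1)
process: node signals $x_t = \phi\, x_{t-1} + \varepsilon_t$ with
$\varepsilon_t \sim N\!\big(0, (1-\phi^2)\,\Sigma\big)$, so the lag-0
covariance equals the model covariance $\Sigma$ exactly and each node has
lag-1 autocorrelation $\phi$ (default 0.3, a typical value for TR = 3 s
resting-state data after high-pass filtering). This is deliberately a
*stand-in*: no published signal model exists for the emulated study, and
the Gaussian AR(1) choice captures the two properties that matter for the
pipeline — a controlled cross-correlation structure and temporal
autocorrelation — while ignoring hemodynamic convolution, scanner physics,
non-stationarity and spatial signal leakage. Conclusions from passing tests
are about pipeline correctness and statistical calibration, not about the
biological realism of the simulator.

$\Sigma$ is a modular correlation matrix: nodes are assigned to 8
contiguous modules; within-module correlations are drawn from
$U(0.35, 0.6)$ and between-module correlations from $U(0.05, 0.2)$ —
ranges in line with reported parcel-level resting-state correlations — and
the matrix is projected to the nearest positive-definite correlation matrix
by eigenvalue clipping (floor $10^{-4}$) and rescaling to unit diagonal.

**Planted effects** perturb $\Sigma$ for one (group, timepoint) condition;
metrics are never manipulated directly, so recovering a planted effect
exercises the full path simulation → cleaning → graph → ANOVA:

* `clustering_down` / `clustering_up` scale (toward 0, or toward 0.8) the
  correlations **among the target node's within-module neighbours**,
  thinning or thickening its neighbourhood without touching its own edges —
  the weighted clustering coefficient responds while strength is nearly
  unchanged.
* `betweenness_up` strengthens the target node's correlations with a few
  (4) nodes in *every* module toward 0.75, making it an inter-module
  shortcut that weighted shortest paths must cross. An earlier design that
  bridged only two modules produced betweenness shifts comparable to the
  baseline variability of shortest-path routing and was discarded in favour
  of the shortcut form.
* `betweenness_down` scales all of the target node's correlations by
  $1 - m$, pushing it to the periphery.

The default magnitude is $m = 0.5$. The default effect set mirrors the
emulated trial's findings (`trial_effects()`): betweenness up in the right
precentral gyrus and clustering down in the left amygdala and left middle
temporal gyrus at T1; betweenness down in the left caudate and clustering
up in the left amygdala and vermis III at T2 — all in the treated arm.

Physiological contamination adds the first two harmonics of cardiac
(1.1 Hz) and respiratory (0.3 Hz) phase to every region, with
region-specific phase offsets and second-harmonic amplitude at half the
first. Instantaneous rates are slowly modulated (3% and 5% sinusoidal
variation over ~3 and ~2 minutes) to emulate heart-rate and breathing
variability. This matters beyond realism: with strictly constant rates on
a TR = 3 s grid, the aliased interaction frequencies (cardiac ±
respiratory) coincide exactly with aliased harmonic frequencies and the
12-column RETROICOR design becomes rank-deficient. The design reports that
degeneracy when it occurs, and the regression drops collinear columns, but
the default simulator does not produce it. Motion is two slow sinusoids
per rigid-body parameter (drift ≤ 0.1 mm / 0.002 rad) plus single-volume
spikes at 2% of volumes.

The default cohort reproduces the trial's shape: 15 + 15 subjects, three
sessions of 240 volumes at TR = 3 s (first five discarded), demographics
standardized to the published group means/SDs, and the published attrition
(2 placebo subjects unusable from T0, 1 treated from T1, 2 treated + 1
placebo at T2), leaving 12 + 12 complete cases.

## Preprocessing choices

The stage order is fixed: discard initial volumes → confound regression
(RETROICOR + FWD and its backward difference, plus intercept) → demean →
linear detrend → de-spike → band-pass. Choices where the field's
conventions had to be pinned down:

* **RETROICOR interaction terms**: sine and cosine of the sum and
  difference phases (cardiac ± respiratory) — the standard 4-term
  multiplicative set completing the 12-column design.
* **FWD**: sum of absolute backward differences of the three translations
  plus rotations converted to arc length at a 50 mm head radius; first
  volume 0.
* **De-spiking**: clipping at robust z (median/MAD) 4, preserving sign.
  Clipping (rather than interpolation) is monotone, idempotent and
  preserves alignment.
* **Band-pass**: 4th-order Butterworth, 0.01–0.15 Hz, applied
  forward-backward (`signal::filtfilt`) for zero phase; the effective
  response is the squared magnitude. The suite verifies ≤5% amplitude
  error at 0.05 Hz and ≥80% attenuation at 0.005 Hz on TR = 3 s series.
* **Regression level**: confound regression runs at whatever level the
  input is supplied (the linear algebra is identical); the default
  pipeline applies it to ROI series. Low-frequency heart-rate / breathing-rate
  effects are available as optional sliding-window (9-volume) rate
  regressors (`rate_design()`), off by default: the published variants of
  this correction differ in their response models, so only the windowed
  rates themselves are offered and no convolved response is modelled.
* Rank-deficient designs are handled by pivoted QR: collinear columns are
  dropped with a warning naming them, and residuals are exactly orthogonal
  to the retained regressors.

## Connectome construction

Similarity is the **squared** Pearson correlation, so strong negative
coupling counts as strong coupling — the squaring deliberately discards
sign, accommodating hemodynamically inverted couplings. The similarity
matrix is thresholded at the **largest** value τ for which the retained
graph (edges with $w \ge \tau$) still spans all 116 nodes in one
component. τ is located by binary search over the sorted distinct edge
weights; equality $w = \tau$ is retained; weights are kept, not binarized
(the downstream metrics are all weighted). τ equals the bottleneck edge of
the maximum spanning tree, and the suite asserts that equivalence against
`igraph::mst` on random matrices, plus maximality (the next candidate
threshold disconnects the graph) on every tested run.

Node metrics on the thresholded weighted graph:

* **strength** $s_i = \sum_j w_{ij}$ (the weighted reading of degree
  centrality; the binary degree at τ is emitted as a secondary column);
* **eigenvector centrality**: entries of the principal eigenvector of $W$
  (non-negative by Perron–Frobenius on a connected non-negative matrix),
  unit Euclidean norm, computed by dense symmetric eigendecomposition;
* **betweenness**: weighted shortest-path betweenness with edge length
  $1/w$ (the standard similarity-to-length mapping), normalized by
  $(N-1)(N-2)/2$, ties counted fractionally; validated against an
  exhaustive all-simple-paths oracle on graphs of ≤8 nodes;
* **clustering**: the Onnela geometric-mean form
  $C_i = \frac{1}{k_i(k_i-1)} \sum_{j \ne h} (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}$
  with $\hat w = w / \max(w)$ normalized within the graph, $C_i = 0$ for
  $k_i < 2$; validated against a direct triple loop.

## Group inference

The per-node, per-metric test is the classical split-plot decomposition
with group as the between-subject factor and session as the
within-subject factor, computed on **complete cases** (subjects observed
at all three sessions; the emulated analysis's integer df imply the same
choice). The reported statistic is the group-by-time interaction
$F\big((t-1)(k-1),\,(N-k)(t-1)\big)$ — $F(2, 32)$ at 18 complete
subjects. The sums of squares are computed in vectorized form across all
node-metric columns at once (mass-univariate, the same strategy
neuroimaging linear-model packages use); `stats::aov` with an
`Error(subject/session)` stratum serves as the independent oracle in the
tests, to $10^{-10}$. No sphericity correction is applied by default, for
the same integer-df reason.

FDR correction is Benjamini–Hochberg across the 116 nodes **within each
metric** (`fdr_by = "all"` pools across metrics instead). The post-hoc
baseline-controlled contrast computes per-subject change scores
$\Delta = m(E) - m(B)$ for a session pair and compares arms with a Welch
t test; its `delta` is treated-minus-placebo, positive when treatment
increased the metric more than placebo. The dysfunction correlation is
Pearson by default (Spearman by flag) between treated subjects'
somatic-dysfunction counts and their change scores. The Mann–Whitney test
uses the exact U distribution for small tie-free samples, otherwise the
tie-corrected normal approximation. The paired-design power analysis
iterates $n$ upward through the noncentral t distribution
(noncentrality $d\sqrt n$, df $n-1$) and returns the smallest $n$
reaching the target power; one-tailed at $d = 0.55$, $\alpha = 0.05$,
power 0.80 this gives $n = 22$.

```{r}
paired_sample_size(effect_size_d = 0.55, alpha = 0.05, power = 0.80,
                   tails = 1)
```

## Numerical conventions and degenerate inputs

* All generators are bit-reproducible under a fixed seed; the pipeline
  derives per-(subject, session, stage) seeds from the master seed, all
  below $2^{31}$.
* Constant node series make correlation undefined: `similarity_matrix()`
  errors naming the offending node. A node with no positive-weight edge
  cannot be connected: `percolation_threshold()` errors rather than
  returning a disconnected graph.
* Covariance perturbations that break positive-definiteness are
  re-projected; if projection cannot produce a valid correlation matrix
  the magnitude is rejected with an error.
* Ties in the threshold search are resolved by retaining edges with
  $w = \tau$; candidate thresholds are observed weights only.
* `parcellate()` requires every expected label to own at least one voxel
  and errors naming missing labels.

## What the test suite establishes (and at what scale)

The long-running properties run at these problem sizes, chosen to give
stable Monte-Carlo estimates at desk scale:

* **Null calibration**: 100 cohorts of the default shape (12 + 12
  complete cases) with no planted effects, no physiological/motion
  injection (the inferential stage is the thing under test); the fraction
  of per-node interaction tests with $p < 0.05$ must lie in
  $[0.03, 0.07]$, and the mean fraction FDR-significant must be ≤ 0.05.
* **Recovery**: 50 cohorts with the trial effect set at magnitude 0.5;
  the three T1-planted targets must all be FDR-significant in ≥ 80% of
  runs.
* **Full-pipeline effect propagation**: 50 paired runs (with
  physiological and motion contamination and full cleaning) must show the
  planted clustering drop at the left amygdala in ≥ 45 of 50 pairs.
* **Cleaning recovery**: over 20 seeds, the correlation matrix of cleaned
  contaminated data must be closer (Frobenius) to the generating
  correlations than that of the contaminated data in ≥ 18.

Because only sampling noise separates subjects (there is no
between-subject covariance heterogeneity in the generator), these
simulations are *easier* than real cohorts; the recovery rates say the
pipeline transmits planted covariance effects faithfully, not that a real
study of this size would have that power.

## Known limitations

* No hemodynamic response model, no voxel-level spatial structure beyond
  the toy parcellation volumes, no motion-by-signal coupling: the motion
  regressors in the simulator are pure nuisance traces, uncorrelated with
  the signal, so FWD regression is exercised but its real-data benefit is
  not measured.
* Spatial preprocessing (registration, smoothing, slice timing) is out of
  scope; inputs are assumed ROI-resolvable.
* The repeated-measures ANOVA is the classical univariate F without
  sphericity correction; a Greenhouse–Geisser option would change p values
  for strongly non-spherical data.
* Global metrics (path length, modularity, efficiency) and dynamic
  (sliding-window) connectivity are intentionally absent.
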