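---
title: "Communication regimes in brain structural-functional networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Communication regimes in brain structural-functional networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(braincomm)
library(dplyr)
```

## The model

braincomm treats the brain as a communication system in Shannon's sense:
messages travel between regions over a fixed physical substrate — the
structural connectome — while the amount of communication actually taking
place is read off the functional side. Two assumptions anchor everything:

1. two regions can exchange information *directly* only if they are
   structurally connected by white-matter streamlines;
2. the amount of communication between structurally connected regions is
   their functional coupling, measured as the mutual information (MI)
   between their BOLD time series, in bits.

The structural connectome is an N×N symmetric matrix of mean streamline
lengths in millimeters, used unthresholded and unbinarized; a zero entry
encodes an absent connection, never a zero-length one. Communication
channels are approximated by fiber-length shortest paths
`(S, K1, ..., Km, T)`, minimized directly on millimeters.

Two path-level scores are computed for every ordered source–target pair.

**Path processing score (PPS).** With `MI(S, K1)` the coupling of the
source to its first relay, the score accumulates, over every post-source
node `i` of the geodesic,

```
PPS = sum_{i in (K1, ..., Km, T)} [ MI(S, K1) - MI(S, i) ]
```

(the `K1` term is identically zero). It is a relaxation of the data
processing inequality (DPI): along a Markov chain, processing cannot
increase information about the source, so `MI(S, i)` should not exceed
`MI(S, K1)` on a path that is genuinely in use. A PPS near zero means the
signal arrived nearly intact (*relay* communication); a large positive PPS
means it was substantially transformed (*transducted*); a negative PPS
means information about the source *increased* down the path, evidence
the path is not the channel actually used (*absent* communication). PPS
is undefined on single-edge geodesics (*direct* communication) and is
nonsymmetric in (S, T).

**Path broadcasting strength (PBS).** Search information evaluated on
functional weights over the structural geodesic: with `MI_i` the MI of
the edge leaving node `i` along the path and `W_i` node i's structurally
masked MI strength (`W_i = sum over structural neighbors j of MI(i, j)`),

```
PBS_raw = -log2( prod_{i in (S, K1, ..., Km)} MI_i / W_i )      [bits]
PBS     = PBS_raw / |path length in mm|                          [bits/mm]
```

Each ratio `MI_i / W_i` is the share of node i's total structurally
supported coupling that flows along the path edge, so `PBS_raw >= 0`
always (the path edge is one of the strength's own summands). Low PBS
means routing — the signal stays on the path; high PBS means
broadcasting — it also spreads into edges adjacent to the path. Dividing
by millimeters removes the mechanical advantage of longer paths and
fixes the reported unit at bits/mm.

Per-region *nodal broadcasting strengths* aggregate PBS within a regime:
`WBS_sender(k)` sums PBS over pairs with k as source, `WBS_receiver(k)`
over pairs with k as target, and the symmetric `WBS` is their average,
exactly. The sender/receiver split exposes directional asymmetries even
though MI itself is symmetric, because the denominators `W_i` along a
path depend on which endpoint sends.

## Parameters that matter

* **MI binning** (`binning_scheme()`): bins of width 0.5 SD spanning
  \[-3.5, 3.5\] z-score units (14 bins) on z-scored series. Z-scoring uses
  the population SD; the convention is immaterial at realistic T but is
  fixed for bit-for-bit reproducibility. Bin edges are half-open with the
  last bin closed, and out-of-range samples are clipped into the boundary
  bins rather than dropped — the range covers >99.9% of Gaussian mass, so
  clipping preserves T at negligible cost. `bin_sensitivity()` re-estimates
  the connectome at widths 0.5/0.75/1/2 and reports cross-width agreement;
  widths that do not divide the span (0.75) get a final truncated bin.
* **Relay boundaries** (`regime_boundaries()`): the relay regime is the
  closed PPS interval \[-0.04, 0.07\] bits by default — the 5th/95th
  percentiles of the resting-state default-mode-network PPS distribution,
  the published operating point. `estimate_boundaries()` recomputes them
  from any within-network PPS distribution (pool subjects by row-binding
  their scored tables first); it refuses fewer than 20 defined values and
  degenerate distributions. Endpoint inclusivity is not dictated by the
  construction; the closed interval was chosen so that an exactly zero
  PPS is always relay.
* **PPS summand anchor**: the default keeps `MI(S, K1)` as the reference
  in every summand, which is the printed form of the score and agrees
  with its 3-node special case `MI(S,X) - MI(S,T)`. A telescoping
  consecutive-difference reading (`mode = "telescoping"`), which collapses
  to `MI(S,K1) - MI(S,T)` for any length, is available as a non-default
  mode; the two coincide on 2-edge paths.
* **PBS denominator**: the default divides by the full `W_i`, the printed
  form. Classical search information discounts the arrival edge at
  intermediate nodes; that variant is available via
  `exclude_incoming = TRUE`.

## Numerical choices

* **Shortest-path ties.** PPS and PBS depend on the chosen node sequence,
  so tie-breaking must be deterministic: among equal-length paths the one
  with fewer hops wins, then the lexicographically smallest node-index
  sequence. Each unordered pair is resolved once from its lower-index
  endpoint and the reverse orientation is the exact reversal — a
  lexicographic rule applied independently from both ends would not
  guarantee that. Length comparisons are exact double comparisons; ties
  that arise only through floating-point coincidence are still resolved
  deterministically.
* **MI arithmetic.** MI is computed as `H(X) + H(Y) - H(X,Y)` from the
  joint histogram, which makes `MI(X;X) = H(X)` exact in floating point;
  tiny negative rounding residues are clamped to zero. The diagonal of
  the functional connectome stores `H(i)` and is excluded from all
  strength and path computations.
* **Degenerate inputs.** Constant time courses abort z-scoring with the
  region named; zero-MI path edges produce an infinite-PBS marker that is
  excluded from WBS sums (with the exclusion count attached and a
  warning); structurally disconnected pairs carry a `disconnected` marker
  rather than raising.
* **Group averaging.** The subject average of structural connectomes is
  the mean over subjects in which an edge is present (zero means absent,
  not 0 mm); the retention threshold is configurable (`min_fraction`,
  default: present in one subject suffices) because the literature's
  "group average" does not pin this down.

## What the synthetic generator emulates — and what it does not

`synth_structural()` places regions uniformly in a 100 mm box and
connects pairs within a 60 mm radius, with Euclidean length as the edge
weight. Euclidean weights are metric, so direct edges are their own
geodesics and hand verification is possible; `length_noise_sd > 0`
breaks the metric structure to exercise multi-edge geodesics between
structurally adjacent pairs, which real tractography lengths produce.
`synth_gaussian_timeseries()` draws from a multivariate Gaussian with
prescribed correlation, giving every pair the analytic ground truth
`MI = -1/2 log2(1 - rho^2)`; `synth_markov_chain()` builds an AR(1)
telephone-game chain (`corr(source, node j) = hop_rho^(j-1)`) whose
Markov property makes the DPI hold exactly in distribution. All
generators use base R's Mersenne-Twister under `set.seed(seed)`; the
seed is part of the public contract.

These fixtures are Gaussian, stationary and hemodynamics-free: they
validate the estimators and the score algebra, not the neuroscience.
Passing tests show the machinery computes what it claims on data whose
truth is known — they do not show that real BOLD obeys the model's
assumptions, and no cohort-scale empirical values (e.g. per-regime mean
WBS magnitudes from imaging studies) are reproduced at desk scale.

The packaged 374-region atlas mirrors the structure of the standard
multimodal parcellation (360 cortical regions across the seven Yeo
networks, 14 subcortical regions) but its cortical region names are
synthetic placeholders — it is a stand-in for a label table that cannot
be redistributed here, and is named accordingly.

## Estimator bias, and why the analytic oracle is missed at high rho

The plug-in histogram estimator targets the MI of the *discretized* pair,
not of the underlying continuous variables. Two biases matter:

* plug-in (finite-T) bias, positive, roughly `(B-1)^2 / (2 T ln 2)` bits
  for B×B cells — about 0.24 bits at T = 500 and 0.0024 at T = 50,000
  under the default 14 bins;
* quantization bias, negative and T-independent: the exact MI of the
  binned bivariate Gaussian (computed in `binned_gaussian_mi()` by
  numerical integration, independently of the estimator) falls short of
  `-1/2 log2(1 - rho^2)` by about 0.010 bits at rho = 0.5, 0.050 at
  rho = 0.8 and 0.115 at rho = 0.9.

Consequently the estimator matches `binned_gaussian_mi()` to a few
thousandths of a bit at T = 1e5 for all |rho| <= 0.9, but can never come
within 0.05 bits of the *continuous* analytic value at rho >= 0.8 under
the default binning; the acceptance suite asserts the continuous-oracle
band anyway and documents the failure rather than widening it. For the
same reason the error against the analytic value decays monotonically
with T only while the plug-in bias dominates; the consistency test uses
rho in {0.2, 0.3, 0.4}, where it does.

## Problem sizes used in the tests

The suite runs entirely on synthetic data: 5–12-region graphs for path
and score algebra (100 seeded instances against brute-force enumeration
and product-form oracles), T = 1e5 two-region series for estimator
calibration, and 100 seeded 5-node chains at T = 5,000 for the DPI and
relay-recovery simulations. These sizes make every oracle exhaustively
checkable; the implementation itself accepts full 374-region inputs.

## A worked toy example

```{r}
fx <- toy_fixture()
ca <- communication_analysis(fx$sc, fx$fc, parcellation = fx$parcellation)
glance(ca)
tidy(ca) |> filter(source == "A")
```

The A→E geodesic is A→B→C→E (30 mm). Its PPS is
`(0.8-0.8) + (0.8-0.5) + (0.8-0.2) = 0.9` bits — transducted under the
default boundaries — and its raw PBS is
`-log2((0.8/1.2)(0.9/2.0)(0.7/1.6)) ≈ 2.93` bits, i.e. ≈ 0.098 bits/mm.

```{r, fig.width = 6, fig.height = 4}
autoplot(ca)
autoplot(broadcast_strengths(ca$pairs, "direct"), k = 5)
```

## Known limitations

* MI is static and lag-free: no transfer entropy, lagged or multivariate
  information measures, and no time-resolved functional connectivity.
* Only geodesics are scored; path ensembles, navigation and
  communicability are out of scope.
* The quantization bias discussed above caps agreement with continuous
  Gaussian MI at high correlation under the default binning.
* Regime boundaries inherit the arbitrariness of their reference
  distribution; only the within-network percentile construction is
  provided, not alternative null models.
* Statistical comparison of sender/receiver asymmetries is left to the
  caller; `asymmetry_summary()` emits the per-node vectors a rank test
  needs but runs no test itself.
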