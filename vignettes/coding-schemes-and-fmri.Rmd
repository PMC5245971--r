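---
title: "Which neural coding schemes could fMRI recover? Methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Which neural coding schemes could fMRI recover? Methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmricode)
```

## The question

Functional MRI measures the BOLD signal, a proxy of neural activity that is
summed over space (on the order of a million neurons per voxel) and over time
(seconds). Despite this coarse sampling, representational similarity analysis
(RSA) routinely recovers the similarity structure of stimulus sets from voxel
patterns. That empirical success constrains the neural code: it can only
happen if the code is *functionally smooth*, i.e. if similar stimuli map to
similar internal representations,

$$\mathrm{sim}(x_1, x_2) \propto \mathrm{sim}(y_1, y_2), \qquad y_i = f(x_i),$$

with Pearson correlation serving both as the similarity measure and as the
measure of proportionality. This package simulates the measurement process
for a family of candidate coding schemes `f` and quantifies, for each, how
much similarity structure a simulated scanner could recover.

Functional smoothness is distinct from spatial (super-voxel) smoothness: a
random linear map scrambles the spatial layout completely while preserving
pairwise similarities, and a spatially smooth map can carry no stimulus
similarity at all. The package's voxel-summation module
(`spatial_summate()`, `temporal_summate()`, `voxel_inhomogeneity()`)
demonstrates the complementary *sampling* limits: activity patterns finer
than the voxel grid sum away (all voxels equal, zero inhomogeneity), and
burst structure in spike trains is invisible to temporal integration because
equal event totals give equal window sums.

## The stimulus model

Stimuli are abstract activity vectors, not images. A category **prototype**
is `dim = 100` independent draws from a standard normal, z-normalized to
mean 0 and standard deviation 1. Each of 19 **distortions** at level
$i = 1, \dots, 19$ adds fresh independent Gaussian noise with standard
deviation $0.05\,i$ to the prototype and re-normalizes, so every item has
identical first and second moments regardless of distortion level. Input
similarity to the prototype then decays smoothly with level — approximately
$1/\sqrt{1 + (0.05 i)^2}$ at large `dim` — which is exactly the graded
structure an encoder must preserve for RSA to work.

Two conventions here were genuinely open and are worth stating:

* **Normalization** uses the population standard deviation (divide by $n$),
  so "sd = 1" is literal for each item; the sample convention is available
  via `znormalize(type = "sample")`. Pearson similarity is unaffected either
  way.
* **Noise schedule.** The incremental schedule ("each level's sd is the
  previous plus 0.05") is read as *fresh* noise of sd $0.05\,i$ added to the
  prototype at each level, so distortions are conditionally independent given
  the prototype. The alternative — a random walk where level-$i$ noise is
  added to the previous distortion — is available as
  `generate_distortions(cumulative = TRUE)`; it decays faster at high levels
  and is tested but not the default.

## The coding schemes

Eleven models form the main roster (`model_roster()`), ordered from simplest
to deepest:

1. **Vector space** — the identity; the control for which the smoothness
   statistic is exactly 1.
2. **Gain control** — elementwise `tanh`; monotone, hence smooth.
3. **Matrix multiplication** — one linear layer `W x` with standard-normal
   weights; spatially scrambled but similarity-preserving in expectation.
4. **Perceptron** — `tanh(W x)`, the single-layer network.
5.–11. **2- to 8-layer networks** — stacked perceptrons
   `y_k = tanh(W_k y_{k-1})`; the simulated scanner reads only the final
   layer.

All networks are untrained: weights are standard-normal, square
(`dim × dim`), with no bias terms. On a given replication the depth-$k$
models share the first $k$ layers of one 8-layer stack, so differences
between models reflect depth, not weight resampling. Note that with
z-scored 100-dimensional inputs the pre-activations `W x` have standard
deviation ≈ 10, so `tanh` operates deep in saturation from the first layer
on; representations drift toward the hypercube corners (mean |activation|
above 0.9 by layer 8), which is precisely the mechanism that erodes
similarity structure with depth.

Two engineered codes bracket the network family:

* **Factorial design coding** (`build_factorial_design()`,
  `encode_factorial()`): an item described by $n$ binary factors is
  represented by the corresponding row of the $2^n \times 2^n$ two-level
  full factorial design matrix (intercept, main effects, all interactions;
  rows in Yates order, columns ordered by interaction order then
  lexicographically). Every pair of distinct rows has dot product exactly
  zero — `run_factorial_proof()` verifies this in integer arithmetic and
  checks $QQ^\top = Q^\top Q = I$ for the $\sqrt{2^n}$-normalized matrix —
  so the code is invertible yet carries *no* graded similarity: items
  differing in one factor are as dissimilar as items differing in all.
  The encoder deliberately accepts only ±1 factor vectors; mapping
  continuous stimuli into it is not defined by the design and is left out.
* **Hash coding** (`encode_hash()`): each element is serialized to a
  canonical round-trip decimal string (`%.17g`), hashed with SHA-1, and the
  20 digest bytes mapped to reals in $[-1, 1]$. Deterministic and
  invertible-in-principle via table lookup, but by construction any change
  to any element decorrelates its digest block entirely, so similarity
  structure is destroyed. The serialization choice is a documented
  convention; any canonical encoding gives statistically identical results
  because only the pseudo-randomness of the digest matters.

## The smoothness statistic and its aggregation

`functional_smoothness()` computes, for a list of stimulus pairs, the input
similarities and the output similarities, and returns their Pearson
correlation. The default pair set for a stimulus set is the 19
(prototype, distortion) pairs; self-pairs are excluded by construction.
Pairs whose encoded representation is constant (possible in principle under
full saturation) are excluded with a logged count rather than imputed — an
imputed 0 would bias the statistic — and the result records the raw
similarity lists so the statistic is recomputable from its own report.

Aggregation across the 100 replications was a genuinely open choice, so both
modes are implemented and always reported:

* `per_network_mean` (default): the statistic per network over its 19 pairs,
  then averaged. This treats each random network as one draw from the
  ensemble of codes.
* `pooled`: all $100 \times 19$ pairs in a single correlation. This mixes
  between-network variation into the similarity lists and runs a point or
  two lower.

An `all_pairs` option widens the pair set to all 190 distinct item pairs per
replication. It lowers the statistic further at depth (distortion–distortion
pairs have less input-similarity range and noisier output similarities) and
is provided because the phrase "all item pairs" is ambiguous between the two
readings; the default is the prototype-anchored reading.

## Numerical and reproducibility choices

* **Seeding.** Every experiment takes one master seed; each replication
  derives sub-seeds for prototype, noise, and weights through a fixed
  integer mix (`derive_seed()`) that stays below $2^{31}$ and is exact in
  double arithmetic. Whole-pipeline runs are bit-reproducible, and reports
  written with the same seed are byte-identical.
* **Degenerate inputs** (constant vectors, undersized dimensions,
  non-binary factor settings, non-finite hash inputs, indivisible voxel
  grids) raise classed errors rather than returning sentinel values; the
  voxel functions offer an explicit `edge = "truncate"` escape because
  silent partial voxels would break the conservation guarantees.
* **Null bands in the hash demonstration.** The similarity curve's band is a
  *simultaneous* 95% band across the 19 levels, built from the permutation
  null of the per-level mean via the max-statistic construction — the claim
  under test is "every level is at chance", which is one family-wise
  hypothesis, and a pointwise band would be expected to fail somewhere by
  construction. The smoothness statistic's band is the permutation
  distribution of the mean statistic across replications (pairings shuffled
  within every replication).
* **Saturation and exact bounds.** `tanh` outputs can round to exactly
  ±1.0 in double precision; tests and invariants therefore use closed
  bounds.

## What the generator does and does not emulate

The synthetic design captures the core logic — graded, known input
similarity passed through a candidate code and read back by correlation —
under idealized conditions: isotropic Gaussian stimuli, exact per-item
moment matching, untrained random weights, no measurement noise, no
haemodynamic blurring, and a scanner that reads single units rather than
voxel sums. Passing results therefore show what a coding scheme makes
*possible in principle* for fMRI, not what a real acquisition would achieve;
real stimuli have category structure beyond one prototype, real networks are
trained, and real voxels add the spatial summation this package demonstrates
separately. The RSA machinery accepts externally produced activation tables
(`rsa_from_activations()`), so layer-wise analyses of trained networks can
be run on exported activations; shipping or running such networks is out of
scope here, and the sparseness measure that accompanies those analyses
(`gini_sparseness()`) is validated on closed-form cases instead.

## Problem sizes

The reference protocol (100 networks, 19 levels, dim 100) runs in about a
second and is used directly by the acceptance checks. Unit tests exercise
scaled-down runs (5 networks) for pipeline mechanics, 100-replication loops
for distributional properties, a 10,000-draw Monte-Carlo oracle for the
similarity-decay law, and 20 hash replications against 1,000-permutation
null bands.

## Known limitations

* The depth-wise smoothness decline is reported for the saturated-tanh
  regime that the protocol's scales imply; rescaled weights (e.g. variance
  $1/\mathrm{dim}$) would saturate less and decline more slowly, and no such
  rescaling is offered because the protocol fixes unit-variance weights.
* Only `tanh` is offered as the non-linearity; the factorial encoder takes
  binary factor vectors only; no training, convolution, pooling, or
  haemodynamic forward model is included.
* The Gini coefficient uses the standard sorted mean-absolute-difference
  form on absolute activations; other sparseness measures are not provided.
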