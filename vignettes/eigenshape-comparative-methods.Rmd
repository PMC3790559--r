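---
title: "Eigenshape morphometrics and phylogenetic comparative methods in esmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigenshape morphometrics and phylogenetic comparative methods in esmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esmorph)
```

`esmorph` implements the analysis chain used in clade-level ecomorphology
studies of a single skeletal element: digitized 2-D outlines are reduced
to eigenshape axes, and the per-species scores are analyzed on a
time-calibrated phylogeny — phylomorphospace, disparity through time
against a Brownian-motion null, evolutionary model selection, PGLS against
ecological covariates — together with specimen-level quality statistics.
This vignette is the package's account of the methods: the models and
their assumptions, the tunable parameters, the numerical choices, what the
synthetic generator does and does not emulate, and the limitations we know
about.

## From outline to shape function

An outline is an ordered, implicitly closed loop of (x, y) coordinates
with a designated starting landmark — in the motivating application a
curvature maximum on the dorsal margin of the opercle, fixed at
digitization time. Processing makes three standardizations, in order:

1. **Equidistant resampling** (`resample_equidistant`, default
   `p = 100` points). The closed polygon is traversed from the starting
   landmark and points are placed at equal arc length by linear
   interpolation of the cumulative chord length. We deliberately do not
   spline-smooth first: linear interpolation on the digitized polygon is
   the most direct reading of "equidistant points along the outline", and
   smoothing would introduce a bandwidth parameter whose value the
   downstream statistics would inherit invisibly. `p` trades angular
   resolution against noise averaging; 100 points resolve features of
   roughly 1/100 of the perimeter, ample for a smooth bone margin.
2. **Orientation.** Traversal is standardized to counter-clockwise by the
   sign of the polygon's signed area; clockwise input is reversed keeping
   the start point first. Digitizers are inconsistent about handedness,
   and the tangent-angle representation is not mirror-invariant, so this
   must be fixed before any comparison.
3. **Tangent angles** (`zahn_roskies`). With unit steps between the `p`
   resampled points, the step directions θ(j) are accumulated with each
   increment wrapped into (−π, π] — plain `atan2` differences would jump
   by ±2π at branch cuts on concave outlines — and the shape function is
   φ\*(j) = θ(j) − θ(0) − 2πj/p, the net angular deviation from a circle
   traversed at the same rate. φ\*(0) = 0 by construction; a regular
   polygon gives φ\* ≡ 0 to machine precision, which the test suite uses
   as the circle reference. φ\* is invariant to translation, rotation and
   scale; size is carried separately as perimeter and centroid size.

One known departure from the historical FORTRAN implementations: no
optimization of the starting point is performed. The start landmark is
taken from the digitizer (it is biologically homologous by construction),
so specimens are compared at fixed parameterization rather than at the
alignment-optimal offset.

## Eigenshape decomposition

The n × p matrix of φ\* vectors is column-mean-centered and decomposed by
SVD. This is exactly the eigenanalysis of the covariance matrix of shape
functions: axes (right singular vectors) are mutually orthonormal, scores
are projections of the centered specimens, eigenvalues are squared
singular values over n − 1, and variance fractions are eigenvalues over
their total. SVD signs are arbitrary, so each axis is flipped to make its
largest-magnitude loading positive; scores are then reproducible across
runs and platforms. Axis count is capped at min(n − 1, p), the rank of
the centered matrix.

Axis selection uses the broken-stick rule: axis k is retained when its
variance fraction strictly exceeds b_k = (1/p′) Σ_{i=k..p′} 1/i, with p′
the number of nonzero-variance axes, stopping at the first failure. The
strict inequality means fractions exactly at the broken-stick expectation
count as noise.

Shape models (`reconstruct_outline`) invert the transform by integrating
unit steps of length perimeter/p at directions φ\*(j) + 2πj/p. The
integrated path does not close exactly for an arbitrary φ\* vector, so the
closure gap is spread linearly over the points. This makes reconstruction
a slightly lossy inverse: round-tripping a model through `zahn_roskies`
reproduces φ\* to about 1e−3 RMS, which is far below the between-specimen
differences the models are drawn to illustrate.

## Phylomorphospace

Ancestral states per axis are maximum-likelihood estimates under BM,
computed exactly by solving the sparse linear system in which each
internal node is the inverse-branch-length-weighted mean of its
neighbors; this is the weighted squared-change parsimony solution, and the
test suite checks it against both brute-force numerical minimization and
an independent ML implementation. Consequences worth knowing: states are
linear in the tip values and always lie within the tip range, so a
phylomorphospace can never show an ancestor outside the convex hull of
its descendants' axis ranges. Species means (not specimens) are
projected, matching how the comparative analyses consume the scores;
specimen-level spread is the business of the ANOVA/CVA layer instead. No
confidence regions on ancestral positions are drawn — the projection is a
visualization, not an inference.

## Disparity through time and MDI

Disparity is the average pairwise Euclidean distance among species in
score space (`pairwise_disparity`). A mean *squared* distance variant is
available (`squared = TRUE`) because reference implementations of the DTT
method default to it; the plain-distance form is our default since it is
what the motivating studies report. With plain distances a subclade's
disparity can exceed the whole clade's, so relative disparities are not
bounded by 1 and no such assertion is made.

The observed curve evaluates, at each internal node age in ascending
order, the mean over all lineages crossing that age of (disparity of the
lineage's eventual tip descendants) / (whole-clade disparity). At the
root the whole clade is the only lineage, so the curve starts at exactly
1. The curve is evaluated at node ages only — no interpolation grid — and
times are reported relative to tree depth (0 = root, 1 = tips).

The null envelope simulates multivariate BM on the same tree. The rate
matrix is estimated from the data as the cross-product of
phylogenetically independent contrasts over n − 1, i.e. the full
evolutionary covariance of the score columns, preserving their
correlations rather than simulating each axis independently. MDI is the
trapezoid-rule signed area between the observed curve and the pointwise
null median, restricted to relative times ≤ 1 − truncation. The default
truncation of 0.2 omits the most recent 20% of the time axis, where
incomplete species sampling inflates apparent subclade disparity
("tip overdispersion"). Positive MDI means more disparity in the recent
fauna than the BM expectation. MDI is invariant to uniform rescaling of
the scores, and for BM-simulated data its mean is zero to within
Monte-Carlo error — both are tested.

Per-clade disparity sums per-tip contributions (each tip's mean squared
distance to all other tips, normalized by the whole-sample mean so
contributions average 1) within clades, then standardizes by the number
of sampled species per clade. The normalization is a convention — the
published analyses we mirror print only the clade sums — and is
documented as such; the per-species standardization (clade value /
species count) is independent of it.

## Evolutionary models

Three single-trait models are fit to species means, all through one BM
pruning engine:

- **BM**: tip covariance σ²·(shared path length). Two parameters (σ²,
  root state z0), both profiled analytically: z0 is the GLS root
  estimate produced by the pruning pass and σ̂² = RSS/n (ML).
- **OU**: fixed root, single optimum tied to the root state. Covariance
  σ²/(2α)·(1 − e^(−2αs))·e^(−2α(T−s)) for shared time s and depth T,
  implemented exactly as BM on a node-height-transformed tree. The
  alternative stationary-root OU (root drawn from the stationary
  distribution) is not the default because the single-global-optimum,
  fixed-root form is the one the motivating analyses fit; α → 0 reduces
  analytically to BM. Fitting α uses a log-spaced grid from 10⁻³/T to
  50/T (plus 0) refined by golden-section search; at α = 50/T the
  half-life of phylogenetic signal is ~1.4% of tree depth,
  indistinguishable from white noise at 25 tips, so the bound costs no
  realism. A fit ending at the bound is flagged `converged = FALSE`.
- **EB**: rates decline as σ²e^(at), a ≤ 0, implemented by the branch
  transform (e^(a·t2) − e^(a·t1))/a. The lower bound a = log(10⁻⁵)/T
  (a 100 000-fold decline) is configurable.

Parameter counts are BM = 2, OU = 3, EB = 3, and AICc uses n = number of
species. Comparison reports Δᵢ = AICcᵢ − min AICc and Akaike weights
exp(−Δᵢ/2)/Σ exp(−Δⱼ/2); `compare_models` also accepts a bare AICc vector
so printed values from the literature can be re-weighted. Degenerate
inputs (constant traits) are reported with `converged = FALSE` and σ̂² at
the 0 boundary, never silently.

A caution from our own synthetic experiments: specimen averaging and
digitizing noise add a non-phylogenetic variance component to species
means, which the OU model absorbs via large α. Strong OU support on real
outline scores can therefore reflect measurement noise as much as
stabilizing selection; the repeatability stage exists to quantify that
component.

## PGLS and group statistics

PGLS fixes the residual correlation to the BM structure (tree covariance
scaled by depth; no Pagel's λ estimation) and solves the GLS by Cholesky
whitening. Complete cases only: species missing the response or a
predictor are pruned from the tree and listed in the result, mirroring
how isotope coverage is usually a subset of the morphometric sample. The
regression direction is isotope value on score axes, and because "r²" is
ambiguous in GLS we report both a sums-of-squares r² against the
intercept-only GLS model and the likelihood-ratio generalized r²,
1 − exp(−2(logL₁ − logL₀)/n). The overall test is the GLS F-test.

Per-axis ANOVAs multiply each p-value by the number of axes tested
(Bonferroni), with pairwise Welch t-tests (Bonferroni within axis) post
hoc; when a group contains a single specimen the Welch test is undefined
and pooled-variance pairwise tests are used instead. ANOVA degrees of
freedom follow the standard one-way decomposition (N − g). CVA solves
W⁻¹B, retains min(g − 1, k) functions, scales coefficients to unit pooled
within-group variance, and tests successive roots with Bartlett's χ²
approximation to Wilks' Λ. Repeatability is the classic one-way
variance-component estimator with the unbalanced-design effective
replicate count n0; negative among-individual components are clamped to
0, so R ∈ [0, 1] always.

## The synthetic generator

The generator exists to give every stage a ground truth. Its defaults
encode the study conditions the pipeline is meant for: 25 species in 4
clades on an ultrametric pure-birth tree of depth 23 time units, 1–12
specimens per species, 100-point outlines, a single shape axis evolving
by BM (σ² = 1), isotopes coupled to that axis with slope 0.5 ‰ per trait
unit and 0.5 ‰ residual noise. Outlines are a convex Fourier template
(curvature maximum at the start landmark) deformed along one smooth
radial mode in proportion to the species' axis value (axis values are
standardized to unit sd and scaled by `clade_effect_size`, keeping the
deformation in the small-perturbation regime), plus independent radial
Gaussian noise per point. Everything is a pure function of (config,
seed); identical inputs give byte-identical files.

What it does not emulate, hence what passing tests do not show about real
data: digitizing error is modeled as independent radial Gaussian noise —
real tracing error is autocorrelated along the outline and no published
distribution exists for it, so this is an explicit assumption; real bones
vary along many correlated modes, not one; there is no allometry or
ontogenetic series (the motivating studies excluded juveniles); and the
tree is pure-birth rather than a literature phylogeny, although any user
Newick is accepted. Recovery results (ES1 capturing the generating mode,
parameter recovery, DTT self-consistency) validate the machinery, not the
biology.

## Problem sizes and reproducibility

The validation experiments run at sizes chosen to make Monte-Carlo error
small relative to the tolerances being checked: likelihood oracles on 100
random trees of ≤ 10 tips; parameter recovery with 200 replicates on
100-tip trees (median σ̂² and α̂ against generating values); DTT
self-consistency with 200 replicates of 8-trait BM data on a 25-tip tree
against 500-simulation envelopes; 10 000-replicate checks of the
simulators' variance structure on 2–3-tip trees. The acceptance script
(`scripts/acceptance.R`) re-runs a 100-replicate version of each
experiment from a single `--seed` and writes the resulting quantities as
JSON.

## Known limitations

- Outlines only: no landmark/Procrustes machinery, no sliding
  semilandmarks, no 3-D.
- Univariate evolutionary models; axes are fitted one at a time, so
  correlated evolution across axes is visible to the DTT null (through
  the contrasts rate matrix) but not to the model-selection layer.
- No measurement-error term inside the BM/OU/EB likelihoods; see the OU
  caution above.
- The BM correlation in PGLS is fixed, not estimated; if residuals are
  far from BM the standard errors inherit that misspecification.
- MDI is reported without a significance test, as in the analyses this
  package mirrors; the simulation envelope is returned so users can rank
  the observed curve if they wish.
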