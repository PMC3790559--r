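# esmorph

Outline-based geometric morphometrics and phylogenetic comparative
analysis for closed 2-D bone outlines, written for ecomorphology studies
in which a single skeletal element — the motivating case is the opercle,
the craniofacial bone supporting the gill cover in fishes — is digitized
across the species of a radiation and analyzed against a time-calibrated
phylogeny and ecological covariates such as stable-isotope values.

## What it computes

**Eigenshape analysis.** Each specimen's outline (a TPS file block from an
outline digitizer) is resampled to *p* equidistant semilandmarks starting
at a fixed landmark, standardized to counter-clockwise traversal, and
converted to the circle-normalized Zahn–Roskies tangent-angle function

φ\*(j) = θ(j) − θ(0) − 2πj/p,

which is invariant to rotation, translation and scale. The specimen ×
point matrix of φ\* values is mean-centered and decomposed by SVD; the
right singular vectors are the eigenshape axes ES1, ES2, …, each specimen
gets a score per axis, and the broken-stick rule selects the axes that
carry more variance than expected from random partitioning. Shape models
along any axis are reconstructed back into outline coordinates.

**Phylogenetic comparative layer.** Per-species mean scores feed:

- *Phylomorphospace*: ML-under-BM ancestral states (equivalently weighted
  squared-change parsimony) project internal nodes into any plane of axes.
- *Disparity through time*: at each internal node age, the mean relative
  subclade disparity (average pairwise Euclidean distance of each crossing
  lineage's descendants over the whole-clade disparity) is compared to a
  Brownian-motion simulation envelope whose rate matrix is estimated from
  independent contrasts; the MDI statistic is the signed area between the
  observed curve and the null median, with the most recent 20% of the
  time axis truncated.
- *Model selection*: BM, single-optimum OU and early-burst models are fit
  by ML (pruning likelihood, analytic profiling of the root state and
  rate) and compared by AICc differences and Akaike weights
  w_i = exp(−Δ_i/2) / Σ_j exp(−Δ_j/2).
- *PGLS*: isotope values (δ13C, δ15N in ‰) regressed on score axes under
  BM residual covariance.
- *Sample quality*: per-axis ANOVA with Bonferroni correction, canonical
  variates analysis with Wilks' Λ, and measurement-error repeatability
  R = s²_among / (s²_among + s²_within) from replicated digitizations.

A synthetic-data generator (pure-birth trees, BM/OU/EB traits, parametric
outlines with one known deformation mode, coupled isotope tables) provides
ground truth for every stage.

## Worked example

```r
library(esmorph)

# a synthetic study: 25 species in 4 clades, shape axis evolving by BM
cfg <- synthetic_config(seed = 42)
ds  <- generate_dataset(cfg, dir = "study")

res <- run_pipeline(pipeline_config(
  tps = "study/outlines.tps", tree = "study/tree.nwk",
  specimens = "study/specimens.csv", isotopes = "study/isotopes.csv",
  output_dir = "study_out", dtt_n_sim = 1000, dtt_seed = 1))
```

The run log prints (values for this seed):

```
read 176 outlines, 25 species, tree depth 23
eigenshape: 100 axes, 2 significant under broken-stick, ES1 = 69.0%
DTT: MDI = 0.0959 (1000 simulations, truncation 20%)
model fitting ES1: best = OU (weight 1.000)
model fitting ES2: best = OU (weight 1.000)
PGLS d13C ~ ES1-8: n = 25 (0 species excluded, no isotope data), F(8, 16) = 29.248, p = 3.898e-08
PGLS d15N ~ ES1-8: n = 25 (0 species excluded, no isotope data), F(8, 16) = 9.898, p = 6.478e-05
```

Reading: the single generated deformation mode dominates shape variance
(ES1 = 69.0% here; with digitizing noise switched off it exceeds 99%), the
broken-stick rule keeps two axes, MDI slightly above 0 means disparity in
the recent fauna is a bit higher than the BM expectation for this draw,
and the PGLS recovers the isotope–shape coupling built into the generator
(both isotopes were coupled to the ES1 axis, hence the small p-values).
`study_out/` contains the scores, loadings, phylomorphospace coordinates,
DTT curve, model-comparison and PGLS tables as CSV, plus the serialized
config and run log that make the run reproducible.

Individual stages are plain functions if you prefer not to use the
pipeline: `read_tps()`, `resample_equidistant()`, `zahn_roskies()`,
`eigenshape()`, `broken_stick()`, `phylomorphospace()`,
`disparity_through_time()`, `fit_trait_model()`, `compare_models()`,
`pgls()`, `anova_per_axis()`, `cva_wilks()`, `repeatability()`.

## Vignette

`vignettes/eigenshape-comparative-methods.Rmd` documents the models, the
numerical choices (resampling, angle unwrapping, optimizer bounds,
tie-breaks), what the synthetic generator does and does not emulate, and
the package's known limitations.
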