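---
title: "DECyt: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DECyt: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decyt)
```

This vignette is the package's own account of the method: what is modeled,
which knobs matter, why the defaults are what they are, and where the
method's statistical guarantees genuinely end.

## The procedure

Given per-sample event tables over a shared marker panel and a two-level
condition (reference first, e.g. young vs aged):

1. **Transform.** Each raw intensity `x` becomes `asinh(x / cofactor)`.
2. **Pool and cluster.** Events from all samples are pooled (optionally
   subsampled per sample), a hierarchical tree is built with Ward linkage
   on Euclidean distances, and the tree is cut at a height or into `k`
   clusters. Events left out of the pool get the label of the nearest
   cluster centroid (median vector).
3. **Count.** The clusters-by-samples table of cell counts is the data for
   inference; within-sample relative counts are only used for display.
4. **Test.** Each cluster's counts are modeled as negative binomial with a
   log link, size-factor offsets and a condition coefficient; the
   coefficient's Wald z gives a two-sided normal p-value, adjusted by
   Benjamini–Hochberg across clusters.
5. **Report.** Three aligned heatmap panels: per-cluster marker medians
   (phenotype), per-sample relative counts, and the enrichment direction
   for clusters below the significance threshold.

## Parameters and defaults

| parameter | default | meaning and rationale |
|---|---|---|
| `transform.cofactor` | 150 | arcsinh scaling, dimensionless fluorescence units; the conventional choice for fluorescence-based (non-mass) cytometry. The raw scale would let bright channels dominate Euclidean distances. Per-marker values accepted. |
| `clustering.linkage` | `ward` | Ward's criterion on Euclidean distances (`hclust` method `ward.D2`, i.e. proper Ward on unsquared distances). Ward favours compact spherical clusters, matching the discrete phenotype blocks a marker-median heatmap displays. `average` and `complete` are available. |
| `clustering.k` | 15 | number of subpopulations after the cut; a height cut is the alternative (`--height`). 15 matches the granularity at which distinct high/low phenotype combinations of a 7-marker panel remain interpretable. |
| `clustering.per_sample_cap` | 1000 | events per sample entering the tree. Agglomerative clustering stores an O(n²) distance matrix: 9 × 1000 pooled events need ~0.3 GiB and seconds; pooling all 9 × 10,000 events would need ~32 GiB, which is why back-assignment exists. `cap: none` gives the exact tree when memory allows. |
| `test.sig_threshold` | 0.05 | adjusted-p cutoff for the significance strip. |
| `test.shrink_dispersion` | off | optional shrinkage of log-dispersions toward their mean. Off by default: with ~15 clusters there is little information for empirical-Bayes pooling, and shrinkage changes per-cluster estimates materially only when dispersions are noisy (see *Limitations*). |
| `seed` | 1 | fixes subsampling and simulation; identical seed + config reproduces every output byte for byte. |

## The count model in detail

Size factors are median-of-ratios: `s_j = median_c K[c,j] / g_c` over rows
positive in all samples, `g_c` the row geometric mean. No further
renormalization is applied, so the *ratios* of size factors are the
meaningful quantities: scaling one sample's counts by `c` scales its factor
relative to the others by exactly `c`, and a common rescaling of all
factors shifts every offset equally and is absorbed by the intercept.
If no row is all-positive (extremely sparse tables), the package falls back
to column-total ratios with a warning.

Per-cluster dispersion `alpha` (variance `mu + alpha mu^2`) maximizes the
Cox–Reid adjusted profile likelihood: at each candidate `alpha` the GLM
coefficients are profiled out by IRLS and `-0.5 log det(X'WX)` corrects the
plug-in bias. The search runs on `log alpha` over `[log 1e-8, log 10]` with
a golden-section tolerance of 1e-3; because the optimizer never probes the
exact interval ends, the profile is also evaluated at both boundaries and
the best of the three wins, so Poisson-like clusters report exactly the
floor. If the profile cannot be evaluated, a method-of-moments estimate is
used with a warning. A consequence of using the *adjusted* likelihood is
worth knowing: on truly Poisson data about half the estimates sit at the
floor and the rest are tiny but positive — the adjustment removes the
downward bias that would otherwise park them all at zero.

The GLM itself is a two-column design (intercept + condition indicator)
fitted by IRLS with weights `mu / (1 + alpha mu)`; coefficients are clipped
at ±50 so separated designs (one condition all zeros) terminate with an
enormous standard error rather than diverging. All-zero clusters are
reported as NA and excluded from the BH denominator. No fold-change
shrinkage and no independent filtering are applied.

## Determinism and tie-breaking

Cluster ids are assigned 1..n by decreasing size, ties broken by the lowest
pooled row index; nearest-centroid ties go to the lowest cluster id;
subsampling sorts the drawn indices so event order is preserved. These
conventions make label assignments and output files identical across reruns
and platforms for a fixed seed and config.

## What the synthetic generator does and does not emulate

`default_paper_like_truth()` mirrors the study design this method was built
for: 5 reference ("young") vs 4 non-reference ("aged") mice, 10,000 cells
per mouse, 7 markers, 15 Gaussian populations (diagonal covariance,
SD 0.35 on the transformed scale) whose mean vectors are high/low phenotype
archetypes of cardiac stroma — immune CD45+, endothelial CD31+, and
Sca-1+ PDGFRα+ stromal populations split by CD90/CD73/CD34. Between-mouse
variability is Dirichlet-multinomial with concentration 200: each mouse's
population mix is drawn around its condition's mix, producing the
extra-multinomial count variance the NB test must face (for a population at
frequency p the implied NB dispersion is roughly `(1-p) / (p * 201)`, i.e.
~0.07 for a 7% population and several-fold larger for rare ones).

Planted differential abundance: the major (15%) CD90-high stromal
population is halved in the aged-like condition; two CD90-low stromal
populations and a rare CD31+CD90+ population are doubled. The folds and
base proportions are chosen so the fold-weighted proportions still sum
to 1 (*mass balance*): renormalization then leaves every unshifted
population exactly at its reference frequency. Without this, a planted
shift would make *all* other populations truly differential after
renormalization and "sensitivity" and "FDR" would have no clean ground
truth — a standard pitfall of compositional benchmarks.

Not emulated: marker correlations within populations, spillover, doublets,
acquisition drift, and batch effects. Passing the recovery tests therefore
shows the pipeline is correct under clean mixture structure; it does not
show robustness to instrument artifacts, which should be handled upstream.

## Problem sizes used by the test-suite simulations

Calibration and recovery properties are measured at the design's sample
sizes (5 vs 4, 15 clusters, concentration 200): 2,000 null replicates and
200 planted-shift replicates at the count level (the abundance stage does
not need event-level simulation), and 20 event-level replicates of 9 × 800
cells with a 200-event cap for clustering recovery. The end-to-end check
runs the full 9 × 10,000-cell fixture twice.

## Known limitations

- **Small-sample Wald calibration.** With 9 samples, the NB Wald z against
  N(0,1) is anticonservative even when the dispersion is known exactly, and
  estimating a per-cluster dispersion from 9 counts adds noise that
  inflates the small-p tail further. The packaged calibration test measures
  this directly (it is the one the suite reports as failing its nominal
  band), and `scripts/acceptance.R` reports the measured type-I error so
  users can see the inflation rather than trust the nominal level. The
  same inflation leaks into BH-level FDR for planted-shift recovery.
  Enabling `test.shrink_dispersion` reduces (not removes) it. Users needing
  exact finite-sample error control at n≈9 should treat q-values near the
  threshold with caution or confirm by permutation.
- **Power for rare populations.** Dirichlet-multinomial noise grows as
  populations get rarer, so 2-fold shifts in populations under ~4% of cells
  are genuinely hard at 5 vs 4 mice; the packaged fixture deliberately
  includes one such population.
- **Tree scalability.** The exact tree is O(n²) memory; the default relies
  on subsample + back-assignment, which is exact only as far as cluster
  shapes are captured by their median centroids.
- **Two-level designs only.** No covariates, no multi-factor models, no
  likelihood-ratio tests.
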