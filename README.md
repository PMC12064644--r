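# wingmorph

Landmark-based geometric morphometrics of honey bee (*Apis mellifera*)
forewings, built for population-level questions about Africanized honey
bees: how strongly do populations diverge in wing shape, does shape track
geography, how many groups are present without using labels, and to which
Old World evolutionary lineage (A, C, M, O) does an unknown sample belong?

The package is aimed at researchers analysing wing venation data — tables
of digitized landmark coordinates (the standard here is 19 vein-junction
landmarks per forewing) with colony, site and geographic metadata — and at
anyone who wants a fully synthetic, truth-known testbed for this kind of
analysis.

## What it computes

Let each wing be a configuration of k = 19 planar landmarks. The pipeline:

1. **Generalized Procrustes analysis (GPA).** Each configuration is
   centered, scaled to unit centroid size `CS = sqrt(Σᵢ ‖xᵢ − x̄‖²)`, and
   rotated (reflection-free, det R = +1) onto an iteratively refined
   consensus; coordinates are then projected orthogonally onto the tangent
   space at the consensus. For 2-D data this removes exactly four degrees
   of freedom, so the covariance of aligned 19-landmark shapes has exactly
   4 zero eigenvalues and 34 informative dimensions.
2. **Analysis units.** Workers from one colony are not independent, so
   aligned coordinates are averaged within colonies
   (`average_within_groups`); single wings collected along a transect are
   pooled into consecutive 10-wing samples ordered along the dominant
   geographic axis (`chunk_transect`).
3. **Ordination.** PCA of the unit mean shapes (34 components retained;
   the clustering stage uses the leading components explaining 95% of
   variance) and PCoA (classical scaling) of distance matrices.
4. **Classification and divergence.** Linear discriminant analysis in the
   truncated PC space with the unbiased pooled within-group covariance W
   (divisor n − g) and equal priors; leave-one-out cross-validation;
   pairwise Mahalanobis distances
   `D(a,b) = sqrt((μa − μb)ᵀ W⁻¹ (μa − μb))`; MANOVA (Pillai trace) with
   permutation-tested pairwise comparisons.
5. **Shape-on-geography regression.** Sequential multivariate regression
   of shape on latitude then longitude, with residual-randomization
   permutation (RRPP) p-values.
6. **Model-based clustering.** Gaussian mixtures over six covariance
   families (spherical/diagonal/full × equal/varying), EM from a
   deterministic Ward initialization, model selected by
   `BIC = 2 logL − npar·log n`.
7. **Lineage assignment.** A reference panel (consensus + PC basis +
   discriminant model over lineages A, C, M, O) stored as a portable text
   file; unknowns are aligned to the panel consensus and receive
   classification probabilities `∝ exp(−D²c/2)` rescaled to sum to one.
8. **Synthetic data.** `simulate_dataset()` generates the whole hierarchy
   (populations at an exact target pairwise Mahalanobis separation,
   colonies of 12 workers, digitization noise, a latitude-linked shape
   gradient, random image rotations/scales) with the generating truth
   returned, enabling parameter-recovery validation.

## Worked example

```r
library(wingmorph)

sim <- simulate_dataset(synthetic_config(
  n_populations = 4, colonies_per_population = 40,
  workers_per_colony = 12, pairwise_D = 7, seed = 102))
fit  <- align_gpa(sim$dataset)              # GPA + tangent projection
st   <- average_within_groups(fit, "colony_id")
pca  <- shape_pca(st$mean_shapes, m_retain = 34)
conf <- loocv_lda(pca$scores, st$meta$population)
dist <- mahalanobis_pairwise(fit_lda(pca$scores, st$meta$population))
round(dist, 2)
```

```
      pop_1 pop_2 pop_3 pop_4
pop_1  0.00  8.25  7.72  7.17
pop_2  8.25  0.00  8.24  7.56
pop_3  7.72  8.24  0.00  7.15
pop_4  7.17  7.56  7.15  0.00
```

Every pair was generated at true separation D = 7; the estimates are
inflated by a few percent because W is estimated in 34 dimensions from
40 colony means per population (the bias shrinks with more colonies).
The cross-validated confusion matrix for the same data is almost
diagonal (99.4% overall accuracy), and regressing the Mexico-like
transect dataset (one population, 245 colonies, latitude gradient on)
gives:

```
      term  df        SS        MS      F p_perm
  latitude   1 0.0103146 0.0103146 15.952  0.001
 longitude   1 0.0006214 0.0006214  0.961  0.524
```

— the injected latitude gradient is recovered at the permutation floor
(p = 1/(999+1)), while longitude, which carries no signal, is null.

The numbered scripts under `analysis/` run this workflow end to end
(simulate → align/average → population divergence → geography →
clustering → lineage assignment), writing labeled CSV tables under
`results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

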