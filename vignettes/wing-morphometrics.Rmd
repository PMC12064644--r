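---
title: "Wing geometric morphometrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wing geometric morphometrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingmorph)
```

This vignette is the package's own account of the statistical machinery
it implements: the shape model and its assumptions, the parameters that
matter and their defaults, what the synthetic-data generator does and
does not emulate, and the choices made where the design was genuinely
open.

## The shape model

A wing is a configuration of k = 19 labelled planar landmarks at vein
junctions; landmark order is anatomically meaningful and fixed.
Differences in position, orientation and size are nuisance variation:
what remains after removing them is *shape*.

`align_gpa()` performs partial Procrustes superimposition. Each
configuration is translated to the origin, scaled to unit centroid size
(the square root of summed squared landmark distances from the
centroid), and rotated onto an evolving consensus by the reflection-free
orthogonal solution (SVD with a determinant correction, so mirrored
wings are *never* silently unmirrored — a mirrored image is a data
error this package refuses to hide). The consensus is recomputed as the
renormalized mean and the sweep repeats until it moves less than `tol`.
After convergence a final rotation pass superimposes everything on the
converged consensus.

With `project = TRUE` (default) the aligned rows are orthogonally
projected onto the tangent space at the consensus,
`x ↦ x − (x·c − 1)c`. Centering removes the two translation directions
exactly and the optimal rotation annihilates the rotation direction
exactly; the projection removes the scale direction. For 2-D data the
aligned covariance therefore has *exactly* four null eigenvalues — for
19 landmarks, 34 informative dimensions out of 38. This is why
downstream analyses retain 34 principal components by default: the
truncation is lossless. Without projection the rank deficiency is only
approximate, which is the reason projection is on by default.

Assumptions worth stating: variation is small relative to the consensus
(so the tangent-space linearization is accurate — with shape noise at
the 0.5–2% of centroid size typical of digitized wings, linearization
error is second order); landmarks are complete (missing landmarks are
rejected, not imputed); and data are 2-D (no semilandmarks, no 3-D).

### Numerical choices

* Initial consensus: the first configuration after centering/scaling.
  Any starting point converges to the same fixed point up to a global
  rotation; results are reported in that fitted frame.
* `tol = 1e-8` on consensus Procrustes movement, `max_iter = 100`.
  Non-convergence is recorded as a flag and warning, not an error.
* Degenerate rotation ties (equal singular values) resolve by the
  canonical SVD convention plus the determinant correction, making
  output deterministic.
* Eigenvector signs in `shape_pca()` and discriminant axes in
  `fit_lda()` are fixed so the largest-magnitude loading is positive;
  classification ties break to the earlier class in label order.

## Analysis units

Workers from one colony share ancestry, so the independent unit is the
colony: `average_within_groups()` takes coordinate-wise means of aligned
rows, averaging latitude/longitude and taking modal categorical labels.
For transect collections of single wings, `chunk_transect()` orders
specimens along the first principal axis of their (latitude, longitude)
scatter — ties broken by latitude, longitude, then specimen id, so chunk
membership is independent of file row order — and cuts consecutive
blocks of 10, the final block keeping the remainder (177 wings give 18
samples with a final 7; 99 give 10 with a final 9). Pooling by
collection order instead of geography would be equally defensible; the
geographic rule was chosen because such transects are quasi-linear, and
it is the deterministic, order-free reading.

## Classification and divergence

All discriminant computation happens in truncated PC space (default 34
components) to keep the pooled within-group covariance W well
conditioned; W uses the unbiased divisor n − g. Priors are equal across
classes by default because class sample sizes reflect sampling effort,
not prevalence; proportional priors are available. Classification
probabilities are `prior · exp(−D²/2)` rescaled to sum to one, with D²
the squared Mahalanobis distance under W — evaluated in log space so
well-separated classes do not underflow. Pairwise population divergence
is the Mahalanobis distance between class means under W, which is
invariant to any affine transformation of the score space (so it does
not matter whether it is computed in PC space or discriminant space when
no dimensions are discarded).

Leave-one-out cross-validation refits the model for every held-out
sample; it exists because discriminant separation is optimistically
biased when dimensions are many and samples few.

## Permutation tests

`regress_shape_rrpp()` decomposes the total squared coordinate variation
sequentially (type I) over covariates in the order given — latitude
first for geographic models, since a latitudinal cline is the leading
hypothesis. Each term's F is referenced to a null distribution obtained
by permuting the *reduced-model residuals* (RRPP): the fitted values of
the model with all preceding terms are kept, residuals are shuffled and
added back, and F recomputed; `p = (b + 1)/(n_perm + 1)`, so the
smallest attainable p is 1/(n_perm + 1). Default `n_perm = 999` (floor
0.001). F is invariant to affine rescaling of covariates, so degrees
versus radians is immaterial.

`manova_populations()` reports the Pillai trace with its standard F
approximation for the overall test, and permutation p-values (default
`n_perm = 9999`, floor 0.0001) for each pair of groups, recomputing the
two-group Pillai statistic under label permutation. Exhaustive
enumeration over all label assignments is available for small groups.
The pairwise matrix is returned unadjusted — matching the convention of
reporting raw pairwise values — with Bonferroni/Holm available through
`adjust`. Each pairwise test needs an invertible total SSCP, so the
component count must stay below the smallest pair's sample count minus
two; the pipeline caps it automatically.

## Model-based clustering

`fit_gmm()` implements EM over six canonical covariance families —
spherical, diagonal and full, each either shared or varying across
components. Initialization is the agglomerative Ward partition of the
features, which is deterministic: a fixed (seed, data) pair yields a
bit-identical model. `select_model_bic()` fits every (K, family)
combination and keeps the maximum of `BIC = 2 logL − npar log n`,
returning the full BIC table. Restricting to six families (rather than
every orientation-constrained variant in the wider mixture literature)
covers the structures that differ materially for PCA scores, whose axes
are already variance-ordered.

Guard rails: an empty component triggers one restart from perturbed
responsibilities, then an error; a singular component covariance
receives a diagonal floor of 1e-8 × the mean feature variance and the
fit is flagged `regularized`; per-component full covariances require at
least m + 1 effective members per component, otherwise that fit is
recorded as failed in the BIC table instead of producing a degenerate
likelihood spike.

Clustering runs on the leading components explaining 95% of variance —
the threshold, not a fixed count, is the contract; on typical wing data
this lands near 18–30 components depending on the noise spectrum.

## The lineage panel

A reference panel bundles a consensus shape, a truncated PC basis and a
discriminant model over evolutionary-lineage labels, serialized to a
versioned plain-text format so panels can be shared *without*
redistributing raw reference coordinates (the historical lineage
reference collections are not freely redistributable; every panel in
this package's tests is synthetic). `assign_lineages()` aligns an
unknown onto the panel consensus — so assignment is invariant to rigid
motion and scale of the input — projects it into the basis, and returns
rescaled probabilities. The softmax-of-distances rule is a documented
choice: it preserves the ranking of the underlying class densities and
its argmax equals the maximum-density class, which is what matters for
assignment; absolute probability calibration between differently built
panels is not claimed. A caution inherent to forced-choice assignment:
hybrids between two lineages are typically absorbed by the nearer
parent with only mildly elevated minor-parent probability, so "assigned
to lineage A" must not be read as "pure lineage A".

## The synthetic generator

`simulate_dataset()` emulates the hierarchical sampling design the
analysis assumes: populations → colonies (default 12 workers each, the
typical field sample) → workers, plus per-landmark digitization noise
and random image rotation/translation/scale that the alignment must
undo. Population effects, colony effects and the latitude gradient are
drawn in the tangent space at a fixed built-in wing template (a
synthetic but geometrically plausible 19-landmark venation layout — it
carries no claim of being a measured wing), orthogonal to the
translation/rotation/scale generators. Because of that, the target
pairwise Mahalanobis separation `pairwise_D` is *exact* at the
colony-mean level: population mean offsets are scaled orthonormal
directions with `‖μa − μb‖ = D · s`, where
`s² = colony_sd² + (worker_sd² + digitization_sd²)/workers` is the
colony-mean variance per tangent coordinate.

Default noise scales (template centroid size 1): `colony_sd = 0.004`,
`worker_sd = 0.006`, `digitization_sd = 0.003` — digitization error
about half the biological worker variation, and colony-level variance a
bit below worker-level, the regime reported for digitized insect wings.
The default latitude gradient (0.01 per degree along a fixed tangent
direction) is calibrated so the geographic signal-to-noise at a couple
hundred colonies resembles published transect analyses (multivariate F
near 10). Populations occupy adjacent longitude bands but share the
latitude range, so the gradient adds within-population variance without
confounding population means, and gradient and population directions
are mutually orthogonalized so `pairwise_D` stays exact.

What the generator does **not** emulate: anisotropic, landmark-specific
covariance (real venation varies much more at some junctions than
others — real data reach 95% variance in fewer components than the
isotropic generator does); allometry (shape–size correlation, removed
here by construction); measurement error correlated between neighboring
landmarks; and non-Gaussian tails. Passing the recovery tests therefore
shows the *machinery* is correct and calibrated, not that any
particular biological dataset satisfies the model.

## Problem sizes used in validation

The validation suite exercises, as the package's chosen designs:
parameter recovery of pairwise D = 6 with 3 populations × 100 colonies
× 12 workers over 20 seeds (mean relative error well under the 15%
acceptance band, the residual being the known upward bias of plug-in
Mahalanobis estimates in 34 dimensions); cluster-count recovery with 5
clusters × 50 units in 18 dimensions at separation 6; RRPP null
calibration with 500 replicates at 199 permutations; and a full
five-population pipeline (60 colonies each) for label-free cluster
recovery. `scripts/acceptance.R` re-runs these from a single seed.

## Known limitations

* 2-D complete configurations only: no sliding semilandmarks, no
  missing-landmark estimation, no 3-D.
* The MANOVA pairwise tests and LDA require more analysis units than
  retained components per (pair of) group(s); with few units, reduce
  `m_retain` — errors say so explicitly.
* Mahalanobis estimates are upward-biased at small n per group
  (no bias correction is applied; the effect is visible and documented
  in the recovery tests).
* BIC cluster selection is information-limited: with few units in many
  dimensions, closely spaced clusters are legitimately merged. The BIC
  table is part of the output so such decisions are inspectable.
* Permutation p-values are Monte Carlo estimates with floor
  1/(n_perm + 1); exact enumeration is feasible only for small groups.
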