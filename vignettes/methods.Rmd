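---
title: "Quantifying skull integration and modularity: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying skull integration and modularity: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(integmod)
```

# The problem

Linear distances measured on a skull do not vary independently: growth,
development and function couple them. `integmod` quantifies that coupling at
the population level — how strongly traits are correlated overall
(integration) and whether correlations concentrate within anatomically
motivated groups of traits (modularity) — and then asks, across a clade,
whether *differences* between species in their covariance structure track
phylogeny, climate, or climate that is itself phylogenetically structured.

The package was written around a canonical study design: a clade of toad
species measured for 21 inter-landmark skull distances, with a priori
modularity hypotheses from three sources — embryonic bone origin in the
cranial neural crest streams (developmental units), thyroid-hormone
sensitivity ranked by ossification timing during metamorphosis (hormonal
units), and adult functional regions of the skull (functional units). All of
the machinery is, however, generic over any trait set.

# The estimation chain

## P-matrices

The unit of analysis is the species **P-matrix**: the pooled within-species
phenotypic covariance (and correlation) matrix. Sex and locality shift trait
means within species; left uncorrected, those mean shifts masquerade as
trait correlations. `fit_residuals()` therefore fits, per species, a
multivariate linear model of all traits on sex and locality and keeps a
covariate only when its MANOVA (Wilks) p-value falls below `alpha` (default
0.05; the threshold is exposed because reasonable analysts differ).
`estimate_pmatrix()` divides the residual cross-product by the residual
degrees of freedom `n - rank(design)` — unbiased under the fitted model —
with `denominator = "n-1"` available for the plain sample-covariance
convention. Normality screening (`normality_screen()`, a Lilliefors test per
trait) is deliberately report-only: no automatic specimen deletion, because
no defensible automatic rule exists.

Sampling noise in a P-matrix is quantified by **matrix repeatability**:
draw `B` parametric replicates (`n` observations from a multivariate normal
with the empirical covariance), re-estimate, and average the Random Skewers
similarity between the empirical matrix and its replicates. Values near 1
mean the matrix is stable at the realized sample size.

## Three faces of size

A dominant, same-sign first principal component is the signature of size
variation, and it inflates every correlation, masking modularity. The
package produces three matrix variants per species:

* **with size** — the raw residual covariance;
* **no isometric size** — Somers' procedure: log-transform, subtract each
  specimen's mean log value (its isometric size score), then center each
  trait (`remove_isometric()`). Acting on data, not on the matrix, it
  removes only uniform scaling;
* **no allometric size** — deflation of the leading eigenpair,
  `cov - lambda1 v1 v1'`, converted to a correlation matrix
  (`remove_allometric()`). PC1 with same-sign but unequal loadings is
  allometric size; removing it removes disproportionate growth too.

Order of operations: Somers runs on covariate-corrected data
(`fit_residuals(..., keep_means = TRUE)` preserves the measurement scale),
so group mean effects cannot leak into the size score. PC1 deflation acts on
the raw-scale covariance; a flag to deflate the log-scale covariance instead
is available through the estimation scale choice. The deflated matrix has
rank `p - 1`; anything that inverts it (relative eigenanalysis) must first
pass through `extend_matrix()`.

## Modular signal: AVG diff

For a unit (trait set) `M`, `avg_diff()` computes the mean correlation over
pairs inside `M` (AVG+), over pairs crossing the boundary (AVG−), and their
difference. `avg_diff_ci()` wraps the statistic in a parametric bootstrap:
`B = 1000` replicate P-matrices by default, the requested size transform
applied to *each replicate* (so sampling noise propagates through the size
removal — the alternative, transforming once and bootstrapping the
transformed matrix, is available by transforming first and bootstrapping
with `transform = "none"`), and a percentile 95% interval. Percentile
intervals, not BCa: the plain interval is what "95% confidence interval"
means absent further qualification, and its type-I error calibrates at the
nominal 5% in the acceptance suite.

The Somers transform acts on data, so its bootstrap path resamples
*log-scale data* from the empirical log-scale covariance (`log_cov`,
which the caller must supply), double-centers each replicate and
re-estimates. This is stated prominently because it is the one place where
a matrix alone is not enough input.

For total models `avg_diff_total()` excludes pairs touching background
traits by default; a flag counts them into AVG−. The exclusion matches the
view that a total model makes claims only about its named units.

## Likelihood comparison of modularity models

`fit_model()` scores a partition of the `p(p-1)/2` trait pairs into
correlation sets: each observed correlation, Fisher-z transformed, is
modeled as normal around the set's common `z(rho)` with standard deviation
`1/sqrt(n - 3)`. The set MLE is the inverse transform of the mean z — a
closed form that the test suite verifies against a 0.001-step grid search.
Models are ranked by `AICc = -2 logL + 2K + 2K(K+1)/(n_pairs - K - 1)` and
summarized by Akaike-weight posterior probabilities; a best model below
posterior 0.5 is flagged unreliable. Signed correlation estimation is the
default (size-removed matrices have genuinely negative correlations);
`allow_negative = FALSE` fits magnitudes.

Set bookkeeping is explicit and configurable (`pair_partition()`): each
module's within-pairs form a set, module-spanning pairs form one set
(`between = "single"`) or one per module pair, and background-touching
pairs form their own set by default or merge into the between set. `K`
follows directly, so either accounting convention for two-module models
(`K = 4` with merged background, `K = 5` with a separate background set)
can be reproduced; no single convention is privileged.

Two cautions, both reproduced as tests. First, the likelihood treats the
pairwise correlations as independent; they are not (they share one sample),
and a shared background correlation couples them strongly. Under a
compound-symmetric truth the no-modules baseline is the modal winner with
the highest average posterior, but spurious structure wins a minority of
replicates even at `n = 100` — more often as the background correlation
grows. Second, when overall integration is high (mean correlation at or
above 0.6) the same modular covariance contrast is compressed on the
correlation scale and the best model's posterior drops relative to a
low-integration regime. Model selection on highly integrated matrices
should be read with these limits in mind.

## Comparing covariance structure across species

`random_skewers()` applies the same random unit-length selection gradients
to two covariance matrices and correlates their response vectors
(`dz = P beta`); the mean cosine over skewers is the similarity `S`,
converted to a dissimilarity as `sqrt(1 - S)`. Skewers are isotropic
Gaussian normalized to unit length by default — isotropy makes the index
basis-independent — with the historical uniform-component variant behind
`dist = "uniform"`; the two agree closely in practice and neither is
claimed to reproduce any published third decimal. Within a dissimilarity
matrix, each species pair draws its skewers from a seed derived from the
master seed and the pair's sorted labels, so results cannot depend on
enumeration order.

`relative_eigen_distance()` is the affine-invariant metric
`sqrt(sum(log(lambda_i)^2))` over the eigenvalues of one matrix in the
metric of the other, computed through the symmetric whitened form
`P2^{-1/2} P1 P2^{-1/2}` for numerical stability. It requires strictly
positive-definite inputs, which is why `extend_matrix()` exists: trailing
eigenvalues below a cutoff rank are floored at the cutoff eigenvalue,
keeping the eigenvectors. When no explicit cutoff is given it is chosen at
the first standardized eigenvalue gap `(lambda_j - lambda_{j+1})/lambda_1`
below `1e-4`; the tolerance and the cutoff are both exposed because the
underlying method is defined only up to this choice.

## Phylogeny, climate, and variation partitioning

The comparative layer asks what explains between-species differences in
P-matrix structure:

* `pcoa()` embeds a dissimilarity matrix in Euclidean axes (Gower
  centering; negative eigenvalues reported, Cailliez correction optional
  but off by default — corrections change axis geometry and should be a
  conscious choice). Axis signs are fixed by making the largest-magnitude
  score positive.
* Phylogeny enters as PCo axes of the cophenetic (patristic) distance
  matrix, not as phylogenetic eigenvector maps; climate as principal
  components of z-scored locality climate variables averaged to species
  (z-scoring because temperature and precipitation live on incomparable
  scales). The 17-variable bioclim schema (BIO1..BIO19 without the
  derived BIO3 and BIO7) is the default climate layout.
* `kmult()` measures multivariate phylogenetic signal: the ratio of raw to
  phylogenetically whitened mean squared deviations from the phylogenetic
  mean, scaled by its Brownian-motion expectation, with a permutation test.
  It averages 1 under Brownian motion (verified over 200 simulations) and
  reduces to Blomberg's K at one trait (verified against an independent
  implementation).
* `screen_axes()` retains response axes significantly correlated with at
  least one predictor and predictors significant against a retained axis —
  deliberately without multiple-testing correction, matching the screening
  practice this step descends from; a Holm option exists for the cautious.
* `variation_partition()` decomposes the adjusted redundancy-analysis
  R-squared of the retained axes into the fraction unique to phylogeny,
  unique to climate, and their shared component — the phylogenetically
  structured climatic variation. Ezekiel adjustment makes fractions
  comparable across predictor counts; negative adjusted fractions are
  reported as computed, never clipped. Unique fractions are tested by
  permutation of reduced-model residuals (999 by default; raw-data
  permutation by flag); the shared fraction has no degrees of freedom and
  is reported untested.

# The synthetic clade generator

`simulate_clade()` is the package's ground-truth instrument, not a fixture.
On the log scale, a specimen of species `i` is

```
x = mu_i + delta_sex + delta_loc + a * sigma_s * s + L_i u + e
```

a species mean plus sex/locality mean shifts, a common size factor with
positive unequal loadings `a` (unequal: allometry), one latent factor per
module of the true modularity model, and independent noise; traits are then
exponentiated to the measurement scale, so Somers' log/double-centering is
exactly the right inverse (raw-scale generation by flag). Climate evolves
as Brownian motion on a pure-birth, unit-depth tree and couples to
covariance structure multiplicatively: the designated climate-sensitive
module's loadings are scaled by `1 + gamma * c_i`, with `c_i` the species'
standardized climate PC1 score. One knob (`gamma`) thus creates
climate-associated P-matrix divergence that is phylogenetically structured
exactly insofar as climate is.

Defaults emulate the study conditions the design descends from: 11 species,
21 traits, 100 specimens per species (about a thousand specimens in all),
three localities per species, a size factor dimensioned so PC1 carries
roughly 70% of the variance (inside the 57–84% band reported for such
data), mean within-species correlations near 0.7, sex dimorphism of 0.04
log units, locality shifts of 0.03, 17 climate variables with Brownian rate
1, and `gamma = 0.5`. Module loadings (0.06) against trait noise (0.05) give
a with-size modular signal around 0.05–0.1 — detectable but small, as in
real skull data — that triples when size is removed.

What the generator does *not* emulate: measurement error at the landmark
level, missing data, unbalanced sexes, age structure, non-normal trait
distributions, correlated module factors, and climate that affects more
than one module. Passing tests on this generator therefore demonstrate the
estimators' correctness and calibration under the model's assumptions, not
robustness to every pathology of museum data.

`recovery_suite()` runs the full chain per replicate clade and scores:
Random Skewers similarity of each estimated P-matrix to its true
covariance; AVG-diff significance for the true modules and for a decoy
unit built to carry no signal (at most one trait per true module plus
background); whether model comparison recovers the generating model with
posterior above 0.5 on size-removed correlations; and the significance of
the climate fractions in the partitioning.

# Numerical choices and degenerate inputs

* Observed correlations at ±1 are shrunk to ±(1 − 1e-6) before the z
  transform; the likelihood stays finite and the bias is far below
  sampling noise.
* Effective sample size for the correlation likelihood defaults to the
  P-matrix residual df + 1 (sampling variance of r depends on what the
  design left over), with raw `n` a caller choice.
* `remove_allometric()` refuses matrices whose two leading eigenvalues tie
  within tolerance — PC1 is then not identified.
* Zero-variance traits yield zero correlations (not NaN) in
  `cov2cor_safe()`, with the unit diagonal preserved.
* All Monte-Carlo machinery (resampling, skewers, bootstrap, permutations)
  is seeded explicitly; per-pair and per-replicate seeds are derived
  deterministically from the master seed so that parallel or reordered
  evaluation cannot change results.
* Negative intraclass repeatability estimates are clipped to zero with a
  warning, the standard variance-component convention.

# Problem sizes in the shipped analyses

The numbered scripts under `analysis/` run the whole pipeline on the
default 11-species clade (about 15 seconds for simulation, P-matrices and
model selection; the bootstrap CI table over 16 units × 3 matrix kinds ×
500 replicates is the slow stage at a few minutes). The test suite and the
acceptance script use scaled-down versions of the same computations —
6–8 species, 6–10 traits, bootstrap and permutation counts of 100–500,
200-replicate calibration loops — sizes chosen so the full set of
calibration checks (type-I rates, Brownian-motion K, recovery rates)
re-runs from scratch in a few minutes while binomial tolerances remain
tight enough to detect real miscalibration.

# Known limitations

* The correlation-set likelihood ignores the dependence among pairwise
  correlation estimates; its AICc comparisons are therefore approximate,
  and most so at high integration (see the cautions above).
* With 11 species, variation partitioning runs at the edge of its degrees
  of freedom: single-clade fractions fluctuate strongly from draw to draw,
  and only ensemble statements (medians over replicate clades) are stable.
  The acceptance suite asserts exactly that.
* The bootstrap-then-transform CI propagates matrix sampling noise but
  conditions on the empirical matrix as the generating truth, as every
  parametric bootstrap does; coverage is nominal in calibration but is not
  an exact finite-sample guarantee.
* `kmult()` permutes species across tips, a null of no signal; it does not
  test Brownian motion itself.
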