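# integmod

Morphological integration and modularity of skull linear distances, from
specimen tables to phylogenetic variation partitioning.

## What it is for

Skull traits do not vary independently: growth inflates every correlation,
while development and function concentrate correlations within anatomical
units (modules). `integmod` implements a complete pipeline for analyzing
this structure across a clade from specimen-level linear-distance data:

1. **P-matrices** — pooled within-species phenotypic covariance and
   correlation matrices, estimated from the residuals of per-species
   multivariate linear models that remove significant sex and locality mean
   effects (MANOVA screen), with Monte-Carlo matrix repeatability.
2. **Size control** — three matrix variants per species: with size, without
   isometric size (Somers log double-centering of the data) and without
   allometric size (deflation of PC1, `Σ − λ₁v₁v₁ᵀ`).
3. **Modularity tests** — the AVG statistic for an a priori unit *M*:
   AVG+ (mean correlation within *M*), AVG− (mean correlation between *M*
   and the rest), and AVG diff = AVG+ − AVG−, with parametric-bootstrap 95%
   confidence intervals. Built-in encodings ship for the developmental
   (cranial-neural-crest stream), hormonal (T3 sensitivity) and functional
   skull units over the standard 21-distance, 22-landmark scheme.
4. **Model selection** — maximum likelihood over partitions of trait pairs
   into correlation sets: `z(r) ~ N(z(ρ_set), 1/(n−3))`, ranked by
   `AICc = −2logL + 2K + 2K(K+1)/(n_pairs−K−1)` and Akaike-weight
   posterior probabilities.
5. **Matrix comparison** — Random Skewers (mean response-vector correlation
   to shared random selection gradients `Δz = Pβ`, dissimilarity
   `√(1−S)`) and the affine-invariant relative-eigenanalysis distance
   `√Σ(ln λᵢ)²` over the eigenvalues of `P₂⁻¹P₁`, with noise extension for
   rank-deficient matrices.
6. **Comparative inference** — principal coordinates of the P-matrix
   dissimilarity, cophenetic phylogenetic distances, climate PCA on
   z-scored bioclim variables, multivariate phylogenetic signal
   (K_mult, = 1 under Brownian motion), reciprocal axis screening, and
   variation partitioning of P-matrix divergence into fractions unique to
   phylogeny, unique to climate, and shared (phylogenetically structured
   climatic variation), with adjusted R² and permutation tests.
7. **Synthetic clades** — a generator with known ground truth (size
   factor, modular factors, sex/locality shifts, Brownian climate, tunable
   climate→covariance coupling γ) used to validate every stage end to end.

See `vignettes/methods.Rmd` for the models, assumptions, parameter
defaults and known limitations.

## Worked example

Simulate a small clade, estimate a species P-matrix, test a functional
unit for modular signal after removing allometric size, and compare
composite modularity models:

```r
library(integmod)

cfg <- clade_config(n_species = 4, n_specimens = 120, seed = 7)
dat <- simulate_clade(cfg)
traits <- dat$traits
tn <- trait_names(traits)
traits[tn] <- log(traits[tn])                     # analyze log-mm distances

fr <- fit_residuals(traits, covariates = c("sex", "locality"))
sub <- fr$residuals[fr$residuals$species == "sp01", ]
P <- estimate_pmatrix(sub, model_rank = unname(fr$rank["sp01"]),
                      species = "sp01")
P
#> P-matrix (sp01)
#>   traits: 21  n: 120  df: 117  kind: with_size
#>   mean |r| = 0.796, mean r = 0.796
size_report(P)
#> PC1: 81.2% of total variance; same-sign loadings: TRUE
```

Mean correlations near 0.8 and a same-sign PC1 carrying 81% of the
variance: a heavily size-integrated matrix. Testing the snout unit on the
size-removed matrix:

```r
avg_diff_ci(P, builtin_units()$snout, B = 1000, seed = 1,
            transform = "no_allometric")
#>   avg_plus avg_minus avg_diff ci_low ci_high significant
#> 1     0.09    -0.104    0.194   0.13    0.26        TRUE
```

Snout correlations exceed snout-to-rest correlations by 0.19 (95% CI
0.13–0.26): a significant modular signal once allometric size is removed.
Model comparison on the same deflated correlation matrix recovers the
generating functional model decisively:

```r
compare_models(remove_allometric(P)$cor, n_spec = P$df + 1,
               models = builtin_models()[c("developmental_Ib",
                                           "hormonal_I", "functional_I")])
#>              model    MaxL K   AICc  Post_Prob
#> 1     functional_I  144.80 4 -281.4  1.000e+00
#> 2 developmental_Ib  -98.73 4  205.6 1.722e-106
#> 3       hormonal_I -170.68 4  349.6 9.692e-138
#> 4       no_modules -183.40 1  368.8 6.369e-142
```

Species-level divergence in covariance structure, by Random Skewers:

```r
covs <- lapply(split(fr$residuals, fr$residuals$species), function(s)
  estimate_pmatrix(s, model_rank = unname(fr$rank[s$species[1]]))$cov)
dissimilarity_matrix(covs, method = "rs", n_skewers = 1000, seed = 2)
#> Dissimilarity matrix (rs_sqrt1mS) over 4 species
#>        sp01   sp02   sp03   sp04
#> sp01 0.0000 0.2425 0.2572 0.3125
#> ...
```

## The full analysis

The numbered scripts under `analysis/` run the complete study on the
default synthetic clade (11 species × 100 specimens × 21 distances) and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate_clade.R    # clade inputs -> results/clade/
Rscript analysis/02_pmatrices.R         # P-matrices, repeatability, size
Rscript analysis/03_modularity.R        # AVG-diff CIs, 3 matrix kinds
Rscript analysis/04_model_selection.R   # AICc model comparison per species
Rscript analysis/05_comparative.R       # RS/RE distances, PCoA, K_mult,
                                        # variation partitioning
```

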