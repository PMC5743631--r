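#!/usr/bin/env Rscript
# Stage 5 -- phylogeny, climate and P-matrix divergence.
#
# Builds Random Skewers and relative-eigenanalysis dissimilarity matrices
# among the species covariance matrices (the latter on noise-extended
# matrices), ordinates them by principal coordinates, extracts climate PCs
# from the z-scored locality table, measures multivariate phylogenetic
# signal (K_mult) of the species climate, screens ordination axes against
# the phylogenetic and climatic predictors, and partitions the variance of
# the retained P-matrix axes into phylogenetic, climatic and shared
# (phylogenetically structured climatic) fractions. Writes
# results/dissimilarity_{rs,re}.csv, results/varpart.{csv,json}.

suppressMessages(library(integmod))

seed <- 20260920L
species <- sub("\\.json$", "",
               list.files("results/pmatrices", pattern = "\\.json$"))
pms <- lapply(species, function(sp)
  read_pmatrix(file.path("results/pmatrices", sp)))
names(pms) <- species
covs <- lapply(pms, `[[`, "cov")

D_rs <- dissimilarity_matrix(covs, method = "rs", n_skewers = 1000,
                             seed = seed)
covs_ext <- lapply(covs, extend_matrix)
D_re <- dissimilarity_matrix(covs_ext, method = "re")
write_dist_matrix(D_rs, "results/dissimilarity_rs")
write_dist_matrix(D_re, "results/dissimilarity_re")
cat(sprintf("RS dissimilarity: mean %.3f (max %.3f); RE: mean %.2f\n",
            mean(D_rs$values[upper.tri(D_rs$values)]),
            max(D_rs$values),
            mean(D_re$values[upper.tri(D_re$values)])))

ord <- pcoa(D_rs)
phy_d <- cophenetic_from_newick("results/clade/tree.nwk")
phy_d$values <- phy_d$values[species, species]
phy_d$labels <- species
phy_ord <- pcoa(phy_d)
climate <- read_climate("results/clade/climate.csv", drop = character(0))
cpca <- climate_pca(climate)
cat(sprintf("Climate PC1 explains %.0f%% of climatic variance\n",
            cpca$variance_explained[1]))

tree <- ape::read.tree("results/clade/tree.nwk")
clim_sp <- cpca$species_scores[tree$tip.label, 1:3]
km <- kmult(tree, clim_sp, n_perm = 999, seed = seed)
cat(sprintf("Phylogenetic signal of climate: K_mult = %.2f, p = %.3f\n",
            km$K, km$p))

# Desdevises-style reciprocal screening of candidate axes
preds <- cbind(phy_PCo1 = phy_ord$axes[species, 1],
               climate_PC1 = cpca$species_scores[species, 1])
scr <- screen_axes(ord$axes[, seq_len(min(3, ncol(ord$axes))), drop = FALSE],
                   preds)
cat("Axis screening (Pearson, alpha = 0.05):\n")
print(scr$table, row.names = FALSE, digits = 2)

resp <- if (length(scr$retained_axes) > 0) {
  ord$axes[, scr$retained_axes, drop = FALSE]
} else {
  cat("No axis passed the screen; using PCo1 for the partitioning report.\n")
  ord$axes[, 1, drop = FALSE]
}
vp <- variation_partition(resp,
                          X1 = phy_ord$axes[species, 1, drop = FALSE],
                          X2 = cpca$species_scores[species, 1, drop = FALSE],
                          n_perm = 999, seed = seed)
write_varpart(vp, "results/varpart")
cat("\nVariation partitioning of P-matrix divergence (results/varpart.csv):\n")
print(vp)
print(vp$tests, row.names = FALSE, digits = 3)
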