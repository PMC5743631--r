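#' Configuration of the synthetic clade generator
#'
#' Bundles every generating parameter of the synthetic clade with validated
#' defaults. Traits are generated on the log scale (then exponentiated to
#' measurement scale) as
#' `x = mu_i + delta_sex + delta_loc + a * sigma_s * s + L_i u + e`,
#' i.e. species mean + sex and locality mean shifts + a common size factor
#' with per-trait loadings `a` (unequal positive entries = allometry) + one
#' latent factor per module of the true modularity model + independent
#' trait noise. Climate evolves as Brownian motion on a pure-birth tree and
#' can modulate one module's loadings multiplicatively
#' (`L_i = L * (1 + gamma * c_i)` with `c_i` the species' standardized
#' climate PC1 score), coupling P-matrix divergence to climate.
#'
#' The defaults emulate the statistical structure of a clade of ~11 toad
#' species measured for 21 skull distances: around 100 specimens per
#' species, a dominant size factor placing PC1 in the 57-84% band of total
#' variance, mean trait correlations near 0.7, modest sexual dimorphism and
#' locality mean shifts, and 17 bioclimatic variables with Brownian
#' phylogenetic signal.
#'
#' @param n_species number of species (default 11).
#' @param p number of traits (default 21, named `d1..dp`).
#' @param n_specimens specimens per species (scalar or vector, default 100).
#' @param n_localities localities per species (default 3).
#' @param size_loadings positive per-trait size loadings `a`; unequal
#'   values give allometry (default a fixed gradient over `[0.8, 1.2]`).
#' @param size_sd standard deviation `sigma_s` of the common size factor on
#'   the log scale (default 0.108, placing PC1 near 70% of total variance).
#' @param true_model `modularity_model` wired into the covariance (default
#'   `builtin_models()$functional_I` when `p = 21`, else two generic
#'   modules).
#' @param module_loading latent-factor loading per module trait
#'   (default 0.06, log scale).
#' @param noise_sd per-trait residual standard deviation (default 0.05).
#' @param sex_effect per-trait log-scale mean shift between the sexes
#'   (default 0.04 on every trait).
#' @param locality_sd standard deviation of locality mean shifts
#'   (default 0.03).
#' @param species_mean_sd standard deviation of per-species deviations
#'   around the baseline log trait means (default 0.05).
#' @param q_climate number of climate variables (default 17).
#' @param climate_sd Brownian-motion rate of the climate variables
#'   (default 1).
#' @param climate_signal phylogenetic-signal multiplier in `[0, 1]`
#'   applied to the off-diagonal of the Brownian tip covariance (1 = pure
#'   Brownian motion, 0 = star phylogeny).
#' @param gamma climate-to-covariance coupling (default 0.5); 0 decouples
#'   P-matrix structure from climate.
#' @param climate_module name of the climate-sensitive module (default the
#'   first module of `true_model`).
#' @param log_scale generate on the log scale and exponentiate (default
#'   TRUE); FALSE generates directly on measurement scale.
#' @param seed integer seed.
#' @return validated list of class `clade_config`.
#' @export
clade_config <- function(n_species = 11, p = 21, n_specimens = 100,
                         n_localities = 3,
                         size_loadings = NULL, size_sd = 0.108,
                         true_model = NULL, module_loading = 0.06,
                         noise_sd = 0.05, sex_effect = 0.04,
                         locality_sd = 0.03, species_mean_sd = 0.05,
                         q_climate = 17, climate_sd = 1,
                         climate_signal = 1, gamma = 0.5,
                         climate_module = NULL, log_scale = TRUE,
                         seed = 1) {
  if (n_species < 3) stop("need at least 3 species")
  if (p < 2) stop("need at least 2 traits")
  if (is.null(size_loadings)) {
    size_loadings <- seq(0.8, 1.2, length.out = p)
  }
  if (any(size_loadings <= 0)) stop("size loadings must be positive")
  if (length(size_loadings) != p) stop("size_loadings must have length p")
  if (is.null(true_model)) {
    true_model <- if (p == 21) builtin_models()$functional_I else {
      half <- floor(p / 3)
      modularity_model("generic_two_module",
                       list(A = paste0("d", 1:half),
                            B = paste0("d", (half + 1):(2 * half))),
                       trait_names = paste0("d", 1:p))
    }
  }
  if (any(c(size_sd, module_loading, noise_sd, climate_sd) <= 0)) {
    stop("variance parameters must be positive")
  }
  if (climate_signal < 0 || climate_signal > 1) {
    stop("climate_signal must be in [0, 1]")
  }
  n_specimens <- rep_len(n_specimens, n_species)
  if (any(n_specimens < p + 2)) {
    warning("some species have fewer than p + 2 specimens; ",
            "their P-matrices will be noisy or singular")
  }
  if (is.null(climate_module)) climate_module <- names(true_model$modules)[1]
  if (!climate_module %in% names(true_model$modules)) {
    stop("climate_module must name a module of true_model")
  }
  sex_effect <- rep_len(sex_effect, p)
  structure(list(
    n_species = n_species, p = p, n_specimens = n_specimens,
    n_localities = n_localities, size_loadings = size_loadings,
    size_sd = size_sd, true_model = true_model,
    module_loading = module_loading, noise_sd = noise_sd,
    sex_effect = sex_effect, locality_sd = locality_sd,
    species_mean_sd = species_mean_sd, q_climate = q_climate,
    climate_sd = climate_sd, climate_signal = climate_signal,
    gamma = gamma, climate_module = climate_module,
    log_scale = log_scale, seed = as.integer(seed)),
    class = "clade_config")
}

#' Simulate a pure-birth ultrametric tree of unit depth
#'
#' @param n_species number of tips (>= 3); tips are labeled `sp01, sp02, ...`.
#' @param seed integer seed.
#' @return an `ape::phylo`, ultrametric with root-to-tip depth 1.
#' @export
simulate_tree <- function(n_species, seed = 1) {
  if (n_species < 3) stop("need at least 3 species")
  set.seed(seed)
  phy <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length / depth
  phy$tip.label <- sprintf("sp%02d", seq_len(n_species))
  phy
}

#' Simulate climate variables evolving on a tree
#'
#' Each variable is an independent Brownian motion on the tree: tip values
#' are multivariate normal with covariance `climate_sd^2 * C`, where `C` is
#' the tree's phylogenetic covariance. A `signal` multiplier below 1 shrinks
#' the off-diagonal of `C` toward a star phylogeny, weakening the
#' phylogenetic signal; at `signal = 1` the expected K_mult of the output
#' is 1.
#'
#' @param tree phylo / newick.
#' @param q number of variables.
#' @param climate_sd Brownian-motion rate (tip standard deviation on a
#'   unit-depth tree).
#' @param seed integer seed.
#' @param signal phylogenetic-signal multiplier in `[0, 1]` (default 1).
#' @return species x q matrix with tip-label rownames; columns named with
#'   the 17-variable bioclim schema when `q = 17` (`BIO1..BIO19` without
#'   BIO3 and BIO7), else `clim1..climq`.
#' @export
simulate_climate <- function(tree, q, climate_sd = 1, seed = 1, signal = 1) {
  phy <- as_phylo(tree)
  C <- ape::vcv(phy)
  Cs <- signal * C + (1 - signal) * diag(diag(C))
  n <- nrow(C)
  set.seed(seed)
  X <- t(MASS::mvrnorm(q, mu = rep(0, n), Sigma = climate_sd^2 * Cs))
  if (q == 1) X <- matrix(X, ncol = 1)
  rownames(X) <- rownames(C)
  colnames(X) <- bioclim_names(q)
  X
}

bioclim_names <- function(q) {
  if (q == 17) paste0("BIO", setdiff(1:19, c(3, 7))) else paste0("clim", seq_len(q))
}

# true log-scale covariance of species i given its module-loading matrix
true_sigma <- function(cfg, module_scale) {
  tn <- paste0("d", seq_len(cfg$p))
  S <- cfg$size_sd^2 * tcrossprod(cfg$size_loadings)
  for (m in names(cfg$true_model$modules)) {
    l <- numeric(cfg$p)
    l[match(cfg$true_model$modules[[m]], tn)] <-
      cfg$module_loading * module_scale[m]
    S <- S + tcrossprod(l)
  }
  S <- S + diag(rep(cfg$noise_sd^2, cfg$p))
  dimnames(S) <- list(tn, tn)
  S
}

#' Simulate a synthetic clade with known ground truth
#'
#' Generates the full input bundle of the pipeline: a pure-birth tree,
#' Brownian climate, per-species specimen trait tables with sex and
#' locality mean shifts, and the realized true covariance of every species.
#'
#' @param cfg a [clade_config()].
#' @return list of class `clade_dataset`: `traits` (one trait table, all
#'   species), `tree` (phylo), `climate` (locality-level data.frame:
#'   locality, species, variables), `truth` (list: `config`, `sigma`
#'   (per-species true log-scale covariance), `climate_scores`
#'   (standardized species climate PC1 scores), `module_scale` (per-species
#'   named multipliers on the module loadings)).
#' @export
simulate_clade <- function(cfg) {
  stopifnot(inherits(cfg, "clade_config"))
  tn <- paste0("d", seq_len(cfg$p))
  tree <- simulate_tree(cfg$n_species, seed = cfg$seed)
  climate_sp <- simulate_climate(tree, cfg$q_climate,
                                 climate_sd = cfg$climate_sd,
                                 seed = cfg$seed + 1,
                                 signal = cfg$climate_signal)
  species <- tree$tip.label
  # standardized species climate PC1 score drives the coupling
  pc1 <- stats::prcomp(scale(climate_sp))$x[, 1]
  c_i <- as.vector(scale(pc1))
  names(c_i) <- species
  set.seed(cfg$seed + 2)
  # baseline log trait means: distances spanning ~2-18 mm
  mu0 <- log(seq(2.5, 18, length.out = cfg$p))
  tables <- vector("list", cfg$n_species)
  sigmas <- vector("list", cfg$n_species)
  module_scales <- vector("list", cfg$n_species)
  climate_loc <- list()
  for (i in seq_len(cfg$n_species)) {
    sp <- species[i]
    n <- cfg$n_specimens[i]
    mu_i <- mu0 + stats::rnorm(cfg$p, 0, cfg$species_mean_sd)
    scale_m <- stats::setNames(rep(1, length(cfg$true_model$modules)),
                               names(cfg$true_model$modules))
    scale_m[cfg$climate_module] <- max(1 + cfg$gamma * c_i[i], 0.1)
    module_scales[[i]] <- scale_m
    Sig <- true_sigma(cfg, scale_m)
    sigmas[[i]] <- Sig
    # group structure
    sex <- rep_len(c("F", "M"), n)
    loc_names <- sprintf("%s_loc%d", sp, seq_len(cfg$n_localities))
    locality <- rep_len(loc_names, n)
    loc_shift <- matrix(stats::rnorm(cfg$n_localities * cfg$p, 0,
                                     cfg$locality_sd),
                        nrow = cfg$n_localities,
                        dimnames = list(loc_names, tn))
    # latent factors
    s <- stats::rnorm(n)
    X <- matrix(stats::rnorm(n * cfg$p, 0, cfg$noise_sd), n, cfg$p)
    X <- X + outer(s, cfg$size_loadings * cfg$size_sd)
    for (m in names(cfg$true_model$modules)) {
      l <- numeric(cfg$p)
      l[match(cfg$true_model$modules[[m]], tn)] <-
        cfg$module_loading * scale_m[m]
      X <- X + outer(stats::rnorm(n), l)
    }
    X <- X + matrix(mu_i, n, cfg$p, byrow = TRUE)
    X <- X + outer(as.numeric(sex == "M"), cfg$sex_effect)
    X <- X + loc_shift[locality, , drop = FALSE]
    if (cfg$log_scale) X <- exp(X)
    tab <- data.frame(specimen_id = sprintf("%s_%04d", sp, seq_len(n)),
                      species = sp, sex = sex, locality = locality,
                      stringsAsFactors = FALSE)
    tab[tn] <- as.data.frame(X)
    tables[[i]] <- tab
    clim_i <- climate_sp[rep(i, cfg$n_localities), , drop = FALSE] +
      matrix(stats::rnorm(cfg$n_localities * cfg$q_climate, 0,
                          0.1 * cfg$climate_sd),
             cfg$n_localities, cfg$q_climate)
    climate_loc[[i]] <- data.frame(locality = loc_names, species = sp,
                                   stringsAsFactors = FALSE)
    climate_loc[[i]][colnames(climate_sp)] <- as.data.frame(clim_i)
  }
  names(sigmas) <- species
  names(module_scales) <- species
  structure(list(
    traits = do.call(rbind, tables),
    tree = tree,
    climate = do.call(rbind, climate_loc),
    truth = list(config = cfg, sigma = sigmas, climate_scores = c_i,
                 module_scale = module_scales,
                 species_climate = climate_sp)),
    class = "clade_dataset")
}

#' Run the estimation pipeline on a clade dataset
#'
#' Convenience driver used by the analysis scripts and the recovery suite:
#' removes sex/locality mean effects per species, estimates the with-size
#' P-matrix (on the log scale when the dataset was generated by
#' exponentiation, matching the scale of the generating covariance), builds
#' the Random Skewers dissimilarity matrix, its principal coordinates, the
#' climate PCA, and the variation partitioning of P-matrix divergence into
#' phylogeny and climate components (response: first PCo axis; predictors:
#' first phylogenetic PCo axis and climate PC1).
#'
#' @param dataset a `clade_dataset`.
#' @param n_skewers skewers per pairwise comparison (default 500).
#' @param n_perm permutations in the partitioning tests (default 199).
#' @param seed integer seed.
#' @param log_traits analyze log-transformed traits (default: the dataset's
#'   `log_scale` flag, so estimates live on the scale of the true
#'   covariances).
#' @return list: `pmatrices` (per species), `dissimilarity`, `ordination`,
#'   `climate_pca`, `kmult_climate`, `varpart`.
#' @export
clade_pipeline <- function(dataset, n_skewers = 500, n_perm = 199, seed = 1,
                           log_traits = dataset$truth$config$log_scale) {
  traits <- dataset$traits
  tn <- trait_names(traits)
  if (log_traits) traits[tn] <- log(traits[tn])
  fr <- fit_residuals(traits, covariates = c("sex", "locality"))
  pms <- lapply(split(fr$residuals, fr$residuals$species), function(sub) {
    sp <- as.character(sub$species[1])
    estimate_pmatrix(sub, model_rank = unname(fr$rank[sp]), species = sp)
  })
  covs <- lapply(pms, `[[`, "cov")
  D <- dissimilarity_matrix(covs, method = "rs", n_skewers = n_skewers,
                            seed = seed)
  ord <- pcoa(D)
  phyd <- cophenetic_from_newick(dataset$tree)
  phyd$values <- phyd$values[names(covs), names(covs)]
  phyd$labels <- names(covs)
  phy_ord <- pcoa(phyd)
  cpca <- climate_pca(dataset$climate)
  km <- kmult(dataset$tree,
              dataset$truth$species_climate[names(covs), , drop = FALSE],
              n_perm = n_perm, seed = seed + 1)
  sp_order <- ord$labels
  Y <- ord$axes[, 1, drop = FALSE]
  X1 <- phy_ord$axes[match(sp_order, phy_ord$labels), 1, drop = FALSE]
  X2 <- cpca$species_scores[match(sp_order, rownames(cpca$species_scores)),
                            1, drop = FALSE]
  vp <- variation_partition(Y, X1, X2, n_perm = n_perm, seed = seed + 2)
  list(pmatrices = pms, dissimilarity = D, ordination = ord,
       phylo_ordination = phy_ord, climate_pca = cpca, kmult_climate = km,
       varpart = vp)
}

#' End-to-end recovery scoring of the pipeline on synthetic data
#'
#' Runs the full pipeline on `replicates` independently generated clades
#' and scores how well each stage recovers the known ground truth:
#' (i) Random Skewers similarity of each estimated P-matrix to the species'
#' true covariance; (ii) AVG-diff significance for the true modules and for
#' a decoy unit (a trait set drawn across module boundaries, which carries
#' no modular signal); (iii) whether ML model comparison picks the
#' generating model with posterior above 0.5 (no-allometric correlations);
#' (iv) the significance of the climate fraction (conditional and shared)
#' in the variation partitioning.
#'
#' @param cfg a [clade_config()]; replicate r uses `seed = cfg$seed + r`.
#' @param replicates number of replicate clades.
#' @param seed seed offset added to the config seed.
#' @param candidate_models models for stage (iii); default the four
#'   composite with-size models plus the generating model (deduplicated).
#' @param B_ci bootstrap replicates for the AVG-diff CIs (default 200).
#' @param n_skewers,n_perm pipeline sizes, see [clade_pipeline()].
#' @return data.frame with one row per replicate: `rs_truth_median`,
#'   `true_unit_sig` (fraction of true modules significant),
#'   `decoy_sig`, `model_recovered`, `best_posterior`,
#'   `climate_cond_p`, `frac_a`, `frac_b`, `frac_c`.
#' @export
recovery_suite <- function(cfg, replicates = 5, seed = 0,
                           candidate_models = NULL, B_ci = 200,
                           n_skewers = 500, n_perm = 199) {
  stopifnot(inherits(cfg, "clade_config"))
  if (is.null(candidate_models)) {
    bm <- builtin_models()
    candidate_models <- bm[c("developmental_Ia", "developmental_Ib",
                             "hormonal_I", "functional_I")]
    if (!cfg$true_model$name %in% vapply(candidate_models, `[[`,
                                         character(1), "name")) {
      candidate_models <- c(candidate_models, list(cfg$true_model))
    }
  }
  rows <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + seed + 1000L * r
    dat <- simulate_clade(cfg_r)
    pipe <- clade_pipeline(dat, n_skewers = n_skewers, n_perm = n_perm,
                           seed = cfg_r$seed)
    species <- names(pipe$pmatrices)
    rs_truth <- vapply(species, function(sp) {
      random_skewers(pipe$pmatrices[[sp]]$cov, dat$truth$sigma[[sp]],
                     n_skewers = n_skewers, seed = cfg_r$seed + 7)$similarity
    }, numeric(1))
    # stage (ii): AVG-diff on the species with most specimens
    big <- species[which.max(vapply(pipe$pmatrices, `[[`, integer(1), "n"))]
    P <- pipe$pmatrices[[big]]
    tnames <- P$trait_names
    true_units <- cfg$true_model$modules
    unit_sig <- vapply(true_units, function(u) {
      avg_diff_ci(P, u, B = B_ci, seed = cfg_r$seed + 11)$significant
    }, logical(1))
    decoy <- decoy_unit(cfg$true_model, tnames, seed = cfg_r$seed + 13)
    decoy_sig <- avg_diff_ci(P, decoy, B = B_ci,
                             seed = cfg_r$seed + 17)$significant
    # stage (iii): model recovery on no-allometric correlations
    cr <- remove_allometric(P)$cor
    cmp <- compare_models(cr, n_spec = P$df + 1, models = candidate_models)
    rows[[r]] <- data.frame(
      replicate = r,
      rs_truth_median = stats::median(rs_truth),
      true_unit_sig = mean(unit_sig),
      decoy_sig = decoy_sig,
      model_recovered = cmp$model[1] == cfg$true_model$name &&
        cmp$Post_Prob[1] > 0.5,
      best_model = cmp$model[1],
      best_posterior = cmp$Post_Prob[1],
      climate_cond_p = pipe$varpart$tests$p[pipe$varpart$tests$fraction == "X2|X1"],
      frac_a = pipe$varpart$frac_a,
      frac_b = pipe$varpart$frac_b,
      frac_c = pipe$varpart$frac_c,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# a unit with no two traits from the same true module: at most one trait
# per module plus background traits, so it carries no modular signal
decoy_unit <- function(model, trait_names, seed = 1) {
  set.seed(seed)
  one_each <- vapply(model$modules, function(m) sample(m, 1), character(1))
  bg <- setdiff(trait_names, unlist(model$modules))
  u <- c(one_each, sample(bg, min(length(bg), 4)))
  unname(u)
}
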