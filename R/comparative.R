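#' Principal coordinates analysis of a dissimilarity matrix
#'
#' Gower-centers the squared dissimilarities, `B = -1/2 J D^2 J` with `J`
#' the centering projector, eigendecomposes `B` and returns axes scaled by
#' the square roots of their (positive) eigenvalues. Axes with eigenvalues
#' below `eps` times the largest are dropped; negative eigenvalues (non-
#' Euclidean input) are reported and, optionally, removed by the Cailliez
#' constant-addition correction. Axis signs are fixed by making each axis's
#' largest-magnitude score positive.
#'
#' @param D a `dist_matrix`, `dist` object, or symmetric matrix with zero
#'   diagonal.
#' @param eps relative eigenvalue tolerance for axis retention
#'   (default `1e-8`).
#' @param correction `"none"` (default) or `"cailliez"`.
#' @return object of class `ordination`: `labels`, `axes` (objects x
#'   retained axes, columns `PCo1..`), `eigenvalues` (all, decreasing),
#'   `negative_eigenvalue_flag`.
#' @export
pcoa <- function(D, eps = 1e-8, correction = c("none", "cailliez")) {
  correction <- match.arg(correction)
  M <- dist_values(D)
  n <- nrow(M)
  if (correction == "cailliez") {
    c_star <- cailliez_constant(M)
    if (c_star > 0) {
      M <- M + c_star
      diag(M) <- 0
    }
  }
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (M^2) %*% J
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  lam <- eg$values
  if (all(lam <= eps * max(abs(lam), 1e-300))) {
    if (max(abs(M)) == 0) {
      return(structure(list(labels = rownames(M),
                            axes = matrix(0, n, 0,
                                          dimnames = list(rownames(M), NULL)),
                            eigenvalues = lam,
                            negative_eigenvalue_flag = FALSE),
                       class = "ordination"))
    }
    stop("no positive eigenvalues: input is not a dissimilarity matrix")
  }
  keep <- which(lam > eps * lam[1])
  axes <- eg$vectors[, keep, drop = FALSE] %*% diag(sqrt(lam[keep]),
                                                   length(keep))
  # reproducible orientation: largest |score| positive on each axis
  for (k in seq_len(ncol(axes))) {
    i <- which.max(abs(axes[, k]))
    if (axes[i, k] < 0) axes[, k] <- -axes[, k]
  }
  dimnames(axes) <- list(rownames(M), paste0("PCo", seq_along(keep)))
  structure(list(labels = rownames(M), axes = axes, eigenvalues = lam,
                 negative_eigenvalue_flag = any(lam < -eps * lam[1])),
            class = "ordination")
}

# smallest constant c added to off-diagonal dissimilarities making the
# configuration Euclidean (Cailliez 1983): largest eigenvalue of the
# companion 2n x 2n matrix
cailliez_constant <- function(M) {
  n <- nrow(M)
  J <- diag(n) - matrix(1 / n, n, n)
  B1 <- -0.5 * J %*% (M^2) %*% J
  B2 <- -0.5 * J %*% M %*% J
  big <- rbind(cbind(matrix(0, n, n), 2 * B1),
               cbind(-diag(n), -4 * B2))
  max(Re(eigen(big, only.values = TRUE)$values))
}

dist_values <- function(D) {
  M <- if (inherits(D, "dist_matrix")) D$values else as.matrix(D)
  if (nrow(M) != ncol(M)) stop("dissimilarity matrix must be square")
  if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
    stop("dissimilarity matrix must be symmetric")
  }
  if (any(abs(diag(M)) > 1e-10)) stop("dissimilarity matrix needs a zero diagonal")
  if (is.null(rownames(M))) {
    rownames(M) <- colnames(M) <- paste0("obj", seq_len(nrow(M)))
  }
  M
}

#' Cophenetic (patristic) distance matrix from a newick tree
#'
#' Entry (i, j) is the sum of branch lengths on the path between tips i and
#' j.
#'
#' @param tree newick string, path to a newick file, or an `ape::phylo`.
#' @return `dist_matrix` with tip labels.
#' @export
cophenetic_from_newick <- function(tree) {
  phy <- as_phylo(tree)
  if (is.null(phy$edge.length)) stop("tree has no branch lengths")
  if (anyDuplicated(phy$tip.label)) stop("tip labels must be unique")
  M <- ape::cophenetic.phylo(phy)
  M <- M[sort(rownames(M)), sort(rownames(M))]
  structure(list(labels = rownames(M), values = M, method = "cophenetic",
                 seed = NA_integer_), class = "dist_matrix")
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is.character(tree) && length(tree) == 1) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stop("tree must be a phylo object, newick string, or newick file path")
}

#' Principal components of z-scored climate variables
#'
#' z-scores every climate variable across localities, runs a PCA on the
#' resulting correlation structure and averages locality scores per species.
#' The default variable schema is the 17-variable bioclimatic set (BIO1..
#' BIO19 without BIO3 and BIO7, which are linear combinations of others and
#' are dropped on load by [read_climate()]).
#'
#' @param climate data.frame with columns `locality`, `species` and numeric
#'   climate variables.
#' @return list of class `climate_pca`: `species_scores` (species x PCs),
#'   `locality_scores`, `loadings`, `variance_explained` (percent per PC).
#' @export
climate_pca <- function(climate) {
  meta <- intersect(c("locality", "species"), names(climate))
  if (!"species" %in% meta) stop("climate table needs a species column")
  vars <- setdiff(names(climate), c("locality", "species"))
  if (length(vars) < 2) stop("need at least 2 climate variables")
  X <- as.matrix(climate[vars])
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant climate variable(s): ",
         paste(vars[sds == 0], collapse = ", "))
  }
  Z <- scale(X)
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  scores <- pc$x
  sp <- as.character(climate$species)
  agg <- rowsum(scores, sp) / as.vector(table(sp)[sort(unique(sp))])
  ve <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  structure(list(species_scores = agg, locality_scores = scores,
                 loadings = pc$rotation,
                 variance_explained = ve), class = "climate_pca")
}

#' Multivariate phylogenetic signal (K_mult)
#'
#' Multivariate generalization of Blomberg's K: the ratio of the observed
#' quotient of mean squared deviations from the phylogenetic mean (raw vs.
#' phylogenetically whitened) to its Brownian-motion expectation
#' `(tr(C) - n / sum(solve(C))) / (n - 1)`, with `C` the phylogenetic
#' covariance of the tree. K = 1 under Brownian motion; values above 1 mean
#' closer relatives are more similar than Brownian motion predicts.
#' Significance is assessed by permuting species rows across tips and
#' counting permuted K greater than or equal to the observed value.
#'
#' @param tree phylo object / newick with branch lengths.
#' @param species_traits species x q numeric matrix with species rownames
#'   matching the tip labels (a vector is treated as q = 1).
#' @param n_perm permutations (default 999); `p = (1 + #{K* >= K}) /
#'   (1 + n_perm)`.
#' @param seed integer seed for the permutations.
#' @return list of class `kmult_result`: `K`, `p`, `n_perm`, `permuted`.
#' @export
kmult <- function(tree, species_traits, n_perm = 999, seed = 1) {
  phy <- as_phylo(tree)
  if (is.vector(species_traits)) {
    species_traits <- matrix(species_traits,
                             dimnames = list(names(species_traits), "t1"))
  }
  Y <- as.matrix(species_traits)
  if (is.null(rownames(Y))) stop("species_traits needs species rownames")
  mismatch <- c(setdiff(rownames(Y), phy$tip.label),
                setdiff(phy$tip.label, rownames(Y)))
  if (length(mismatch) > 0) {
    stop("tip/species label mismatch: ", paste(mismatch, collapse = ", "))
  }
  Y <- Y[phy$tip.label, , drop = FALSE]
  C <- ape::vcv(phy)[phy$tip.label, phy$tip.label]
  n <- nrow(Y)
  Cinv <- solve(C)
  ones <- rep(1, n)
  denom_exp <- (sum(diag(C)) - n / sum(Cinv)) / (n - 1)
  k_stat <- function(Y) {
    a <- crossprod(ones, Cinv %*% Y) / sum(Cinv)   # phylogenetic mean
    R <- Y - ones %*% a
    mse0 <- sum(R^2) / (n - 1)
    mse <- sum(R * (Cinv %*% R)) / (n - 1)
    (mse0 / mse) / denom_exp
  }
  K <- k_stat(Y)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    k_stat(Y[sample.int(n), , drop = FALSE])
  }, numeric(1))
  p <- (1 + sum(perm >= K)) / (1 + n_perm)
  structure(list(K = K, p = p, n_perm = n_perm, permuted = perm),
            class = "kmult_result")
}

#' @export
print.kmult_result <- function(x, ...) {
  cat(sprintf("K_mult = %.3f, p = %.3f (%d permutations)\n",
              x$K, x$p, x$n_perm))
  invisible(x)
}

#' Screen ordination axes against candidate predictors
#'
#' Pearson correlation tests between every candidate response axis and
#' every predictor; response axes significantly correlated with at least one
#' predictor are retained, as are predictors significantly correlated with
#' at least one retained axis (the reciprocal screening used to choose
#' variation-partitioning inputs). No multiple-testing correction is applied
#' by default; `adjust = "holm"` is available.
#'
#' @param axes numeric matrix of candidate response axes (objects x axes).
#' @param predictors numeric matrix or list of predictor vectors.
#' @param alpha retention level (default 0.05).
#' @param adjust p-value adjustment method (default `"none"`).
#' @return list of class `axis_screen`: `table` (axis, predictor, cor, p),
#'   `retained_axes`, `retained_predictors` (integer indices).
#' @export
screen_axes <- function(axes, predictors, alpha = 0.05, adjust = "none") {
  axes <- as.matrix(axes)
  if (is.list(predictors) && !is.data.frame(predictors)) {
    predictors <- do.call(cbind, predictors)
  }
  predictors <- as.matrix(predictors)
  if (nrow(axes) != nrow(predictors)) stop("row mismatch")
  if (nrow(axes) < 4) stop("need at least 4 objects for correlation tests")
  if (is.null(colnames(axes))) colnames(axes) <- paste0("axis", seq_len(ncol(axes)))
  if (is.null(colnames(predictors))) {
    colnames(predictors) <- paste0("pred", seq_len(ncol(predictors)))
  }
  tab <- expand.grid(axis = colnames(axes), predictor = colnames(predictors),
                     stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(tab)), function(k) {
    ct <- stats::cor.test(axes[, tab$axis[k]], predictors[, tab$predictor[k]])
    c(cor = unname(ct$estimate), p = ct$p.value)
  })
  tab$cor <- vapply(res, `[[`, numeric(1), "cor")
  tab$p <- vapply(res, `[[`, numeric(1), "p")
  tab$p_adj <- stats::p.adjust(tab$p, method = adjust)
  sig <- tab$p_adj < alpha
  retained_axes <- which(colnames(axes) %in% unique(tab$axis[sig]))
  keep_pred <- sig & tab$axis %in% colnames(axes)[retained_axes]
  retained_predictors <- which(colnames(predictors) %in%
                                 unique(tab$predictor[keep_pred]))
  structure(list(table = tab, retained_axes = retained_axes,
                 retained_predictors = retained_predictors),
            class = "axis_screen")
}

#' Variation partitioning between two predictor sets
#'
#' Redundancy-analysis decomposition of the variance of a (multivariate)
#' response explained by two predictor sets X1 and X2: R-squared values for
#' X1, X2 and their union are adjusted by Ezekiel's formula
#' `1 - (1 - R2)(n - 1)/(n - m - 1)` and combined into the unique fractions
#' `[a] = R2adj(full) - R2adj(X2)`, `[c] = R2adj(full) - R2adj(X1)` and the
#' shared fraction `[b] = R2adj(X1) + R2adj(X2) - R2adj(full)`. Marginal
#' fractions (X1, X2) are tested by permutation of the response rows; the
#' conditional fractions by permutation of the residuals of the reduced
#' model. The shared fraction has no degrees of freedom and is reported
#' untested. Negative adjusted fractions are reported as computed.
#'
#' @param Y response matrix (objects x variables) or vector.
#' @param X1,X2 predictor matrices (objects x variables) or vectors.
#' @param n_perm permutations for the F-tests (default 999).
#' @param seed integer seed.
#' @param perm_conditional `"residual"` (default: permute reduced-model
#'   residuals) or `"raw"` (permute Y rows).
#' @return list of class `varpart_result`: `r2adj_X1`, `r2adj_X2`,
#'   `r2adj_full`, `frac_a`, `frac_b`, `frac_c`, `residual`, `tests`
#'   (data.frame: fraction, F, p; shared fraction has NA entries).
#' @export
variation_partition <- function(Y, X1, X2, n_perm = 999, seed = 1,
                                perm_conditional = c("residual", "raw")) {
  perm_conditional <- match.arg(perm_conditional)
  Y <- as.matrix(Y)
  X1 <- as.matrix(X1)
  X2 <- as.matrix(X2)
  n <- nrow(Y)
  if (nrow(X1) != n || nrow(X2) != n) stop("row mismatch")
  m1 <- ncol(X1); m2 <- ncol(X2)
  if (n <= m1 + m2 + 1) stop("need n > combined predictor count + 1")
  if (qr(cbind(scale(X1, scale = FALSE), scale(X2, scale = FALSE)))$rank <
      m1 + m2) {
    stop("collinear full design (X1 union X2)")
  }
  Yc <- scale(Y, scale = FALSE)
  tot <- sum(Yc^2)
  if (tot == 0) stop("response has no variance")
  r2 <- function(X) {
    Q <- qr.Q(qr(cbind(1, X)))
    sum((Q %*% crossprod(Q, Yc))^2) / tot
  }
  adj <- function(R2, m) 1 - (1 - R2) * (n - 1) / (n - m - 1)
  r2_1 <- r2(X1); r2_2 <- r2(X2); r2_f <- r2(cbind(X1, X2))
  a1 <- adj(r2_1, m1); a2 <- adj(r2_2, m2); af <- adj(r2_f, m1 + m2)
  frac_a <- af - a2
  frac_c <- af - a1
  frac_b <- a1 + a2 - af
  set.seed(seed)
  tests <- rbind(
    marginal_test(Yc, X1, n_perm),
    marginal_test(Yc, X2, n_perm),
    conditional_test(Yc, X1, X2, n_perm, perm_conditional),
    conditional_test(Yc, X2, X1, n_perm, perm_conditional),
    data.frame(F = NA_real_, p = NA_real_))
  tests <- cbind(fraction = c("X1", "X2", "X1|X2", "X2|X1", "shared"), tests)
  rownames(tests) <- NULL
  structure(list(r2adj_X1 = a1, r2adj_X2 = a2, r2adj_full = af,
                 frac_a = frac_a, frac_b = frac_b, frac_c = frac_c,
                 residual = 1 - af, tests = tests,
                 n = n, n_perm = n_perm, seed = seed),
            class = "varpart_result")
}

# permutation F-test of Y ~ X (rows of Y permuted)
marginal_test <- function(Yc, X, n_perm) {
  n <- nrow(Yc)
  m <- ncol(X)
  Q <- qr.Q(qr(cbind(1, X)))
  fstat <- function(Y) {
    H <- Q %*% crossprod(Q, Y)
    fit <- sum(H^2)
    res <- sum((Y - H)^2)          # explicit residual norm: never negative
    (fit / m) / (res / (n - 1 - m))
  }
  f0 <- fstat(Yc)
  perm <- vapply(seq_len(n_perm),
                 function(i) fstat(Yc[sample.int(n), , drop = FALSE]),
                 numeric(1))
  data.frame(F = f0, p = (1 + sum(perm >= f0)) / (1 + n_perm))
}

# partial permutation F-test of Y ~ X | W (residuals of reduced model permuted)
conditional_test <- function(Yc, X, W, n_perm, scheme) {
  n <- nrow(Yc)
  m <- ncol(X)
  mw <- ncol(W)
  Qw <- qr.Q(qr(cbind(1, W)))
  Qf <- qr.Q(qr(cbind(1, W, X)))
  fstat <- function(Y) {
    fit_w <- sum((Qw %*% crossprod(Qw, Y))^2)
    Hf <- Qf %*% crossprod(Qf, Y)
    fit_f <- sum(Hf^2)
    res <- sum((Y - Hf)^2)
    (max(fit_f - fit_w, 0) / m) / (res / (n - 1 - m - mw))
  }
  f0 <- fstat(Yc)
  fit_w <- Qw %*% crossprod(Qw, Yc)
  res_w <- Yc - fit_w
  perm <- vapply(seq_len(n_perm), function(i) {
    Yp <- if (scheme == "residual") {
      fit_w + res_w[sample.int(n), , drop = FALSE]
    } else {
      Yc[sample.int(n), , drop = FALSE]
    }
    fstat(Yp)
  }, numeric(1))
  data.frame(F = f0, p = (1 + sum(perm >= f0)) / (1 + n_perm))
}

#' @export
print.varpart_result <- function(x, ...) {
  cat("Variation partitioning (adjusted R2)\n")
  cat(sprintf("  X1 total      : %+.3f\n", x$r2adj_X1))
  cat(sprintf("  X2 total      : %+.3f\n", x$r2adj_X2))
  cat(sprintf("  [a] X1 | X2   : %+.3f\n", x$frac_a))
  cat(sprintf("  [b] shared    : %+.3f (untestable)\n", x$frac_b))
  cat(sprintf("  [c] X2 | X1   : %+.3f\n", x$frac_c))
  cat(sprintf("  residual      : %+.3f\n", x$residual))
  invisible(x)
}
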