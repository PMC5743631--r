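#' Remove isometric size by Somers double-centering
#'
#' Log-transforms all traits, then subtracts each specimen's own row mean
#' (its log-size score) and finally each trait's column mean. A specimen
#' whose traits all differ from another's by one multiplicative constant
#' becomes identical to it, so uniform (isometric) scaling is removed while
#' disproportionate (allometric) variation is retained. The output feeds
#' [estimate_pmatrix()] to give the "no isometric size" P-matrix.
#'
#' Apply this to covariate-corrected data (traits reconstructed as species
#' mean + residual) or to raw single-group data; trait values must be
#' strictly positive since they are logged.
#'
#' @param residuals a trait table with strictly positive trait values.
#' @return trait table of log-scale, double-centered values (row means and
#'   column means are 0 within each species).
#' @export
remove_isometric <- function(residuals) {
  validate_trait_table(residuals)
  tn <- trait_names(residuals)
  out <- residuals
  for (sp in unique(residuals$species)) {
    idx <- residuals$species == sp
    M <- as.matrix(residuals[idx, tn, drop = FALSE])
    if (any(M <= 0)) {
      bad <- residuals$specimen_id[idx][rowSums(M <= 0) > 0]
      stop("nonpositive trait value(s); cannot log-transform specimens: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    L <- log(M)
    L <- L - rowMeans(L)          # remove per-specimen isometric size score
    L <- sweep(L, 2, colMeans(L)) # center each trait
    out[idx, tn] <- L
  }
  out
}

#' Remove allometric size by deflating the first principal component
#'
#' Subtracts the variance associated with PC1 of the covariance matrix,
#' `cov_res = cov - lambda1 * v1 %*% t(v1)`, and returns the result as a
#' correlation matrix. When PC1 has same-sign loadings it is interpreted as
#' allometric size, so the residual matrix carries the size-free correlation
#' structure. The deflated matrix has rank `p - 1`, which is recorded so
#' that downstream inversions know to noise-extend first.
#'
#' @param P a [pmatrix].
#' @param tol relative tolerance below which the two leading eigenvalues are
#'   considered tied (PC1 ambiguous) and an error is thrown.
#' @return a [pmatrix] of kind `"no_allometric"` whose `cov` is the deflated
#'   covariance and `cor` its correlation; attribute `rank` is `p - 1`.
#' @export
remove_allometric <- function(P, tol = 1e-8) {
  stopifnot(inherits(P, "pmatrix"))
  eg <- eigen(P$cov, symmetric = TRUE)
  if ((eg$values[1] - eg$values[2]) <= tol * eg$values[1]) {
    stop("leading eigenvalues are tied; PC1 (allometric size) is ambiguous")
  }
  v1 <- eg$vectors[, 1]
  covr <- P$cov - eg$values[1] * tcrossprod(v1)
  covr <- (covr + t(covr)) / 2
  dimnames(covr) <- dimnames(P$cov)
  out <- P
  out$cov <- covr
  out$cor <- cov2cor_safe(covr)
  out$kind <- "no_allometric"
  attr(out, "rank") <- ncol(covr) - 1
  out
}

#' Size structure of a P-matrix
#'
#' Leading-eigenpair summary used to judge whether PC1 can be read as
#' (allometric) size: the percent of total variance on PC1 and whether all
#' its loadings share one sign. PC1 is oriented so its loading mean is
#' positive. `allometry_coeffs` are the deviations of the normalized
#' loadings from the isometric vector `1/sqrt(p)`; non-zero deviations with
#' same-sign loadings indicate allometry rather than pure isometry.
#'
#' @param P a [pmatrix].
#' @return list of class `size_report`: `pc1_loadings`, `pc1_percent`,
#'   `same_sign`, `allometry_coeffs`, `dominant` (FALSE when PC1 carries no
#'   more variance than the average eigenvalue, i.e. no dominant axis).
#' @export
size_report <- function(P) {
  stopifnot(inherits(P, "pmatrix"))
  eg <- eigen(P$cov, symmetric = TRUE)
  p <- length(eg$values)
  v1 <- eg$vectors[, 1]
  if (mean(v1) < 0) v1 <- -v1
  pct <- 100 * eg$values[1] / sum(eg$values)
  same_sign <- all(v1 > 0) || all(v1 < 0)
  dominant <- eg$values[1] > (1 + 1e-8) * mean(eg$values)
  structure(list(
    pc1_loadings = stats::setNames(v1, P$trait_names),
    pc1_percent = pct,
    same_sign = same_sign,
    allometry_coeffs = stats::setNames(v1 - 1 / sqrt(p), P$trait_names),
    dominant = dominant), class = "size_report")
}

#' @export
print.size_report <- function(x, ...) {
  cat(sprintf("PC1: %.1f%% of total variance; same-sign loadings: %s%s\n",
              x$pc1_percent, x$same_sign,
              if (!x$dominant) " (no dominant axis)" else ""))
  invisible(x)
}

#' Build the three size-treatment variants of a species P-matrix
#'
#' Convenience wrapper producing the matrix variants analyzed throughout
#' the pipeline: with size, without isometric size (Somers double-centering
#' of the data, then re-estimation) and without allometric size (PC1
#' deflation of the covariance).
#'
#' @param residual_table covariate-corrected trait table for one species on
#'   the measurement scale: residuals with the species trait means kept
#'   (`fit_residuals(..., keep_means = TRUE)`), strictly positive so that
#'   the Somers log transform applies.
#' @param model_rank design rank used for the residual df.
#' @return named list of [pmatrix] objects: `with_size`, `no_isometric`,
#'   `no_allometric`.
#' @export
size_variants <- function(residual_table, model_rank = 1) {
  validate_trait_table(residual_table)
  sp <- as.character(residual_table$species[1])
  tn <- trait_names(residual_table)
  centered <- residual_table
  centered[tn] <- scale(as.matrix(residual_table[tn]), scale = FALSE)
  with_size <- estimate_pmatrix(centered, model_rank = model_rank,
                                species = sp, kind = "with_size")
  dc <- remove_isometric(residual_table)
  no_iso <- estimate_pmatrix(dc, model_rank = model_rank, species = sp,
                             kind = "no_isometric")
  no_allo <- remove_allometric(with_size)
  list(with_size = with_size, no_isometric = no_iso, no_allometric = no_allo)
}
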