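#' Random Skewers similarity between two covariance matrices
#'
#' Applies the same random unit-length selection vectors (skewers) `beta` to
#' both matrices via the multivariate selection equation `dz = P beta` and
#' measures, per skewer, the vector correlation (cosine of the angle)
#' between the two response vectors; the similarity `S` is the mean over
#' skewers. Identical (or proportional) matrices give `S = 1`.
#'
#' @param P1,P2 covariance matrices of equal dimension.
#' @param n_skewers number of skewers (default 1000).
#' @param seed integer seed; results are deterministic given the seed.
#' @param dist skewer component distribution before normalization:
#'   `"gaussian"` (isotropic, uniform on the sphere; default) or
#'   `"uniform"` (components uniform on `[-1, 1]`, the historical variant).
#' @return list of class `skewer_result`: `similarity`, `n_skewers`,
#'   `seed`, `per_skewer` (vector of per-skewer correlations).
#' @export
random_skewers <- function(P1, P2, n_skewers = 1000, seed = 1,
                           dist = c("gaussian", "uniform")) {
  dist <- match.arg(dist)
  P1 <- as.matrix(P1)
  P2 <- as.matrix(P2)
  if (!all(dim(P1) == dim(P2))) stop("matrices must have equal dimensions")
  p <- ncol(P1)
  set.seed(seed)
  B <- if (dist == "gaussian") {
    matrix(stats::rnorm(p * n_skewers), nrow = p)
  } else {
    matrix(stats::runif(p * n_skewers, -1, 1), nrow = p)
  }
  B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  Z1 <- P1 %*% B
  Z2 <- P2 %*% B
  num <- colSums(Z1 * Z2)
  den <- sqrt(colSums(Z1^2) * colSums(Z2^2))
  r <- ifelse(den == 0, 0, num / den)
  structure(list(similarity = mean(r), n_skewers = n_skewers, seed = seed,
                 per_skewer = r), class = "skewer_result")
}

#' @export
print.skewer_result <- function(x, ...) {
  cat(sprintf("Random Skewers similarity S = %.4f (%d skewers)\n",
              x$similarity, x$n_skewers))
  invisible(x)
}

#' Random Skewers dissimilarity
#'
#' Converts a similarity `S` into a dissimilarity, `sqrt(1 - S)`.
#'
#' @param S similarity value (or vector), `S <= 1`.
#' @return `sqrt(1 - S)`.
#' @export
rs_dissimilarity <- function(S) {
  if (any(S > 1 + 1e-12)) stop("similarity cannot exceed 1")
  sqrt(pmax(1 - S, 0))
}

#' Relative-eigenanalysis distance between covariance matrices
#'
#' The metric `d = sqrt(sum(log(lambda_i)^2))` over the relative eigenvalues
#' `lambda_i` of `P1` in the metric of `P2` (the eigenvalues of
#' `solve(P2) %*% P1`). Computed through the symmetric whitened form
#' `C^(-1/2) P1 C^(-1/2)` with `C = P2` for numerical stability; both
#' matrices must be strictly positive definite (noise-extend first, see
#' [extend_matrix()]). The distance is symmetric in its arguments and
#' invariant to a common invertible linear change of the trait basis.
#'
#' @param P1,P2 strictly positive-definite matrices of equal dimension.
#' @return nonnegative distance.
#' @export
relative_eigen_distance <- function(P1, P2) {
  P1 <- as.matrix(P1)
  P2 <- as.matrix(P2)
  if (!all(dim(P1) == dim(P2))) stop("matrices must have equal dimensions")
  e2 <- eigen(P2, symmetric = TRUE)
  if (min(e2$values) <= 0 ||
      min(eigen(P1, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("matrices must be positive definite; apply extend_matrix() first")
  }
  w <- e2$vectors %*% (t(e2$vectors) / sqrt(e2$values))  # P2^(-1/2)
  M <- t(w) %*% P1 %*% w
  M <- (M + t(M)) / 2
  lam <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(lam)^2))
}

#' Dissimilarity matrix among species covariance matrices
#'
#' Compares all unordered pairs of species matrices either by Random Skewers
#' (dissimilarity `sqrt(1 - S)`) or by the relative-eigenanalysis distance.
#' For the RS path each pair uses a fresh random stream whose seed is
#' derived deterministically from the master seed and the pair's sorted
#' labels, so the matrix does not depend on enumeration order.
#'
#' @param mats named list of covariance matrices (>= 3 species).
#' @param method `"rs"` or `"re"`.
#' @param n_skewers skewers per pair for the RS path.
#' @param seed master seed for the RS path.
#' @param dist skewer distribution, see [random_skewers()].
#' @return object of class `dist_matrix`: list with `labels`, `values`
#'   (symmetric matrix, zero diagonal), `method`, `seed`.
#' @export
dissimilarity_matrix <- function(mats, method = c("rs", "re"),
                                 n_skewers = 1000, seed = 1,
                                 dist = "gaussian") {
  method <- match.arg(method)
  labels <- names(mats)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("matrices must carry unique species labels")
  }
  k <- length(mats)
  if (k < 3) stop("need at least 3 species")
  D <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- if (method == "rs") {
        s <- random_skewers(mats[[i]], mats[[j]], n_skewers = n_skewers,
                            seed = pair_seed(seed, labels[i], labels[j]),
                            dist = dist)$similarity
        rs_dissimilarity(s)
      } else {
        relative_eigen_distance(mats[[i]], mats[[j]])
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  structure(list(labels = labels, values = D,
                 method = if (method == "rs") "rs_sqrt1mS" else "relative_eigen",
                 seed = if (method == "rs") as.integer(seed) else NA_integer_),
            class = "dist_matrix")
}

# deterministic per-pair seed from master seed and sorted labels
pair_seed <- function(seed, a, b) {
  lab <- paste(sort(c(a, b)), collapse = "|")
  h <- sum(utf8ToInt(lab) * seq_along(utf8ToInt(lab)))
  as.integer((seed * 7919 + h * 104729) %% 2147483647L)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("Dissimilarity matrix (", x$method, ") over ",
      length(x$labels), " species\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}
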