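test_that("estimate_pmatrix matches hand computation and the loop oracle", {
  # n = 2 residual rows of a rank-1 design: denominator n - rank = 1
  R <- matrix(c(1, 1, -1, -1), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("d1", "d2")))
  P <- estimate_pmatrix(R, model_rank = 1)
  expect_equal(unname(P$cov), matrix(2, 2, 2))
  expect_equal(unname(P$cor), matrix(1, 2, 2))

  # random residuals: equals sum of outer products over df
  set.seed(5)
  R <- scale(matrix(rnorm(60), 20, 3), scale = FALSE)
  oracle <- matrix(0, 3, 3)
  for (i in 1:20) oracle <- oracle + tcrossprod(R[i, ])
  oracle <- oracle / (20 - 2)
  P <- estimate_pmatrix(R, model_rank = 2)
  expect_equal(unname(P$cov), oracle, tolerance = 1e-12)
  expect_equal(P$df, 18)

  # intercept-only residuals reproduce the sample covariance (n - 1)
  X <- matrix(rnorm(80), 20, 4)
  Rc <- scale(X, scale = FALSE)
  P1 <- estimate_pmatrix(Rc, model_rank = 1)
  expect_equal(unname(P1$cov), unname(cov(X)), tolerance = 1e-12)

  expect_error(estimate_pmatrix(R[1:2, ], model_rank = 2), "n > model_rank")
})

test_that("pmatrix correlations have unit diagonal and entries in [-1, 1]", {
  for (s in 1:20) {
    P <- estimate_pmatrix(matrix(rnorm(8 * 12), 12, 8), model_rank = 1)
    expect_equal(unname(diag(P$cor)), rep(1, 8))
    expect_true(all(abs(P$cor) <= 1 + 1e-12))
    expect_equal(P$cor, cov2cor(P$cov), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("residuals of a balanced two-group shift give the pooled covariance", {
  set.seed(9)
  Sigma <- random_spd(4, seed = 2)
  n <- 60
  X <- MASS::mvrnorm(2 * n, mu = rep(0, 4), Sigma = Sigma)
  X[1:n, 1] <- X[1:n, 1] + 3          # sex mean offset on one trait
  tab <- as_trait_table(X, sex = rep(c("M", "F"), each = n))
  fr <- fit_residuals(tab, covariates = "sex")
  expect_true(fr$report$retained[fr$report$covariate == "sex"])
  P <- estimate_pmatrix(fr$residuals, model_rank = unname(fr$rank["spA"]))

  # oracle: group-wise centering then average of group covariances
  g1 <- scale(X[1:n, ], scale = FALSE)
  g2 <- scale(X[(n + 1):(2 * n), ], scale = FALSE)
  pooled <- (crossprod(g1) + crossprod(g2)) / (2 * n - 2)
  expect_equal(unname(P$cov), unname(pooled), tolerance = 1e-10)
})

test_that("pooling invariance: balanced shift removal equals mean of group covariances", {
  set.seed(77)
  X <- MASS::mvrnorm(40, rep(0, 3), random_spd(3, seed = 3))
  X[1:20, ] <- X[1:20, ] + 5
  tab <- as_trait_table(X, sex = rep(c("A", "B"), each = 20))
  fr <- fit_residuals(tab, covariates = "sex", alpha = 1)
  P <- estimate_pmatrix(fr$residuals, model_rank = 2)
  cov_g <- (cov(X[1:20, ]) * 19 + cov(X[21:40, ]) * 19) / 38
  expect_equal(unname(P$cov), unname(cov_g), tolerance = 1e-10)
})

test_that("single-level or absent covariates reduce to species-mean centering", {
  set.seed(13)
  tab <- as_trait_table(matrix(rnorm(50), 25, 2))
  fr0 <- fit_residuals(tab, covariates = character(0))
  expect_equal(as.matrix(fr0$residuals[c("d1", "d2")]),
               scale(as.matrix(tab[c("d1", "d2")]), scale = FALSE),
               ignore_attr = TRUE)
  fr1 <- fit_residuals(tab, covariates = "sex")  # sex constant
  expect_equal(fr1$residuals, fr0$residuals)
  expect_equal(unname(fr1$rank["spA"]), 1)
})

test_that("non-significant covariates are dropped by the MANOVA screen", {
  set.seed(17)
  X <- MASS::mvrnorm(80, rep(0, 3), diag(3))
  tab <- as_trait_table(X, sex = rep(c("M", "F"), 40))
  fr <- fit_residuals(tab, covariates = "sex", alpha = 1e-12)
  expect_equal(unname(fr$rank["spA"]), 1)  # screened out at tiny alpha
})

test_that("resampled P-matrices are deterministic and unbiased", {
  P <- pmatrix(random_spd(4, seed = 4), n = 50, df = 49)
  rs1 <- resample_pmatrices(P, B = 20, seed = 101)
  rs2 <- resample_pmatrices(P, B = 20, seed = 101)
  expect_identical(rs1$matrices, rs2$matrices)

  # mean of replicate covariances approaches the parent
  rs <- resample_pmatrices(P, B = 500, seed = 5)
  m <- Reduce(`+`, rs$matrices) / rs$B
  expect_lt(norm(m - P$cov, "F") / norm(P$cov, "F"), 0.05)

  # identity parent at large n: off-diagonals are sampling noise only
  Pi <- pmatrix(diag(4), n = 1e4, df = 1e4 - 1)
  ri <- resample_pmatrices(Pi, B = 100, seed = 6)
  offmax <- max(vapply(ri$matrices, function(M) max(abs(M[row(M) != col(M)])),
                       numeric(1)))
  expect_lt(offmax, 0.05)
})

test_that("matrix repeatability reflects sampling noise and trait order", {
  P <- pmatrix(random_spd(5, seed = 7), n = 1e5, df = 1e5 - 1)
  rs_big <- resample_pmatrices(P, B = 20, seed = 8)
  rep_big <- matrix_repeatability(P, rs_big, n_skewers = 200, seed = 9)
  expect_gt(as.numeric(rep_big), 0.99)

  # smaller samples give strictly lower repeatability
  Ps <- pmatrix(P$cov, n = 6, df = 5)
  rs_small <- resample_pmatrices(Ps, B = 20, seed = 8)
  rep_small <- suppressWarnings(
    matrix_repeatability(Ps, rs_small, n_skewers = 200, seed = 9))
  expect_lt(as.numeric(rep_small), as.numeric(rep_big))

  # replicate identical to the parent: similarity 1 up to MC error
  rs1 <- resample_pmatrices(P, B = 1, seed = 10)
  rs1$matrices[[1]] <- P$cov
  expect_equal(as.numeric(matrix_repeatability(P, rs1, n_skewers = 100)),
               1, tolerance = 1e-10)

  # invariance to a consistent trait reordering
  perm <- c(3, 1, 5, 2, 4)
  Pp <- pmatrix(P$cov[perm, perm], n = P$n, df = P$df)
  rs_perm <- rs_big
  rs_perm$parent <- Pp
  rs_perm$matrices <- lapply(rs_big$matrices, function(M) M[perm, perm])
  rp <- matrix_repeatability(Pp, rs_perm, n_skewers = 200, seed = 9)
  # skewers are drawn in the (permuted) trait basis, so equality holds up
  # to skewer Monte-Carlo error
  expect_equal(as.numeric(rp), as.numeric(rep_big), tolerance = 1e-4)
})

test_that("noise extension floors trailing eigenvalues and keeps eigenvectors", {
  v <- eigen(random_spd(5, seed = 12), symmetric = TRUE)$vectors
  lam <- c(10, 5, 1, 0.01, 0.001)
  S <- v %*% diag(lam) %*% t(v)
  dimnames(S) <- list(paste0("d", 1:5), paste0("d", 1:5))
  E <- extend_matrix(S, cutoff = 4)
  eg <- eigen(E, symmetric = TRUE)
  expect_equal(eg$values, c(10, 5, 1, 0.01, 0.01), tolerance = 1e-9)
  # eigenvectors unchanged (up to sign) where eigenvalues are distinct
  for (k in 1:3) {
    expect_equal(abs(sum(eg$vectors[, k] * v[, k])), 1, tolerance = 1e-8)
  }
  # eigenvalues above the cutoff untouched; smallest never decreases
  expect_equal(eg$values[1:4], lam[1:4], tolerance = 1e-9)
  expect_gte(min(eg$values), min(lam))
  expect_error(extend_matrix(S, cutoff = 1), "cutoff")
  expect_error(extend_matrix(S, cutoff = 5), "cutoff")
})

test_that("automatic extension cutoff makes a deflated matrix invertible", {
  P <- pmatrix(random_spd(6, seed = 13), n = 40, df = 39)
  defl <- remove_allometric(P)
  expect_lt(min(eigen(defl$cov, symmetric = TRUE)$values), 1e-10)
  ext <- extend_matrix(defl)
  expect_gt(min(eigen(ext$cov, symmetric = TRUE)$values), 0)
})

test_that("the normality screen reports but never removes specimens", {
  set.seed(19)
  tab <- as_trait_table(cbind(rnorm(60), rexp(60)))
  scr <- normality_screen(tab)
  expect_equal(nrow(scr), 2)
  expect_false(scr$flagged[1])
  expect_true(scr$flagged[2])
})
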