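#' P-matrix objects
#'
#' A `pmatrix` bundles the pooled within-species phenotypic covariance and
#' correlation matrices for one species together with its sample size and the
#' residual degrees of freedom of the linear model whose residuals it was
#' estimated from.
#'
#' @param cov symmetric covariance matrix with trait dimnames.
#' @param n specimen count.
#' @param df residual degrees of freedom used as the covariance denominator.
#' @param species species label.
#' @param kind size-treatment label, one of `"with_size"`, `"no_isometric"`,
#'   `"no_allometric"`.
#' @return an object of class `pmatrix` with elements `species`, `cov`,
#'   `cor`, `n`, `df`, `trait_names`, `kind`.
#' @export
pmatrix <- function(cov, n, df, species = "", kind = "with_size") {
  cov <- as.matrix(cov)
  if (nrow(cov) != ncol(cov)) stop("cov must be square")
  if (max(abs(cov - t(cov))) > 1e-8 * max(1, max(abs(cov)))) {
    stop("cov must be symmetric")
  }
  cov <- (cov + t(cov)) / 2
  tn <- rownames(cov)
  if (is.null(tn)) {
    tn <- paste0("d", seq_len(nrow(cov)))
    dimnames(cov) <- list(tn, tn)
  }
  structure(list(species = species, cov = cov, cor = cov2cor_safe(cov),
                 n = as.integer(n), df = as.numeric(df), trait_names = tn,
                 kind = kind),
            class = "pmatrix")
}

#' @export
print.pmatrix <- function(x, ...) {
  cat("P-matrix", if (nzchar(x$species)) paste0("(", x$species, ")"), "\n")
  cat("  traits:", length(x$trait_names),
      " n:", x$n, " df:", x$df, " kind:", x$kind, "\n")
  offd <- x$cor[upper.tri(x$cor)]
  cat(sprintf("  mean |r| = %.3f, mean r = %.3f\n", mean(abs(offd)), mean(offd)))
  invisible(x)
}

# correlation from covariance tolerating zero-variance rows (left as 0, diag 1)
cov2cor_safe <- function(cov) {
  s <- sqrt(diag(cov))
  s[s == 0] <- NA
  cr <- cov / outer(s, s)
  cr[is.na(cr)] <- 0
  diag(cr) <- 1
  cr <- pmin(pmax(cr, -1), 1)
  dimnames(cr) <- dimnames(cov)
  cr
}

#' Remove mean effects of sex and locality by multivariate linear models
#'
#' Fits, per species, a multivariate linear model of all traits on the
#' requested covariates and returns the residuals (species mean added back is
#' NOT kept: residuals are centered). Each covariate is screened by MANOVA
#' (Wilks' lambda): covariates whose multivariate effect has `p >= alpha` are
#' dropped from the model, so only significant group-mean differences are
#' removed before P-matrix estimation. Per-trait univariate F-tests are
#' reported alongside.
#'
#' @param table a trait table (single or multiple species).
#' @param covariates character subset of `c("sex", "locality")`.
#' @param alpha significance level of the MANOVA screen (default 0.05);
#'   set to 1 to force all requested covariates into the model.
#' @param keep_means add each species' trait means back onto the residuals
#'   (default FALSE). Mean-kept residuals stay on the measurement scale
#'   (strictly positive for positive traits), as required by the Somers
#'   isometric-size removal.
#' @return list with `residuals` (trait table whose trait columns hold
#'   residuals), `report` (data.frame: species, covariate, wilks, F, df1,
#'   df2, p, retained), `rank` (named integer: design rank per species).
#' @export
fit_residuals <- function(table, covariates = c("sex", "locality"),
                          alpha = 0.05, keep_means = FALSE) {
  validate_trait_table(table)
  covariates <- intersect(covariates, c("sex", "locality"))
  tn <- trait_names(table)
  out <- table
  report <- list()
  rank <- integer(0)
  for (sp in unique(table$species)) {
    idx <- table$species == sp
    sub <- table[idx, , drop = FALSE]
    Y <- as.matrix(sub[tn])
    keep <- character(0)
    for (cv in covariates) {
      f <- factor(sub[[cv]])
      if (nlevels(f) < 2) next
      if (any(tabulate(f) < 2)) {
        warning("species ", sp, ": covariate ", cv,
                " has levels with < 2 specimens; skipped")
        next
      }
      man <- tryCatch(summary(stats::manova(Y ~ f), test = "Wilks"),
                      error = function(e) NULL)
      if (is.null(man)) next
      st <- man$stats
      report[[length(report) + 1]] <- data.frame(
        species = sp, covariate = cv,
        wilks = st[1, "Wilks"], F = st[1, "approx F"],
        df1 = st[1, "num Df"], df2 = st[1, "den Df"],
        p = st[1, "Pr(>F)"],
        retained = st[1, "Pr(>F)"] < alpha,
        stringsAsFactors = FALSE)
      if (st[1, "Pr(>F)"] < alpha) keep <- c(keep, cv)
    }
    if (length(keep) == 0) {
      fit <- stats::lm(Y ~ 1)
    } else {
      design <- sub[keep]
      design[] <- lapply(design, factor)
      fit <- stats::lm(Y ~ ., data = design)
      if (fit$qr$rank < ncol(stats::model.matrix(fit))) {
        stop("species ", sp, ": singular design; aliased coefficients: ",
             paste(colnames(stats::model.matrix(fit))[is.na(stats::coef(fit)[, 1])],
                   collapse = ", "))
      }
    }
    res <- stats::residuals(fit)
    if (keep_means) res <- sweep(res, 2, colMeans(Y), "+")
    out[idx, tn] <- res
    rank[sp] <- fit$qr$rank
  }
  report <- if (length(report) > 0) do.call(rbind, report) else
    data.frame(species = character(0), covariate = character(0),
               wilks = numeric(0), F = numeric(0), df1 = numeric(0),
               df2 = numeric(0), p = numeric(0), retained = logical(0))
  list(residuals = out, report = report, rank = rank)
}

#' Univariate per-trait effect tests for a covariate
#'
#' Companion report to [fit_residuals()]: per-trait one-way ANOVA F-tests of
#' a covariate within one species.
#'
#' @param table single-species trait table.
#' @param covariate `"sex"` or `"locality"`.
#' @return data.frame with trait, F, df1, df2, p.
#' @export
univariate_effects <- function(table, covariate = "sex") {
  validate_trait_table(table)
  f <- factor(table[[covariate]])
  tn <- trait_names(table)
  do.call(rbind, lapply(tn, function(tr) {
    a <- stats::anova(stats::lm(table[[tr]] ~ f))
    data.frame(trait = tr, F = a$`F value`[1], df1 = a$Df[1], df2 = a$Df[2],
               p = a$`Pr(>F)`[1], stringsAsFactors = FALSE)
  }))
}

#' Normality screen of trait distributions
#'
#' Lilliefors (Kolmogorov-Smirnov with estimated parameters) test per trait,
#' reported for inspection only; no specimens are removed.
#'
#' @param table single-species trait table.
#' @param alpha flagging level (default 0.05).
#' @return data.frame with trait, D statistic, p, flagged.
#' @export
normality_screen <- function(table, alpha = 0.05) {
  validate_trait_table(table)
  tn <- trait_names(table)
  do.call(rbind, lapply(tn, function(tr) {
    x <- table[[tr]]
    lt <- lilliefors(x)
    data.frame(trait = tr, D = lt$statistic, p = lt$p,
               flagged = lt$p < alpha, stringsAsFactors = FALSE)
  }))
}

# Lilliefors test: KS distance to a normal with estimated mean/sd, p-value
# by the Dallal-Wilkinson approximation as used in standard implementations.
lilliefors <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 5) stop("Lilliefors test needs n >= 5")
  z <- stats::pnorm((x - mean(x)) / stats::sd(x))
  dplus <- max(seq_len(n) / n - z)
  dminus <- max(z - (seq_len(n) - 1) / n)
  d <- max(dplus, dminus)
  # Dallal & Wilkinson (1986) approximation
  if (n > 100) {
    dd <- d * (n / 100)^0.49
    nn <- 100
  } else {
    dd <- d
    nn <- n
  }
  p <- exp(-7.01256 * dd^2 * (nn + 2.78019) + 2.99587 * dd *
             sqrt(nn + 2.78019) - 0.122119 + 0.974598 / sqrt(nn) +
             1.67997 / nn)
  if (p > 0.1) {
    kd <- (sqrt(n) - 0.01 + 0.85 / sqrt(n)) * d
    p <- if (kd <= 0.302) 1 else if (kd <= 0.5)
      2.76773 - 19.828315 * kd + 80.709644 * kd^2 - 138.55152 * kd^3 +
        81.218052 * kd^4
    else if (kd <= 0.9)
      -4.901232 + 40.662806 * kd - 97.490286 * kd^2 + 94.029866 * kd^3 -
        32.355711 * kd^4
    else if (kd <= 1.31)
      6.198765 - 19.558097 * kd + 23.186922 * kd^2 - 12.234627 * kd^3 +
        2.423045 * kd^4
    else 0
  }
  list(statistic = d, p = min(max(p, 0), 1))
}

#' Estimate a P-matrix from linear-model residuals
#'
#' Pooled within-group covariance `cov = t(R) %*% R / (n - model_rank)` on
#' the residual matrix `R`, i.e. the residual cross-product divided by the
#' residual degrees of freedom of the fitted design (the matrix-from-residuals
#' convention). Set `denominator = "n-1"` for the plain sample-covariance
#' denominator regardless of design rank.
#'
#' @param residuals trait table of residuals for ONE species (or a plain
#'   numeric matrix).
#' @param model_rank rank of the fitted design (1 for intercept-only).
#' @param species species label carried into the result.
#' @param kind size-treatment label.
#' @param denominator `"n-rank"` (default) or `"n-1"`.
#' @return a [pmatrix].
#' @export
estimate_pmatrix <- function(residuals, model_rank = 1, species = "",
                             kind = "with_size", denominator = c("n-rank", "n-1")) {
  denominator <- match.arg(denominator)
  if (is.data.frame(residuals)) {
    if (!nzchar(species) && "species" %in% names(residuals)) {
      species <- as.character(residuals$species[1])
    }
    R <- trait_matrix(residuals)
  } else {
    R <- as.matrix(residuals)
  }
  n <- nrow(R)
  if (n <= model_rank) stop("need n > model_rank (n = ", n,
                            ", rank = ", model_rank, ")")
  df <- if (denominator == "n-rank") n - model_rank else n - 1
  # R holds residuals of a fitted design, so it is already centered;
  # the estimator is the raw residual cross-product over the residual df
  cov <- crossprod(R) / df
  pmatrix(cov, n = n, df = df, species = species, kind = kind)
}

#' Monte-Carlo resampling of a P-matrix
#'
#' Draws `B` replicate P-matrices, each the sample covariance of `P$n`
#' observations from a zero-mean multivariate normal with covariance
#' `P$cov`, mirroring the sampling noise of the empirical estimate.
#'
#' @param P a [pmatrix].
#' @param B number of replicates (default 1000).
#' @param seed integer seed; the draw is deterministic given `seed`.
#' @param n override for the number of observations per replicate
#'   (defaults to `P$n`).
#' @return list of class `resample_set` with `parent`, `B`, `seed`, `n` and
#'   `matrices` (list of `B` covariance matrices; correlations via
#'   [cov2cor_safe()] on demand).
#' @export
resample_pmatrices <- function(P, B = 1000, seed = 1, n = P$n) {
  stopifnot(inherits(P, "pmatrix"), B >= 1)
  ev <- eigen(P$cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(ev)) {
    stop("covariance is indefinite; apply extend_matrix() first")
  }
  if (n <= ncol(P$cov)) {
    warning("replicate sample size n <= p; replicate matrices are singular")
  }
  set.seed(seed)
  mats <- vector("list", B)
  for (b in seq_len(B)) {
    X <- MASS::mvrnorm(n, mu = rep(0, ncol(P$cov)), Sigma = P$cov)
    mats[[b]] <- stats::cov(X)
    dimnames(mats[[b]]) <- dimnames(P$cov)
  }
  structure(list(parent = P, B = B, seed = seed, n = n, matrices = mats),
            class = "resample_set")
}

#' Matrix repeatability by Random Skewers
#'
#' Mean Random Skewers similarity between the empirical matrix and each of
#' its Monte-Carlo resampled replicates; values near 1 mean the empirical
#' matrix is estimated with little sampling noise.
#'
#' @param P a [pmatrix]; must be the parent of `rs`.
#' @param rs a `resample_set` from [resample_pmatrices()].
#' @param use compare covariance (`"cov"`, default) or correlation
#'   (`"cor"`) matrices.
#' @param n_skewers skewers per comparison (default 1000).
#' @param seed master seed for the skewer draws.
#' @return mean similarity in `[0, 1]` with attribute `per_replicate`.
#' @export
matrix_repeatability <- function(P, rs, use = c("cov", "cor"),
                                 n_skewers = 1000, seed = 1) {
  use <- match.arg(use)
  stopifnot(inherits(P, "pmatrix"), inherits(rs, "resample_set"))
  if (!identical(rs$parent$cov, P$cov)) {
    stop("resample set was not generated from this P-matrix")
  }
  target <- if (use == "cov") P$cov else P$cor
  sims <- vapply(seq_along(rs$matrices), function(b) {
    M <- rs$matrices[[b]]
    if (use == "cor") M <- cov2cor_safe(M)
    random_skewers(target, M, n_skewers = n_skewers, seed = seed + b)$similarity
  }, numeric(1))
  structure(mean(sims), per_replicate = sims)
}

#' Noise extension of a covariance matrix
#'
#' Replaces trailing near-zero eigenvalues by the eigenvalue at a cutoff
#' rank, keeping the original eigenvectors, so that the matrix becomes
#' strictly positive definite and can be inverted (needed by relative
#' eigenanalysis). When `cutoff` is `NULL` it is chosen as the first rank
#' `j` at which the standardized eigenvalue gap
#' `(lambda_j - lambda_{j+1}) / lambda_1` falls below `tol`.
#'
#' @param P a [pmatrix] or covariance matrix.
#' @param cutoff eigenvalue rank to keep (in `2..p-1`) or `NULL` for the
#'   automatic gap rule.
#' @param tol standardized-gap tolerance for the automatic rule
#'   (default `1e-4`).
#' @return object of the same type with the extended covariance (and
#'   refreshed correlation when a `pmatrix` is supplied).
#' @export
extend_matrix <- function(P, cutoff = NULL, tol = 1e-4) {
  is_pm <- inherits(P, "pmatrix")
  cov <- if (is_pm) P$cov else as.matrix(P)
  p <- ncol(cov)
  eg <- eigen(cov, symmetric = TRUE)
  lam <- eg$values
  if (is.null(cutoff)) {
    gaps <- (lam[-p] - lam[-1]) / lam[1]
    hit <- which(gaps < tol)
    cutoff <- if (length(hit) == 0) p - 1 else max(2, min(hit[1], p - 1))
  }
  if (cutoff <= 1 || cutoff >= p) stop("cutoff must be in 2..p-1")
  lam2 <- lam
  lam2[(cutoff + 1):p] <- lam[cutoff]
  out <- eg$vectors %*% (lam2 * t(eg$vectors))
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(cov)
  if (is_pm) {
    res <- P
    res$cov <- out
    res$cor <- cov2cor_safe(out)
    attr(res, "extended_at") <- cutoff
    res
  } else {
    attr(out, "extended_at") <- cutoff
    out
  }
}
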