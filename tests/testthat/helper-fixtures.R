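# fixture builders shared across test files; everything is generated in code

# block correlation matrix: r_within inside each module, r_between elsewhere
block_cor <- function(p, modules, r_within, r_between = 0) {
  tn <- paste0("d", seq_len(p))
  R <- matrix(r_between, p, p, dimnames = list(tn, tn))
  rw <- rep_len(r_within, length(modules))
  for (k in seq_along(modules)) {
    idx <- match(modules[[k]], tn)
    R[idx, idx] <- rw[k]
  }
  diag(R) <- 1
  R
}

# random symmetric positive-definite matrix
random_spd <- function(p, seed = 1, jitter = 0.5) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  S <- crossprod(A) / p + jitter * diag(p)
  dimnames(S) <- list(paste0("d", 1:p), paste0("d", 1:p))
  S
}

# minimal trait table around a given data matrix
as_trait_table <- function(X, species = "spA", sex = "F", locality = "loc1") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("d", seq_len(ncol(X)))
  df <- data.frame(
    specimen_id = sprintf("s%04d", seq_len(nrow(X))),
    species = rep_len(species, nrow(X)),
    sex = rep_len(sex, nrow(X)),
    locality = rep_len(locality, nrow(X)),
    stringsAsFactors = FALSE)
  df[colnames(X)] <- as.data.frame(X)
  df
}

# draw a trait table from a MVN with the given covariance (positive traits
# when a mean on the raw scale is supplied)
mvn_trait_table <- function(n, Sigma, mu = NULL, seed = 1, ...) {
  set.seed(seed)
  p <- ncol(Sigma)
  if (is.null(mu)) mu <- rep(0, p)
  X <- MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
  colnames(X) <- if (!is.null(colnames(Sigma))) colnames(Sigma) else
    paste0("d", 1:p)
  as_trait_table(X, ...)
}

# a small clade config that keeps simulation-based tests fast
small_clade_config <- function(...) {
  args <- list(...)
  defaults <- list(n_species = 8, p = 10, n_specimens = 40,
                   q_climate = 5,
                   true_model = modularity_model(
                     "toy_two_module",
                     list(A = paste0("d", 1:4), B = paste0("d", 5:8)),
                     trait_names = paste0("d", 1:10)))
  do.call(clade_config, utils::modifyList(defaults, args))
}
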