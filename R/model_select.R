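#' Fisher r-to-z transform and its inverse
#'
#' @param r correlation in `(-1, 1)`.
#' @param z real value.
#' @return `fisher_z`: `atanh(r)`; `inverse_fisher_z`: `tanh(z)`.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop("fisher_z needs |r| < 1; shrink boundary values first")
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(z) tanh(z)

#' Partition of trait pairs induced by a modularity model
#'
#' Assigns every unordered trait pair to exactly one correlation set: the
#' module's within-set when both traits share a module, the between-set
#' otherwise. Pairs touching background traits form their own background set
#' (`background = "own_set"`, the default) or join the between-set
#' (`background = "with_between"`). With `between = "single"` all
#' module-spanning pairs share one set; `between = "per_pair"` gives each
#' ordered-free module pair its own set. The number of sets is the `K` of
#' the resulting likelihood fit.
#'
#' @param model a `modularity_model` with disjoint modules.
#' @param trait_names trait set; defaults to the model's traits + background.
#' @param background `"own_set"` or `"with_between"`.
#' @param between `"single"` or `"per_pair"`.
#' @return object of class `pair_partition`: named list of two-column
#'   matrices of trait-name pairs; attribute `trait_names`.
#' @export
pair_partition <- function(model, trait_names = NULL,
                           background = c("own_set", "with_between"),
                           between = c("single", "per_pair")) {
  background <- match.arg(background)
  between <- match.arg(between)
  if (!is_partition(model)) stop("pair_partition requires disjoint modules")
  if (is.null(trait_names)) {
    trait_names <- c(unlist(model$modules), model$background)
  }
  p <- length(trait_names)
  assign <- rep(NA_character_, p)
  names(assign) <- trait_names
  for (m in names(model$modules)) assign[model$modules[[m]]] <- m
  sets <- list()
  add <- function(sets, key, i, j) {
    sets[[key]] <- rbind(sets[[key]], c(trait_names[i], trait_names[j]))
    sets
  }
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ai <- assign[i]; aj <- assign[j]
      key <- if (!is.na(ai) && !is.na(aj) && ai == aj) {
        paste0("within_", ai)
      } else if (!is.na(ai) && !is.na(aj)) {
        if (between == "single") "between" else
          paste0("between_", paste(sort(c(ai, aj)), collapse = "_"))
      } else {
        if (background == "own_set") "background" else "between"
      }
      sets <- add(sets, key, i, j)
    }
  }
  structure(sets, class = "pair_partition", trait_names = trait_names)
}

#' Maximum-likelihood fit of a correlation-set model
#'
#' Likelihood of the observed correlations under a model that assigns one
#' common correlation to each pair set: each Fisher-z transformed observed
#' correlation is normal with mean `z(rho_set)` and standard deviation
#' `1/sqrt(n_spec - 3)`. The MLE of each set correlation is the inverse
#' transform of the mean z within the set (closed form); with
#' `allow_negative = FALSE` the set estimate is constrained nonnegative by
#' fitting the absolute correlations. Model score is
#' `AICc = -2 logL + 2K + 2K(K+1)/(n_pairs - K - 1)` with `K` the number of
#' sets and `n_pairs = p(p-1)/2`.
#'
#' @param cor observed correlation matrix with trait dimnames.
#' @param n_spec effective sample size behind the correlations (use the
#'   residual df + 1 of the P-matrix).
#' @param partition a [pair_partition()].
#' @param allow_negative estimate signed set correlations (default TRUE).
#' @return list of class `model_fit`: `rho` (named per-set estimates),
#'   `logL`, `K`, `AICc`, `n_pairs`, `partition`.
#' @export
fit_model <- function(cor, n_spec, partition, allow_negative = TRUE) {
  if (n_spec <= 3) stop("need n_spec > 3")
  cor <- as.matrix(cor)
  tn <- attr(partition, "trait_names")
  if (!all(tn %in% rownames(cor))) {
    stop("partition traits missing from matrix: ",
         paste(setdiff(tn, rownames(cor)), collapse = ", "))
  }
  K <- length(partition)
  n_pairs <- sum(vapply(partition, nrow, integer(1)))
  if (n_pairs != length(tn) * (length(tn) - 1) / 2) {
    stop("partition does not cover all trait pairs exactly once")
  }
  if (n_pairs <= K + 1) stop("more sets than AICc can support (n_pairs <= K + 1)")
  sd_z <- 1 / sqrt(n_spec - 3)
  shrink <- function(r) pmin(pmax(r, -(1 - 1e-6)), 1 - 1e-6)
  logL <- 0
  rho <- numeric(K)
  names(rho) <- names(partition)
  for (s in names(partition)) {
    prs <- partition[[s]]
    if (nrow(prs) < 1) stop("empty pair set: ", s)
    r <- vapply(seq_len(nrow(prs)),
                function(k) cor[prs[k, 1], prs[k, 2]], numeric(1))
    r_use <- if (allow_negative) r else abs(r)
    z <- atanh(shrink(r_use))
    zhat <- mean(z)
    rho[s] <- tanh(zhat)
    logL <- logL + sum(stats::dnorm(z, mean = zhat, sd = sd_z, log = TRUE))
  }
  aicc <- -2 * logL + 2 * K + 2 * K * (K + 1) / (n_pairs - K - 1)
  structure(list(rho = rho, logL = logL, K = K, AICc = aicc,
                 n_pairs = n_pairs, partition = partition),
            class = "model_fit")
}

#' Compare modularity models by AICc
#'
#' Fits every supplied model plus the mandatory no-modules baseline (a
#' single correlation set, `K = 1`), ranks by AICc and reports posterior
#' model probabilities as Akaike weights
#' `exp(-dAICc/2) / sum(exp(-dAICc/2))`. Following standard practice the
#' best model is flagged unreliable when its posterior is below 0.5.
#'
#' @param cor observed correlation matrix.
#' @param n_spec effective sample size (see [fit_model()]).
#' @param models list of `modularity_model` objects.
#' @param allow_negative passed to [fit_model()].
#' @param background,between passed to [pair_partition()].
#' @return data.frame sorted by AICc with columns `model`, `MaxL`, `K`,
#'   `AICc`, `dAICc`, `Post_Prob`, `reliable`; attribute `fits` holds the
#'   per-model `model_fit` objects.
#' @export
compare_models <- function(cor, n_spec, models, allow_negative = TRUE,
                           background = "own_set", between = "single") {
  if (length(models) < 1) stop("need at least one model")
  nms <- vapply(models, function(m) m$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate model names: ",
                               paste(nms[duplicated(nms)], collapse = ", "))
  tn <- rownames(as.matrix(cor))
  fits <- lapply(models, function(m) {
    part <- pair_partition(m, trait_names = tn, background = background,
                           between = between)
    fit_model(cor, n_spec, part, allow_negative = allow_negative)
  })
  names(fits) <- nms
  # no-modules baseline: one set holding every pair
  base_part <- structure(
    list(all = t(utils::combn(tn, 2))),
    class = "pair_partition", trait_names = tn)
  fits$no_modules <- fit_model(cor, n_spec, base_part,
                               allow_negative = allow_negative)
  aicc <- vapply(fits, `[[`, numeric(1), "AICc")
  d <- aicc - min(aicc)
  w <- exp(-d / 2)
  w <- w / sum(w)
  out <- data.frame(
    model = names(fits),
    MaxL = vapply(fits, `[[`, numeric(1), "logL"),
    K = vapply(fits, `[[`, numeric(1), "K"),
    AICc = aicc, dAICc = d, Post_Prob = w,
    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$AICc), ]
  rownames(out) <- NULL
  out$reliable <- c(out$Post_Prob[1] >= 0.5, rep(NA, nrow(out) - 1))
  attr(out, "fits") <- fits
  out
}
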