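#' Modularity models
#'
#' A modularity model names disjoint (for model selection) or possibly
#' overlapping (for single-unit AVG tests) sets of traits as modules;
#' traits in no module form the background.
#'
#' @param name model name.
#' @param modules named list of character vectors of trait names.
#' @param trait_names full trait set the model is defined over
#'   (default `d1..d21`).
#' @return object of class `modularity_model` with `name`, `modules`,
#'   `background`.
#' @export
modularity_model <- function(name, modules, trait_names = paste0("d", 1:21)) {
  modules <- lapply(modules, as.character)
  unknown <- setdiff(unlist(modules), trait_names)
  if (length(unknown) > 0) {
    stop("model ", name, " references unknown trait(s): ",
         paste(unknown, collapse = ", "))
  }
  bad <- names(modules)[vapply(modules, length, integer(1)) < 2]
  if (length(bad) > 0) {
    stop("model ", name, " has module(s) with fewer than 2 traits: ",
         paste(bad, collapse = ", "))
  }
  structure(list(name = name, modules = modules,
                 background = setdiff(trait_names, unlist(modules))),
            class = "modularity_model")
}

#' @export
print.modularity_model <- function(x, ...) {
  cat("Modularity model:", x$name, "\n")
  for (m in names(x$modules)) {
    cat("  ", m, ": ", paste(x$modules[[m]], collapse = " "), "\n", sep = "")
  }
  if (length(x$background) > 0) {
    cat("  background: ", paste(x$background, collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

is_partition <- function(model) {
  all(table(unlist(model$modules)) == 1)
}

#' Built-in modular units of the skull distance set
#'
#' The a priori hypothesis units over the 21 skull distances. Developmental
#' units follow the embryonic origin of each bone from the three cranial
#' neural crest streams (branchial, hyoid, mandibular); because the
#' frontoparietal, premaxilla and parasphenoid derive from more than one
#' stream, numbered variants differ in where those bones are assigned
#' (I: with frontoparietal + premaxilla/parasphenoid; II: without
#' frontoparietal; III: without premaxilla/parasphenoid). Hormonal units
#' rank bones by thyroid-hormone (T3) sensitivity inferred from ossification
#' timing during metamorphosis (T3+++ ossifies first / most sensitive).
#' Functional units divide the skull into regions with distinct adult
#' functional roles; suspensorium II adds the frontoparietal distances to
#' suspensorium I.
#'
#' @return named list of character vectors of trait names (`d1..d21`).
#' @export
builtin_units <- function() {
  fp <- c("d2", "d5")                 # frontoparietal distances
  psx <- c("d14", "d15", "d16")       # parasphenoid + premaxilla distances
  hyoid_core <- c("d1", "d3", "d4", "d9", "d10", "d11")     # nasal + prenasal
  mand_core <- c("d7", "d12", "d13", "d17", "d19", "d20", "d21")
  list(
    # developmental (cranial neural crest streams)
    branchial      = c(fp, "d8"),
    hyoid_I        = sort_traits(c(hyoid_core, fp, psx)),
    hyoid_II       = sort_traits(c(hyoid_core, psx)),
    hyoid_III      = sort_traits(c(hyoid_core, fp)),
    mandibular_I   = sort_traits(c(mand_core, fp, psx)),
    mandibular_II  = sort_traits(c(mand_core, psx)),
    mandibular_III = sort_traits(c(mand_core, fp)),
    # hormonal (T3 sensitivity / ossification order)
    T3_plus        = c("d18", "d19", "d20", "d21"),
    T3_plusplus    = sort_traits(c("d1", "d3", "d4", "d7", "d9", "d10",
                                   "d11", "d12", "d13", "d16", "d17")),
    T3_plusplusplus = c("d2", "d5", "d8", "d14", "d15"),
    # functional (adult skull regions)
    roof           = sort_traits(c("d1", "d2", "d3", "d4", "d5", "d8",
                                   "d10", "d11")),
    neurocranium   = c("d2", "d5", "d14", "d15"),
    snout          = sort_traits(c("d1", "d3", "d4", "d9", "d10", "d11",
                                   "d12", "d16", "d17", "d18")),
    suspensorium_I = c("d7", "d13", "d19", "d20", "d21"),
    suspensorium_II = c("d2", "d5", "d7", "d13", "d19", "d20", "d21"),
    orbit          = c("d5", "d6", "d11", "d19")
  )
}

sort_traits <- function(x) x[order(as.integer(sub("^d", "", x)))]

#' Built-in composite modularity models
#'
#' Disjoint-module models assembled from the built-in units for likelihood
#' model comparison. A trailing `*` in a unit name marks a variant with some
#' bones removed from its full composition: `hyoid_II*` / `mandibular_II*`
#' drop the premaxilla and parasphenoid distances (resolving their overlap),
#' `neurocranium*` drops one frontoparietal distance and `neurocranium**`
#' both, `roof*` keeps only the frontoparietal and occipital distances, and
#' `mandibular_III*` drops the frontoparietal. Where full units overlap on
#' single distances (the orbit unit shares d11 with snout and d19 with
#' suspensorium), the shared distance stays with the larger anatomical unit
#' and the orbit variant keeps its core (`orbit*`).
#'
#' @return named list of `modularity_model` objects.
#' @export
builtin_models <- function() {
  u <- builtin_units()
  hyoid_II_star <- setdiff(u$hyoid_II, c("d14", "d15", "d16"))
  mand_II_star <- setdiff(u$mandibular_II, c("d14", "d15", "d16"))
  mand_III_star <- setdiff(u$mandibular_III, c("d2", "d5"))
  orbit_star <- c("d5", "d6")
  neuro_star <- setdiff(u$neurocranium, "d5")     # one frontoparietal out
  neuro_2star <- c("d14", "d15")                  # both frontoparietals out
  roof_star <- c("d2", "d8")
  snout_full <- u$snout
  susp_II_star <- setdiff(u$suspensorium_II, "d5")
  mk <- function(name, modules) modularity_model(name, modules)
  list(
    developmental_Ia = mk("developmental_Ia", list(
      `hyoid_II*` = hyoid_II_star, mandibular_II = u$mandibular_II)),
    developmental_Ib = mk("developmental_Ib", list(
      hyoid_II = u$hyoid_II, `mandibular_II*` = mand_II_star)),
    developmental_II = mk("developmental_II", list(
      branchial = u$branchial, hyoid_II = u$hyoid_II)),
    developmental_IV = mk("developmental_IV", list(
      branchial = u$branchial, hyoid_II = u$hyoid_II,
      `mandibular_III*` = mand_III_star)),
    hormonal_I = mk("hormonal_I", list(
      T3_plus = u$T3_plus, T3_plusplus = u$T3_plusplus)),
    hormonal_III = mk("hormonal_III", list(
      T3_plus = u$T3_plus, T3_plusplus = u$T3_plusplus,
      T3_plusplusplus = u$T3_plusplusplus)),
    functional_I = mk("functional_I", list(
      snout = snout_full, suspensorium_I = u$suspensorium_I)),
    functional_II = mk("functional_II", list(
      `neurocranium*` = neuro_star, snout = snout_full,
      `orbit*` = orbit_star, suspensorium_I = u$suspensorium_I)),
    functional_IIIb = mk("functional_IIIb", list(
      `roof*` = roof_star, snout = snout_full, `orbit*` = orbit_star,
      suspensorium_I = u$suspensorium_I)),
    functional_VII = mk("functional_VII", list(
      `neurocranium**` = neuro_2star, snout = snout_full,
      `orbit*` = orbit_star, `suspensorium_II*` = susp_II_star)),
    total_development_II = mk("total_development_II", list(
      branchial = u$branchial, hyoid_II = u$hyoid_II,
      `mandibular_II*` = mand_II_star)),
    total_hormonal = mk("total_hormonal", list(
      T3_plus = u$T3_plus, T3_plusplus = u$T3_plusplus,
      T3_plusplusplus = u$T3_plusplusplus))
  )
}

#' AVG+/AVG- modular-signal statistic for one unit
#'
#' `avg_plus` is the mean correlation over trait pairs with both traits in
#' the unit, `avg_minus` the mean over pairs with exactly one trait in the
#' unit, and their difference is the modular signal: positive values mean
#' within-unit correlations exceed unit-to-outside correlations.
#'
#' @param cor correlation matrix with trait dimnames.
#' @param unit character vector of trait names (at least 2, fewer than all).
#' @return named numeric vector `c(avg_plus, avg_minus, avg_diff)`.
#' @export
avg_diff <- function(cor, unit) {
  cor <- as.matrix(cor)
  tn <- rownames(cor)
  if (is.null(tn)) stop("correlation matrix needs trait dimnames")
  unit <- as.character(unit)
  if (length(unit) < 2) stop("unit needs at least 2 traits")
  if (!all(unit %in% tn)) {
    stop("unit traits not in matrix: ",
         paste(setdiff(unit, tn), collapse = ", "))
  }
  if (length(unit) >= length(tn)) stop("unit must leave at least one trait outside")
  inside <- tn %in% unit
  within <- cor[inside, inside, drop = FALSE]
  avg_plus <- mean(within[upper.tri(within)])
  between <- cor[inside, !inside, drop = FALSE]
  avg_minus <- mean(between)
  c(avg_plus = avg_plus, avg_minus = avg_minus,
    avg_diff = avg_plus - avg_minus)
}

#' AVG+/AVG- statistic for a whole (total) modularity model
#'
#' `avg_plus` averages correlations over pairs within any one module;
#' `avg_minus` over pairs spanning two different modules. Pairs touching
#' background traits are excluded by default (`background = "exclude"`) or
#' counted into `avg_minus` (`background = "between"`).
#'
#' @param cor correlation matrix with trait dimnames.
#' @param model a `modularity_model` whose modules are disjoint.
#' @param background `"exclude"` (default) or `"between"`.
#' @return named numeric vector `c(avg_plus, avg_minus, avg_diff)`.
#' @export
avg_diff_total <- function(cor, model, background = c("exclude", "between")) {
  background <- match.arg(background)
  cor <- as.matrix(cor)
  tn <- rownames(cor)
  if (length(model$modules) < 2) stop("total test needs at least 2 modules")
  if (!is_partition(model)) stop("total test requires disjoint modules")
  assign <- rep(NA_character_, length(tn))
  names(assign) <- tn
  for (m in names(model$modules)) assign[model$modules[[m]]] <- m
  within <- c()
  between <- c()
  p <- length(tn)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      ai <- assign[i]; aj <- assign[j]
      if (is.na(ai) || is.na(aj)) {
        if (background == "between") between <- c(between, cor[i, j])
      } else if (ai == aj) {
        within <- c(within, cor[i, j])
      } else {
        between <- c(between, cor[i, j])
      }
    }
  }
  avg_plus <- mean(within)
  avg_minus <- mean(between)
  c(avg_plus = avg_plus, avg_minus = avg_minus,
    avg_diff = avg_plus - avg_minus)
}

#' Parametric-bootstrap confidence interval for AVG diff
#'
#' Resamples `B` replicate P-matrices (Monte-Carlo draws of `P$n`
#' observations from the empirical covariance), applies the requested size
#' transform to each replicate, recomputes AVG diff, and reports the 2.5/97.5
#' percentile interval. The modular signal is significant when the interval
#' excludes zero. The bootstrap propagates sampling noise through the size
#' removal (transform applied per replicate).
#'
#' For `transform = "no_isometric"` the resampling works on the log-scale
#' data rather than on the matrix (Somers double-centering acts on data):
#' supply `log_cov`, the empirical covariance of the log-transformed,
#' covariate-corrected data; each replicate draws `n` log-scale observations,
#' double-centers them and re-estimates the correlation matrix.
#'
#' @param P a [pmatrix] (with-size, on raw scale).
#' @param unit_or_model trait-name vector (single unit) or a
#'   `modularity_model` (total test).
#' @param B bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param transform `"none"`, `"no_allometric"` or `"no_isometric"`.
#' @param log_cov empirical log-scale covariance (required for
#'   `transform = "no_isometric"`).
#' @param background passed to [avg_diff_total()] for total tests.
#' @return data.frame of class `avg_diff_ci` with columns `unit`,
#'   `avg_plus`, `avg_minus`, `avg_diff`, `ci_low`, `ci_high`,
#'   `significant`, `B`, `seed`, `transform`.
#' @export
avg_diff_ci <- function(P, unit_or_model, B = 1000, seed = 1,
                        transform = c("none", "no_allometric", "no_isometric"),
                        log_cov = NULL, background = "exclude") {
  transform <- match.arg(transform)
  stopifnot(inherits(P, "pmatrix"))
  is_model <- inherits(unit_or_model, "modularity_model")
  stat <- function(cr) {
    if (is_model) avg_diff_total(cr, unit_or_model, background = background)
    else avg_diff(cr, unit_or_model)
  }
  emp_cor <- transformed_cor(P$cov, transform, log_cov, P$n)
  emp <- stat(emp_cor)
  base_cov <- if (transform == "no_isometric") {
    if (is.null(log_cov)) {
      stop("transform = 'no_isometric' needs log_cov (empirical log-scale covariance)")
    }
    as.matrix(log_cov)
  } else P$cov
  set.seed(seed)
  diffs <- numeric(B)
  redrawn <- 0L
  b <- 1L
  while (b <= B) {
    X <- MASS::mvrnorm(P$n, mu = rep(0, ncol(base_cov)), Sigma = base_cov)
    cr <- tryCatch({
      if (transform == "no_isometric") {
        X <- X - rowMeans(X)
        X <- sweep(X, 2, colMeans(X))
        cv <- stats::cov(X)
        dimnames(cv) <- dimnames(base_cov)
        cov2cor_safe(cv)
      } else {
        cv <- stats::cov(X)
        dimnames(cv) <- dimnames(base_cov)
        transformed_cor(cv, transform, NULL, P$n)
      }
    }, error = function(e) NULL)
    if (is.null(cr)) {
      redrawn <- redrawn + 1L
      if (redrawn > 10L * B) stop("too many failed bootstrap replicates")
      next
    }
    diffs[b] <- stat(cr)["avg_diff"]
    b <- b + 1L
  }
  ci <- stats::quantile(diffs, c(0.025, 0.975), names = FALSE)
  res <- data.frame(
    unit = if (is_model) unit_or_model$name else paste(unit_or_model, collapse = "+"),
    avg_plus = emp["avg_plus"], avg_minus = emp["avg_minus"],
    avg_diff = emp["avg_diff"], ci_low = ci[1], ci_high = ci[2],
    significant = ci[1] > 0 | ci[2] < 0,
    B = B, seed = seed, transform = transform, redrawn = redrawn,
    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("avg_diff_ci", class(res))
  attr(res, "replicates") <- diffs
  res
}

# correlation matrix after the requested size transform of a covariance
transformed_cor <- function(cov, transform, log_cov, n) {
  if (transform == "no_allometric") {
    pm <- remove_allometric(pmatrix(cov, n = n, df = n - 1))
    pm$cor
  } else if (transform == "no_isometric") {
    if (is.null(log_cov)) stop("no_isometric transform needs log_cov")
    # empirical statistic on the double-centered log covariance:
    # double-centering data corresponds to I - 11'/p projection of log-cov
    p <- ncol(log_cov)
    J <- diag(p) - matrix(1 / p, p, p)
    cv <- J %*% as.matrix(log_cov) %*% J
    dimnames(cv) <- dimnames(log_cov)
    cov2cor_safe(cv)
  } else {
    cov2cor_safe(cov)
  }
}
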