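test_that("Fisher z and its inverse satisfy the closed forms", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), log(3) / 2)
  grid <- seq(-0.99, 0.99, by = 0.03)
  expect_equal(inverse_fisher_z(fisher_z(grid)), grid, tolerance = 1e-12)
  expect_error(fisher_z(1), "shrink")
})

test_that("pair partitions count sets and pairs correctly", {
  # two modules covering all traits: within-A, within-B, between
  m <- modularity_model("cover", list(A = paste0("d", 1:3),
                                      B = paste0("d", 4:6)),
                        trait_names = paste0("d", 1:6))
  pp <- pair_partition(m)
  expect_setequal(names(pp), c("within_A", "within_B", "between"))
  expect_equal(sum(vapply(pp, nrow, integer(1))), 15)

  # nonempty background adds a fourth set
  m2 <- modularity_model("bg", list(A = paste0("d", 1:3),
                                    B = paste0("d", 4:6)),
                         trait_names = paste0("d", 1:8))
  pp2 <- pair_partition(m2)
  expect_setequal(names(pp2),
                  c("within_A", "within_B", "between", "background"))
  expect_equal(sum(vapply(pp2, nrow, integer(1))), 28)

  # functional model over the full 21-trait set covers all 210 pairs
  pp3 <- pair_partition(builtin_models()$functional_I,
                        trait_names = paste0("d", 1:21))
  expect_equal(sum(vapply(pp3, nrow, integer(1))), 21 * 20 / 2)

  # per-pair between sets and background-into-between variants
  m3 <- modularity_model("three", list(A = c("d1", "d2"), B = c("d3", "d4"),
                                       C = c("d5", "d6")),
                         trait_names = paste0("d", 1:7))
  expect_equal(length(pair_partition(m3, between = "per_pair",
                                     background = "with_between")), 7)
  expect_equal(length(pair_partition(m3)), 5)
})

test_that("single-set likelihood peaks at the common correlation", {
  R <- matrix(0.5, 3, 3, dimnames = list(paste0("d", 1:3),
                                         paste0("d", 1:3)))
  diag(R) <- 1
  m <- modularity_model("one", list(A = paste0("d", 1:3)),
                        trait_names = paste0("d", 1:3))
  n_spec <- 50
  fit <- fit_model(R, n_spec, pair_partition(m))
  expect_equal(unname(fit$rho), 0.5, tolerance = 1e-12)
  expect_equal(fit$logL, 3 * log(sqrt(n_spec - 3) / sqrt(2 * pi)),
               tolerance = 1e-10)
  expect_equal(fit$K, 1)
})

test_that("closed-form set correlations agree with a 0.001-step grid search", {
  set.seed(23)
  R <- cov2cor(random_spd(6, seed = 8))
  m <- modularity_model("g", list(A = paste0("d", 1:3), B = paste0("d", 4:6)),
                        trait_names = paste0("d", 1:6))
  part <- pair_partition(m)
  n_spec <- 40
  fit <- fit_model(R, n_spec, part)
  sd_z <- 1 / sqrt(n_spec - 3)
  for (s in names(part)) {
    prs <- part[[s]]
    z <- atanh(vapply(seq_len(nrow(prs)),
                      function(k) R[prs[k, 1], prs[k, 2]], numeric(1)))
    grid <- seq(-0.999, 0.999, by = 0.001)
    ll <- vapply(grid, function(r) {
      sum(dnorm(z, atanh(r), sd_z, log = TRUE))
    }, numeric(1))
    expect_lt(abs(unname(fit$rho[s]) - grid[which.max(ll)]), 0.001)
  }
  # mean-z estimate lies strictly between extreme observed correlations
  z2 <- c(atanh(0.2), atanh(0.8))
  rho <- inverse_fisher_z(mean(z2))
  expect_gt(rho, 0.2); expect_lt(rho, 0.8)
})

test_that("signed estimation preserves negative sets; abs mode does not", {
  R <- matrix(-0.4, 4, 4, dimnames = list(paste0("d", 1:4),
                                          paste0("d", 1:4)))
  diag(R) <- 1
  m <- modularity_model("neg", list(A = paste0("d", 1:4)),
                        trait_names = paste0("d", 1:4))
  part <- pair_partition(m)
  expect_lt(fit_model(R, 30, part)$rho[["within_A"]], 0)
  expect_gt(fit_model(R, 30, part, allow_negative = FALSE)$rho[["within_A"]], 0)
})

test_that("merging sets never increases the maximized likelihood", {
  set.seed(29)
  for (rep in 1:5) {
    R <- cov2cor(random_spd(6, seed = 100 + rep))
    fine <- modularity_model("fine", list(A = paste0("d", 1:3),
                                          B = paste0("d", 4:6)),
                             trait_names = paste0("d", 1:6))
    coarse <- modularity_model("coarse", list(A = paste0("d", 1:6)),
                               trait_names = paste0("d", 1:6))
    ll_fine <- fit_model(R, 30, pair_partition(fine))$logL
    ll_coarse <- fit_model(R, 30, pair_partition(coarse))$logL
    expect_gte(ll_fine, ll_coarse - 1e-10)
  }
})

test_that("fit is invariant to simultaneous relabeling of traits and model", {
  R <- cov2cor(random_spd(6, seed = 55))
  m <- modularity_model("m", list(A = c("d1", "d2", "d3")),
                        trait_names = paste0("d", 1:6))
  fit <- fit_model(R, 25, pair_partition(m))
  perm <- c(4, 1, 6, 2, 3, 5)
  Rp <- R[perm, perm]
  new_names <- rownames(R)[perm]
  mp <- modularity_model("m", list(A = c("d1", "d2", "d3")),
                         trait_names = new_names)
  fitp <- fit_model(Rp, 25, pair_partition(mp, trait_names = new_names))
  expect_equal(fit$logL, fitp$logL, tolerance = 1e-10)
  expect_equal(fit$AICc, fitp$AICc, tolerance = 1e-10)
})

test_that("model comparison recovers generating structure and sums posteriors", {
  models <- builtin_models()[c("developmental_Ia", "developmental_Ib",
                               "hormonal_I", "functional_I")]
  gen <- builtin_models()$functional_I
  hits <- 0
  for (rep in 1:20) {
    R <- block_cor(21, gen$modules, r_within = c(0.7, 0.6),
                   r_between = 0.2)
    set.seed(500 + rep)
    X <- MASS::mvrnorm(100, rep(0, 21), R)
    colnames(X) <- paste0("d", 1:21)
    cmp <- compare_models(cor(X), n_spec = 100, models = models)
    expect_equal(sum(cmp$Post_Prob), 1, tolerance = 1e-12)
    if (cmp$model[1] == "functional_I" && cmp$Post_Prob[1] > 0.8) {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 18)
})

test_that("compound-symmetric data prefer the no-modules baseline", {
  # with no modular structure the single-set baseline is the modal winner
  # and carries the highest average posterior; the check runs at zero
  # background correlation, where pairwise correlation estimates are
  # mutually independent as the likelihood assumes (a shared background
  # correlation couples them and lets spurious structure win more often,
  # the same pathology that depresses posteriors at high integration)
  models <- builtin_models()[c("developmental_Ia", "hormonal_I",
                               "functional_I")]
  winners <- character(20)
  post <- matrix(0, 20, 4,
                 dimnames = list(NULL, c(names(models), "no_modules")))
  for (rep in 1:20) {
    R <- diag(21)
    dimnames(R) <- list(paste0("d", 1:21), paste0("d", 1:21))
    set.seed(900 + rep)
    X <- MASS::mvrnorm(100, rep(0, 21), R)
    colnames(X) <- paste0("d", 1:21)
    cmp <- compare_models(cor(X), n_spec = 100, models = models)
    winners[rep] <- cmp$model[1]
    post[rep, cmp$model] <- cmp$Post_Prob
  }
  tally <- table(factor(winners, levels = colnames(post)))
  expect_identical(names(which.max(tally)), "no_modules")
  expect_gte(tally[["no_modules"]], 10)
  mean_post <- colMeans(post)
  expect_identical(names(which.max(mean_post)), "no_modules")
})

test_that("duplicate model names are rejected", {
  m <- builtin_models()$functional_I
  R <- diag(21); dimnames(R) <- list(paste0("d", 1:21), paste0("d", 1:21))
  expect_error(compare_models(R, 50, list(m, m)), "duplicate")
})
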