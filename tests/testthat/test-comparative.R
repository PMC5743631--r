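test_that("PCoA reconstructs 1-D and random Euclidean configurations", {
  x <- c(0, 3, 4)
  D <- as.matrix(dist(x))
  rownames(D) <- colnames(D) <- c("a", "b", "c")
  ord <- pcoa(D)
  expect_equal(sum(ord$eigenvalues > 1e-8), 1)
  expect_equal(as.matrix(dist(ord$axes[, 1])), unname(D), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_false(ord$negative_eigenvalue_flag)

  set.seed(7)
  X <- matrix(rnorm(8 * 3), 8, 3)
  DX <- as.matrix(dist(X))
  ordX <- pcoa(DX)
  expect_false(ordX$negative_eigenvalue_flag)
  expect_equal(as.matrix(dist(ordX$axes)), DX, tolerance = 1e-8,
               ignore_attr = TRUE)
  # axes ordered by decreasing eigenvalue
  expect_true(all(diff(ordX$eigenvalues) <= 1e-10))
})

test_that("PCoA handles degenerate input and flags non-Euclidean matrices", {
  Z <- matrix(0, 4, 4)
  expect_equal(ncol(pcoa(Z)$axes), 0)

  # non-Euclidean dissimilarity: negative eigenvalues flagged, Cailliez fixes
  D <- matrix(c(0, 1, 1, 1,
                1, 0, 1, 1,
                1, 1, 0, 2.8,
                1, 1, 2.8, 0), 4, 4)
  ord <- pcoa(D)
  expect_true(ord$negative_eigenvalue_flag)
  ordc <- pcoa(D, correction = "cailliez")
  expect_false(ordc$negative_eigenvalue_flag)
})

test_that("PCoA agrees with the reference implementation on distances", {
  set.seed(9)
  X <- matrix(rnorm(14), 7, 2)
  D <- as.matrix(dist(X))
  ours <- pcoa(D)
  ref <- ape::pcoa(as.dist(D))
  k <- ncol(ref$vectors)
  expect_equal(abs(ours$axes[, 1:k]), abs(ref$vectors), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("cophenetic distances are path sums of branch lengths", {
  D <- cophenetic_from_newick("((A:1,B:1):1,C:2);")
  expect_equal(D$values["A", "B"], 2)
  expect_equal(D$values["A", "C"], 4)
  expect_equal(D$values["B", "C"], 4)

  # ultrametric tree: all distances through the root are equal
  phy <- simulate_tree(6, seed = 4)
  depths <- ape::node.depth.edgelength(phy)[1:6]
  expect_equal(depths, rep(1, 6), tolerance = 1e-10)

  # independent oracle: path enumeration from the edge list
  Dp <- cophenetic_from_newick(phy)
  edge <- phy$edge
  len <- phy$edge.length
  n_tip <- length(phy$tip.label)
  root <- n_tip + 1
  path_to_root <- function(node) {
    path <- c()
    while (node != root) {
      k <- which(edge[, 2] == node)
      path <- c(path, k)
      node <- edge[k, 1]
    }
    path
  }
  for (i in 1:(n_tip - 1)) for (j in (i + 1):n_tip) {
    pi <- path_to_root(i); pj <- path_to_root(j)
    shared <- intersect(pi, pj)
    d <- sum(len[setdiff(pi, shared)]) + sum(len[setdiff(pj, shared)])
    expect_equal(Dp$values[phy$tip.label[i], phy$tip.label[j]], d,
                 tolerance = 1e-12)
  }

  noblen <- ape::read.tree(text = "((A,B),C);")
  expect_error(cophenetic_from_newick(noblen), "branch lengths")
})

test_that("climate PCA z-scores, decomposes and averages by species", {
  # two perfectly correlated variables: PC1 carries everything
  clim <- data.frame(locality = paste0("L", 1:6),
                     species = rep(c("A", "B", "C"), each = 2),
                     v1 = 1:6, v2 = 2 * (1:6) + 3)
  cp <- climate_pca(clim)
  expect_equal(cp$variance_explained[1], 100, tolerance = 1e-10)

  # full-rank reconstruction reproduces the z-scored data
  set.seed(12)
  clim2 <- data.frame(locality = paste0("L", 1:10),
                      species = rep(c("A", "B"), 5),
                      matrix(rnorm(40), 10, 4))
  cp2 <- climate_pca(clim2)
  Z <- scale(as.matrix(clim2[, 3:6]))
  expect_equal(cp2$locality_scores %*% t(cp2$loadings), Z,
               tolerance = 1e-10, ignore_attr = TRUE)
  # species scores are means of locality scores
  expect_equal(cp2$species_scores["A", ],
               colMeans(cp2$locality_scores[clim2$species == "A", ]),
               tolerance = 1e-12)

  clim2$v_const <- 1
  expect_error(climate_pca(clim2), "v_const")
})

test_that("univariate K_mult equals an independent Blomberg K computation", {
  skip_if_not_installed("phytools")
  phy <- simulate_tree(12, seed = 21)
  set.seed(22)
  y <- as.vector(MASS::mvrnorm(1, rep(0, 12), ape::vcv(phy)))
  names(y) <- phy$tip.label
  ours <- kmult(phy, y, n_perm = 9, seed = 1)
  ref <- phytools::phylosig(phy, y, method = "K")
  expect_equal(ours$K, as.numeric(ref), tolerance = 1e-6)
})

test_that("K_mult is calibrated at 1 under Brownian motion", {
  phy <- simulate_tree(12, seed = 31)
  C <- ape::vcv(phy)
  ks <- vapply(1:200, function(r) {
    set.seed(4000 + r)
    Y <- t(MASS::mvrnorm(3, rep(0, 12), C))
    rownames(Y) <- phy$tip.label
    kmult(phy, Y, n_perm = 0, seed = 1)$K
  }, numeric(1))
  expect_equal(mean(ks), 1, tolerance = 0.1)
})

test_that("K_mult p-values are calibrated on a star phylogeny", {
  star <- ape::read.tree(text = paste0("(",
    paste(sprintf("t%d:1", 1:10), collapse = ","), ");"))
  set.seed(41)
  ps <- vapply(1:60, function(r) {
    Y <- matrix(rnorm(20), 10, 2, dimnames = list(star$tip.label, NULL))
    kmult(star, Y, n_perm = 49, seed = r)$p
  }, numeric(1))
  # uniform p-values: rejection rate near alpha (binomial 99% band)
  expect_lt(mean(ps <= 0.1), 0.1 + 3 * sqrt(0.1 * 0.9 / 60))
  ks <- vapply(1:60, function(r) {
    set.seed(100 + r)
    Y <- matrix(rnorm(20), 10, 2, dimnames = list(star$tip.label, NULL))
    kmult(star, Y, n_perm = 0, seed = 1)$K
  }, numeric(1))
  expect_equal(mean(ks), 1, tolerance = 0.15)
})

test_that("K_mult validates tip labels", {
  phy <- simulate_tree(5, seed = 3)
  Y <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("x", 1:5), NULL))
  expect_error(kmult(phy, Y), "mismatch")
})

test_that("axis screening retains correlated pairs and nothing else", {
  set.seed(51)
  n <- 20
  ax <- cbind(a1 = rnorm(n), a2 = rnorm(n))
  pred <- cbind(p1 = ax[, 1] + rnorm(n, 0, 1e-8), p2 = rnorm(n))
  scr <- screen_axes(ax, pred)
  expect_true(1 %in% scr$retained_axes)
  expect_true(1 %in% scr$retained_predictors)
  expect_equal(scr$table$cor[scr$table$axis == "a1" &
                               scr$table$predictor == "p1"], 1,
               tolerance = 1e-6)
  expect_error(screen_axes(ax[1:3, ], pred[1:3, ]), "at least 4")
})

test_that("independent axes are retained at roughly the nominal error rate", {
  set.seed(61)
  hits <- vapply(1:500, function(r) {
    ax <- matrix(rnorm(11), 11, 1)
    pred <- matrix(rnorm(22), 11, 2)
    length(screen_axes(ax, pred)$retained_axes) > 0
  }, logical(1))
  # one axis tested against two predictors at alpha = .05: retention
  # probability about 1 - (1 - .05)^2 ~ 0.0975
  expect_lt(abs(mean(hits) - 0.0975), 0.045)
})

test_that("variation partitioning fractions obey their algebraic identities", {
  set.seed(71)
  n <- 30
  X1 <- matrix(rnorm(2 * n), n, 2)
  X2 <- matrix(rnorm(n), n, 1)
  Y <- X1 %*% c(1, -1) + 0.5 * X2[, 1] + rnorm(n, 0, 0.5)
  vp <- variation_partition(Y, X1, X2, n_perm = 99, seed = 5)
  expect_equal(vp$frac_a + vp$frac_b + vp$frac_c, vp$r2adj_full,
               tolerance = 1e-10)
  expect_equal(vp$frac_a + vp$frac_b + vp$frac_c + vp$residual, 1,
               tolerance = 1e-10)
  expect_true(is.na(vp$tests$p[vp$tests$fraction == "shared"]))

  # invariance to invertible reparameterization within a set
  A <- matrix(c(2, 1, 0, 3), 2, 2)
  vp2 <- variation_partition(Y, X1 %*% A, X2, n_perm = 0, seed = 5)
  expect_equal(c(vp$frac_a, vp$frac_b, vp$frac_c),
               c(vp2$frac_a, vp2$frac_b, vp2$frac_c), tolerance = 1e-10)
})

test_that("orthogonal and duplicated designs give the expected fractions", {
  n <- 24
  X1 <- matrix(rep(c(1, -1), n / 2), n, 1)
  X2 <- matrix(rep(c(1, 1, -1, -1), n / 4), n, 1)  # orthogonal to X1
  Y <- X1  # response identical to X1
  vp <- variation_partition(Y, X1, X2, n_perm = 99, seed = 7)
  # X2 explains nothing, so its adjusted R2 is a small negative number and
  # the unique X1 fraction equals the full fraction up to that adjustment
  expect_lt(abs(vp$frac_a - vp$r2adj_full), 0.06)
  expect_equal(vp$frac_c, 0, tolerance = 1e-10)
  expect_lt(vp$tests$p[1], 0.05)

  expect_error(variation_partition(Y, X1, X1), "collinear")
  # near-duplicate predictors push everything into the shared fraction
  X2n <- X1 + matrix(rnorm(n, 0, 1e-4), n, 1)
  vpn <- variation_partition(Y, X1, X2n, n_perm = 0, seed = 7)
  expect_equal(vpn$frac_a, 0, tolerance = 0.02)
  expect_equal(vpn$frac_c, 0, tolerance = 0.02)
  expect_equal(vpn$frac_b, vpn$r2adj_full, tolerance = 0.02)
})

test_that("fractions match the reference RDA implementation", {
  skip_if_not_installed("vegan")
  set.seed(81)
  n <- 25
  Y <- matrix(rnorm(2 * n), n, 2)
  X1 <- matrix(rnorm(2 * n), n, 2)
  X2 <- matrix(rnorm(n), n, 1)
  Y[, 1] <- Y[, 1] + X1[, 1] + X2[, 1]
  vp <- variation_partition(Y, X1, X2, n_perm = 0, seed = 1)
  ref <- vegan::varpart(Y, X1, X2)
  # vegan's indfract rows: [a] = X1|X2, [b] = X2|X1, [c] = shared, [d]
  fr <- ref$part$indfract$Adj.R.square
  expect_equal(vp$frac_a, fr[1], tolerance = 1e-6)
  expect_equal(vp$frac_c, fr[2], tolerance = 1e-6)
  expect_equal(vp$frac_b, fr[3], tolerance = 1e-6)
  expect_equal(vp$residual, fr[4], tolerance = 1e-6)
})
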