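test_that("mahalanobis_dist reduces to Euclidean for the identity metric", {
  I2 <- metric_matrix(diag(2))
  expect_equal(mahalanobis_dist(I2, c(1, 2), c(4, 6)), 5)
  expect_equal(mahalanobis_dist(I2, c(3, -1), c(3, -1)), 0)
  expect_equal(mahalanobis_dist(metric_matrix(diag(c(4, 1))),
                                c(1, 0), c(0, 0)), 2)
  expect_error(metric_matrix(diag(c(1, -1))), "semi-definite")
  expect_error(mahalanobis_dist(I2, c(1, 2, 3), c(0, 0, 0)), "length")
})

test_that("metric distance equals the Euclidean norm under the factor P", {
  set.seed(20)
  for (i in 1:20) {
    A <- matrix(rnorm(16), 4)
    m <- psd_project(crossprod(A))
    x <- rnorm(4); y <- rnorm(4)
    expect_equal(mahalanobis_dist(m, x, y),
                 sqrt(sum((t(m$P) %*% (x - y))^2)), tolerance = 1e-8)
    expect_lt(max(abs(m$P %*% t(m$P) - m$M)), 1e-8)
  }
})

test_that("metric distance is symmetric and satisfies the triangle inequality", {
  set.seed(33)
  for (i in 1:20) {
    m <- psd_project(crossprod(matrix(rnorm(9), 3)))
    x <- rnorm(3); y <- rnorm(3); z <- rnorm(3)
    expect_equal(mahalanobis_dist(m, x, y), mahalanobis_dist(m, y, x))
    expect_lte(mahalanobis_dist(m, x, z),
               mahalanobis_dist(m, x, y) + mahalanobis_dist(m, y, z) + 1e-12)
  }
})

test_that("psd_project symmetrizes and clips negative eigenvalues", {
  # PSD input is unchanged
  M <- crossprod(matrix(rnorm(9), 3))
  expect_lt(max(abs(psd_project(M)$M - M)), 1e-10)
  # eigenvalue clipping
  expect_equal(psd_project(diag(c(1, -1)))$M, diag(c(1, 0)))
  # asymmetric input: symmetrize to [[0,1],[1,0]] (eigenvalues 1, -1),
  # clip to the rank-1 closed form 0.5 * [[1,1],[1,1]]
  got <- psd_project(matrix(c(0, 0, 2, 0), 2))$M
  expect_equal(got, matrix(c(0.5, 0.5, 0.5, 0.5), 2), tolerance = 1e-12)
  expect_error(psd_project(matrix(c(1, NA, 0, 1), 2)), "finite")
})

test_that("build_pair_sets enumerates and samples pairs reproducibly", {
  feats <- matrix(rnorm(6), 3, 2)
  ps <- build_pair_sets(feats, c(0, 0, 1), max_pairs = 10)
  expect_equal(ps$S, matrix(c(1, 2), 1, 2, dimnames = NULL))
  expect_equal(nrow(ps$D), 2)
  expect_setequal(lapply(asplit(ps$D, 1), as.numeric),
                  list(c(1, 3), c(2, 3)))

  ps1 <- build_pair_sets(feats, c(0, 0, 1), max_pairs = 1)
  expect_equal(nrow(ps1$S), 1)
  expect_equal(nrow(ps1$D), 1)

  set.seed(1)
  feats50 <- matrix(rnorm(100), 50, 2)
  labs <- sample(0:2, 50, replace = TRUE)
  a <- build_pair_sets(feats50, labs, max_pairs = 100, seed = 42)
  b <- build_pair_sets(feats50, labs, max_pairs = 100, seed = 42)
  expect_identical(a, b)
  expect_error(build_pair_sets(feats, c(1, 1, 1), 10), "two classes")
})

test_that("pgdm_loss matches direct substitution and a double-loop oracle", {
  # one S pair with difference (1,0), one D pair with difference (0,1), identity
  feats <- rbind(c(0, 0), c(1, 0), c(0, 1))
  ps <- structure(list(S = matrix(c(2, 1), 1), D = matrix(c(3, 1), 1),
                       features = feats), class = "pair_sets")
  expect_equal(pgdm_loss(diag(2), ps), 1 - log(1))
  expect_error(pgdm_loss(matrix(0, 2, 2), ps), "zero")

  set.seed(10)
  feats5 <- matrix(rnorm(15), 5, 3)
  labs <- c(0, 0, 1, 1, 2)
  ps5 <- build_pair_sets(feats5, labs, max_pairs = 100)
  # naive double-loop oracle
  s_sum <- 0
  for (i in seq_len(nrow(ps5$S))) {
    d <- feats5[ps5$S[i, 1], ] - feats5[ps5$S[i, 2], ]
    s_sum <- s_sum + sum(d^2)
  }
  d_sum <- 0
  for (i in seq_len(nrow(ps5$D))) {
    d <- feats5[ps5$D[i, 1], ] - feats5[ps5$D[i, 2], ]
    d_sum <- d_sum + sqrt(sum(d^2))
  }
  expect_equal(pgdm_loss(diag(3), ps5), s_sum - log(d_sum),
               tolerance = 1e-12)
})

# planted-direction toy: two classes separated along axis 1 only, axis 2 is
# pure within-class noise (twice the spread), so the learned metric should
# down-weight axis 2 relative to the class-informative axis 1.
planted_toy <- function(n = 30, seed = 2) {
  set.seed(seed)
  x1 <- cbind(rnorm(n, -1, 0.3), rnorm(n, 0, 1))
  x2 <- cbind(rnorm(n, 1, 0.3), rnorm(n, 0, 1))
  build_pair_sets(rbind(x1, x2), rep(0:1, each = n), max_pairs = 300,
                  seed = seed)
}

# brute-force oracle: minimize the PGDM objective over diagonal metrics on
# a log-spaced grid
diag_grid_minimum <- function(pairs) {
  grid <- 10^seq(-3, 1, length.out = 41)
  best <- NULL; best_loss <- Inf
  for (a in grid) for (b in grid) {
    l <- pgdm_loss(diag(c(a, b)), pairs)
    if (l < best_loss) { best_loss <- l; best <- c(a, b) }
  }
  list(m = best, loss = best_loss)
}

test_that("pgdm_fit de-emphasizes the noise axis like the grid-search oracle", {
  ps <- planted_toy()
  fit <- pgdm_fit(ps, max_iter = 300, step = 0.05)
  # loss trace is non-increasing
  tr <- attr(fit, "trace")
  expect_true(all(diff(tr) <= 1e-12))
  # learned metric beats the identity under the PGDM objective
  expect_lt(pgdm_loss(fit, ps), pgdm_loss(diag(2), ps))
  # axis preference: noisy within-class axis gets the smaller weight,
  # matching the diagonal grid-search minimizer
  oracle <- diag_grid_minimum(ps)
  expect_lt(oracle$m[2], oracle$m[1])
  expect_lt(fit$M[2, 2], fit$M[1, 1])
  # the D-constraint holds after the final rescale
  dD <- ps$features[ps$D[, 1], ] - ps$features[ps$D[, 2], ]
  expect_gte(sum(sqrt(rowSums((dD %*% fit$M) * dD))), 1 - 1e-8)
})

test_that("pgdm_fit stays near isotropic when classes are exchangeable", {
  set.seed(6)
  # whitened data, both "classes" drawn from the same distribution: no axis
  # is informative, so no direction should dominate. The argument is a
  # population symmetry, so the sample must be large enough for the
  # pair sums to approach their expectations.
  x <- matrix(rnorm(800), 400, 2)
  x <- scale(x)
  ps <- build_pair_sets(x, rep(0:1, each = 200), max_pairs = 2000, seed = 3)
  fit <- pgdm_fit(ps, max_iter = 200, step = 0.05)
  ev <- eigen(fit$M, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[1] / ev[2], 1.2)
})

test_that("pgdm_fit with max_iter = 0 returns the identity initialization", {
  ps <- planted_toy(n = 10)
  fit <- pgdm_fit(ps, max_iter = 0)
  # identity up to the admissible positive rescale for the D-constraint
  ratio <- fit$M[1, 1]
  expect_gt(ratio, 0)
  expect_equal(fit$M, diag(2) * ratio, tolerance = 1e-12)
})

test_that("learned metric separates class centroids more than Euclidean", {
  ps <- planted_toy(n = 40, seed = 5)
  fit <- pgdm_fit(ps, max_iter = 300, step = 0.05)
  feats <- ps$features
  c0 <- colMeans(feats[1:40, ]); c1 <- colMeans(feats[41:80, ])
  # normalize each metric by its total within-class spread so the
  # comparison is scale-free
  spread <- function(metric) {
    d <- feats[ps$S[, 1], ] - feats[ps$S[, 2], ]
    M <- if (inherits(metric, "metric_matrix")) metric$M else metric
    sqrt(mean(rowSums((d %*% M) * d)))
  }
  gap_learned <- mahalanobis_dist(fit, c0, c1) / spread(fit)
  gap_eucl <- mahalanobis_dist(metric_matrix(diag(2)), c0, c1) /
    spread(diag(2))
  expect_gt(gap_learned, gap_eucl)
})
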