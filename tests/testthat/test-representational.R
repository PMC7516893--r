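# Representational heterogeneity: categorical delegation and the
# multivariate-Gaussian continuous machinery, validated against
# quadrature oracles of the defining integrals.

test_that("categorical RRH reduces to Hill numbers on label counts", {
  # deterministic one-hot posteriors, uniform weights: between equals the
  # classical Hill number of the class frequencies
  labels <- c(1, 1, 1, 2, 2, 3, 3, 3, 3, 3)
  F_mat <- one_hot(labels, 3)
  freq <- as.numeric(table(labels)) / length(labels)
  for (q in c(0, 0.5, 1, 2, Inf)) {
    dec <- categorical_rrh(F_mat, q)
    expect_equal(dec$within, 1, tolerance = 1e-12)
    expect_equal(dec$between, brute_hill(freq, q), tolerance = 1e-9)
  }
  # all-uniform posteriors: no between-observation structure
  F_u <- matrix(1/4, 6, 4)
  dec <- categorical_rrh(F_u, 1)
  expect_equal(dec$pooled, 4, tolerance = 1e-12)
  expect_equal(dec$between, 1, tolerance = 1e-12)
  # two disjoint certain observations replicate
  expect_equal(categorical_rrh(rbind(c(1, 0), c(0, 1)), 2)$between, 2,
               tolerance = 1e-12)
  # point heterogeneity: confidence scale
  expect_equal(categorical_point_heterogeneity(c(1, 0, 0), 2), 1)
  expect_equal(categorical_point_heterogeneity(rep(0.25, 4), 3), 4)
  expect_equal(categorical_point_heterogeneity(c(0.5, 0.25, 0.25), 1),
               2^1.5, tolerance = 1e-12)
})

test_that("Gaussian Renyi closed form matches quadrature of the defining integral", {
  # printed closed-form anchors
  expect_equal(gaussian_renyi(matrix(1), 1), sqrt(2 * pi * exp(1)),
               tolerance = 1e-12)
  expect_equal(gaussian_renyi(matrix(1), 2), sqrt(4 * pi),
               tolerance = 1e-12)
  expect_equal(gaussian_renyi(diag(2), 1), 2 * pi * exp(1),
               tolerance = 1e-12)
  expect_equal(gaussian_renyi(matrix(1), Inf), sqrt(2 * pi),
               tolerance = 1e-12)
  # scaling: Sigma -> c^2 Sigma multiplies the volume by c^nz
  S <- rand_cov(2)
  expect_equal(gaussian_renyi(4 * S, 2), 4 * gaussian_renyi(S, 2),
               tolerance = 1e-9)
  # oracle: quadrature of (int f^q)^(1/(1-q)) for random covariances
  set.seed(21)
  for (i in 1:6) {
    nz <- sample(1:2, 1)
    S <- rand_cov(nz)
    mu <- rnorm(nz)
    d <- dens_gauss(mu, S)
    sd <- sqrt(diag(S))
    for (q in c(0.5, 1, 2, 5)) {
      expect_equal(gaussian_renyi(S, q),
                   quad_volume(d, mu - 10 * sd, mu + 10 * sd, q),
                   tolerance = 1e-6)
    }
    # q = Inf as the limit of the closed form
    expect_equal(gaussian_renyi(S, Inf), gaussian_renyi(S, 1e3),
                 tolerance = 1e-2)
  }
  expect_error(gaussian_renyi(diag(2), 0), "undefined")
  expect_warning(v <- gaussian_renyi(matrix(0, 1, 1), 2), "singular")
  expect_equal(v, 0)
})

test_that("continuous point heterogeneity recovers uniform support length", {
  L <- 2.5
  unif <- function(z) ifelse(z >= 0 & z <= L, 1 / L, 0)
  for (q in c(0.5, 2, 3))
    expect_equal(continuous_point_heterogeneity(unif, q, -1, L + 1), L,
                 tolerance = 1e-6)
  gauss <- function(z) dnorm(z)
  expect_equal(continuous_point_heterogeneity(gauss, 1, -10, 10),
               sqrt(2 * pi * exp(1)), tolerance = 1e-8)
  expect_equal(continuous_point_heterogeneity(gauss, 2, -10, 10),
               sqrt(4 * pi), tolerance = 1e-8)
})

test_that("parametric pooling matches the law of total covariance", {
  # single component: identity
  S <- rand_cov(2); mu <- c(1, -2)
  g <- gaussian_component_set(matrix(mu, 1), list(S))
  pool <- parametric_pool_gaussian(g)
  expect_equal(pool$mu_star, mu)
  expect_equal(pool$Sigma_star, S, tolerance = 1e-12)
  # two point masses at +/-1: pooled variance 1
  g <- gaussian_component_set(matrix(c(-1, 1), 2),
                              list(matrix(0, 1, 1), matrix(0, 1, 1)))
  pool <- parametric_pool_gaussian(g)
  expect_equal(pool$mu_star, 0)
  expect_equal(pool$Sigma_star[1, 1], 1, tolerance = 1e-12)
  # Monte-Carlo oracle: sample moments of the mixture
  set.seed(31)
  g <- gaussian_cluster_set(4, 2, separation = 2, seed = 77)
  pool <- parametric_pool_gaussian(g)
  comp <- sample.int(4, 1e5, replace = TRUE, prob = g$w)
  z <- t(vapply(seq_len(1e5), function(i) {
    R <- chol(g$Sigma[[comp[i]]])
    g$mu[comp[i], ] + as.numeric(t(R) %*% rnorm(2))
  }, numeric(2)))
  expect_equal(colMeans(z), pool$mu_star, tolerance = 0.02)
  expect_equal(stats::cov(z), pool$Sigma_star, tolerance = 0.02)
})

test_that("Gaussian within-observation volume matches the quadrature oracle", {
  # single component reduces to the plain Gaussian volume
  S <- rand_cov(2)
  g <- gaussian_component_set(matrix(0, 1, 2), list(S))
  for (q in c(0.5, 1, 2, Inf))
    expect_equal(gaussian_within(g, q), gaussian_renyi(S, q),
                 tolerance = 1e-9)
  # identical covariances across components: factorizes for all q
  g <- gaussian_component_set(matrix(rnorm(6), 3, 2), S)
  for (q in c(0.5, 1, 2, 7, Inf))
    expect_equal(gaussian_within(g, q), gaussian_renyi(S, q),
                 tolerance = 1e-9)
  # heterogeneous 1-D components against direct quadrature
  g <- gaussian_component_set(matrix(c(0, 0), 2),
                              list(matrix(1), matrix(4)))
  for (q in c(0.5, 1, 2, 5))
    expect_equal(gaussian_within(g, q),
                 quad_within(g$mu, g$Sigma, g$w, q), tolerance = 1e-6)
  # random 1-D and 2-D sets, random weights
  set.seed(13)
  for (i in 1:4) {
    nz <- sample(1:2, 1)
    N <- sample(2:4, 1)
    g <- gaussian_component_set(
      matrix(rnorm(N * nz), N, nz),
      replicate(N, rand_cov(nz), simplify = FALSE),
      w = rand_p(N))
    for (q in c(0.5, 1, 2, 5))
      expect_equal(gaussian_within(g, q),
                   quad_within(g$mu, g$Sigma, g$w, q), tolerance = 1e-6)
    # q = Inf agrees with a large finite order
    expect_equal(gaussian_within(g, Inf), gaussian_within(g, 5e3),
                 tolerance = 1e-2)
  }
  expect_error(gaussian_within(g, 0), "undefined")
})

test_that("non-parametric pooling matches closed forms where they exist", {
  S <- rand_cov(1)
  g <- gaussian_component_set(matrix(c(0.3, 0.3), 2), list(S, S))
  for (q in c(0.5, 1, 2))
    expect_equal(nonparametric_pooled(g, q), gaussian_renyi(S, q),
                 tolerance = 1e-6, ignore_attr = TRUE)
  # well-separated equal components double the effective volume
  g <- gaussian_component_set(matrix(c(-10, 10), 2),
                              list(matrix(1), matrix(1)))
  expect_equal(as.numeric(nonparametric_pooled(g, 2)), 2 * sqrt(4 * pi),
               tolerance = 1e-6)
  expect_equal(as.numeric(nonparametric_pooled(g, 1)),
               2 * sqrt(2 * pi * exp(1)), tolerance = 1e-4)
  # Monte-Carlo path agrees with quadrature on a 2-D mixture
  g <- gaussian_cluster_set(3, 2, separation = 3, seed = 5)
  quad <- as.numeric(nonparametric_pooled(g, 2, method = "quadrature"))
  mc <- nonparametric_pooled(g, 2, method = "mc", n_mc = 2e5)
  expect_equal(as.numeric(mc), quad, tolerance = 0.02)
  expect_true(is.numeric(attr(mc, "se")))
})

test_that("continuous RRH decomposition behaves under replication and rotation", {
  # identical components: between = 1 under either pooling
  S <- rand_cov(2)
  g <- gaussian_component_set(matrix(1, 3, 2), S)
  for (pooling in c("parametric", "nonparametric")) {
    dec <- continuous_rrh(g, 2, pooling = pooling)
    expect_equal(dec$between, 1, tolerance = 1e-6)
    expect_equal(dec$pooled, dec$within * dec$between, tolerance = 1e-9)
  }
  # well-separated identical components: between -> N (non-parametric)
  g <- gaussian_component_set(matrix(c(-30, 0, 30), 3),
                              list(matrix(1), matrix(1), matrix(1)))
  dec <- continuous_rrh(g, 1, pooling = "nonparametric")
  expect_equal(dec$between, 3, tolerance = 1e-3)
  # affine equivariance: orthogonal rotation leaves every part unchanged
  set.seed(17)
  g <- gaussian_cluster_set(4, 2, separation = 2, seed = 23)
  R <- qr.Q(qr(matrix(rnorm(4), 2)))
  g_rot <- gaussian_component_set(g$mu %*% t(R),
                                  lapply(g$Sigma, function(S) R %*% S %*% t(R)),
                                  w = g$w)
  for (q in c(0.5, 1, 2)) {
    d1 <- continuous_rrh(g, q); d2 <- continuous_rrh(g_rot, q)
    expect_equal(d1$pooled, d2$pooled, tolerance = 1e-9)
    expect_equal(d1$within, d2$within, tolerance = 1e-9)
  }
  # subset analysis renormalizes weights and decomposes consistently
  dec <- continuous_rrh(g, 1, subset = 1:2)
  g_sub <- gaussian_component_set(g$mu[1:2, ], g$Sigma[1:2])
  ref <- continuous_rrh(g_sub, 1)
  expect_equal(dec$between, ref$between, tolerance = 1e-12)
})

test_that("covariance input conventions are promoted and repaired consistently", {
  # log-variance convention (variational-encoder output)
  lv <- matrix(log(c(1, 4, 9, 16)), 2, 2)
  g <- gaussian_component_set(matrix(0, 2, 2), lv, logvar = TRUE)
  expect_equal(g$Sigma[[1]], diag(c(1, 9)))
  expect_equal(g$Sigma[[2]], diag(c(4, 16)))
  # tiny negative eigenvalues are clipped, larger ones rejected
  S <- diag(c(1, -5e-10))
  g <- gaussian_component_set(matrix(0, 1, 2), list(S))
  expect_gte(min(eigen(g$Sigma[[1]])$values), 0)
  expect_error(gaussian_component_set(matrix(0, 1, 2), list(diag(c(1, -1)))),
               "positive semi-definite")
})
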