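# Independent oracles and small fixture builders used across the suite.
# Oracles are written directly against the defining integrals/sums, not
# against package internals.

# brute-force Hill number: direct power sum, no log-space tricks
brute_hill <- function(p, q) {
  p <- p[p > 0]
  if (q == 0) return(length(p))
  if (is.infinite(q)) return(1 / max(p))
  if (q == 1) return(exp(-sum(p * log(p))))
  sum(p^q)^(1 / (1 - q))
}

# random probability vector (normalized gammas = symmetric Dirichlet)
rand_p <- function(n, concentration = 1) {
  g <- rgamma(n, concentration)
  g / sum(g)
}

# random positive-definite covariance via random rotation of positive
# eigenvalues
rand_cov <- function(nz, scale = 1) {
  A <- matrix(rnorm(nz * nz), nz)
  Q <- qr.Q(qr(A))
  S <- Q %*% diag(runif(nz, 0.3, 3) * scale^2, nz) %*% t(Q)
  (S + t(S)) / 2
}

# hand-rolled multivariate Gaussian density (vectorized over rows of z)
dens_gauss <- function(mu, Sigma) {
  nz <- length(mu)
  Sinv <- solve(Sigma)
  ld <- determinant(Sigma, logarithm = TRUE)$modulus[1]
  function(z) {
    z <- matrix(z, ncol = nz)
    d <- sweep(z, 2, mu)
    q2 <- rowSums((d %*% Sinv) * d)
    exp(-0.5 * (q2 + ld + nz * log(2 * pi)))
  }
}

# high-accuracy integral of g over a 1-D interval or 2-D box, by (nested)
# adaptive Gauss-Kronrod quadrature; g takes a matrix with one row per
# evaluation point
quad_integral <- function(g, lower, upper) {
  if (length(lower) == 1L) {
    stats::integrate(function(z) g(matrix(z, ncol = 1)),
                     lower, upper, rel.tol = 1e-11,
                     subdivisions = 800L)$value
  } else {
    outer_f <- function(z1v) {
      vapply(z1v, function(z1) {
        stats::integrate(function(z2)
          g(cbind(rep(z1, length(z2)), z2)),
          lower[2], upper[2], rel.tol = 1e-11,
          subdivisions = 800L)$value
      }, numeric(1))
    }
    stats::integrate(outer_f, lower[1], upper[1], rel.tol = 1e-11,
                     subdivisions = 800L)$value
  }
}

# quadrature oracle for the effective volume (int f^q)^{1/(1-q)} of an
# arbitrary 1-D or 2-D density; q = 1 via the differential-entropy limit
quad_volume <- function(dens, lower, upper, q) {
  ig <- if (q == 1) {
    function(z) { f <- dens(z); ifelse(f > 0, -f * log(f), 0) }
  } else {
    function(z) dens(z)^q
  }
  val <- quad_integral(ig, lower, upper)
  if (q == 1) exp(val) else val^(1 / (1 - q))
}

# quadrature oracle for the within-group effective volume of a weighted
# set of Gaussian components: power-mean of per-component power integrals
quad_within <- function(mu, Sigmas, w, q) {
  pint <- vapply(seq_len(nrow(mu)), function(i) {
    d <- dens_gauss(mu[i, ], Sigmas[[i]])
    sd <- sqrt(diag(Sigmas[[i]]))
    lower <- mu[i, ] - 12 * sd
    upper <- mu[i, ] + 12 * sd
    ig <- if (q == 1) {
      function(z) { f <- d(z); ifelse(f > 0, -f * log(f), 0) }
    } else {
      function(z) d(z)^q
    }
    quad_integral(ig, lower, upper)
  }, numeric(1))
  if (q == 1) return(exp(sum(w * pint)))
  wq <- w^q / sum(w^q)
  sum(wq * pint)^(1 / (1 - q))
}

# scaled quadrature oracle for very large orders: integrates
# (f/f(mu))^q (which stays in [0,1]) and reassembles the effective volume
# in log space
quad_volume_large_q <- function(mu, Sigma, q) {
  d <- dens_gauss(mu, Sigma)
  fmax <- d(matrix(mu, 1))
  sd <- sqrt(diag(Sigma))
  ig <- function(z) (d(z) / fmax)^q
  val <- quad_integral(ig, mu - 0.5 * sd, mu + 0.5 * sd)
  exp((q * log(fmax) + log(val)) / (1 - q))
}

# one-hot posterior matrix with given class assignment
one_hot <- function(labels, nz) {
  F_mat <- matrix(0, length(labels), nz)
  F_mat[cbind(seq_along(labels), labels)] <- 1
  F_mat
}
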