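# Seeded generators for every input class the package consumes, so tests
# and demos run without external data. Each generator is a pure function
# of its arguments (seed included); the caller's RNG state is restored on
# exit.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(expr)
}

# symmetric-Dirichlet draw via normalized gammas
rdirichlet1 <- function(n, concentration) {
  g <- stats::rgamma(n, shape = concentration, rate = 1)
  if (sum(g) == 0) g[sample.int(n, 1)] <- 1   # guard extreme concentrations
  g / sum(g)
}

#' Random categorical distribution from a symmetric Dirichlet
#'
#' @param n number of states (`>= 1`).
#' @param concentration symmetric Dirichlet concentration (`> 0`): large
#'   values give near-uniform distributions, small values near-one-hot.
#' @param seed RNG seed; identical arguments give identical output.
#' @return probability vector of length `n`.
#' @export
random_distribution <- function(n, concentration = 1, seed = DEFAULT_SEED) {
  stopifnot(n >= 1, concentration > 0)
  with_seed(seed, rdirichlet1(n, concentration))
}

#' Ensemble of disjoint, equally heterogeneous subsystems
#'
#' Builds `N` subsystems on disjoint blocks of `block_size` states each,
#' every subsystem carrying the same within-block distribution (drawn once
#' from a symmetric Dirichlet, then placed on its own block). With equal
#' weights this is exactly the setting of the replication principle: the
#' pooled system has `between = N`.
#'
#' @param N number of subsystems.
#' @param block_size states per subsystem block.
#' @param concentration Dirichlet concentration of the shared block
#'   distribution.
#' @param seed RNG seed.
#' @return a [subsystem_ensemble()] over `N * block_size` states.
#' @export
disjoint_replication_ensemble <- function(N, block_size = 3,
                                          concentration = 1,
                                          seed = DEFAULT_SEED) {
  stopifnot(N >= 1, block_size >= 1)
  base <- with_seed(seed, rdirichlet1(block_size, concentration))
  P <- matrix(0, N, N * block_size)
  for (i in seq_len(N))
    P[i, ((i - 1) * block_size + 1):(i * block_size)] <- base
  subsystem_ensemble(P)
}

# random PSD covariance: random rotation of positive eigenvalues
random_psd <- function(nz, scale = 1) {
  A <- matrix(stats::rnorm(nz * nz), nz)
  Q <- qr.Q(qr(A))
  vals <- stats::rexp(nz, rate = 1) + 0.1
  S <- Q %*% diag(vals * scale^2, nz) %*% t(Q)
  (S + t(S)) / 2
}

#' Seeded set of Gaussian latent components in clusters
#'
#' Emulates the structure of per-observation Gaussian posteriors produced
#' by a variational encoder: component means placed on a seeded random
#' sphere of radius `separation`, covariances random positive definite
#' matrices scaled by `covariance_scale`.
#'
#' @param N number of components.
#' @param nz latent dimension.
#' @param separation radius of the mean configuration (latent units);
#'   0 puts all means at the origin.
#' @param covariance_scale linear scale of the random covariances.
#' @param identical_sigma use one shared covariance for all components.
#' @param seed RNG seed.
#' @return a [gaussian_component_set()].
#' @export
gaussian_cluster_set <- function(N, nz, separation = 1,
                                 covariance_scale = 1,
                                 identical_sigma = FALSE,
                                 seed = DEFAULT_SEED) {
  stopifnot(N >= 1, nz >= 1, separation >= 0, covariance_scale > 0)
  with_seed(seed, {
    mu <- matrix(stats::rnorm(N * nz), N, nz)
    nrm <- sqrt(rowSums(mu^2))
    nrm[nrm == 0] <- 1
    mu <- separation * mu / nrm
    Sig <- if (identical_sigma) {
      S <- random_psd(nz, covariance_scale)
      replicate(N, S, simplify = FALSE)
    } else {
      replicate(N, random_psd(nz, covariance_scale), simplify = FALSE)
    }
    gaussian_component_set(mu, Sig)
  })
}

#' Sample observations (with latent labels) from the beta mixture
#'
#' Ancestral sampling: draw the component label from the prior, then the
#' observation from the corresponding beta component.
#'
#' @inheritParams bmm_density
#' @param n sample size.
#' @param seed RNG seed.
#' @return data frame with columns `x` (draws in `(0, 1)`) and `z`
#'   (latent component labels 1/2).
#' @export
bmm_sample <- function(theta, n, seed = DEFAULT_SEED) {
  th <- as_bmm(theta)
  stopifnot(n >= 1)
  with_seed(seed, {
    z <- 1L + stats::rbinom(n, 1L, th$theta1)
    x <- ifelse(z == 1L,
                stats::rbeta(n, th$theta2, th$theta3),
                stats::rbeta(n, th$theta3, th$theta2))
    data.frame(x = x, z = z)
  })
}
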