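# Representational Renyi heterogeneity: heterogeneity of a sample measured
# on the latent posteriors an encoder assigns to each observation, either
# categorical (delegates to the core decomposition) or continuous with
# multivariate-Gaussian closed forms.

#' Heterogeneity of a single categorical latent posterior
#'
#' The Renyi heterogeneity of the posterior `f(x)` an encoder assigns to
#' one observation: 1 means a perfectly confident assignment, `nz` means
#' maximal uncertainty across the `nz` latent categories.
#'
#' @param f_x probability vector over latent categories.
#' @param q elasticity order `>= 0` or `Inf`.
#' @return numbers-equivalent value in `[1, nz]`.
#' @export
categorical_point_heterogeneity <- function(f_x, q) {
  renyi_heterogeneity(f_x, q)
}

#' Categorical representational Renyi heterogeneity
#'
#' Treats each observation's latent posterior as a subsystem and applies
#' the pooled/within/between decomposition. The between component is the
#' effective number of distinct observations with respect to the
#' categorical latent variation; with one-hot (deterministic) posteriors
#' and uniform weights it reduces to the classical Hill numbers on the
#' latent class frequencies.
#'
#' @param F_mat N x nz matrix of per-observation posteriors (rows sum to 1),
#'   or a [subsystem_ensemble()].
#' @param q elasticity order.
#' @param w optional observation weights (default uniform).
#' @return a `heterogeneity_decomposition`.
#' @export
categorical_rrh <- function(F_mat, q, w = NULL) {
  e <- as_ensemble(F_mat, w)
  suppressWarnings(between_heterogeneity(e, q))
}

# ---- Gaussian component sets -------------------------------------------

#' Construct a set of per-observation Gaussian latent posteriors
#'
#' @param mu N x nz matrix of posterior means (latent-space units); a
#'   vector is taken as N means in one latent dimension.
#' @param Sigma covariances: a list of N symmetric PSD nz x nz matrices, a
#'   single matrix recycled to all components, or an N x nz matrix of
#'   per-axis variances (diagonal covariances). Use `logvar = TRUE` when
#'   the matrix holds log-variances (the usual variational-encoder output
#'   convention).
#' @param w observation weights (default uniform).
#' @param logvar interpret a matrix-valued `Sigma` as log-variances.
#' @return object of class `"gaussian_component_set"` with elements
#'   `mu` (N x nz), `Sigma` (list of N matrices), `w`, `N`, `nz`.
#' @export
gaussian_component_set <- function(mu, Sigma, w = NULL, logvar = FALSE) {
  if (is.vector(mu)) mu <- matrix(mu, ncol = 1L)
  mu <- as.matrix(mu)
  N <- nrow(mu); nz <- ncol(mu)
  if (is.list(Sigma)) {
    if (length(Sigma) != N) stop("need one covariance per component",
                                 call. = FALSE)
    Sig <- lapply(Sigma, repair_psd, nz = nz)
  } else {
    Sigma <- as.matrix(Sigma)
    if (nrow(Sigma) == nz && ncol(Sigma) == nz && N != nz) {
      Sig <- replicate(N, repair_psd(Sigma, nz), simplify = FALSE)
    } else if (nrow(Sigma) == N && ncol(Sigma) == nz) {
      if (logvar) Sigma <- exp(Sigma)
      if (any(Sigma < 0))
        stop("diagonal variances must be non-negative", call. = FALSE)
      Sig <- lapply(seq_len(N), function(i)
        diag(Sigma[i, ], nrow = nz, ncol = nz))
    } else if (N == nz && nrow(Sigma) == nz && ncol(Sigma) == nz) {
      # ambiguous square case: treat as one covariance shared by all
      Sig <- replicate(N, repair_psd(Sigma, nz), simplify = FALSE)
    } else {
      stop("`Sigma` must be a list of N matrices, one nz x nz matrix, or ",
           "an N x nz (log-)variance matrix", call. = FALSE)
    }
  }
  if (is.null(w)) w <- rep(1 / N, N)
  w <- validate_distribution(w, arg = "w")
  if (length(w) != N) stop("length of `w` must equal N", call. = FALSE)
  structure(list(mu = mu, Sigma = Sig, w = w, N = N, nz = nz),
            class = "gaussian_component_set")
}

# symmetrize, then clip tiny negative eigenvalues; reject genuinely
# indefinite matrices (min eigenvalue below -1e-9 relative)
repair_psd <- function(S, nz) {
  S <- as.matrix(S)
  if (nrow(S) != nz || ncol(S) != nz)
    stop("covariance has wrong dimension", call. = FALSE)
  if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
    stop("covariance is not symmetric", call. = FALSE)
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE)
  scale <- max(1, max(abs(ev$values)))
  if (min(ev$values) < -1e-9 * scale)
    stop("covariance is not positive semi-definite", call. = FALSE)
  if (min(ev$values) < 0) {
    vals <- pmax(ev$values, 0)
    S <- ev$vectors %*% diag(vals, nz) %*% t(ev$vectors)
    S <- (S + t(S)) / 2
  }
  S
}

#' @export
print.gaussian_component_set <- function(x, ...) {
  cat(sprintf("Gaussian component set: %d components in %d latent dims\n",
              x$N, x$nz))
  invisible(x)
}

# log-determinant of a symmetric PSD matrix via eigen; returns -Inf when
# singular
logdet_psd <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return(-Inf)
  sum(log(ev))
}

#' Renyi heterogeneity of a multivariate Gaussian
#'
#' Closed-form effective volume of latent space occupied by a Gaussian
#' with covariance `Sigma`:
#' `(2*pi)^(nz/2) * q^(nz/(2*(q-1))) * det(Sigma)^(1/2)` for finite
#' `q > 0`, with the limits `(2*pi*e)^(nz/2) * det(Sigma)^(1/2)` at
#' `q = 1` and `(2*pi)^(nz/2) * det(Sigma)^(1/2)` at `q = Inf`. The order
#' `q = 0` is undefined for continuous densities with unbounded support.
#'
#' @param Sigma symmetric positive semi-definite covariance matrix (or a
#'   single variance for one latent dimension).
#' @param q order, `> 0` or `Inf`.
#' @return effective volume (may be below 1); 0 with a warning when
#'   `Sigma` is singular (degenerate support).
#' @examples
#' gaussian_renyi(diag(2), q = 1)   # 2*pi*e
#' @export
gaussian_renyi <- function(Sigma, q) {
  if (is.vector(Sigma) && length(Sigma) == 1L) Sigma <- matrix(Sigma, 1, 1)
  nz <- nrow(Sigma)
  Sigma <- repair_psd(Sigma, nz)
  check_order(q)
  if (q == 0)
    stop("Renyi heterogeneity of a Gaussian is undefined at q = 0",
         call. = FALSE)
  ld <- logdet_psd(Sigma)
  if (is.infinite(ld)) {
    warning("singular covariance: degenerate support, heterogeneity 0",
            call. = FALSE)
    return(0)
  }
  lq <- if (is.infinite(q)) 0 else if (abs(q - 1) < Q_ONE_TOL) nz / 2 else
    nz * log(q) / (2 * (q - 1))
  exp(nz / 2 * log(2 * pi) + lq + ld / 2)
}

#' Effective latent volume of an arbitrary continuous posterior
#'
#' Numerically evaluates `(int f(z)^q dz)^(1/(1-q))` (with the
#' differential-entropy limit `exp(-int f log f)` at `q = 1`) for a
#' user-supplied density over a 1- or 2-dimensional latent space by
#' adaptive quadrature on a bounding box. Intended as the generic (and
#' oracle) pathway; use [gaussian_renyi()] for the Gaussian closed form.
#'
#' @param density function: for `nz = 1` a vectorized function of `z`; for
#'   `nz = 2` a function `f(z1, z2)` vectorized in both arguments.
#' @param q order (`> 0` or `Inf` is not supported here; use the closed
#'   form for `q = Inf`).
#' @param lower,upper numeric vectors (length `nz`) bounding the
#'   integration box; the box must carry essentially all of the mass.
#' @return effective volume (positive; may be below 1).
#' @export
continuous_point_heterogeneity <- function(density, q, lower, upper) {
  check_order(q)
  if (is.infinite(q))
    stop("use the parametric closed form for q = Inf", call. = FALSE)
  if (q == 0)
    stop("order q = 0 is undefined for continuous densities", call. = FALSE)
  nz <- length(lower)
  if (length(upper) != nz || nz > 2)
    stop("quadrature supports 1- or 2-dimensional latent spaces",
         call. = FALSE)
  if (abs(q - 1) < Q_ONE_TOL) {
    integrand <- function(f) ifelse(f > 0, -f * log(f), 0)
    h <- quad_box(function(...) integrand(density(...)), lower, upper)
    return(exp(h))
  }
  s <- quad_box(function(...) density(...)^q, lower, upper)
  if (!is.finite(s) || s <= 0)
    stop("quadrature of the density power failed to converge",
         call. = FALSE)
  s^(1 / (1 - q))
}

quad_box <- function(f, lower, upper) {
  if (length(lower) == 1L) {
    stats::integrate(f, lower, upper, rel.tol = 1e-9,
                     subdivisions = 500L)$value
  } else {
    # nested adaptive quadrature: markedly more accurate than tiled 2-D
    # rules on peaked integrands
    outer_f <- function(z1v) {
      vapply(z1v, function(z1)
        stats::integrate(function(z2) f(rep(z1, length(z2)), z2),
                         lower[2], upper[2], rel.tol = 1e-9,
                         subdivisions = 500L)$value, numeric(1))
    }
    stats::integrate(outer_f, lower[1], upper[1], rel.tol = 1e-9,
                     subdivisions = 500L)$value
  }
}

#' Moment-matched (parametric) pooling of Gaussian components
#'
#' Summarizes a weighted set of Gaussian posteriors by the single Gaussian
#' with the mixture's mean and covariance (law of total covariance):
#' `mu* = sum w_i mu_i` and
#' `Sigma* = -mu* mu*^T + sum w_i (Sigma_i + mu_i mu_i^T)`.
#'
#' @param g a [gaussian_component_set()].
#' @return list with elements `mu_star` and `Sigma_star`.
#' @export
parametric_pool_gaussian <- function(g) {
  stopifnot(inherits(g, "gaussian_component_set"))
  mu_star <- as.numeric(crossprod(g$mu, g$w))
  S <- -tcrossprod(mu_star)
  for (i in seq_len(g$N))
    S <- S + g$w[i] * (g$Sigma[[i]] + tcrossprod(g$mu[i, ]))
  S <- (S + t(S)) / 2
  list(mu_star = mu_star, Sigma_star = S)
}

#' Within-observation heterogeneity of a Gaussian component set
#'
#' Effective latent volume occupied per observation: the power-mean
#' aggregation of the per-component Gaussian integrals,
#' `(2*pi)^(nz/2) * q^(nz/(2(q-1))) *`
#' `[sum_i wbar_i^q det(Sigma_i)^((1-q)/2)]^(1/(1-q))` with
#' `wbar_i^q = w_i^q / sum_k w_k^q`, derived by substituting the Gaussian
#' power integral into the generic continuous within-group formula. The
#' `q = 1` limit is `exp((nz + sum_i w_i log((2*pi)^nz det(Sigma_i))) / 2)`
#' and the `q = Inf` limit is `(2*pi)^(nz/2) * min_i det(Sigma_i)^(1/2)`
#' over the maximal-weight components.
#'
#' @param g a [gaussian_component_set()].
#' @param q order, `> 0` or `Inf` (`q = 0` is undefined).
#' @return effective volume.
#' @export
gaussian_within <- function(g, q) {
  stopifnot(inherits(g, "gaussian_component_set"))
  check_order(q)
  if (q == 0)
    stop("within-observation heterogeneity is undefined at q = 0",
         call. = FALSE)
  nz <- g$nz
  ld <- vapply(g$Sigma, logdet_psd, numeric(1))
  if (any(is.infinite(ld))) {
    warning("singular component covariance: degenerate support, ",
            "within-heterogeneity 0", call. = FALSE)
    return(0)
  }
  w <- g$w
  pos <- w > 0
  if (is.infinite(q)) {
    top <- which(w >= max(w) - 1e-12)
    return(exp(nz / 2 * log(2 * pi) + min(ld[top]) / 2))
  }
  if (abs(q - 1) < Q_ONE_TOL) {
    return(exp((nz + sum(w[pos] * (nz * log(2 * pi) + ld[pos]))) / 2))
  }
  lw <- q * log(w[pos])
  terms <- lw + (1 - q) / 2 * ld[pos]
  m1 <- max(terms); m2 <- max(lw)
  lsum <- (m1 + log(sum(exp(terms - m1)))) - (m2 + log(sum(exp(lw - m2))))
  exp(nz / 2 * log(2 * pi) + nz * log(q) / (2 * (q - 1)) + lsum / (1 - q))
}

# mixture density of a gaussian_component_set, vectorized over rows of z
mixture_density <- function(g) {
  chols <- lapply(g$Sigma, function(S) {
    R <- tryCatch(chol(S), error = function(e) NULL)
    if (is.null(R)) stop("singular component covariance in mixture density",
                         call. = FALSE)
    R
  })
  ldets <- vapply(chols, function(R) 2 * sum(log(diag(R))), numeric(1))
  nz <- g$nz
  function(z) {
    z <- matrix(z, ncol = nz)
    out <- numeric(nrow(z))
    for (i in seq_len(g$N)) {
      if (g$w[i] == 0) next
      d <- sweep(z, 2L, g$mu[i, ])
      u <- backsolve(chols[[i]], t(d), transpose = TRUE)
      q2 <- colSums(u^2)
      out <- out + g$w[i] *
        exp(-0.5 * (q2 + ldets[i] + nz * log(2 * pi)))
    }
    out
  }
}

# integration box: pooled mean +/- 8 pooled standard deviations per axis
pooled_box <- function(g, half_width = 8) {
  pool <- parametric_pool_gaussian(g)
  sd <- sqrt(pmax(diag(pool$Sigma_star), 0))
  sd[sd == 0] <- max(sd, 1e-3)
  list(lower = pool$mu_star - half_width * sd,
       upper = pool$mu_star + half_width * sd)
}

#' Non-parametric (model-average) pooled heterogeneity
#'
#' Effective latent volume of the weighted mixture density
#' `sum_i w_i f(z | x_i)`, evaluated by adaptive quadrature on a box of
#' +/- 8 pooled standard deviations per axis for `nz <= 2`, or by Monte
#' Carlo over draws from the mixture for higher dimension
#' (`method = "mc"`). The Monte-Carlo path reports its standard error and
#' warns when the relative standard error exceeds 1%.
#'
#' @param g a [gaussian_component_set()].
#' @param q order (`> 0`, finite; use parametric pooling for `q = Inf`).
#' @param method `"quadrature"` (default for `nz <= 2`) or `"mc"`.
#' @param n_mc Monte-Carlo sample size.
#' @param seed RNG seed for the Monte-Carlo path.
#' @return effective volume; for `method = "mc"` the estimate carries an
#'   attribute `"se"` with its delta-method standard error.
#' @export
nonparametric_pooled <- function(g, q, method = NULL, n_mc = 1e5,
                                 seed = DEFAULT_SEED) {
  stopifnot(inherits(g, "gaussian_component_set"))
  check_order(q)
  if (q == 0 || is.infinite(q))
    stop("non-parametric pooling supports finite q > 0", call. = FALSE)
  if (is.null(method)) method <- if (g$nz <= 2) "quadrature" else "mc"
  method <- match.arg(method, c("quadrature", "mc"))
  dens <- mixture_density(g)
  if (method == "quadrature") {
    if (g$nz > 2)
      stop("quadrature pooling supports nz <= 2; use method = \"mc\"",
           call. = FALSE)
    box <- pooled_box(g)
    if (g$nz == 1L) {
      # split the interval at the component means so adaptive quadrature
      # cannot step over narrow, widely separated peaks
      ig <- if (abs(q - 1) < Q_ONE_TOL) {
        function(z) { f <- dens(z); ifelse(f > 0, -f * log(f), 0) }
      } else {
        function(z) dens(z)^q
      }
      breaks <- sort(unique(c(box$lower, g$mu[, 1], box$upper)))
      breaks <- breaks[breaks >= box$lower & breaks <= box$upper]
      s <- sum(vapply(seq_len(length(breaks) - 1L), function(i)
        stats::integrate(ig, breaks[i], breaks[i + 1L], rel.tol = 1e-9,
                         subdivisions = 500L)$value, numeric(1)))
      return(if (abs(q - 1) < Q_ONE_TOL) exp(s) else s^(1 / (1 - q)))
    }
    f <- function(z1, z2) {
      out <- dens(cbind(as.numeric(z1), as.numeric(z2)))
      if (!is.null(dim(z1))) dim(out) <- dim(z1)
      out
    }
    return(continuous_point_heterogeneity(f, q, box$lower, box$upper))
  }
  # importance-free MC: draws from the mixture itself give
  # int m^q dz = E_m[m^{q-1}]  and  -int m log m = E_m[-log m]
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  z <- sample_gaussian_mixture(g, n_mc)
  m <- dens(z)
  if (abs(q - 1) < Q_ONE_TOL) {
    v <- -log(m)
    est <- exp(mean(v))
    se <- est * stats::sd(v) / sqrt(n_mc)
  } else {
    v <- m^(q - 1)
    mu <- mean(v)
    est <- mu^(1 / (1 - q))
    se <- abs(est / ((1 - q) * mu)) * stats::sd(v) / sqrt(n_mc)
  }
  if (se / est > 0.01)
    warning(sprintf("Monte-Carlo relative standard error %.2g%% exceeds 1%%",
                    100 * se / est), call. = FALSE)
  structure(est, se = se)
}

sample_gaussian_mixture <- function(g, n) {
  comp <- sample.int(g$N, n, replace = TRUE, prob = g$w)
  z <- matrix(0, n, g$nz)
  for (i in unique(comp)) {
    idx <- comp == i
    ni <- sum(idx)
    R <- chol(g$Sigma[[i]] + diag(1e-12, g$nz))
    z[idx, ] <- matrix(stats::rnorm(ni * g$nz), ni) %*% R +
      matrix(g$mu[i, ], ni, g$nz, byrow = TRUE)
  }
  z
}

#' Continuous representational Renyi heterogeneity
#'
#' Full pooled/within/between decomposition for a set of Gaussian latent
#' posteriors. Pooling is either parametric (moment-matched Gaussian,
#' closed form) or non-parametric (mixture density, numerical). The
#' between component is the effective number of distinct observations in
#' the sample with respect to the continuous latent representation. A
#' subset of observations can be analyzed by passing `subset`; its weights
#' are renormalized internally.
#'
#' @param g a [gaussian_component_set()].
#' @param q order (`> 0`; `Inf` allowed with parametric pooling).
#' @param pooling `"parametric"` (default) or `"nonparametric"`.
#' @param subset optional integer vector of component indices to analyze.
#' @param ... passed to [nonparametric_pooled()].
#' @return a `heterogeneity_decomposition`. A between value below 1 is
#'   possible in the continuous case and triggers a warning rather than an
#'   error.
#' @export
continuous_rrh <- function(g, q, pooling = c("parametric", "nonparametric"),
                           subset = NULL, ...) {
  stopifnot(inherits(g, "gaussian_component_set"))
  pooling <- match.arg(pooling)
  check_order(q)
  if (!is.null(subset)) {
    wsub <- g$w[subset]
    g <- gaussian_component_set(g$mu[subset, , drop = FALSE],
                                g$Sigma[subset], w = wsub / sum(wsub))
  }
  pooled <- if (pooling == "parametric") {
    gaussian_renyi(parametric_pool_gaussian(g)$Sigma_star, q)
  } else {
    as.numeric(nonparametric_pooled(g, q, ...))
  }
  within <- gaussian_within(g, q)
  dec <- new_decomposition(q, pooled, within)
  if (dec$between < 1 - 1e-9)
    warning("between-observation heterogeneity below 1: the continuous ",
            "decomposition does not guarantee Lande's bound here",
            call. = FALSE)
  dec
}
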