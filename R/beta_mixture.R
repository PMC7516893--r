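# Fully analytic two-component beta-mixture benchmark: a degenerate
# optimal-threshold classifier over the latent component label yields a
# closed-form categorical representational heterogeneity, compared head to
# head with the distance/similarity-sensitive comparator indices.

#' Beta-mixture parameters
#'
#' @param theta1 mixture weight of component 2, in `[0, 1]`.
#' @param theta2,theta3 positive shape parameters. Component 1 is
#'   `Beta(theta2, theta3)`; component 2 is the mirror `Beta(theta3,
#'   theta2)`.
#' @return validated list of class `"bmm_params"`.
#' @export
bmm_params <- function(theta1, theta2, theta3) {
  if (!is.numeric(theta1) || length(theta1) != 1L || is.na(theta1) ||
      theta1 < 0 || theta1 > 1)
    stop("`theta1` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(theta2) || length(theta2) != 1L || is.na(theta2) ||
      theta2 <= 0 || !is.numeric(theta3) || length(theta3) != 1L ||
      is.na(theta3) || theta3 <= 0)
    stop("shape parameters `theta2`, `theta3` must be positive",
         call. = FALSE)
  structure(list(theta1 = theta1, theta2 = theta2, theta3 = theta3),
            class = "bmm_params")
}

as_bmm <- function(theta) {
  if (inherits(theta, "bmm_params")) return(theta)
  if (is.numeric(theta) && length(theta) == 3L)
    return(bmm_params(theta[1], theta[2], theta[3]))
  stop("`theta` must be a bmm_params object or numeric vector of length 3",
       call. = FALSE)
}

#' Marginal density of the beta mixture
#'
#' `p(x) = (1 - theta1) Beta(theta2, theta3)(x) + theta1 Beta(theta3,
#' theta2)(x)` on the open unit interval.
#'
#' @param x numeric vector in `(0, 1)`.
#' @param theta a [bmm_params()] or numeric `(theta1, theta2, theta3)`.
#' @return density values.
#' @export
bmm_density <- function(x, theta) {
  th <- as_bmm(theta)
  if (any(x <= 0) || any(x >= 1))
    stop("`x` must lie in the open interval (0, 1)", call. = FALSE)
  (1 - th$theta1) * stats::dbeta(x, th$theta2, th$theta3) +
    th$theta1 * stats::dbeta(x, th$theta3, th$theta2)
}

#' Prior over the latent component label
#'
#' @inheritParams bmm_density
#' @return probability vector `(1 - theta1, theta1)` over components 1, 2.
#' @export
bmm_prior <- function(theta) {
  th <- as_bmm(theta)
  c(1 - th$theta1, th$theta1)
}

#' Bayes-optimal decision threshold of the degenerate classifier
#'
#' The classifier assigns latent label 1 when `x <= tau` and 2 otherwise,
#' with `tau` solving the posterior-equality condition
#' `p(z=1 | x=tau) = p(z=2 | x=tau)`. Because the component likelihood
#' ratio is `(x/(1-x))^(theta3-theta2)`, the log posterior odds are
#' monotone in `x` and the root is found by safeguarded root-finding.
#' Degenerate cases are handled explicitly: identical shapes give
#' `tau = 0` when `theta1 > 1/2` and `tau = 1` otherwise, and pure
#' mixtures (`theta1` 0 or 1) give `tau = 1` or `tau = 0`.
#'
#' @inheritParams bmm_density
#' @return threshold in `[0, 1]`.
#' @examples
#' optimal_threshold(c(0.5, 5, 20))   # symmetry gives 0.5
#' @export
optimal_threshold <- function(theta) {
  th <- as_bmm(theta)
  if (th$theta1 == 0) return(1)
  if (th$theta1 == 1) return(0)
  d <- th$theta3 - th$theta2
  if (d == 0) return(if (th$theta1 > 0.5) 0 else 1)
  # log odds z=2 vs z=1 at x: log(theta1/(1-theta1)) + d * logit(x)
  odds <- function(x) log(th$theta1 / (1 - th$theta1)) + d * stats::qlogis(x)
  root <- stats::uniroot(odds, lower = 1e-12, upper = 1 - 1e-12,
                         tol = 1e-14, extendInt = "no")$root
  min(max(root, 0), 1)
}

#' Pooled probability of latent component 2 under the threshold model
#'
#' Expected classifier output `E[f(z = 2 | x)]` under the data-generating
#' marginal: the mixture mass above the optimal threshold, computed with
#' regularized incomplete beta functions,
#' `(1-theta1) * I_[tau,1](theta2, theta3) + theta1 * I_[tau,1](theta3,
#' theta2)`.
#'
#' @inheritParams bmm_density
#' @return probability `fbar(z = 2)`; `fbar(z = 1)` is its complement.
#' @export
pooled_component_weight <- function(theta) {
  th <- as_bmm(theta)
  tau <- optimal_threshold(th)
  (1 - th$theta1) * stats::pbeta(tau, th$theta2, th$theta3,
                                 lower.tail = FALSE) +
    th$theta1 * stats::pbeta(tau, th$theta3, th$theta2, lower.tail = FALSE)
}

#' Representational heterogeneity of the beta-mixture threshold model
#'
#' Because the classifier posterior is degenerate (one-hot) at every `x`,
#' the within-observation heterogeneity is identically 1, so the between
#' component equals the pooled Renyi heterogeneity of the two pooled
#' component weights. This is the closed-form categorical RRH of the
#' benchmark.
#'
#' @inheritParams bmm_density
#' @param q order `>= 0` or `Inf`.
#' @return a `heterogeneity_decomposition` with `within = 1`.
#' @examples
#' bmm_rrh(c(0.5, 5, 20), q = 2)$between   # 2: two effective components
#' @export
bmm_rrh <- function(theta, q) {
  th <- as_bmm(theta)
  check_order(q)
  f2 <- pooled_component_weight(th)
  pooled <- renyi_het_unchecked(c(1 - f2, f2), q)
  new_decomposition(q, pooled, within = 1)
}

#' Expected absolute distance between two independent beta variables
#'
#' `E|X - Y|` for `X ~ Beta(a1, b1)` and `Y ~ Beta(a2, b2)` independent.
#' Evaluated by reducing the inner expectation to regularized incomplete
#' beta functions,
#' `E|x - Y| = x (2 F_Y(x) - 1) + m_Y (1 - 2 F_{Y+}(x))` with
#' `m_Y = a2/(a2+b2)` and `F_{Y+}` the CDF of `Beta(a2+1, b2)`, and
#' integrating over `x` by adaptive quadrature (absolute tolerance
#' `1e-10`).
#'
#' @param a1,b1,a2,b2 positive shape parameters.
#' @return expected absolute distance in `[0, 1]`.
#' @examples
#' expected_beta_distance(1, 1, 1, 1)   # two uniforms: 1/3
#' @export
expected_beta_distance <- function(a1, b1, a2, b2) {
  stopifnot(a1 > 0, b1 > 0, a2 > 0, b2 > 0)
  m2 <- a2 / (a2 + b2)
  inner <- function(x)
    x * (2 * stats::pbeta(x, a2, b2) - 1) +
      m2 * (1 - 2 * stats::pbeta(x, a2 + 1, b2))
  f <- function(x) stats::dbeta(x, a1, b1) * inner(x)
  stats::integrate(f, 0, 1, abs.tol = 1e-10, rel.tol = 1e-10,
                   subdivisions = 1000L)$value
}

# pairwise expected-distance matrix between the two mixture components;
# self-distance either 0 (categorical distance-matrix convention) or the
# expected absolute distance between two independent draws of the same
# component
bmm_distance_matrix <- function(th, self_distance = c("zero", "expected")) {
  self_distance <- match.arg(self_distance)
  d12 <- expected_beta_distance(th$theta2, th$theta3, th$theta3, th$theta2)
  if (self_distance == "zero") {
    d11 <- d22 <- 0
  } else {
    d11 <- expected_beta_distance(th$theta2, th$theta3, th$theta2, th$theta3)
    d22 <- expected_beta_distance(th$theta3, th$theta2, th$theta3, th$theta2)
  }
  matrix(c(d11, d12, d12, d22), 2, 2)
}

#' Comparator indices on the two-component beta mixture
#'
#' Best-case evaluation of the three non-categorical comparator indices on
#' the benchmark: the state space is the pair of mixture components with
#' the true prior as the probability vector, and distances are expected
#' absolute distances between component draws (already on the unit
#' interval, so the quadratic-entropy rescaling is not reapplied). The
#' similarity matrix for the Leinster-Cobbold index is `exp(-u * D)`.
#'
#' @inheritParams bmm_rrh
#' @param u similarity scaling for the Leinster-Cobbold index.
#' @param self_distance `"zero"` (default; distance-matrix convention) or
#'   `"expected"`, which puts `E|X - X'|` of each component on the
#'   diagonal. The diagonal always enters the Leinster-Cobbold similarity
#'   through `exp(-u * D)`; for `"zero"` that diagonal is 1.
#' @return named list with elements `Qe`, `Fq`, `Lq` (numbers equivalent).
#' @export
bmm_comparator_indices <- function(theta, q, u = 1,
                                   self_distance = c("zero", "expected")) {
  th <- as_bmm(theta)
  check_order(q)
  self_distance <- match.arg(self_distance)
  D <- bmm_distance_matrix(th, self_distance)
  p <- bmm_prior(th)
  q1 <- as.numeric(t(p) %*% D %*% p)
  qe <- if (q1 < 1) 1 / (1 - q1) else NA_real_
  fq <- if (q1 > 0) {
    qq_ratio <- function(qv) {
      pq <- outer(p, p); m <- pq > 0
      sum(D[m] * pq[m]^qv) / q1
    }
    if (is.infinite(q)) {
      pq <- outer(p, p)
      1 / sqrt(max(pq[D > 0 & pq > 0]))
    } else if (abs(q - 1) < 1e-6) {
      eps <- 1e-6
      sqrt(qq_ratio(1 + eps)^(1 / (2 * (-eps))) *
             qq_ratio(1 - eps)^(1 / (2 * eps)))
    } else {
      qq_ratio(q)^(1 / (2 * (1 - q)))
    }
  } else NA_real_
  S <- exp(-u * D)
  sp <- as.numeric(S %*% p)
  pos <- p > 0
  lq <- if (is.infinite(q)) {
    1 / max(sp[pos])
  } else if (abs(q - 1) < Q_ONE_TOL) {
    exp(-sum(p[pos] * log(sp[pos])))
  } else {
    sum(p[pos] * sp[pos]^(q - 1))^(1 / (1 - q))
  }
  list(Qe = qe, Fq = fq, Lq = lq)
}

#' Benchmark profile of all four indices over the mixture-weight grid
#'
#' Sweeps the mixture weight `theta1` for one or more component
#' separations and tabulates the representational heterogeneity alongside
#' the three comparator indices, in tidy long-format rows.
#'
#' @param theta2,theta3 shape parameters (scalars or equal-length vectors
#'   giving several separation regimes).
#' @param q_list orders to evaluate.
#' @param theta1_grid mixture weights to sweep (default 50 points on
#'   `[0.5, 0.99]`).
#' @param u similarity scaling for the Leinster-Cobbold index.
#' @param self_distance diagonal convention, see
#'   [bmm_comparator_indices()].
#' @return data frame with columns `theta1`, `theta2`, `theta3`, `q`,
#'   `index`, `value`.
#' @export
bmm_index_profile <- function(theta2 = 5, theta3 = 20, q_list = c(1, 2),
                              theta1_grid = seq(0.5, 0.99, length.out = 50),
                              u = 1,
                              self_distance = c("zero", "expected")) {
  self_distance <- match.arg(self_distance)
  stopifnot(length(theta2) == length(theta3))
  rows <- list()
  for (k in seq_along(theta2)) {
    for (q in q_list) {
      for (t1 in theta1_grid) {
        th <- bmm_params(t1, theta2[k], theta3[k])
        rrh <- bmm_rrh(th, q)$between
        cmp <- bmm_comparator_indices(th, q, u = u,
                                      self_distance = self_distance)
        rows[[length(rows) + 1L]] <- data.frame(
          theta1 = t1, theta2 = theta2[k], theta3 = theta3[k], q = q,
          index = c("RRH", "Qe", "Fq", "Lq"),
          value = c(rrh, cmp$Qe, cmp$Fq, cmp$Lq))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
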