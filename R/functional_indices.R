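# Distance- and similarity-sensitive numbers-equivalent indices:
# numbers-equivalent quadratic entropy, functional Hill numbers, and the
# Leinster-Cobbold index, plus the 3-state triangular toy system used to
# compare them.

SYM_TOL <- 1e-9

#' Construct/validate a pairwise distance matrix
#'
#' @param D square numeric matrix of pairwise dissimilarities: symmetric
#'   within `1e-9`, zero diagonal, non-negative entries.
#' @return the validated matrix with class `"distance_matrix"`.
#' @export
distance_matrix <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D))
    stop("distance matrix must be square", call. = FALSE)
  if (anyNA(D) || !is.numeric(D))
    stop("distance matrix must be numeric without NAs", call. = FALSE)
  if (max(abs(D - t(D))) > SYM_TOL)
    stop("distance matrix is not symmetric (tolerance 1e-9)", call. = FALSE)
  if (any(abs(diag(D)) > SYM_TOL))
    stop("distance matrix must have a zero diagonal", call. = FALSE)
  if (any(D < 0))
    stop("distance matrix has negative entries", call. = FALSE)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  class(D) <- c("distance_matrix", class(D))
  D
}

#' Construct/validate a pairwise similarity matrix
#'
#' @param S square numeric symmetric matrix with unit diagonal and entries
#'   in `[0, 1]`.
#' @return the validated matrix with class `"similarity_matrix"`.
#' @export
similarity_matrix <- function(S) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S))
    stop("similarity matrix must be square", call. = FALSE)
  if (max(abs(S - t(S))) > SYM_TOL)
    stop("similarity matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(S) - 1) > SYM_TOL))
    stop("similarity matrix must have a unit diagonal", call. = FALSE)
  if (any(S < 0) || any(S > 1 + SYM_TOL))
    stop("similarity entries must lie in [0, 1]", call. = FALSE)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  class(S) <- c("similarity_matrix", class(S))
  S
}

check_dims <- function(D, p) {
  if (nrow(D) != length(p))
    stop("dimension mismatch between matrix and probability vector",
         call. = FALSE)
}

#' Rao's quadratic entropy
#'
#' Expected pairwise dissimilarity between two independent draws from `p`:
#' `sum_ij D_ij p_i p_j`.
#'
#' @param D a [distance_matrix()] (or coercible matrix).
#' @param p probability vector over the states indexing `D`.
#' @return expected pairwise distance (units of `D`).
#' @export
rao_quadratic_entropy <- function(D, p) {
  D <- distance_matrix(D)
  p <- validate_distribution(p)
  check_dims(D, p)
  as.numeric(t(p) %*% unclass(D) %*% p)
}

#' Rescale a distance matrix to the unit interval
#'
#' Affine rescaling `(D - min) / (max - min)` over all entries (diagonal
#' included, so the diagonal stays zero whenever the minimum is zero).
#'
#' @inheritParams rao_quadratic_entropy
#' @return the rescaled [distance_matrix()].
#' @export
rescale_distance <- function(D) {
  D <- distance_matrix(D)
  rng <- range(D)
  if (diff(rng) <= 0)
    stop("cannot rescale a constant distance matrix", call. = FALSE)
  distance_matrix((unclass(D) - rng[1]) / diff(rng))
}

#' Numbers-equivalent quadratic entropy
#'
#' Ricotta-Szeidl transformation of Rao's quadratic entropy onto the
#' numbers-equivalent scale: `1 / (1 - Q1(D, p))`, where `D` is first
#' rescaled to `[0, 1]` (opt out with `rescale = FALSE` when the distances
#' already live on the unit interval). For a categorical 0/1 distance
#' matrix this reduces exactly to the inverse Simpson concentration
#' `Pi_2(p)`.
#'
#' @inheritParams rao_quadratic_entropy
#' @param rescale apply the unit-interval rescaling first (default `TRUE`).
#' @return numbers-equivalent value.
#' @export
numbers_equivalent_qe <- function(D, p, rescale = TRUE) {
  D <- distance_matrix(D)
  p <- validate_distribution(p)
  check_dims(D, p)
  if (rescale) D <- rescale_distance(D)
  q1 <- as.numeric(t(p) %*% unclass(D) %*% p)
  if (q1 >= 1)
    stop("rescaled quadratic entropy >= 1: numbers equivalent undefined",
         call. = FALSE)
  1 / (1 - q1)
}

#' Generalized Rao quadratic entropy of order q
#'
#' `sum_ij D_ij (p_i p_j)^q`, with the `0^0 = 0` convention at `q = 0`
#' (pairs where either probability is zero do not contribute).
#'
#' @inheritParams rao_quadratic_entropy
#' @param q elasticity order `>= 0`.
#' @return generalized quadratic entropy (units of `D`).
#' @export
generalized_rqe <- function(D, p, q) {
  D <- distance_matrix(D)
  p <- validate_distribution(p)
  check_dims(D, p)
  check_order(q)
  pq <- outer(p, p)
  m <- pq > 0
  out <- unclass(D)[m] * pq[m]^q
  sum(out)
}

#' Functional Hill numbers of order q
#'
#' `F_q = [Q_q(D, p) / Q_1(D, p)]^{1/(2(1-q))}`: the number of states of an
#' idealized system with constant between-state distance matching the
#' quadratic entropy of `(D, p)`. At `q = 1` the limit is evaluated by
#' symmetric bracketing at `q = 1 +/- 1e-6` (geometric mean of the two
#' evaluations), since the limit has no convenient closed form.
#'
#' @inheritParams generalized_rqe
#' @return numbers-equivalent value. Note `F_q` may exceed the number of
#'   states `n` for unequal `p` — a documented pathology of this index.
#' @export
functional_hill <- function(D, p, q) {
  D <- distance_matrix(D)
  p <- validate_distribution(p)
  check_dims(D, p)
  check_order(q)
  q1 <- as.numeric(t(p) %*% unclass(D) %*% p)
  if (q1 <= 0)
    stop("Q1(D, p) = 0 (degenerate p or zero distances): Fq undefined",
         call. = FALSE)
  fq_at <- function(q) {
    (generalized_rqe(D, p, q) / q1)^(1 / (2 * (1 - q)))
  }
  if (is.infinite(q)) {
    # q -> Inf: Qq is dominated by the largest p_i p_j among contributing
    # pairs, so Fq -> (max p_i p_j)^{-1/2}
    pq <- outer(p, p)
    m <- max(pq[unclass(D) > 0 & pq > 0])
    return(1 / sqrt(m))
  }
  if (abs(q - 1) < 1e-6) {
    eps <- 1e-6
    return(sqrt(fq_at(1 + eps) * fq_at(1 - eps)))
  }
  fq_at(q)
}

#' Similarity matrix from a distance matrix by exponential decay
#'
#' `S_ij = exp(-u * D_ij)`. At `u = 0` all states are fully similar
#' (S is all ones); as `u -> Inf`, `S` approaches the identity and
#' similarity-sensitive indices recover the categorical Renyi
#' heterogeneity.
#'
#' @inheritParams rao_quadratic_entropy
#' @param u non-negative scaling factor (inverse units of `D`).
#' @return a [similarity_matrix()].
#' @export
similarity_from_distance <- function(D, u) {
  D <- distance_matrix(D)
  if (!is.numeric(u) || length(u) != 1L || is.na(u) || u < 0)
    stop("`u` must be a single non-negative number", call. = FALSE)
  similarity_matrix(exp(-u * unclass(D)))
}

#' Leinster-Cobbold similarity-sensitive heterogeneity
#'
#' `L_q = [sum_i p_i ((S p)_i)^{q-1}]^{1/(1-q)}`, the numbers equivalent of
#' a system whose state topology is governed by the similarity matrix `S`.
#' With `S` the identity this is exactly the categorical Renyi
#' heterogeneity. Analytic limits: at `q = 1`,
#' `exp(-sum_i p_i log (S p)_i)`; at `q = Inf`, `1 / max_i (S p)_i` over
#' the support of `p`.
#'
#' @param S a [similarity_matrix()] (or coercible matrix).
#' @param p probability vector.
#' @param q elasticity order `>= 0`.
#' @return numbers-equivalent value in `[1, n]`.
#' @export
leinster_cobbold <- function(S, p, q) {
  S <- similarity_matrix(S)
  p <- validate_distribution(p)
  check_dims(S, p)
  check_order(q)
  sp <- as.numeric(unclass(S) %*% p)
  pos <- p > 0
  if (is.infinite(q)) return(1 / max(sp[pos]))
  if (abs(q - 1) < Q_ONE_TOL)
    return(exp(-sum(p[pos] * log(sp[pos]))))
  x <- log(p[pos]) + (q - 1) * log(sp[pos])
  m <- max(x)
  exp((m + log(sum(exp(x - m)))) / (1 - q))
}

#' Metric and ultrametric checks for a distance matrix
#'
#' Exhaustively verifies the (ultra)metric axioms over all ordered triples:
#' non-negativity, symmetry, identity of indiscernibles
#' (`D_ij = 0 <=> i = j`), and the triangle inequality
#' `D_ik <= D_ij + D_jk` (metric) or `D_ik <= max(D_ij, D_jk)`
#' (ultrametric). Inequalities are tested with absolute tolerance `1e-9`
#' so that boundary geometries classify stably.
#'
#' @inheritParams rao_quadratic_entropy
#' @return logical flag.
#' @export
is_metric <- function(D) {
  metric_check(D, ultra = FALSE)
}

#' @rdname is_metric
#' @export
is_ultrametric <- function(D) {
  metric_check(D, ultra = TRUE)
}

metric_check <- function(D, ultra) {
  D <- unclass(distance_matrix(D))
  n <- nrow(D)
  off <- D[upper.tri(D)]
  if (n > 1 && any(off <= SYM_TOL)) return(FALSE)  # indiscernible distinct states
  if (n < 3) return(TRUE)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n)) {
    if (i == j || j == k || i == k) next
    bound <- if (ultra) max(D[i, j], D[j, k]) else D[i, j] + D[j, k]
    if (D[i, k] > bound + SYM_TOL) return(FALSE)
  }
  TRUE
}

#' Three-state toy system: probability vector
#'
#' A one-parameter family interpolating smoothly from a degenerate
#' distribution on state 1 (`kappa = 0`) through the uniform distribution
#' (`kappa = 1`) to a degenerate distribution on state 3
#' (`kappa = Inf`): `p(kappa) = (1, sqrt(kappa), kappa)` normalized.
#'
#' @param kappa inequality parameter `>= 0` (or `Inf`).
#' @return probability vector of length 3.
#' @export
toy_probability <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1L || is.na(kappa) || kappa < 0)
    stop("`kappa` must be a single non-negative number", call. = FALSE)
  if (is.infinite(kappa)) return(c(0, 0, 1))
  v <- c(1, sqrt(kappa), kappa)
  v / sum(v)
}

#' Three-state toy system: triangular distance matrix
#'
#' States arranged as a triangle with base `b` (distance between states 1
#' and 2) and height `h`; state 3 sits at distance `sqrt(b^2/4 + h^2)`
#' from each base state. The matrix is ultrametric iff
#' `h >= b * sqrt(3) / 2` and metric otherwise.
#'
#' @param h triangle height (> 0, length units).
#' @param b triangle base (> 0, same units).
#' @return a 3x3 [distance_matrix()].
#' @export
toy_distance <- function(h, b = 1) {
  if (!is.numeric(h) || length(h) != 1L || is.na(h) || h <= 0)
    stop("`h` must be a single positive number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || is.na(b) || b <= 0)
    stop("`b` must be a single positive number", call. = FALSE)
  s <- sqrt(b^2 / 4 + h^2)
  distance_matrix(matrix(c(0, b, s,
                           b, 0, s,
                           s, s, 0), 3, 3, byrow = TRUE))
}
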