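# Categorical Renyi heterogeneity (Hill numbers) and its decomposition.

Q_ONE_TOL <- 1e-10   # |q - 1| below this uses the perplexity limit
PROB_TOL  <- 1e-6    # probability/weight vectors renormalized within this of 1

#' Validate (and renormalize) a categorical probability distribution
#'
#' @param p numeric vector of state probabilities, all non-negative and
#'   summing to 1 within `1e-6` (small file round-off is renormalized away).
#' @param arg name used in error messages.
#' @return the validated, renormalized probability vector.
#' @keywords internal
validate_distribution <- function(p, arg = "p") {
  if (!is.numeric(p) || length(p) < 1L)
    stop(sprintf("`%s` must be a non-empty numeric vector", arg), call. = FALSE)
  if (anyNA(p))
    stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  if (any(p < 0))
    stop(sprintf("`%s` has negative entries", arg), call. = FALSE)
  s <- sum(p)
  if (abs(s - 1) > PROB_TOL)
    stop(sprintf("`%s` sums to %.8g, not 1 (tolerance %g)", arg, s, PROB_TOL),
         call. = FALSE)
  p / s
}

# log of the power sum  sum_i p_i^q  over the support of p, computed by
# log-sum-exp over q * log p_i so that extreme q neither under- nor overflows
log_power_sum <- function(p, q) {
  lp <- log(p[p > 0])
  x <- q * lp
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Renyi heterogeneity (Hill number) of order q
#'
#' The numbers equivalent of a categorical distribution: the number of
#' states of a uniform system whose probability of a homogeneous sample of
#' size `q` matches that of `p`. Equals `(sum(p^q))^(1/(1-q))` for
#' `q` outside `{0, 1, Inf}`; the observed richness at `q = 0`; the
#' perplexity `exp(H(p))` at `q = 1`; and the Berger-Parker diversity
#' `1/max(p)` at `q = Inf`.
#'
#' @param p probability vector (validated; non-negative, sums to 1).
#' @param q elasticity order, a single number `>= 0` or `Inf`. `q = Inf`
#'   must be passed explicitly; large finite `q` is evaluated directly
#'   (in log space, so `q` up to a few hundred is safe).
#' @return a single numbers-equivalent value in `[1, length(p)]`.
#' @examples
#' renyi_heterogeneity(c(0.7, 0.3), 2)      # inverse Simpson, ~1.724
#' renyi_heterogeneity(c(0.5, 0.25, 0.25), 1)  # perplexity, 2^1.5
#' @export
renyi_heterogeneity <- function(p, q) {
  p <- validate_distribution(p)
  check_order(q)
  renyi_het_unchecked(p, q)
}

check_order <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0)
    stop("order `q` must be a single non-negative number (Inf allowed)",
         call. = FALSE)
  invisible(q)
}

# core evaluation on an already-validated p
renyi_het_unchecked <- function(p, q) {
  pp <- p[p > 0]
  if (is.infinite(q)) return(1 / max(pp))
  if (q == 0) return(as.numeric(length(pp)))        # 0^0 = 0 convention
  if (abs(q - 1) < Q_ONE_TOL) return(exp(-sum(pp * log(pp))))
  exp(log_power_sum(pp, q) / (1 - q))
}

#' Classical diversity and inequality indices derived from Renyi heterogeneity
#'
#' Returns the family of indices that are monotone transforms of (or limits
#' of) the Renyi heterogeneity: observed richness, perplexity, inverse
#' Simpson concentration, Berger-Parker diversity, Renyi entropy
#' `log(Pi_q)`, Shannon entropy, Tsallis entropy, Simpson concentration,
#' Gini-Simpson index, and the generalized entropy index. Tsallis entropy
#' and the generalized entropy index are computed as their analytic
#' `q -> 1` limits when `q = 1`.
#'
#' @inheritParams renyi_heterogeneity
#' @return a named list of index values.
#' @examples
#' derived_indices(rep(0.25, 4), q = 1)$shannon_entropy  # log(4)
#' @export
derived_indices <- function(p, q) {
  p <- validate_distribution(p)
  check_order(q)
  n <- length(p)
  pi_q <- renyi_het_unchecked(p, q)
  pi_1 <- renyi_het_unchecked(p, 1)
  pi_2 <- renyi_het_unchecked(p, 2)
  tsallis <- if (is.infinite(q)) {
    NA_real_
  } else if (abs(q - 1) < Q_ONE_TOL) {
    log(pi_1)                                   # q -> 1 limit is Shannon
  } else {
    (1 - pi_q^(1 - q)) / (q - 1)
  }
  gei <- if (is.infinite(q)) {
    NA_real_
  } else if (abs(q - 1) < Q_ONE_TOL) {
    # limit of (1/(q(q-1))) [ (Pi_q/n)^{1-q} - 1 ] as q -> 1 is
    # Theil's index log(n) - H(p)
    log(n) - log(pi_1)
  } else if (q == 0) {
    NA_real_                                    # 1/(q(q-1)) undefined at 0
  } else {
    ((pi_q / n)^(1 - q) - 1) / (q * (q - 1))
  }
  list(
    richness             = renyi_het_unchecked(p, 0),
    perplexity           = pi_1,
    inverse_simpson      = pi_2,
    berger_parker        = renyi_het_unchecked(p, Inf),
    renyi_entropy        = log(pi_q),
    shannon_entropy      = log(pi_1),
    tsallis_entropy      = tsallis,
    simpson_concentration = 1 / pi_2,
    gini_simpson         = 1 - 1 / pi_2,
    generalized_entropy  = gei
  )
}

#' Construct a weighted ensemble of categorical subsystems
#'
#' Bundles a row-stochastic matrix `P` (row i = state distribution of
#' subsystem i) with subsystem weights `w`. Rows and weights are validated
#' and renormalized within a `1e-6` tolerance; larger deviations are
#' rejected rather than silently fixed.
#'
#' @param P numeric matrix, `N` rows (subsystems) by `n` columns (states).
#' @param w numeric vector of `N` non-negative weights summing to 1;
#'   defaults to uniform weights.
#' @return an object of class `"subsystem_ensemble"` with elements
#'   `P`, `w`, `N`, `n`.
#' @export
subsystem_ensemble <- function(P, w = NULL) {
  P <- as.matrix(P)
  if (!is.numeric(P) || nrow(P) < 1L || ncol(P) < 1L)
    stop("`P` must be a non-empty numeric matrix", call. = FALSE)
  P <- t(apply(P, 1L, validate_distribution, arg = "row of P"))
  if (ncol(P) == 1L) P <- matrix(P, ncol = 1L)  # apply() drops to vector
  N <- nrow(P)
  if (is.null(w)) w <- rep(1 / N, N)
  if (length(w) != N)
    stop("length of `w` must equal nrow(P)", call. = FALSE)
  w <- validate_distribution(w, arg = "w")
  structure(list(P = P, w = w, N = N, n = ncol(P)),
            class = "subsystem_ensemble")
}

as_ensemble <- function(e, w = NULL) {
  if (inherits(e, "subsystem_ensemble")) e else subsystem_ensemble(e, w)
}

#' @export
print.subsystem_ensemble <- function(x, ...) {
  cat(sprintf("Subsystem ensemble: %d subsystems over %d states\n", x$N, x$n))
  invisible(x)
}

#' Pooled heterogeneity of a subsystem ensemble
#'
#' The Renyi heterogeneity of the weighted mixture distribution
#' `p_bar = sum_i w_i p_i`: the effective number of states in the pooled
#' system.
#'
#' @param e a [subsystem_ensemble()] (or a matrix coerced to one).
#' @param q elasticity order, `>= 0` or `Inf`.
#' @param w optional weights when `e` is a plain matrix.
#' @return numbers-equivalent pooled heterogeneity.
#' @export
pooled_heterogeneity <- function(e, q, w = NULL) {
  e <- as_ensemble(e, w)
  check_order(q)
  p_bar <- as.numeric(crossprod(e$P, e$w))
  renyi_het_unchecked(p_bar, q)
}

#' Within-group heterogeneity of a subsystem ensemble
#'
#' The effective number of unique states contributed per subsystem:
#' `[sum_i w_i^q sum_j p_ij^q / sum_k w_k^q]^(1/(1-q))`, with the
#' analytic limits `exp(sum_i w_i H(p_i))` at `q = 1` and, at `q = Inf`,
#' `1 / max p_ij` over the subsystems of maximal weight (the direct limit
#' of the finite-q formula). At `q = 0` subsystems with zero weight are
#' excluded by the `0^0 = 0` convention.
#'
#' @inheritParams pooled_heterogeneity
#' @return numbers-equivalent within-group heterogeneity.
#' @export
within_heterogeneity <- function(e, q, w = NULL) {
  e <- as_ensemble(e, w)
  check_order(q)
  P <- e$P; wts <- e$w
  pos <- wts > 0
  if (is.infinite(q)) {
    # q -> Inf: weight mass concentrates on argmax(w); the power mean then
    # picks out the largest cell probability among those subsystems
    top <- which(wts >= max(wts) - 1e-12)
    return(1 / max(P[top, , drop = FALSE]))
  }
  if (abs(q - 1) < Q_ONE_TOL) {
    h <- apply(P, 1L, function(p) {
      pp <- p[p > 0]; -sum(pp * log(pp))
    })
    return(exp(sum(wts[pos] * h[pos])))
  }
  if (q == 0) {
    rich <- rowSums(P[pos, , drop = FALSE] > 0)
    return(mean(rich)^(1 / (1 - q)))            # w^0 = 1 on support
  }
  lw <- q * log(wts[pos])
  lps <- apply(P[pos, , drop = FALSE], 1L, log_power_sum, q = q)
  lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
  exp((lse(lw + lps) - lse(lw)) / (1 - q))
}

#' Full pooled/within/between decomposition of a subsystem ensemble
#'
#' Computes the multiplicative decomposition `pooled = within * between`.
#' The between-group factor is the effective number of completely distinct
#' subsystems. When subsystem weights are unequal, the interpretation of
#' the between component as lying in `[1, N]` is only guaranteed at
#' `q = 0` and `q = 1` (Jost's condition); a warning is emitted otherwise.
#'
#' @inheritParams pooled_heterogeneity
#' @return an object of class `"heterogeneity_decomposition"`: a list with
#'   elements `q`, `pooled`, `within`, `between`.
#' @examples
#' e <- subsystem_ensemble(rbind(c(.5, .5, 0, 0), c(0, 0, .5, .5)))
#' between_heterogeneity(e, q = 1)   # pooled 4 = within 2 x between 2
#' @export
between_heterogeneity <- function(e, q, w = NULL) {
  e <- as_ensemble(e, w)
  check_order(q)
  unequal <- diff(range(e$w)) > 1e-12
  if (unequal && !is.infinite(q) && q != 0 && abs(q - 1) >= Q_ONE_TOL)
    warning(paste("unequal subsystem weights: between-group heterogeneity",
                  "is only guaranteed to lie in [1, N] at q = 0 or q = 1"),
            call. = FALSE)
  pooled <- pooled_heterogeneity(e, q)
  within <- within_heterogeneity(e, q)
  new_decomposition(q, pooled, within)
}

new_decomposition <- function(q, pooled, within) {
  structure(list(q = q, pooled = pooled, within = within,
                 between = pooled / within),
            class = "heterogeneity_decomposition")
}

#' @export
print.heterogeneity_decomposition <- function(x, ...) {
  cat(sprintf("Heterogeneity decomposition (q = %g)\n", x$q))
  cat(sprintf("  pooled:  %.6g\n  within:  %.6g\n  between: %.6g\n",
              x$pooled, x$within, x$between))
  invisible(x)
}

#' @export
as.data.frame.heterogeneity_decomposition <- function(x, ...) {
  data.frame(q = x$q, pooled = x$pooled, within = x$within,
             between = x$between)
}
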