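---
title: "Measuring heterogeneity in numbers equivalents, on observed and latent spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring heterogeneity in numbers equivalents, on observed and latent spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renyihet)
```

## The measurement problem

Many disciplines need a single number for "how heterogeneous is this
system": species diversity in an ecosystem, concentration of wealth,
diversity of clinical presentations within a diagnostic category. This
package works throughout in the *numbers equivalent*: the heterogeneity
of a system is reported as the size of an idealized uniform system with
the same heterogeneity — the effective number of equally common species,
agents, or mixture components, or, on a continuous latent space, the
effective volume of a uniform distribution. Reporting on this scale makes
values comparable across indices and makes doubling mean doubling.

The core index is the Rényi heterogeneity of order $q$ (equivalently the
Hill numbers, or the exponential of Rényi entropy),

$$\Pi_q(\mathbf p) = \Big(\sum_{i=1}^n p_i^q\Big)^{\frac{1}{1-q}},$$

where the elasticity $q \ge 0$ tunes sensitivity to rare versus common
states. Its limiting cases are the classical indices: observed richness
at $q = 0$, perplexity $\exp H(\mathbf p)$ at $q \to 1$, inverse Simpson
concentration at $q = 2$, and Berger–Parker diversity $1/\max_i p_i$ at
$q \to \infty$. `derived_indices()` exposes the related transforms
(Shannon, Tsallis, Gini–Simpson, generalized entropy index).

Two structural properties motivate the choice of this family. The
*principle of transfers*: any equality-increasing transfer of probability
between states must increase heterogeneity. The *replication principle*:
pooling $N$ disjoint, equally heterogeneous, equally weighted subsystems
must multiply heterogeneity by exactly $N$. Both are verified as property
tests over random distributions in the test suite.

## Decomposition

For a weighted collection of subsystems (rows of a row-stochastic matrix
$P$, weights $\mathbf w$), heterogeneity decomposes multiplicatively,
$\Pi^P_q = \Pi^W_q \cdot \Pi^B_q$:

* `pooled_heterogeneity()` — $\Pi_q$ of the mixture
  $\bar{\mathbf p} = \sum_i w_i \mathbf p_i$;
* `within_heterogeneity()` — the weighted power-mean
  $\big[\sum_i \tilde w_i^{(q)} \sum_j p_{ij}^q\big]^{1/(1-q)}$ with
  $\tilde w_i^{(q)} = w_i^q / \sum_k w_k^q$, the effective number of
  unique states contributed per subsystem;
* `between_heterogeneity()` — their ratio, the effective number of
  completely distinct subsystems.

With equal weights the between component always lies in $[1, N]$; with
unequal weights that guarantee holds only at $q = 0$ and $q = 1$ (Jost's
condition), and the package warns rather than refuses in that regime,
since the decomposition identity itself still holds by construction.

Two limiting cases of the within formula are not spelled out by its
usual presentation and were fixed here as the direct limits of the
finite-$q$ expression: at $q \to 1$ it is $\exp(\sum_i w_i H(\mathbf
p_i))$, and at $q \to \infty$ the weight term concentrates on the
maximal-weight subsystems, giving $1 / \max p_{ij}$ over those rows. The
$q=\infty$ unequal-weight case is checked in the tests against direct
evaluation at very large finite order.

## Distance- and similarity-sensitive comparators

Categorical indices treat all state pairs as equally different. Three
established "functional diversity" comparators relax that, and the
package implements them both for their own sake and as benchmark
baselines:

* **Numbers-equivalent quadratic entropy** `numbers_equivalent_qe()`:
  $\hat Q_e = (1 - Q_1(\tilde D, \mathbf p))^{-1}$, with Rao's quadratic
  entropy $Q_1 = \sum_{ij} D_{ij} p_i p_j$ and $\tilde D$ rescaled to
  $[0,1]$. Rescaling is on by default (required for the
  numbers-equivalent interpretation) with an opt-out for distances
  already on the unit interval.
* **Functional Hill numbers** `functional_hill()`:
  $F_q = [Q_q / Q_1]^{1/(2(1-q))}$ with
  $Q_q = \sum_{ij} D_{ij} (p_i p_j)^q$. No closed form is available for
  the $q \to 1$ limit, so it is evaluated by symmetric bracketing at
  $q = 1 \pm 10^{-6}$ and taking the geometric mean; the bracketing error
  is far below the $10^{-9}$ scale the tests work at.
* **Leinster–Cobbold index** `leinster_cobbold()`:
  $L_q = [\sum_i p_i ((S\mathbf p)_i)^{q-1}]^{1/(1-q)}$ on a similarity
  matrix, typically $S_{ij} = e^{-u D_{ij}}$
  (`similarity_from_distance()`). Its $q = 1$ and $q = \infty$ limits are
  evaluated analytically.

All three reduce exactly to $\Pi_q(\mathbf p)$ in the categorical limit
($D$ the 0/1 matrix, $S$ the identity) at their consistency orders,
which the tests assert on random distributions.

### The triangular toy system

`toy_probability(kappa)` and `toy_distance(h, b)` build the smallest
system in which the comparators' failure modes are visible: three states
at the corners of a triangle with base $b$ and height $h$, with a
one-parameter probability family running from degenerate through uniform
to oppositely degenerate. The distance matrix is ultrametric iff
$h \ge b\sqrt3/2$ (`is_ultrametric()` checks the axioms exhaustively over
triples, with absolute tolerance $10^{-9}$ so the equilateral boundary
classifies stably).

On this system the tests demonstrate: $\hat Q_e$ changes regime exactly
at the ultrametric threshold (increasing in $h$ below it, decreasing
above); $F_q$ is completely insensitive to the geometry when
probabilities are even ($F_q \equiv n$), and can exceed $n$ when they are
not; and $L_q$ approaches $\Pi_q$ only as $u \to \infty$ while never
exceeding it.

One note on the probability family: its middle branch is fixed here as
$(1, \sqrt\kappa, \kappa)$ normalized, the simplest smooth interpolant
consistent with the anchor cases $\kappa \in \{0, 1, \infty\}$; any
smooth interpolant with those anchors yields the same qualitative
comparisons, which is all the toy system is used for. Relatedly, no
numeric table exists for the published comparator curves on this system,
so the tests assert their shapes (monotonicity, regime changes, bounds)
rather than point values.

## Representational heterogeneity

The indices above require a state partition and a distance function on
the observed data. Representational Rényi heterogeneity instead measures
heterogeneity on a *latent representation*: a model maps each
observation $x_i$ to a posterior distribution over a latent space, each
posterior is treated as one subsystem, and the decomposition above is
applied. The between component is then the effective number of distinct
observations with respect to the latent variation the model captures.

**Categorical latent spaces** (`categorical_rrh()`): posteriors are rows
of an $N \times n_z$ matrix. With one-hot posteriors and uniform weights
the within component is identically 1 and the between component reduces
to the classical Hill numbers on label counts — the sense in which
species-diversity and wealth-concentration analyses are special cases of
the representational approach.

**Continuous latent spaces**: the analogue of the power sum is
$\int f^q(z)\,dz$, and the numbers equivalent becomes an effective
volume, which may legitimately fall below 1 for concentrated posteriors.
For multivariate Gaussian posteriors everything is closed-form:

$$\Pi_q(\Sigma) = (2\pi)^{n_z/2}\, q^{\frac{n_z}{2(q-1)}}\, |\Sigma|^{1/2},$$

with limits $(2\pi e)^{n_z/2}|\Sigma|^{1/2}$ at $q = 1$ and
$(2\pi)^{n_z/2}|\Sigma|^{1/2}$ at $q = \infty$; $q = 0$ is undefined for
continuous densities and is rejected explicitly (`gaussian_renyi()`).
The within component (`gaussian_within()`) substitutes the Gaussian
power integral into the generic within formula, giving

$$\Pi^W_q = (2\pi)^{n_z/2}\, q^{\frac{n_z}{2(q-1)}}
\Big[\sum_i \tilde w_i^{(q)} |\Sigma_i|^{\frac{1-q}{2}}\Big]^{\frac{1}{1-q}}.$$

Because printed variants of this formula in the surrounding literature
are easy to mistranscribe, the package treats numerical agreement with
the defining integral as ground truth: the test suite validates both
closed forms against adaptive-quadrature evaluation of the integrals at
relative tolerance $10^{-6}$ for $n_z \in \{1,2\}$ over random rotated
positive-definite covariances, with the $q \to \infty$ regime checked at
order $10^3$ in a numerically scaled form. The $q = \infty$ within-limit
is derived directly from the finite-$q$ expression (the weight power
mean concentrates on maximal-weight components and the determinant term
on the smallest covariance among them).

**Pooling.** Two pooled distributions are supported and deliberately not
interchangeable:

* *parametric* (`parametric_pool_gaussian()`): the moment-matched
  Gaussian, $\mu^* = \sum_i w_i \mu_i$,
  $\Sigma^* = -\mu^*\mu^{*\top} + \sum_i w_i(\Sigma_i +
  \mu_i\mu_i^\top)$ — the law of total covariance, verified against
  Monte-Carlo moments. It imputes mass to regions between components,
  which is an assumption, not an approximation error.
* *non-parametric* (`nonparametric_pooled()`): the mixture density
  itself, integrated numerically — nested adaptive quadrature for
  $n_z \le 2$ (on a box of $\pm 8$ pooled standard deviations per axis,
  split at component means along one axis so that widely separated
  narrow peaks cannot be stepped over), or stratified Monte Carlo from
  the mixture for higher dimension, with a delta-method standard error
  attached and a warning above 1% relative error.

No ordering between the two pooled values is asserted anywhere: neither
dominates in general. `continuous_rrh()` assembles the decomposition
with either pooling, supports subset analysis with renormalized subset
weights, and warns (not errors) when the between component falls below
1, which the continuous decomposition does not preclude.

## The beta-mixture benchmark

The fully analytic benchmark system is a two-component beta mixture on
$(0,1)$: component 1 is $\mathrm{Beta}(\theta_2, \theta_3)$, component 2
the mirrored $\mathrm{Beta}(\theta_3, \theta_2)$, with prior weight
$\theta_1$ on component 2. The representational model is the
Bayes-optimal hard classifier: $z = 1$ iff $x \le \tau$, with $\tau$
solving the posterior-equality condition. Since the likelihood ratio is
$(x/(1-x))^{\theta_3 - \theta_2}$, the log posterior odds are monotone
in $x$; `optimal_threshold()` therefore root-finds on the odds rather
than trusting any transcribed closed form, and hard-codes only the
unambiguous degenerate cases ($\theta_2 = \theta_3$, or pure mixtures).

Because the classifier's posteriors are one-hot, the within component is
*identically* 1 (`bmm_rrh()` returns it as an exact integer, tested to
$10^{-12}$), and the between component equals the pooled Hill number of
the two pooled component weights, computed with regularized incomplete
beta functions (`pooled_component_weight()`, via `pbeta`). At
$\theta = (0.5, 5, 20)$ the between heterogeneity is exactly 2 at every
order; at $\theta_2 = \theta_3$ it is exactly 1 regardless of
$\theta_1$ — the two calibration points the acceptance script recomputes.

The comparator indices are evaluated on the same benchmark in their
best-case configuration: states = the two true components, probabilities
= the true prior, distances = expected absolute distances between
component draws, $\mathbb E|X - Y|$ (`expected_beta_distance()`,
evaluated by reducing the inner expectation to incomplete-beta terms and
integrating the outer variable adaptively to $10^{-10}$; an independent
double-quadrature oracle confirms it). Distances on $(0,1)$ are already
unit-interval, so no rescaling is reapplied. Two diagonal conventions
are supported: zeros (the distance-matrix convention, default) or the
nonzero self-distances $\mathbb E|X - X'|$; the Leinster–Cobbold
weight-invariance at $\theta_2 = \theta_3$ appears under the latter
(the similarity matrix is then constant), while the other qualitative
conclusions — the functional Hill numbers' paradoxical *increase* as the
prior skews (a transfer violation), the Leinster–Cobbold peak deficit
below 2 at finite $u$, and the concavity of the representational index —
hold under both. The similarity scale for the benchmark is not dictated
by the system; it is exposed as `u` with default 1.
`bmm_index_profile()` tabulates all four indices over the
$\theta_1$-grid in tidy long format.

## Numerical choices

* Power sums are computed by log-sum-exp over $q \log p_i$ (zeros
  skipped), so orders up to the thousands neither underflow nor
  overflow; $0^0 = 0$ at $q = 0$ makes $\Pi_0$ observed richness.
* $|q - 1| < 10^{-10}$ is treated as $q = 1$ and routed to the
  perplexity/entropy limits; $q = \infty$ must be passed explicitly as
  `Inf` — no large-$q$ threshold silently switches regimes.
* Probability vectors and weights are renormalized when within
  $10^{-6}$ of unit sum (file round-off) and rejected beyond that.
* Covariances are symmetrized and eigenvalue-clipped when the most
  negative eigenvalue exceeds $-10^{-9}$ (relative), rejected otherwise;
  determinants come from symmetric eigendecompositions, with singular
  covariances mapped to volume 0 plus a warning.
* Monte-Carlo helpers default to one library-wide seed
  (`DEFAULT_SEED = 20200417`) and restore the caller's RNG state.

## Synthetic data, and what the tests do and do not show

All test inputs are generated in code: symmetric-Dirichlet probability
vectors spanning near-one-hot to near-uniform regimes
(`random_distribution()`); disjoint block ensembles realizing the exact
assumptions of the replication principle
(`disjoint_replication_ensemble()`); Gaussian component sets with means
on a seeded sphere of controllable separation and random rotated
covariances, emulating the structure of variational-encoder posteriors
(`gaussian_cluster_set()`); and ancestral samples from the beta mixture
(`bmm_sample()`). Problem sizes were chosen so every property is
exercised where it is sharpest while the whole suite stays interactive:
ensembles up to $N = 5$ blocks, latent dimensions $n_z \le 2$ for
quadrature cross-checks, $10^5$ draws for Monte-Carlo oracles, 100
Dirichlet draws for the transfer property.

These generators emulate the *structural* conditions of the theory —
exact distributional knowledge, disjoint supports, Gaussian posteriors.
They do not emulate real encoders (whose posteriors are neither exactly
Gaussian nor independent of each other), estimation noise from finite
samples (the package deliberately contains no bias correction or
rarefaction — probabilities are treated as known), or high-dimensional
latent spaces, where the non-parametric pooling path relies on Monte
Carlo with its reported standard error. Passing tests therefore certify
the mathematics and the numerics, not the behaviour of any particular
trained representation model.

## Known limitations

* Quadrature pooling is restricted to $n_z \le 2$; higher dimensions use
  Monte Carlo and inherit its error bar.
* Only Gaussian parametric families ship for the continuous path; the
  density interface of `continuous_point_heterogeneity()` accepts
  arbitrary 1-D/2-D densities but pooling machinery is Gaussian-only.
* Conditions under which the continuous between component provably stays
  at or above 1 are not implemented; the package only warns when the
  bound fails.
* Distance inputs are plain matrices; tree-derived distances must be
  converted upstream.
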