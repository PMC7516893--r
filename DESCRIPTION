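Package: renyihet
Title: Representational Renyi Heterogeneity and Numbers-Equivalent Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Numbers-equivalent heterogeneity (Hill numbers) for categorical
    systems and for latent representations. Implements the Renyi heterogeneity
    of order q with its pooled/within/between decomposition, the classical
    diversity and inequality indices it generalizes, three similarity- or
    distance-sensitive comparator indices (numbers-equivalent quadratic
    entropy, functional Hill numbers, Leinster-Cobbold index), closed-form
    Renyi heterogeneity of multivariate Gaussian posteriors with parametric
    and non-parametric pooling, and a fully analytic two-component beta-mixture
    benchmark that contrasts representational heterogeneity with the
    comparator indices. Includes seeded synthetic-data generators and
    delimited-text readers for abundance tables, distance matrices and
    Gaussian embedding sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
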