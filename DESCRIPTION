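Package: poisirt
Title: Log-Linear Poisson Item Response Models for Count Scores
Version: 0.1.0
Authors@R: person("poisirt", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Fits the Rasch Poisson counts model (RPCM) and its
    two-parameter generalization (2PPCM) to fluency-type count scores.
    Provides marginal maximum likelihood estimation via Gauss-Hermite
    quadrature and Bayesian estimation via Hamiltonian Monte Carlo with
    weakly informative prior construction rules, plus the standard
    psychometric post-estimation toolkit: EAP and posterior factor
    scores, item response and information functions, empirical
    reliability, dispersion diagnostics and Pearson residuals,
    posterior predictive checks, expected score frequencies, and
    WAIC/LOO model comparison with pairwise slope contrasts. Includes a
    synthetic-data generator and a command-line workflow driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
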