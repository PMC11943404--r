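---
title: "Poisson count IRT models for fluency scores: models, priors, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poisson count IRT models for fluency scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Fluency-type tests score the number of responses a person produces in
fixed time: ideas for alternate uses of an object, words beginning with
a letter, solution attempts. The scores are non-negative integers whose
variance grows with their mean, so linear factor-analytic machinery is
misspecified for them. `poisirt` treats the score of person $i$ on item
$j$ as

$$X_{ij} \sim \mathrm{Poisson}(\lambda_{ij}), \qquad
  \lambda_{ij} = e^{\,b_j + a_j\theta_i},$$

with item easiness $b_j$ on the log-count scale, item slope
(discrimination) $a_j$, and latent fluency $\theta_i \sim N(0,
\sigma^2)$. Scores are conditionally independent given $\theta_i$
(local independence). Equal slopes give the Rasch Poisson counts model
(RPCM); free slopes give the two-parameter Poisson counts model
(2PPCM), which nests the RPCM. Because the inverse link is
exponential, $e^{b_j}$ is the expected count at average ability and
$e^{a_j}$ the fold change in the expected count per SD of ability —
the package's summaries print both the raw and the exponentiated
tables for this reason.

An equivalent discrimination/difficulty parametrization
$\lambda_{ij} = e^{\alpha_j(\theta_i - \delta_j)}$ is available through
`to_irt_parametrization()` ($\alpha_j = a_j$, $\delta_j = -b_j/a_j$).
We deliberately use the sign convention under which higher ability
raises the expected count; the printed form of this reparametrization
in parts of the count-IRT literature has the opposite sign inside the
exponent, which would make counts *decrease* in ability and contradict
the slope–intercept form, so we do not honor it.

## Identification

Two schemes are supported and must be chosen up front:

* **variance standardization** (default): $\sigma = 1$ exactly.
  Abilities land on a z-scale and all slopes are estimated.
* **marker**: the designated marker item's slope is fixed at exactly 1
  and $\sigma$ is free. This matches structural-equation conventions
  and is useful when a well-understood anchor item exists.

These are hard constraints, not priors: under variance standardization
the fitted `theta_sd` is identically 1, under marker the marker slope
is identically 1 in every posterior draw.

## Prior construction

The package ships two weakly informative construction rules rather
than fixed numbers, so the priors scale with the instrument:

* **Easiness** (`easiness_prior_from_range(min, max)`): a normal
  truncated at 0 with location $\log(1 + \mathrm{range}/2)$ (the log of
  the midpoint count) and scale $\log(\mathrm{range}/2)$ (the log of
  half the range). For scores spanning 1–23 this gives location
  $\log 12 \approx 2.48$ and scale $\log 11 \approx 2.40$. The rule
  degenerates when half the range is $\le 1$ (its log would be
  non-positive); the constructor then refuses and asks for a manual
  prior. Callers decide whether the range is observed or hypothesized —
  the function takes explicit bounds.
* **Slope** (`slope_prior_from_fold(max_fold)`): a normal truncated to
  positive values with location 0 and scale $\log(\mathrm{max\_fold})$,
  expressing "one SD of ability should multiply the count by at most
  this factor". A 4-fold ceiling gives scale $\log 4 \approx 1.39$.

Under marker identification the non-marker slopes instead get an
*untruncated* $N(1, 1)$ prior (they cluster near 1 when the test is
homogeneous, and the literature states this prior without truncation,
so we keep it untruncated), and the free $\sigma$ gets a half-Student-t
with 3 degrees of freedom and scale 2.5 bounded at 0 — the standard
weakly informative default for group-level standard deviations. The
RPCM's single shared slope reuses the 2PPCM slope prior once; no
separate rule exists for it. Flat easiness priors are accepted when
requested explicitly. Truncated densities are renormalized over their
support, and a parameter outside its support yields $-\infty$ (a
rejected state), not an exception.

## Estimation

**Marginal maximum likelihood.** The latent trait is integrated out
with Gauss–Hermite quadrature normalized against the standard-normal
density (61 nodes by default; nodes/weights from the Golub–Welsch
eigenvalue method). The marginal likelihood is maximized by BFGS from a
deterministic moment-matching start — easiness at `log(item mean +
0.5)`, slopes at 0.5, log latent SD at 0 — and standard errors come
from the inverse of the numerically differentiated observed
information; $\sigma$ is optimized on the log scale and its SE
delta-method transformed back. A singular information matrix yields a
fit with flagged-unavailable SEs rather than a failure, and the
convergence report carries the gradient norm in place of MCMC
diagnostics. With 61 nodes the quadrature matches dense-grid
integration to well below $10^{-5}$ for realistic fluency data (counts
of tens, slopes below about 1); extremely informative persons (many
items with very large counts) concentrate the posterior enough that
more nodes would be needed, which is why the node count is exposed.

**MCMC.** The Bayesian backend samples item parameters and all
$\theta_i$ jointly with Hamiltonian Monte Carlo. Positivity constraints
implied by truncated priors (and by $\sigma$ itself) are handled by log
transforms with Jacobian terms; gradients are analytic. Warmup-only
adaptation uses dual averaging for the step size and a diagonal mass
matrix estimated from the middle warmup window; the number of leapfrog
steps is drawn uniformly from the upper half of `1..max_leapfrog`
(default 16). `step_control$target_accept` (default 0.9) plays the role
of the usual step-size-control knob: raising it toward 0.99 makes the
sampler take smaller, safer steps. Defaults mirror common practice — 4
chains, 2000 iterations per chain of which 1000 are warmup, an explicit
seed required; chains run sequentially with seeds derived
deterministically from it, so identical configurations reproduce
identical draws. Divergences are defined as leapfrog trajectories whose
energy error exceeds 50 (or turns non-finite) and are counted post
warmup; a sampler that cannot detect divergences would report 0 with an
explicit not-applicable flag instead of omitting the field. Point
estimates are posterior means on the reporting scale; intervals are
raw 2.5%/97.5% quantiles, with no multiplicity adjustment anywhere.

Convergence is summarized per parameter by rank-normalized split R-hat
and bulk/tail effective sample sizes (Geyer initial monotone
truncation; tail ESS is the minimum over the 5% and 95% quantile
indicator sequences). R-hat above 1.01 or ESS below 400 produces a
warning, not a failure, mirroring standard reporting guidance. R-hat is
`NaN` when all draws are identical and `Inf` when internally constant
chains disagree.

## Scoring, information, reliability

Factor scores come either from quadrature (`eap_scores()`: posterior
mean/SD of $\theta$ on the node grid, intervals by inverting the
discretized CDF with a midpoint correction and linear interpolation) or
from draws (`extract_theta()`: means, SDs and type-7 quantiles across
all post-warmup draws). The two interval conventions are fixed
deliberately — they must be pinned for reproducibility, and the
midpoint correction removes the outward bias the node atoms would
otherwise give the quadrature intervals. Persons not in the training
data can be scored post hoc against fixed item parameters; this is the
standard IRT scoring use case and is clearly a plug-in, not a refit.

Item information is $I_j(\theta) = a_j^2\lambda_{ij}$ (the negative
expected second derivative of the Poisson log-likelihood), test
information its sum over items; both increase with easiness, squared
slope and (for positive slopes) ability, so unlike logistic IRT there
is no information peak. Curve tables default to the plausible ability
range $-3$ to $3$ in steps of 0.01.

Empirical reliability is the classical ratio
$\mathrm{VAR}(\hat\theta) / (\mathrm{VAR}(\hat\theta) +
\overline{SE^2})$, with the person-level variant using the person's own
squared error. The statistic depends on the point-estimate convention;
the package uses posterior means/SDs for MCMC fits and EAP/EAP-SD for
MML fits, and all persons — including ones with few observed items,
who appear as low-reliability outliers — are kept in the group-level
computation.

## Fit diagnostics

Fitted values $\hat y_{ij}$ are posterior means of $\lambda_{ij}$
across draws (MCMC) or plug-in rates at the estimates with EAP
abilities (MML); by Jensen's inequality the former is at least the
rate at the posterior means. Dispersion is
$\phi = \frac{1}{N}\sum (y-\hat y)^2/\hat y$ over the *observed*
records (the textbook divisor $n\cdot m$ assumes complete data; with
missingness we keep $\phi$ a mean of per-record terms), with per-item
versions and the exact identity $\phi = $ mean of squared Pearson
residuals $(y-\hat y)/\sqrt{\hat y}$. Note that because $\hat y$ is
fitted to the same data (the person's $\hat\theta$ absorbs part of the
noise), $\phi$ sits somewhat below 1 even for data simulated from the
model; calibration to 1 holds when the *true* rates are used as fitted
values, which is how the test suite checks it.

Posterior predictive checks simulate replicate counts from
$\mathrm{Poisson}(\lambda_{ij})$ at every retained draw and ask whether
each observation lies inside the smallest integer interval holding at
least 95% of its replicate mass. Discreteness makes exact-95% intervals
unattainable, so the chosen convention is conservative: the nominal
outside rate is a few percent, not exactly 5%. All post-warmup draws
are used unless a seeded subsample is requested, and reports include
grouped (by-item/by-person) summaries plus pooled replicate score
distributions for density overlays. For MML fits the same contract is
provided as a parametric bootstrap: item-parameter draws from the
asymptotic normal at the estimates and abilities from each person's
EAP posterior approximated as normal — an approximation flagged here
because the true EAP posterior is mildly skewed for extreme scorers.
Expected score frequencies sum the Poisson mass at each score over the
fitted rates, reproducing covariate-adjusted frequency tables.

## Model comparison

WAIC and importance-sampling LOO operate on the pointwise
log-likelihood matrix (one Poisson log-pmf per draw per record,
*conditional* on that draw's $\theta$). The conditional formulation is
the one standard draw-based workflows compute and is the default; a
marginal, person-level alternative that integrates $\theta$ back out by
quadrature is exposed as an option because the two differ materially
and answer different prediction questions (new responses from known
persons vs entirely new persons). LOO stabilizes importance ratios by
truncation at $\bar r\,S^{3/4}$ by default — it preserves the
estimator's simple contract — with Pareto-smoothing of the upper tail
optional, and a per-record flag marks heavy-tailed ratio distributions
(fitted Pareto $k > 0.7$). ELPD differences are reported with the
standard error of the pointwise differences; Bayes factors are
deliberately not computed (a poorly estimated harmonic-mean-style BF is
worse than none), and the CLI prints a pointer instead. Pairwise slope
contrasts summarize per-draw slope differences with raw 95% intervals
and sign probabilities; for the RPCM they are identically zero and
reported with a note.

## The synthetic-data generator

`simulate_dataset()` draws $\theta_i \sim N(0, \sigma^2)$ and counts
from the model, with configurable item parameters, a missingness
pattern (which may never silence a person completely), and full seed
determinism. `simulate_example_dataset()` fixes the generator at the
shape of the motivating instrument: 202 persons, three alternate-uses
items, one person observed on a single item (604 records), equal
slopes of 0.34, easiness $(2.06, 1.74, 2.07)$ chosen so expected
counts sit near 6–8 ideas and observed scores span roughly 1–23. The
slopes are equal on purpose: the reference analysis found the items
near-indistinguishable in discrimination, making the RPCM the
generating truth and the 2PPCM the overparametrized candidate — the
configuration the model-comparison tests exercise. What the generator
does *not* emulate: underdispersion (real fluency data often show
variance below the mean; the generator is exactly Poisson), local
dependence between similar prompts, originality/quality scoring, and
any covariate structure. A green test therefore establishes
correctness of the machinery under the stated model, not adequacy of
the Poisson assumption for any particular real test.

## Numerical choices and degenerate inputs

* Log-gamma is used for $\log(y!)$; likelihoods and marginals are
  evaluated with log-sum-exp, so counts up to $10^6$ and linear
  predictors up to $|b + a\theta| \approx 50$ stay finite. Linear
  predictors beyond 500 short-circuit to a rejected state inside the
  sampler.
* Quadrature weights are renormalized to sum exactly to 1 and nodes
  symmetrized against rounding.
* A single-item 2PPCM under variance standardization is weakly
  identified; the fit proceeds with a warning rather than refusing.
* Scores of 0 are legal everywhere (Poisson support), even though
  typical fluency data start at 1.
* Missing responses are represented by absent records, never
  sentinels; every downstream sum runs over observed pairs.
* Ties in the smallest-predictive-interval search resolve to the
  lowest interval, making reports deterministic given the seed.

## Known limitations

Only the Poisson response distribution and exponential inverse link are
implemented — no Conway–Maxwell–Poisson or negative-binomial variants
for non-equidispersed data, no logistic-ceiling links, no bifactor or
testlet structure for local dependence, no differential item
functioning machinery, and no bridge-sampling Bayes factors. The HMC
implementation is a static-trajectory sampler, not a full NUTS; it is
validated against closed-form prior moments and parameter recovery in
the test suite, and its diagnostics (R-hat, ESS, divergences) are the
guardrails a user should actually read before trusting a fit.
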