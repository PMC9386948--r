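---
title: "Calibrating outdoor mosquito traps against the human landing catch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating outdoor mosquito traps against the human landing catch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trapcal)
```

## The calibration problem

The human landing catch (HLC) — volunteers collecting the mosquitoes that
attempt to bite them — is the reference measure of the human-biting rate,
but it is ethically and logistically fraught. Exposure-free alternatives
(Suna trap, BG-Sentinel, Ifakara Tent Trap C, Mosquito Magnet-X, M-Trap,
M-Trap with a CDC light) catch different numbers of mosquitoes with
different efficiencies, and their efficiency may itself change with
mosquito density. A trap is useful for surveillance not when it catches
*many* mosquitoes but when its catches can be *converted* into
HLC-equivalents with quantified uncertainty. `trapcal` provides that
conversion machinery: model fitting, model comparison, and lookup-table
generation, per trap and per taxon (*Anopheles arabiensis*,
*Anopheles funestus*, *Culex* spp., or anything else recorded in the data).

## The observation model

For night $i$, let $N_i$ be the HLC count of the focal taxon and $n_i$ the
count in the alternative trap. Nightly counts are overdispersed, so the
likelihood is negative binomial, written as a Gamma-Poisson mixture:

$$N_i \sim \mathrm{Poisson}(\theta_i \lambda_i), \qquad
  \theta_i \sim \mathrm{Gamma}(\tau \lambda_i,\, \tau \lambda_i),$$

whose marginal has mean $\lambda_i$ and variance
$\lambda_i (1 + 1/\tau)$: $\tau$ is a dispersion parameter, with the
Poisson recovered as $\tau \to \infty$. Marginally this is a negative
binomial with size $\tau\lambda_i$ and success probability
$\tau/(\tau+1)$, which is how `negbin_logpmf()` evaluates it.

Three structural assumptions shape the mean model: the relationship passes
through the origin (no trap catch on a night with no biting activity), it
is positive, and its slope may change with mosquito density. Four nested
forms encode this (`model_spec()`), with $m_i$ the pooled count of all
*other* taxa in the same trap-night and $s_{k,i}$ its per-taxon
components:

| Model | linear predictor (log scale, default) | density dependence |
|-------|----------------------------------------|--------------------|
| 1 | $\beta_1 \log n_i$ | none |
| 2 | $\beta_1 \log n_i + \beta_2 (\log n_i)^2$ | intraspecific |
| 3 | $\beta_1 \log n_i + \beta_2 \log n_i \log(1+m_i)$ | interspecific, pooled |
| 4 | $\beta_1 \log n_i + \sum_k \beta_k \log n_i \log(1+s_{k,i})$ | interspecific, per taxon |

### Why covariates enter on the log scale

The four structures are often written with $n_i$ itself in the linear
predictor ($\log \lambda_i = \beta_1 n_i$, and so on). Taken literally
that form contradicts the origin assumption — it gives $\lambda = 1$ at
$n = 0$ — and implies exponential growth of HLC-equivalents in the trap
count, which is inconsistent with every published conversion table we are
aware of for these traps: those tables are reproduced, to within rounding,
by the zero-intercept power law $\lambda = n^{\beta_1}$, i.e. by putting
$\log n$ in the predictor. `trapcal` therefore defaults to
`scale = "log"`, with $\lambda = 0$ pinned at $n = 0$, and retains
`scale = "raw"` for the literal form. Interaction covariates enter as
$\log(1+\cdot)$ so that zero counts of other taxa are admissible; $n$
itself uses $\log n$ with the $\lambda(0) = 0$ convention.

Under the log scale a night with $n = 0$ but $N > 0$ has zero likelihood.
Such nights carry no usable information about the slope parameters under
the origin constraint, so they are excluded from the likelihood with a
logged count (`sample_posterior()` reports how many). No imputation is
attempted for nights where a trap did not operate; `build_catch_table()`
drops them, again with a logged count, because any imputation rule would
be an invention the data cannot check.

## Priors and sampling

Every slope has a gamma(0.1, 0.1) prior: positive support enforces the
positive-relationship assumption, and the small shape keeps the prior
diffuse. The dispersion $\tau$ has a gamma(0.01, 0.01) prior, a standard
diffuse choice on a positive parameter. Both are `prior_spec()` defaults.

`sample_posterior()` is a self-contained adaptive Metropolis-within-Gibbs
sampler on the log-parameter scale (positivity holds by construction; the
Jacobian is part of the target). Proposal standard deviations adapt in
batches of 50 iterations toward an acceptance rate of 0.44 — the standard
optimum for univariate random-walk updates — during the first half of
each chain, which is discarded as burn-in; adaptation then stops, so the
retained draws come from a fixed transition kernel. Defaults are 30,000
iterations and 2 chains. Convergence is monitored with the split-chain
Gelman-Rubin statistic (`rhat()`); values below about 1.05 on the default
settings are typical for these low-dimensional posteriors. All randomness
flows from a single integer seed, and identical seeds reproduce draws
bit-for-bit, which the test suite checks.

## Model comparison and fit summaries

`compute_dic()` implements the deviance information criterion with the
deviance evaluated at the posterior *mean* of the parameters on the
natural scale (matching the use of posterior means throughout), and
`compare_models()` reports, per model: DIC, $\Delta$DIC relative to the
best model in the set (ties broken toward the simpler model and flagged),
a pseudo-$R^2$, and a held-out RMSE. The pseudo-$R^2$ is defined here as
$100 \times$ the squared Pearson correlation between observed counts and
posterior-mean fitted values — a definition chosen because it is simple,
bounded and scale-free; it is recorded in output metadata so alternative
definitions can be compared. The RMSE comes from a seeded uniform 75/25
train/test split by night, with no stratification by village or season,
and uses posterior-mean $\hat\lambda$ on the test nights (under the
mixture, the posterior-predictive mean coincides with the posterior mean
of $\lambda$, so the convention is innocuous).

## Prediction and lookup tables

`predict_hlc()` propagates full posterior uncertainty: $\lambda(n)$ is
evaluated per draw and summarised by its mean and equal-tailed 2.5/97.5
percentiles. Two intervals are available. The displayed default is the
credible interval for the *expected* catch $\lambda$; published
conversion tables of this kind print intervals far too narrow to be
posterior-predictive intervals for a single night's count, so the
$\lambda$-interval is the faithful reading. Predictive intervals for a
new night (adding the negative binomial observation noise per draw) are
available with `interval = "predictive"`. Because the power law is convex
in $\beta_1$ for $n > 1$, the posterior-mean prediction is at least the
plug-in prediction at the posterior means (Jensen's inequality); the test
suite asserts this ordering.

`make_lookup_table()` tabulates predictions on a grid (10, 20, ..., 100
by default), rounding the displayed cells to integers while retaining the
unrounded values in an attribute. For Models 3-4 a conversion table needs
reference values for the other-taxa covariates; the `hlc_fit` methods
default these to their sample medians, and the choice is recorded in the
table's attributes.

`fit_published_curve()` closes the validation loop: given the
(collected, expected-HLC) pairs of a published Model-1 conversion table,
it estimates the power-law exponent by zero-intercept least squares on
the log-log scale, $\hat\beta_1 = \sum \log n_i \log N_i / \sum (\log
n_i)^2$. Fitting the bundled reference columns for collected counts
10..90 and predicting at 100 reproduces the published headline
conversions (e.g. 194 HLC-equivalents for 100 *An. arabiensis* from a
Suna trap) to within a few percent — `scripts/acceptance.R` recomputes
these.

## The synthetic-data generator

The field data behind the bundled conversion table are not public, so the
generator (`sim_config()`, `simulate_dataset()`) creates datasets with
exactly the statistical structure the models assume: trap counts $n$ and
other-taxa counts $s_k$ drawn from negative binomial marginals (field
counts are overdispersed for all these taxa), and the response drawn from
the Gamma-Poisson mixture at the model-implied $\lambda$. Defaults are a
desk-scale field season: 250 trap-nights (a year-long six-village
rotation yields about 252), mean nightly catch 20 (a typical
*An. arabiensis* HLC average in high-transmission settings), negative
binomial size 1 (strong overdispersion), and a mildly superlinear truth
$\beta_1 = 1.2$, $\tau = 2$. The real data's dispersions are unpublished;
these defaults are conventions and are labelled as such.

What the generator does *not* emulate: seasonal and spatial structure,
hourly biting profiles, trap-position (Latin square) effects,
environmental covariates, and species misidentification. Passing
recovery tests on synthetic data therefore demonstrates that the
estimation machinery is correct under the model's own assumptions — not
that the model is adequate for any particular field dataset.

`recovery_experiment()` runs the simulate-fit-check loop: at the default
design (50 replicates of 250 nights), the 95% interval for $\beta_1$
covers the truth at close to nominal rate and the posterior-mean bias is
small relative to the parameter. The test suite runs this at full
sampler settings; other tests use shorter chains, which is ample for
these two- to four-parameter posteriors.

## Numerical choices and edge cases

* `negbin_logpmf()` handles $\lambda = 0$ as a point mass at zero
  (log-probability 0 for $N = 0$, $-\infty$ otherwise) rather than
  passing a zero size to the negative binomial.
* Proposals that overflow $\lambda$ to non-finite values are rejected by
  treating the target as $-\infty$, keeping the chain on valid states.
* An empty catch table is legal for `log_posterior()` (the prior alone);
  fitting requires at least one usable night.
* DIC identities (`dic = mean_deviance + p_d`,
  `p_d = mean_deviance - deviance_at_mean`) hold exactly by
  construction, and a degenerate (zero-spread) posterior gives
  `p_d = 0`.
* Ties in $\Delta$DIC are broken toward the lowest model id and flagged
  in a message.
* Display rounding in lookup tables is to the nearest integer; all
  downstream computation uses the unrounded values.

## Known limitations

The sampler is a random-walk scheme: adequate for these small
posteriors, but slow-mixing ones (e.g. strongly correlated slopes in
Model 4 with many taxa) may need more iterations. Model 3's pooled count
$m$ follows the "all other species" reading; if a user wants only
non-focal *Anopheles*, that is a choice of `other_taxa` when building
the table. No zero-inflated or hurdle variants are provided, and no
environmental covariates: the framework deliberately stays within the
four nested structures it exists to compare.
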