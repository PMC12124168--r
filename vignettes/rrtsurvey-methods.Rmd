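---
title: "Methods: masked-survey inference for sensitive wildlife use"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: masked-survey inference for sensitive wildlife use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Household surveys of illegal wild-meat use cannot ask directly: respondents
underreport. The unrelated-question randomized-response design masks each
answer with a physical randomizer — a domino drawn from a bag of six, four
of which select the sensitive question — so the interviewer observes a
binary "yes/no" and an ordinal quantity category without knowing which
question was answered. The statistical cost is that every cell-level
quantity must be inferred through the mixture

\[ P(y=1) = p_s\,\pi_s + (1-p_s)\,\pi_{ns}, \qquad p_s = 4/6 , \]

where \(\pi_s\) is the sensitive prevalence of interest and \(\pi_{ns}\)
the prevalence of the innocuous unrelated item. `rrtsurvey` implements the
full inferential chain for a stratified two-municipality design (rural,
peri-urban, urban strata in a large city and a small town; 782 households;
two seasons; six item domains = {chelonians, mammals & birds} ×
{consumption, barter, trade}) together with a synthetic-data generator that
stands in for the undeposited field data.

## Prevalence model

Within one municipality × urbanization × item-domain × season cell the
masked responses are i.i.d. Bernoulli with the mixture mean above. We place
a conjugate Beta(1, 1) prior on \(\pi_s\) and run a data-augmentation Gibbs
sampler: the latent question assignment \(z_i\) given \(y_i\) is Bernoulli,
and given \(z\), \(\pi_s\) has a Beta full conditional. Since
\(P(z_i = \text{sensitive} \mid y_i)\) takes only two values (one per value
of \(y_i\)), the augmentation collapses to two binomial draws per sweep —
the sampler costs O(1) per iteration, which is why the package can afford
honest calibration experiments (hundreds of replicate fits) inside the test
suite.

Default MCMC settings mirror the field study's reported run: 50,000
burn-in iterations discarded, 25,000 retained samples; two chains;
convergence monitored by rank-normalized split-\(\hat R\) (threshold 1.01,
warn above) and bulk effective sample size, both implemented in-package.
Intervals are equal-tailed 95% (2.5th/97.5th percentiles), matching the
symmetric "x% [95% CI a–b]" reporting style; HPD intervals were not used.

**Identifiability.** A single-sample unrelated-question design cannot
separate \(\pi_s\) from \(\pi_{ns}\) with binary data alone: the likelihood
depends on them only through the mixture mean, so the joint posterior has a
ridge. The package therefore defaults to *known-\(\pi_{ns}\)* mode —
\(\pi_{ns}\) is a design quantity taken from the generator config — and the
`beta_prior` mode (both parameters estimated) emits a documented warning.
The grid oracle exhibits the ridge explicitly, and a test asserts that the
marginal posterior spread inflates in this mode.

**Verification oracle.** `grid_posterior_oracle()` evaluates the exact
marginal likelihood on a uniform grid (2,000 points by default; resolution
floor 50) and normalizes. It shares no code with the sampler — no latent
variables, no MCMC — and the acceptance suite requires the Gibbs posterior
mean to sit within 0.01 of the oracle mean (endpoints within 0.02) on
twenty random small cells.

**Method of moments.** \(\hat\pi_s = (\hat p_{obs} - (1-p_s)\pi_{ns})/p_s\)
is provided as a closed-form cross-check; estimates outside \([0,1]\) are
expected at small n, so they are clipped and flagged rather than raised as
errors.

## Quantity model

The quantity used per month (kilograms for mammals and birds, individuals
for chelonians) is recorded as an ordinal category: 0 = none, then K = 4
ordered bins. The published bin edges live in an unavailable appendix, so
the edges are configuration, not code. The estimator is a proportional-odds
(cumulative-logit) regression under the same masking: the latent branch
assignment is re-drawn each sweep from its conditional Bernoulli (the
sensitive branch evaluates the observed category under the current
cutpoints and coefficients; the unrelated branch under its known category
distribution), and \(\beta\), \(\kappa\) are updated by random-walk
Metropolis on the sensitive-branch likelihood. Cutpoints are parameterized
as \(\kappa_1, \log(\kappa_j - \kappa_{j-1})\), so every proposable state
is strictly ordered — non-monotone states are unrepresentable rather than
rejected after the fact. Proposal scales adapt toward 44% acceptance during
burn-in only, preserving detailed balance afterwards.

Priors are weakly informative: Normal(0, 2.5²) on coefficients, Normal(0,
5²) on the transformed cutpoints. Dummy codings follow the study's variable
table exactly (Manaus = 1, multisited = 1, rural = 1 and peri-urban = 1
against the urban reference, dry season = 1); continuous covariates are
standardized to unit sample SD and reported "per 1 SD (= s original
units)", with the scale record retaining s. Households that did not use the
item contribute through category 0; there is no hurdle component.

At \(p_s = 1\) the model must collapse to an ordinary proportional-odds
fit, and a test ties the posterior mean to `MASS::polr` within two
posterior SDs — the Bayesian/frequentist bridge that anchors the sampler.
Whether the original analysis was Bayesian or frequentist is not stated in
the source; we chose Bayesian for coherence with the prevalence model, with
this reduction property as the guard.

## Covariate GLMs

Visit frequencies (urban-market visits by rural/peri-urban households;
rural visits by urban households, wet season as the study specifies) are
modelled as NB2 negative binomial regressions via maximum likelihood with
estimated dispersion, reported as incidence rate ratios with Wald 95%
intervals. Household management (dual vs single adult) and the
dependency-exceedance flag are logistic regressions reported as odds
ratios. Wald rather than profile intervals: standard, fast, and symmetric
on the log scale like the published intervals. Complete separation is an
error naming the covariate; a separation-like blow-up in the NB fit is a
warning. The dependency *ratio* (minors over working adults, missing when
no adult works) and the *exceedance flag* (more minors than all adults) are
computed from the raw counts independently of each other.

## The synthetic world

The generator is a stated world, not a tuning dial. Its defaults are fixed
once:

* **Design**: the exact published strata — Manaus 120/90/299 and Carauari
  73/41/159 (rural/peri-urban/urban), 782 households; domino randomizer
  4-of-6; two seasons; six item domains.
* **Sensitive prevalences**: every dry-season cell estimate printed in the
  source is used verbatim (e.g. urban consumption of mammals and birds 22%
  in Manaus vs 57% in Carauari; peri-urban chelonian barter 79% in the
  small town, 13% in the large city); the unprinted cells were filled once
  with values respecting the printed ordering (rural ≥ peri-urban ≥ urban;
  consumption higher in the small town). Wet season = 0.9 × dry: use was
  reported somewhat higher in the dry season but not significantly so.
* **Unrelated items**: prevalence 0.5 — common legal goods, chosen as the
  neutral midpoint that maximizes randomizer protection; category
  distribution (0.4, 0.3, 0.2, 0.1) over the four non-zero bins.
* **Covariates** (the source reports effects, not distributions): residence
  status Bernoulli per stratum calibrated to 19% multisited overall;
  management from a logistic model using the published ORs (0.41 Manaus,
  1.60 rural, 3.25 peri-urban on a 0.60 small-town-urban base); minors
  Poisson(1.3) over 1 + Poisson(1.0) working adults; visit counts negative
  binomial with the published IRRs (1.30 Manaus and 3.02 peri-urban for
  urban visits; 0.24 Manaus and 4.78 multisited for rural visits) and base
  means/dispersions chosen so the marginal SDs approximate the published
  1-SD equivalents (21.76 urban visits, 6.56 rural visits per season; the
  calibrated defaults reproduce ≈21 and ≈6.6).
* **Quantity generator**: given use, a category 1..4 from an
  ordered-logistic model whose coefficients are the published
  consumption-model ORs on the log scale and whose cutpoints are (−1, 0.5,
  2) for both taxon groups.

One response row per household × item domain × season: the source is
ambiguous about within-sitting repetition, and the household-level
Bernoulli statement matches this convention. The truth file (retaining the
latent assignment `z` and latent use) and the analysis file are split at
write time — an estimator cannot peek even by accident, and the reader
refuses latent columns in analysis-facing files.

What the generator does **not** emulate: interviewer effects, refusals and
item non-response, spatial coordinates, within-household correlation across
item domains beyond shared covariates, and any difference between "working
adults" and "all adults" (the pipeline's dependency model uses working
adults for both measures for that reason). A green acceptance suite
therefore establishes that the estimators are correct and calibrated *under
the stated design*, not that the published field estimates are reproduced —
they cannot be, because the raw data were never deposited.

The estimator's quantity model deliberately differs from the generator's
two-stage story (Bernoulli use, then a category among users): the estimator
treats category 0 as the lowest level of one proportional-odds scale. The
recovery tests for the quantity model therefore simulate from the
proportional-odds model itself; the end-to-end pipeline exercises the
mismatched (hurdle-like) generator, where the quantity coefficients are
summaries of a misspecified fit — expected, and documented here rather
than hidden.

## Numerical choices

* Per-cell and per-chain seeds derive from the master seed by a stable FNV
  string hash of the cell/chain key: runs are reproducible cell-by-cell and
  independent of execution order; all derived seeds stay below 2³¹.
* Grid normalization is exact by construction (mass renormalized after
  exponentiating shifted log densities); the normalization test tolerance
  is 10⁻¹².
* Beta full conditionals guard against 0/0 in the assignment probabilities
  with an additive 10⁻³⁰⁰.
* Degenerate inputs: constant posterior draws yield point summaries with
  `NA` diagnostics; a single chain yields `NA` \(\hat R\) (marked
  unavailable, never fabricated); empty cells are skipped with a warning.
* MoM clipping is flagged, not fatal; a `p_s = 0` design is an error (the
  data carry no information about the sensitive item).
* Text reports round prevalences to whole percent, matching the published
  style; CSVs keep full precision.

## Known limitations

Known-\(\pi_{ns}\) mode is an assumption, not a luxury: if the configured
\(\pi_{ns}\) is wrong by δ, the prevalence estimate is biased by
\(-(1-p_s)\delta/p_s\) (−δ/2 at the default design). Hierarchical pooling
across strata, model comparison (WAIC/LOO), random effects in the GLMs,
zero inflation, and reproduction of the published point estimates are out
of scope. The MCMC defaults (50k/25k) are far beyond what the O(1) sampler
needs for these cell sizes; tests and the acceptance script use smaller,
stated settings to stay within their time budgets.
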