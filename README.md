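# rrtsurvey

Estimation of the prevalence and quantity of a sensitive — here, illegal —
behaviour from **unrelated-question randomized-response** household surveys,
built around a two-municipality, rural / peri-urban / urban study of wild-meat
consumption, barter and commercial trade in the Brazilian Amazon.

Because wildlife use is illegal in Brazil, direct questions underreport it.
In the unrelated-question design each respondent draws a domino from a bag of
6; 4 dominoes route them to the sensitive question ("did your household use
wild meat … ?") and 2 to an innocuous one about legal goods. The interviewer
never sees the draw, so an individual "yes" is uninformative; only the
aggregate mixture identifies the sensitive prevalence.

## The model

With sensitive-question probability `p_s = 4/6`, sensitive prevalence `π_s`
and unrelated-item prevalence `π_ns`, an observed answer is

    P(y = 1) = p_s · π_s + (1 − p_s) · π_ns

`rrtsurvey` provides, per municipality × urbanization × item-domain × season
cell:

* a **method-of-moments** inversion `π̂_s = (p̂_obs − (1 − p_s) π_ns) / p_s`
  (clipped to `[0, 1]` and flagged when clipped);
* a **data-augmentation Gibbs sampler**: the latent question assignment
  `z_i | y_i` is Bernoulli, and `π_s | z` has a conjugate Beta full
  conditional — because `P(z_i | y_i)` depends only on the binary `y_i`, the
  sweep reduces to two binomial draws and is O(1) per iteration;
* an **exact grid-posterior oracle** (no MCMC, no latent variables) used to
  verify the sampler;
* a masked **proportional-odds model** for the quantity used (ordered
  categories of kg or units per month) with adaptive Metropolis-within-Gibbs
  updates and per-1-SD odds ratios;
* **negative binomial** (visit frequency → IRRs) and **logistic** (household
  structure, dependency → ORs) regressions with Wald 95% intervals;
* a fully **seeded synthetic-data generator** for the 782-household design
  (Manaus 120 rural / 90 peri-urban / 299 urban; Carauari 73 / 41 / 159),
  since the original survey data are not deposited;
* a deterministic, config-driven **pipeline** (`generate → estimate →
  report`) with a content-hash manifest.

## Worked example

```r
library(rrtsurvey)

design     <- validate_design(study_design())        # 782 households, p_s = 2/3
params     <- default_true_params(design)
households <- simulate_households(design, params, seed = 2026)
responses  <- simulate_responses(households, params, design, seed = 2027)

sub <- subset(responses$analysis,
              item_domain == "chelonians:trade" & season == "dry" &
              municipality == "manaus" & urbanization == "peri_urban")
mean(sub$use)                                         # 0.467 (masked rate)

mom_estimate(mean(sub$use), p_s = 2/3, pi_ns = 0.5)$estimate   # 0.45

spec <- mixture_model_spec(2/3, "known", pi_ns_value = 0.5)
fit  <- fit_prevalence_gibbs(sub$use, spec, mcmc_config(5000, 10000, 2, seed = 11))
s    <- summarize_posterior(fit$pi_s)
print(s)
#> mean 0.4504  median 0.4500  95% CrI [0.3015, 0.6042]  Rhat 1.000  ESS 9794
format_prevalence(s)
#> "45% [95% CI 30–60]"

grid_posterior_oracle(sub$use, spec)$mean             # 0.4511 (exact oracle)
```

The generator's true prevalence for this cell is 0.44: the masked observed
rate (0.467) is a mixture artifact, the inverted estimate (45% [30–60])
recovers the truth, and the independent grid oracle confirms the sampler to
three decimals. The interval is wide — that is the price of anonymization at
`p_s = 2/3` and n = 90.

## Pipeline

```sh
Rscript inst/cli/rrtsurvey-pipeline.R all --config config.yaml --workdir out
```

with a YAML config holding a mandatory master `seed`, optional design /
parameter overrides, MCMC settings and a model list. Rerunning the same
config reproduces identical artifact hashes (`manifest.json`).

## Limitations

The published point estimates themselves are not reproducible — the raw
survey data were never deposited — so the printed prevalences serve as
generator defaults, not as targets. See `vignettes/rrtsurvey-methods.Rmd`
for the model assumptions, identifiability caveats (known-`π_ns` mode), and
what a green test does and does not establish.
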