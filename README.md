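# saltol

Bayesian models of salinity tolerance across anuran life stages.

Freshwater coastal wetlands are salinizing as sea levels rise, and
amphibians — a salt-sensitive, freshwater order with a complex life cycle —
must cope with that stress at every ontogenetic stage. `saltol` implements
the full inference chain for quantifying that sensitivity and asking whether
chronically salt-exposed populations respond differently from salt-naive
ones:

1. **Dose–response meta-analysis.** Published survivorship proportions
   (one record per study × salinity, per life stage: egg, tadpole, adult)
   are modelled with a Bayesian beta regression in the mean–precision
   parameterization,

   `y_ij ~ Beta(mu_ij * phi, (1 - mu_ij) * phi)`,
   `logit(mu_ij) = beta0 + beta1 * salinity_ij + u_j`,
   `u_j ~ Normal(0, sigma_u^2)`,

   with survivorship and salinity as fixed effects and study as a random
   effect. The posterior yields the LC50 (`-beta0 / beta1`, the salinity
   imposing 50% mortality) and survival curves with 95% credible envelopes.
2. **Common-garden hurdle models.** Oviposition site choice and egg
   hatching from a binary freshwater-vs-saltwater cup design are analysed
   in two stages — a Bernoulli model for whether any eggs were laid (or
   hatched) and a conditional binomial model for the proportion — with
   salinity × source population (coastal vs inland) fixed effects and
   bin-within-location random intercepts. Hatching models take informed
   priors moment-matched to the egg-stage meta posterior.
3. **Ramped tadpole survival.** Daily counts of 50-tadpole groups
   acclimated toward a target salinity over six days follow the
   conditional chain `alive_t ~ Binomial(alive_{t-1}, p_t)` with a
   logit-linear daily survival model (salinity, population, day, clutch
   random effect) and informed priors from the tadpole-stage meta
   posterior; end-of-ramp survival is the product of the daily
   probabilities.

The original raw data (the meta-analysis supplement and the garden trial
tables) were never deposited, so the package ships first-class synthetic
generators (`simulate_meta_dataset()`, `simulate_oviposition()`,
`simulate_tadpoles()`) that emulate all three layers with known ground
truth; every fitting stage is validated by parameter recovery against
them. The package is aimed at ecotoxicologists and amphibian ecologists
who want reproducible LC50 syntheses or a template for propagating a
meta-analytic posterior into experimental analyses.

MCMC runs on JAGS via `rjags` (pre-installed alongside R); convergence is
gated on the Gelman–Rubin statistic (all parameters R̂ < 1.1).

## Worked example

```r
library(saltol)

records <- simulate_meta_dataset(meta_truth("egg"), seed = 1)
fit <- fit_beta_meta(records, stage = "egg")   # 3 chains x 5000, burn 2500
fit
#> Beta-regression meta-analysis (egg stage)
#> 144 observations from 18 studies; converged (max R-hat 1.006)
#>   beta0   beta1 sigma_u     phi
#>  1.2423 -0.2639  0.4739 21.2010

lc50(fit)
#> LC50 [egg]: 4.70 ppt (95% BCI 3.84-5.64)

predict(fit, salinity = c(3.9, 8.3, 11))
#>   salinity      mean        lo        hi
#> 1      3.9 0.5528960 0.4960088 0.6123725
#> 2      8.3 0.2800047 0.2331773 0.3330062
#> 3     11.0 0.1605506 0.1275256 0.1990349
```

The egg-stage generator defaults encode a dose–response whose LC50 is
4.15 ppt; the fit recovers 4.70 ppt (the truth well inside the credible
interval) from one simulated 18-study literature, and the predicted
survivorship at the field salinities (0.55 at 3.9 ppt, 0.28 at 8.3 ppt)
declines as the salinity rises past the LC50.

Downstream, `run_pipeline(run_config(...))` chains everything: meta fits →
LC50/survival tables → informed priors → garden and tadpole fits, writing
CSV outputs and a seed/convergence log. A command-line wrapper with
`simulate`, `meta-fit`, `garden-fit`, `tadpole-fit`, and `report`
subcommands is installed at `inst/cli/saltol.R`.

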