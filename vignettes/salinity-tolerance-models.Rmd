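---
title: "Models of anuran salinity tolerance: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models of anuran salinity tolerance: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`saltol` implements a three-part Bayesian inference chain: a dose–response
meta-analysis of anuran survivorship against salinity for each life stage,
LC50 and survival-curve derivation from its posterior, and common-garden
models (oviposition choice, egg hatching, ramped tadpole survival) whose
priors are propagated from the meta-analysis. This vignette explains each
model, the tunable parameters and their defaults, the numerical choices,
and what the synthetic-data generators do and do not emulate.

## The meta-analysis model

Each record is one study × salinity observation: a proportion surviving
after exposure. Proportions extracted from heterogeneous publications
rarely come with the sample sizes needed to reconstruct counts, so the
observation model is a beta distribution in the mean–precision
parameterization,

$$y_{ij} \sim \mathrm{Beta}(\mu_{ij}\phi,\ (1-\mu_{ij})\phi), \qquad
  \mathrm{logit}(\mu_{ij}) = \beta_0 + \beta_1 s_{ij} + u_j,$$

with salinity $s$ in parts per thousand (ppt), a random intercept
$u_j \sim N(0, \sigma_u^2)$ per study, and a common precision $\phi$.
Fixed effects get diffuse Gaussian priors with mean 0 and **precision**
0.001 (variance 1000). Sampler conventions in the BUGS/JAGS family state
Gaussians by precision; a literal standard deviation of 0.001 would pin
every coefficient at zero, so the package reads the conventional diffuse
prior and exposes both moments through `gaussian_prior()` for anyone who
wants otherwise. The remaining priors are weakly informative defaults:
$\sigma_u \sim U(0, 10)$ and $\phi \sim \mathrm{Gamma}(0.01, 0.01)$.

**Boundary proportions.** The beta support is the open interval, but real
records contain exact 0s and 1s. `compress_proportions()` applies the
standard compression $(y(n-1)+0.5)/n$. Inside `fit_beta_meta()` it is
applied *only* to boundary values: compressing every observation shrinks
the whole sample toward 0.5 and measurably attenuates the slope (about
15–20% at $\phi = 20$, $n = 30$ in recovery simulations), which would
violate the package's own recovery contract. Boundary records lacking a
sample size use $n = 10$, flagged with a message — a deliberately small
default so that an undocumented sample size never manufactures precision.

**Derived quantities.** For a typical study ($u = 0$), survival crosses
50% at $-\beta_0/\beta_1$; `lc50()` transforms each posterior draw,
excludes (and counts) draws with $\beta_1 \ge 0$, truncates negative
crossings to 0 ppt, and reports the posterior median with the central 95%
interval. If more than half the draws have a nonnegative slope the
estimate is refused — survival is not credibly decreasing, and a number
would be meaningless. Predictions (`predict()`, `survival_table()`) are
conditional on the typical study rather than marginalized over
$\sigma_u$: that matches clade-level survival-curve summaries and keeps
the LC50 closed-form per draw.

## Common-garden models

All garden models share a logit-linear predictor with inland (salt-naive)
as the reference population:

$$\mathrm{logit}(p) = \gamma_0 + \gamma_s s + \gamma_L \mathbb{1}[\text{coastal}]
  + \gamma_{sL}\, s\, \mathbb{1}[\text{coastal}] + b_{\text{group}},$$

with $b \sim N(0, \sigma_b^2)$ for bin-within-location (or clutch).
Unlike the meta-analysis, the garden models use weakly informative fixed-
effect priors — Normal(0, sd 5) for intercept and salinity slope,
Normal(0, sd 2.5) for the location, interaction, and day terms. The
source analysis's garden prior is ambiguously described, and the choice
matters here: cup-level binary outcomes separate completely at realistic
design sizes (every coastal cup hatches, say), and under a variance-1000
prior a separated coefficient performs an endless random walk over
implausible values instead of mixing. On the logit scale sd 2.5–5 still
covers any credible effect. The
two-stage (hurdle) decomposition asks distinct questions: the Bernoulli
stage models whether the event occurred at all (any eggs in a cup, any
hatchlings), the binomial stage the magnitude given occurrence. The
analysis unit for the Bernoulli stages is the cup; the investment stage is
bin-level (eggs in the three freshwater cups out of all eggs in the bin,
covariate = the bin's nominal salt treatment). Cups with zero eggs laid or
hatched are excluded from the conditional stages, which is exactly the
hurdle's conditioning.

The ramped tadpole model is a conditional chain on the daily counts,
$\text{alive}_t \sim \mathrm{Binomial}(\text{alive}_{t-1}, p_t)$, with the
daily survival logit linear in the day's ramp salinity, population, their
interaction, and the day index (the functional form for time was an open
choice; linear is the simplest monotone option), plus a clutch random
intercept. Six-day survival is $\prod_t p_t$. Days starting from an empty
group are dropped: they carry no likelihood information, and keeping the
chain defined when a clutch dies out matters more than the bookkeeping.

**Acclimation ramp.** Targets 4/6/8/12 ppt rise by 0.67/1/1.33/2 ppt per
day; the freshwater control stays at 0.5 ppt. Day-$t$ salinity is $t$
times the increment — the first raise happens on day 1 after an overnight
freshwater acclimation — so the day-6 salinity equals the target within
0.02 ppt (the 0.67 and 1.33 increments are rounded).

## Informed-prior propagation

The chain's connective tissue: `build_informed_prior()` moment-matches a
Gaussian to the posterior marginal of an upstream coefficient (mean =
sample mean, sd = inflation × sample sd, floored at 0.01). In the
pipeline, the egg-stage meta posterior informs the hatching models and the
tadpole-stage posterior informs the tadpole model, on the intercept and
salinity slope only — the meta-analysis contains no population contrast,
so location terms keep diffuse priors.

The pipeline's default inflation is 10, and this is a considered choice.
A synthesis across dozens of studies yields slope posteriors with sd on
the order of 0.01; moment-matching at inflation 1 would make the
downstream prior essentially dogmatic, overriding the trial data rather
than informing them. The mismatch is structural, not incidental: the meta
coefficients describe whole-exposure survival while the tadpole model
describes *daily* survival, so the two scales cannot be equated. In fits
under an uninflated prior the conflict surfaces numerically — the model
reroutes the disagreement through location and random effects and mixing
degrades badly. Inflating the sd tenfold keeps the literature's location
while granting the experiment roughly one percent of the literature's
precision; `run_config(inflation = )` exposes the dial, and
`build_informed_prior()` itself defaults to inflation 1 so the primitive
stays neutral.

## MCMC contract and numerics

Chain settings follow the reported practice: 3 chains × 5000 iterations
with 2500 burn-in for the meta and garden models, 4 × 50000 with 25000
burn-in for the tadpole model (`mcmc_config()`). Starting values vary by
an order of magnitude across chains (`spread_init()`), per-chain RNG seeds
derive deterministically from one global seed, and every fit computes the
Gelman–Rubin statistic
$\hat R = \sqrt{((n-1)/n\,W + B/n)/W}$ per parameter; a fit with any
$\hat R \ge 1.1$ is flagged, warns, and (in the pipeline) blocks
downstream informed-prior stages unless explicitly overridden.

Two numerical choices matter:

* **Hierarchical centering.** When every covariate is constant within a
  random-effect group — the bin-level investment response — fixed effects
  in the non-centered parameterization are identified only through the
  random-effect prior and mix pathologically (R̂ ≈ 1.4 after 10,000
  iterations). `fit_binomial_stage()` detects this design and fits the
  hierarchically centered form, an identical joint model whose chains
  converge in seconds (R̂ ≈ 1.00). The JAGS `glm` block-sampling module
  was evaluated as an alternative and rejected: it repaired that fit but
  destabilized boundary-heavy Bernoulli and tadpole fits.
* **Degenerate inputs.** Saturated outcomes (all cups laid, no deaths)
  produce boundary warnings but still fit; a single-study meta-analysis
  warns that the study effect is confounded with the intercept;
  `lc50()` truncates at 0 ppt and refuses non-decreasing posteriors.

## The synthetic generators

The generators exist because neither the meta-analysis supplement nor the
raw trial tables were deposited. They simulate from exactly the processes
the models assume, with known coefficients, so fits against them are
parameter-recovery experiments.

* `simulate_meta_dataset()` draws per-study intercepts and beta-distributed
  proportions on a per-stage salinity grid. The per-stage defaults were
  calibrated once, by least squares against the published stage-specific
  dose–response scale (LC50s of 4.15/5.5/9.0 ppt and the survivorship
  reported at 3.9–23.4 ppt), with study counts reflecting the literature's
  stage coverage — 18 egg and 24 tadpole studies, but only 3 adult studies
  with high between-study spread ($\sigma_u = 0.7$). That last choice has
  teeth: a 3-study random-effects meta-analysis genuinely cannot pin an
  LC50 — across generator seeds the adult point estimate wanders several
  ppt around the generating value of 9 (which the 95% interval always
  covered in our checks) — so adult-stage reproduction tests fail at
  tolerances that egg and tadpole comfortably meet. This is reported as a
  finding about the design, not patched by quieter defaults.
* `simulate_oviposition()` reproduces the binary-choice design (per
  location and replicate, one bin per treatment in 4/6/8/12 ppt, three
  freshwater + three salt cups): clutch size from a rounded log-normal
  (mean 1363 eggs, consistent with the reported 713–3039 range), a
  bin-level freshwater/salt split from the investment model, cup-level
  occupancy from the choice model (a side's eggs are withheld when no cup
  on that side is chosen — the hurdle), and per-cup hatches from the hatch
  model.
* `simulate_tadpoles()` runs the binomial death chain on the ramp
  schedule, 8 clutches per location, 5 targets, 50 tadpoles each.

Garden coefficient defaults are set so the emulation qualitatively matches
the reported population contrast (coastal frogs avoid salt less, hatch
better in salt, and out-survive inland tadpoles at high salinity); they
are documented defaults, not estimates of the original trials. What the
generators do **not** emulate: figure-digitization error and heteroscedastic
extraction noise, unbalanced salinity grids across studies, species- or
family-level structure (the real heterogeneity is taxonomic, not just
study-level), measured cup salinities drifting from nominal treatments,
and any non-logit-linear dose response. Passing recovery tests therefore
demonstrates that the inference machinery is correct under the stated
model, not that the model is adequate for any particular real dataset.

Seeds fan out from one global integer through a deterministic splitter
(`derive_seed()`), so data simulation and each model's chains can be
reproduced independently; identical configurations yield byte-identical
pipeline outputs, each stamped with a configuration hash.

## Problem sizes used in the checks

The test suite fits models at reduced chain lengths (1500–10000
iterations) chosen so each fit still passes the R̂ gate; the acceptance
script uses the full reported settings for the egg and tadpole
meta-analyses (3 × 5000), longer chains (3 × 30000) for the slow-mixing
3-study adult fit, 3 × 30000 for the garden models (binary outcomes near
separation mix slowly even under proper priors), and 4 × 20000 for the
tadpole chain. Multi-seed recovery checks use 10 generator seeds at the
synthetic defaults (30 studies for the meta recovery; 40 bins per arm for
the hurdle interaction).

## Known limitations

* Exposure duration is recorded but not a covariate; survivorship from a
  24-h and a 96-h exposure at the same salinity are treated alike, as in
  the modelled analysis.
* Predictions condition on the typical study/bin/clutch (random effect 0)
  rather than marginalizing; population-averaged probabilities would be
  slightly attenuated.
* The meta-analysis is not phylogenetically corrected, and replicate
  standard deviations, though ingested, do not enter the likelihood.
* The salinity-unit conversions are fixed linear factors; the
  conductivity factor (0.64 g/L per mS/cm) is a freshwater-range
  approximation that understates salinity above ~10 mS/cm.
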