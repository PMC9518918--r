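---
title: "Model and methods: decision-analytic snakebite burden estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: decision-analytic snakebite burden estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snakeburden)
```

## Purpose and scope

`snakeburden` estimates the annual epidemiological, economic and disease
burden of snakebite for a country (or a region of countries) from a small
set of configurable inputs. It is a *cohort expectation* model: one year's
victim cohort is pushed through a decision tree and every downstream
quantity — deaths, amputations, costs, DALYs — is computed as an expected
value in fractional persons. There is no microsimulation and no time
dynamics; the model describes a single year in steady state.

This vignette documents the model structure, every default parameter and
its rationale, the uncertainty machinery, the synthetic data generator, the
numerical conventions, and the limitations.

## The decision tree

Victims enter at the top and follow one of a finite set of mutually
exclusive paths:

1. **Care seeking.** A fraction `p_conventional_first` goes straight to
   conventional (hospital) care. The complement sees a traditional healer
   first; of those, `p_switch_to_conventional` later switch to conventional
   care, the rest stay with traditional care only.
2. **Envenoming.** Independently of the path, a fraction `p_indicated`
   of victims has systemic envenoming for which antivenom is clinically
   indicated. Victims without indication always survive (they can still
   incur conventional-care costs if they sought it).
3. **Antivenom access.** Indicated victims in conventional care receive
   antivenom subject to supply:
   `access = min(1, antivenom_courses / indicated_in_conventional_care)`,
   defined as 1 when nobody is indicated. Treated victims may experience
   an adverse drug reaction (`p_adr`), which affects costs but not
   survival.
4. **Outcome.** Treated indicated victims die with probability
   `p_death_treated`. Untreated indicated victims — whether for lack of
   supply or because they never reached conventional care — die with
   probability `min(1, rr_death_untreated × p_death_treated)`. Survivors
   of envenoming undergo amputation with probability
   `p_amputation_survivor`.

The tree is evaluated separately for each age/sex stratum of the
demographic profile (stratum shares scale the victim cohort), so
age-dependent quantities such as YLL and premature-death productivity
losses use the stratum's mean age at death.

Two independent implementations are shipped: `run_tree()` computes the
expectations directly, and `enumerate_paths()` exhaustively lists every
leaf with its probability (the probabilities provably sum to 1). The test
suite requires them to agree to relative 1e-9 on thousands of random
parameter sets; `enumerate_paths()` is the oracle, `run_tree()` the fast
path.

```{r tree-demo}
cp <- generate_country(1, "mid", name = "Demo")
out <- run_tree(cp)
out$victims_total - (out$indicated + out$not_indicated)   # conservation
agg <- aggregate_paths(enumerate_paths(cp), country_victims(cp))
agg[["deaths"]] - out$deaths                               # oracle agreement
```

## Parameters and defaults

Every uncertain input is a `param_value(point, low, high, family)`; a bare
number is shorthand for a fixed (degenerate) value. Defaults that the
constructor fills in when a config omits them:

| Parameter | Default | Rationale |
|---|---|---|
| `rr_death_untreated` | 2.33 [1.26, 4.06], lognormal | Relative mortality risk without antivenom versus with; a right-skewed ratio, so lognormal with the interval read as 95% bounds. |
| `discount_rate` | 0.03 [0, 0.06], varied in one-way analysis only | Standard 3% annual discounting of future productivity; the 0–6% band is the conventional sensitivity range. |
| `retirement_age` | 60 | End of the productive-life window for the human-capital approach. |
| `daily_income_divisor` | 365 | Daily productivity is GDP per capita divided by 365 calendar days. |

Everything else — incidence (or victim count), tree probabilities,
antivenom supply, lengths of stay, unit costs, exchange rate, GDP and its
growth rate, and the demographic profile — must come from the country
configuration. Exactly one of `incidence` (per 100,000) and `victims` is
given; the other is derived from the population. Configurations are
validated strictly: unknown keys, out-of-range probabilities, overlapping
age bands or shares that do not sum to 1 are errors, never warnings.

## Costing (societal perspective)

All costs are annual, converted from local currency to USD via the
configured exchange rate.

**Direct medical** — hospitalization (length of stay × cost per bed-day,
summed over every group that received conventional care, with a separate
length of stay for non-envenomed attendees), antivenom (cost per course
plus per-course logistics, for treated victims), adverse-reaction
management, and amputation care.

**Direct non-medical** — transport (per conventional-care episode) and
food for the victim *plus one accompanying relative* over the length of
stay.

**Indirect (human capital)** — two components:

- *Episode loss*: 2 × person-days per conventional episode (victim and the
  accompanying relative, for the length of stay) × daily productivity
  (GDP per capita / 365).
- *Premature death*: for a death at age $a$ with retirement age $R$,
  annual GDP per capita $y$, growth $g$ and discount rate $r$,
  $$\text{loss} = y \sum_{t=0}^{\lfloor R-a\rfloor - 1}
      \left(\frac{1+g}{1+r}\right)^t ,$$
  i.e. whole remaining working years only, the first year undiscounted,
  and zero for deaths at or after retirement age. The closed form
  $y\,(1-k^n)/(1-k)$ with $k=(1+g)/(1+r)$ is used in the tests as an
  independent check, with the $k \to 1$ limit $y\,n$.

```{r discount-demo}
premature_death_loss(30, gdp_per_capita = 2000, growth = 0.02, discount = 0.03)
premature_death_loss(60, 2000, 0.02, 0.03)   # at retirement: zero
```

## DALYs

DALY = YLL + YLD, undiscounted and without age weighting.

- **YLL**: deaths per stratum × residual life expectancy at the stratum's
  mean age at death, linearly interpolated from the bundled life table
  (`inst/extdata/life_table_synthetic.csv`). The table is a *synthetic
  reconstruction* of a standard-population life table (life expectancy
  88.9 years at birth declining to 3.3 at age 100), not observed national
  data; supply your own via `load_life_table()` for real analyses.
- **YLD, episode**: every envenomed victim (indicated), treated or not,
  accrues the acute-episode disability weight (default 0.133) for the
  episode duration (default 0.022 years ≈ 8 days).
- **YLD, amputation**: lifelong — weight (default 0.021) × residual life
  expectancy at the stratum mean age. The bundled disability weights are
  likewise labelled synthetic and replaceable via
  `default_disability_specs(path = ...)`.

Applying the episode YLD to *all* envenomed victims (not only the treated)
was a deliberate choice: the disability is caused by the envenoming, not by
the treatment.

## Uncertainty analysis

**Probabilistic sensitivity analysis.** `run_psa(cp, n = 1000, seed)`
draws every non-fixed parameter independently, re-evaluates the full
pipeline per draw, and summarises each output with its base-case point
value and a percentile credible interval (default 95%, computed with
`stats::quantile()` type 7, R's default). Families are moment-matched to
`point`/`low`/`high` with `sd = (high - low) / (2 × qnorm(0.975))`:

- *beta* for probabilities (mean = point). When the implied variance is
  infeasible for a beta distribution, the sampler falls back to a uniform
  on [low, high] with a warning — never silently.
- *gamma* for positive quantities (same mean/sd matching).
- *lognormal* for relative risks: `meanlog = log(point)`,
  `sdlog = (log(high) - log(low)) / (2 × qnorm(0.975))`, so the point
  value is the *geometric* mean and the low/high bounds map to the
  2.5th/97.5th percentiles exactly.
- *uniform* and *fixed* as stated.

The discount rate is **not** sampled in the PSA by default
(`sample_discount = FALSE`); it is varied only in the one-way analysis.
Discounting is a normative choice rather than a stochastic quantity, so
folding it into the Monte Carlo would blur parameter uncertainty with
methodological preference.

**Regional PSA.** `run_region_psa()` seeds once, draws each country's
parameters sequentially, sums the additive outputs *per draw*, and takes
quantiles of the summed draws. This preserves within-draw correlation of
the regional total with its components; countries are sampled
independently of one another (no shared regional shocks — a limitation,
noted below).

**One-way analysis.** `one_way_sa()` moves each parameter in turn to its
low and high bound with all others at their point values, records both
outputs and the absolute swing, and returns the rows sorted by swing
(tornado order). The region variant moves the parameter in *all* countries
simultaneously. `plot_tornado()` renders the diagram when `ggplot2` is
available.

```{r psa-demo}
psa <- run_psa(fixed <- generate_country(3, "mid"), n = 200, seed = 9)
subset(psa$summary, quantity %in% c("deaths", "dalys", "total_cost"))
```

## PTSD scenario

The base case ignores psychiatric sequelae. With `scenario = TRUE`, a
post-traumatic stress disorder layer is added on top, strictly additively:

- PTSD cases = survivors of envenoming × `p_after_envenoming`
  (default 0.08 [0.02, 0.18], beta) + non-envenomed victims ×
  `p_after_no_envenoming` (default 0.02, fixed).
- YLD adds cases × weight (default 0.158) × duration (default 1 year).
- Indirect costs add cases × duration × 365 days × daily productivity ×
  `productivity_loss_fraction` (default 0.25, i.e. a quarter of work
  capacity lost while symptomatic).

Scenario outputs therefore can never fall below the base case; the test
suite enforces this additivity on hundreds of random parameter sets.

## Synthetic data generator

`generate_country(seed, archetype)` and `generate_region(seed, n)` emit
fully valid country configurations for testing and demonstration. Three
archetypes span the plausible envelope of real settings:

- `high_access_low_incidence`: incidence 5–30 per 100,000, antivenom
  access 0.90–1.
- `mid`: intermediate on both axes.
- `low_access_high_incidence`: incidence 100–250 per 100,000, access
  0.02–0.25.

The generator draws a point value inside the archetype range for each
parameter, then wraps it in an uncertainty interval with a relative
half-width drawn once per country from 10–35%. Antivenom supply is set as
`target_access × base-case indicated victims` and held *fixed*, so the
generated country's base-case access equals its archetype target exactly —
that invariant is what the tests check. Each country gets a four-stratum
demographic profile (sex × child/adult).

What the generator emulates: the orders of magnitude, the correlation of
poor access with high incidence and lower GDP, local-currency unit costs
with an exchange rate, and heterogeneous uncertainty widths. What it does
**not** emulate: real countries, real surveillance data, seasonality,
species mix, subnational variation, or any correlation structure between
parameters within a country. Numbers produced from synthetic
configurations demonstrate the machinery; they are not burden estimates of
any actual place.

The bundled region (`inst/extdata/synthetic_region/`, seven countries) is
`generate_region(7100, 7)` written to YAML; a test asserts the files match
regeneration exactly, and `write_country_config()` guarantees exact numeric
round-trip by emitting 17 significant digits.

## Numerical and design conventions

- Expectations in double precision throughout; no rounding inside the
  model. Rounding happens only in the display tables
  (`write_region_outputs()`: counts to whole persons, costs to thousand
  USD at one decimal), alongside a full-precision CSV.
- Credible intervals use `stats::quantile()` type 7.
- Derived Monte Carlo seeds stay below 2^31.
- Regional report rows sum the additive columns and *recompute* the rates
  (per-100k, % of GDP, shares) from the sums — never averaging rates.
- Degenerate inputs are handled explicitly: zero victims gives zero
  burden, zero rates and undefined (NA) cost shares; zero indicated gives
  access 1; population or GDP ≤ 0 is an error.
- S3 classes and data frames, snake_case API, configuration as plain
  YAML/JSON — the shape of an epidemiological pipeline, deliberately
  lightweight.

## Limitations

- A one-year expectation model: no dynamics, no herd effects of improved
  supply, no queuing — antivenom access is a simple supply/demand ratio.
- Parameters are sampled independently within and across countries; real
  uncertainties (e.g. incidence and case fatality) may be correlated.
- The human-capital approach values lost production only to retirement age
  and ignores informal and household work beyond the GDP-per-capita proxy.
- The bundled life table and disability weights are synthetic
  placeholders; substantive analyses must supply real ones.
- The PTSD scenario uses a reconstructed default parameterisation
  (weight, duration, productivity fraction) and a purely additive
  structure; it does not model treatment of PTSD or its costs.
- Traditional-healer care is assumed to incur no out-of-pocket cost in the
  model; only conventional-care episodes generate direct costs.
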