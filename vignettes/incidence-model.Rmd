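---
title: "Modeling the incidence of state alcohol tax increases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the incidence of state alcohol tax increases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alcotax)
```

## The question and the model

Opponents of alcohol tax increases argue that they punish moderate
("responsible") drinkers and the poor. Because consumption is heavily
right-skewed — excessive drinkers account for most drinks sold — a tax per
drink is in fact borne mostly by excessive drinkers. `alcotax` makes that
argument quantitative: it simulates how much more each adult would spend on
alcohol (product plus tax) per year under hypothetical state tax increases,
and aggregates the burden by drinking pattern, household income, employment
status, and race/ethnicity.

The model is a static, single-period microsimulation with four layers:

1. **Consumption.** From the three past-30-day survey questions, average
   daily volume is `days × usual / 30` and annual volume is `D = daily ×
   365`. Classification into nondrinker / nonexcessive / excessive follows
   the standard surveillance definitions (binge ≥5/≥4 drinks on an occasion
   for men/women; heavy >2/>1 drinks per day on average; any drinking at
   ages 18–20). Binge status is judged from the largest-occasion count
   alone: the definition needs only that a binge occurred, not how often.
2. **State cost per drink.** `c = p + t`. The price `p` blends national
   off- and on-premise prices per standard drink at 75%/25% — roughly the
   off-premise share of US alcohol volume — and weights beverages by the
   state's consumption mix. The tax `t` converts each excise from $/gallon
   using standard-drink servings (12 oz beer, 5 oz wine, 1.5 oz spirits;
   about 0.6 oz ethanol each) and adds ad valorem and sales taxes applied
   to the blended pre-tax price (a simpler base than price-plus-excise;
   the choice is isolated in one function and switchable by editing it).
3. **Scenario and response.** A scenario sets `c′ = c + pass_through × Δ`
   or `c′ = c(1 + s)`. Consumption responds through a constant-elasticity
   approximation applied to the relative change in the *tax-inclusive*
   cost, `D′ = max(0, D(1 + ε(c′ − c)/c))`, since that is the price
   consumers actually face. Net cost is `D′c′ − Dc`.
4. **Aggregation.** Survey-weighted per-capita costs, excessive :
   nonexcessive per-capita ratios, shares of aggregate cost, and
   across-state summaries (population-weighted mean, unweighted state
   min/max).

Useful identities that the test suite exercises: with ε = 0 the net cost is
exactly `D × Δ`; for small Δ it is `DΔ(1 + ε)` up to the exact remainder
`DεΔ²/c`; and within a state all drinkers share `c` and ε, so net cost is
proportional to `D` and every between-group cost ratio equals the ratio of
group mean consumption.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `off_premise_weight` | 0.75 | fraction | share of US volume sold off-premise |
| serving sizes | 12 / 5 / 1.5 | oz per drink | US standard-drink convention |
| elasticities ε | −0.46 / −0.69 / −0.80 | — | meta-analytic beer/wine/spirits values |
| `pass_through` | 1.0 | fraction | conventional full-shifting incidence assumption |
| scenario battery | $0.05, $0.10, $0.25, 5% | $/drink, % | the policy range of interest |

Elasticities are validated to [−2, 0] (override flag available). A single
share-weighted ε applies to every drinker in a state; heavier drinkers are
plausibly less price-responsive, so a group-specific ε would shift even
more of the burden onto excessive drinkers — the homogeneous-ε estimate is
conservative in that direction. The hook for group-specific elasticities is
deliberately left out of scope.

## Control states

States that monopolize wine or spirits retailing apply markups instead of
transparent taxes. Among statutory-taxing states the beer tax per drink
predicts the overall weighted tax per drink well, so a single OLS fit of
overall tax on beer tax (at least 3 states, via `stats::lm`) imputes the
per-drink tax of each monopolized beverage from the control state's own
beer tax. One shared model is used for wine and spirits rather than
per-beverage fits — with only ~17 control states there is little to gain
and the imputed quantity is the same either way. Whether the regressed
"overall tax" includes sales taxes is not pinned down by convention; here
it does, consistently on both sides of the fit. Negative predictions are
floored at zero with a warning.

## The synthetic-data generator

Restricted microdata, proprietary price data, and tax extracts cannot be
shipped, so `generate_population()` and `generate_states()` emulate their
statistical structure.

The population generator is calibrated to the published 2011 US adult
marginals (`national_marginals_2011()`): 44.9% nondrinkers, 33.6%
nonexcessive drinkers (mean 128.0 drinks/yr), 21.5% excessive drinkers
(mean 689.1 drinks/yr), and the per-group income/employment/race
distributions. Design choices, made once:

* **Volume model.** Monthly volume is gamma-distributed (a standard
  right-skewed consumption model; shapes 1.5 and 1.2 for the two drinking
  groups, chosen for realistic skew). For nonexcessive drinkers the gamma
  is truncated at the sex-specific heavy cap (30/60 drinks per month) and
  its scale is solved numerically (`uniroot`) so the *truncated* mean hits
  the group target — calibration therefore holds exactly in expectation,
  not just approximately after rejection. Volume factors exactly into
  `days × usual`, with `usual` kept below the binge cutoff for
  nonexcessive drinkers, so every record classifies into its sampled
  category by construction.
* **Excessive drinkers** get a forced binge occasion (`max(usual, cutoff)`),
  except a configurable underage fraction (default 5%) aged 18–20, who
  qualify through any drinking. Excessive-by-heavy-only drinkers are not
  generated separately; in US data over 90% of excessive drinkers binge.
* **Strata** are sampled independently within drinking group from the
  marginal distributions. The published tables give only marginals, so any
  cross-stratum correlation (e.g. income × race) would be invented; it is
  deliberately omitted, which means stratum-by-stratum *joint* analyses of
  synthetic data carry no real-world correlation signal.
* **Weights** are lognormal(0, 0.3) — mildly dispersed positives. The
  survey's raking is not emulated; weighted and unweighted compositions
  coincide in expectation.
* **Sex** is 50/50; the published marginals do not stratify by sex.

The state generator drives everything off ranges with plausible US
magnitudes (off-premise prices near $1/drink, on-premise markups 2.5–4×,
beer excises $0.15–$1.20/gallon, sales taxes 0–8%, a national mix of about
50/17/33 beer/wine/spirits). It plants a known linear relation between beer
tax and overall tax per drink by back-solving wine and spirits excises from
the target overall tax (ad valorem is held at zero in the generator so the
inversion is exact), so interpolator recovery is testable: with zero noise
the fit returns the planted intercept and slope to machine precision.

What passing tests on synthetic data do **not** show: robustness to real
BRFSS editing and nonresponse patterns, state-level price heterogeneity
(national prices are applied uniformly, a stated limitation of the
approach), cross-border purchasing, or consumption underreporting — all
out of scope, and underreporting means real-data estimates of excessive
drinkers' burden would if anything be larger.

## Denominators and rendering

Per-capita cost depends on who counts as the denominator, and the source
tables differ: population-style cells divide by *all adults* in the
stratum, nondrinkers included, while drinker-style cells divide by the
drinkers of the named group only. Both policies are first-class:
`build_incidence_report()` returns a `population` table (all-adults
denominator), and `drinkers`/`states` tables (group-drinkers denominator).
Whether the published consumption-group rows used one or the other is
ambiguous in the original footnotes; rather than resolving the ambiguity,
both are reported. Rendered CSVs round dollars to 2 decimals and
ratios/percentages to 1, mirroring print precision; `report.json` keeps
full precision. All internal computation is double precision with no
intermediate rounding.

Degenerate inputs are handled explicitly: zero-amount scenarios produce
exactly zero net cost; consumption floors at zero under extreme `εΔ/c`;
empty member sets, zero total weight, zero denominators, and degenerate
(zero-variance) regression designs raise errors rather than NaNs; a
missing sex is an error only where the male/female cutoffs actually
disagree (largest occasion in [4, 5) or daily average in (1, 2]).

## Problem sizes and verification

The test suite covers the worked arithmetic examples, exhaustive
enumeration of the heavy-threshold equivalence (daily-average vs
monthly-total form, all integer day × drink combinations), property checks
(weight-splitting invariance, partition conservation, monotonicity in the
tax increase over ε ∈ [−0.65, 0], c ≥ $1.75, Δ ≤ $0.25), an independent
normal-equations oracle for the OLS fit, and calibration recovery for the
generator at n = 50,000 respondents (category proportions within 1
percentage point, group means within 2%). End-to-end pipeline checks run at
a few thousand respondents across a handful of states — ample for the
structural and determinism properties they assert. The homogeneity oracle —
one state, common `c` and ε, group means set to the published 128.0 and
689.1 drinks/yr — turns the headline incidence claims into closed-form
checks: a per-capita cost ratio of 689.1/128.0 ≈ 5.38, an excessive
aggregate-cost share of about 77.6%, and a maximum stratum-level
nonexcessive share of about 27.9%.

## Known limitations

* Static, single-period demand with no beverage substitution, no income
  effects, and no demand curvature.
* One elasticity per state for all drinkers (see above).
* National prices applied to every state: states with below-average prices
  get overestimated net costs.
* Monopoly-state markups are imputed, not observed.
* Synthetic strata are independent within drinking group; joint-stratum
  conclusions from synthetic runs are structural only.
* No design-based variances: point estimates only, as in the source
  analysis.
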