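---
title: "Scoring familial longevity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring familial longevity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flossr)
```

This vignette is the package's own account of the statistical machinery:
what is estimated, under which assumptions, which knobs matter, and where
the design was genuinely open and a choice had to be made.

## The scoring model

Let $S_{c}(a \mid 40)$ be the probability that a person of sex and
birth-cohort stratum $c$ who is alive at age 40 survives past age $a$. For a
sibship member $i$ with attained age $a_i$ (age at death for the deceased,
age at the last known-alive year otherwise), define the *exceedance*

$$u_i = -\log S_{c(i)}(a_i \mid 40).$$

If lifespans truly follow the stratum's survival law, $u_i$ for a death is a
unit-exponential variable — mean 1 regardless of sex or cohort — which is
what makes exceedances addable across siblings born decades apart. For a
member alive at $a_i$, $u_i$ is the exceedance already banked; by the
memorylessness of the unit exponential the expected *eventual* exceedance is
$u_i + 1$, so living members receive an additive bonus (`alive_bonus`,
default 1). This is also the feature that favours families with very old
*living* members, who are the ones a recruitment effort can actually enrol.

The family score of a sibship with $n$ scored members is

$$\mathrm{FLoSS} = \sum_{i=1}^{n}\bigl(u_i + \text{bonus}\cdot
  \mathbf{1}\{\text{alive}_i\}\bigr) \;-\; \text{penalty}\cdot n,$$

with `size_penalty = 1` by default: each member's contribution is centered
at its null expectation. The centering matters. The raw sum is
non-negative and grows linearly in sibship size, so any fixed threshold
mostly selects large families; the centered score is approximately
$\Gamma(n,1)-n$ under the null — mean 0, about half the distribution
negative — so a threshold of 7 means "seven units of exceedance beyond
expectation" for sibships of any size, a *lower* tail (default $\le -4.5$)
exists to anti-select clustered early mortality, and the population mean of
the score sits near zero with a standard deviation of roughly
$\sqrt{\bar n}$ inflated by familial clustering. No further size
normalisation is applied: among equally-centered families, a large sibship
with many exceptional members legitimately outscores a small one. Setting
`size_penalty = 0` recovers the raw additive sum.

Two scoring modes exist because enrolment decisions and retrospective
validation see different information. With `reference_year` unset, final
observed status is used. With `reference_year = y`, vital status and
attained age are recomputed *as of* $y$: a member who died later is treated
as alive at age $y - $ birth year (and receives the bonus), a member
censored before $y$ contributes their last-known exceedance without bonus,
and members not yet 40 at $y$ drop out of the sum. The cross-sectional
analysis uses the as-of-year mode, matching what a selector standing in year
$y$ could have known.

Where tabulated survival has reached zero (the oldest observed death), the
exceedance is truncated at $-\log$ of the smallest strictly positive
tabulated value, keeping record-age scores finite.

## Conditional cohort life tables

$S_c(\cdot \mid 40)$ is estimated per sex and birth band with the
product-limit estimator on the age scale: every individual attaining age 40
enters the risk set at 40 (left truncation), exits at death (event) or at
the last known-alive age (right-censoring), and ties are resolved deaths
before censorings. Bands are decades, with births before 1850 pooled (small
numbers) and the terminal band widened to absorb a short remainder
(1900–1910), so the default 1779–1910 range yields eight bands per sex.

Choices a reader should know about:

* **Integer ages.** Lifespans are calendar-year differences; no month/day
  resolution exists in the intended data. Survival is stored on an integer
  grid; queries between grid points interpolate $\log S$ linearly (this only
  matters for plotting and for continuous null draws). A death at exactly
  the base age carries no information beyond conditioning and is excluded
  from the risk set.
* **Beyond the last event** survival is carried forward flat; the last
  strictly positive value is retained for score truncation.
* **Estimator mode.** `method = "empirical"` replaces the product-limit
  estimate with the empirical survival of the deceased only, for data where
  censoring is negligible or for comparison with simple death-count tables;
  the default handles censoring correctly and is used throughout.
* In the calibration tests, tables are compared against a closed-form
  Gompertz law. Because the estimator sees `floor(T)`, the honest oracle on
  the integer grid is the correspondingly discretised law
  $S(t+1)/S(41)$, not $S(t)$ — comparing against $S(t)$ itself would
  misattribute a half-year discretisation offset to estimation error.

## Group comparisons

The validation designs both reduce to comparing two groups' survival at old
age:

* **Study year.** Individuals alive and aged 80+ in the study year (default
  1980) are partitioned by their own sibship's as-of-year score:
  `exceptional` (FLoSS ≥ 7) versus `ordinary` (everyone else alive at 80+).
  Follow-up runs from the study year, with *age at the study year* as the
  left-truncation entry — entering people only when they come under
  observation avoids immortal-time bias.
* **Offspring.** Offspring born after 1900 are `exceptional` if at least one
  parent belongs to a sibship scoring ≥ 7, `ordinary` if both parents are
  scored below 7, and excluded if a parent is unscorable (defaulting such
  offspring to `ordinary` would contaminate that group; this is
  configurable in spirit by pre-filtering the assignment). Their curves are
  conditioned on reaching 80 by left-truncating at 80.

Curves are Kaplan–Meier with delayed entry, reported at event ages
(right-continuous steps). Tests are log-rank with hypergeometric
tie-corrected variance and truncation-aware risk sets, $p$ from the
$\chi^2_1$ upper tail. Group differences are summarised by the restricted
mean survival time over ages 80–95 (exact step-function integration): the
extra years an average group member lives in that window.

Sexes are analysed separately throughout — age 80 is a far more extreme
threshold for men than for women, so pooling mixes different baseline
hazards. The combined analysis is therefore *sex-stratified*: the log-rank
accumulates observed-minus-expected and variance within sex, the RMST gap is
the size-weighted mean of the per-sex gaps, and curve dominance is judged on
the weighted per-sex survival difference. Naive pooling is genuinely
misleading here — in simulated samples where both per-sex contrasts are
positive, a male-heavier exceptional group can drag the pooled statistic
toward (or past) zero.

## The synthetic pedigree generator

`simulate_pedigrees()` produces the statistical structure the analysis
assumes, at registry-like scale, with known ground truth:

* Two linked generations inside a 1779–1910 birth window with mortality
  follow-up through 2013: founder couples; their children (the *index*
  sibships, births up to 1880); spouses with their own founder parents (so
  spouses pass the parent-information filter and are scoreable — otherwise
  every offspring would have an unscorable parent and the ordinary-offspring
  group would be structurally empty); and grandchildren (offspring sibships,
  births 1881 up to the cap).
* Mortality is Gompertz, $h(t) = a\,z\,e^{bt}$, with $a = 10^{-4}$ per year
  for women, a male/female hazard ratio of 1.5, and $b = \log 2 / 8$ (the
  canonical ~8-year adult mortality doubling time). These give median adult
  lifespans in the low 70s/high 60s — plausible for the era without
  modelling infant mortality, which the age-40 conditioning discards anyway.
* Familial clustering is a gamma frailty $z$ with mean 1 and variance 0.3
  shared by all siblings of a sibship. An offspring sibship's frailty is
  $w \cdot \bar z_{\text{parents}} + (1-w) \cdot z_{\text{fresh}}$ with
  `heritability_weight` $w = 0.5$, making sibling lifespan correlation
  strictly stronger than parent–offspring correlation — the pattern that
  drives the expected *attenuation* of the survival advantage from the
  selected generation to their children.
* Sibship sizes are zero-truncated Poisson with mean 6 and reproducing
  members have Poisson(6) children; after the birth-window truncation this
  yields roughly four scored members per sibship, matching the large-family
  registries this design emulates.
* Censoring: per-year loss-to-follow-up hazard 0.002 (Exponential), plus
  administrative censoring at 2013; both produce last known-alive years.
  Adoption flags (rate 0.01) and blanked vital years (rate 0.005) exercise
  the eligibility and inclusion filters.

What the generator does *not* emulate: marriage/fertility dynamics,
migration, period shocks (wars, pandemics), secular mortality improvement
across cohorts, and record-linkage error. Passing tests on this fixture
therefore demonstrate that the pipeline recovers a known frailty signal
through the full scoring-and-selection chain — not that any particular real
registry satisfies the model.

`simulate_null_from_table()` is the calibration companion: it draws
lifespans from a life table's own law by inverse transform through the same
log-linear interpolation the score lookup uses, so $-\log S(T)$ of a draw is
exactly $-\log U$ — unit-exponential up to truncation at the table's last
positive value. This makes the null calibration of the score a sharp test
rather than an approximate one.

## Problem sizes and determinism

The test suite runs the full study on a 5,000-family sample (~140,000
individuals, simulated and analysed in a few seconds), uses 50,000 draws for
the null calibration, 10,000 for the life-table convergence check, and
exhaustive brute-force oracles on record sets of up to 10 for the
truncation-aware estimators. All stochastic fixtures are seeded; the
study-report JSON is byte-identical across reruns with the same seed. At
this deliberately moderate scale the *point estimates* of tail quantities
(RMST over ages 80–95 with a few hundred exceptional subjects) carry visible
Monte-Carlo noise; the fixed-seed property tests assert the qualitative
structure (direction, ordering, dominance), and re-simulating with other
seeds will wiggle the numbers and can occasionally reorder the two
generations' gap estimates.

## Known limitations

* Integer-year ages throughout; sub-year timing is out of scope.
* No covariate adjustment (no proportional-hazards or parametric frailty
  *fitting*) — the frailty model is a data-generating device, not an
  estimator; heritability of the frailty is not estimated from data.
* Half-siblings are split by the full-sib keying (configurable to
  mother-only); individuals with any unknown parent form singleton sibships
  rather than being dropped, and a singleton's score is well defined.
* Confidence bands for curves and RMST differences are not provided;
  inference rests on the log-rank test.
* The inclusion filters snapshot parent-information availability at sibship
  derivation, so filtering is idempotent even though the parents' own
  records may themselves be filtered out downstream.
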