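---
title: "Methods: scoring, categorisation, simulation and inference in mhfii"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, categorisation, simulation and inference in mhfii}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhfii)
```

`mhfii` links two survey instruments — a 52-item food frequency
questionnaire (FFQ) and the nine-item Household Food Insecurity Access Scale
(HFIAS) — through a diet-quality index and a small set of standard
epidemiological models. This vignette explains each piece, the assumptions
it makes, and the choices we made where a published description leaves the
design open.

## Frequency coding

The FFQ records consumption of each item over the past month on seven
ordered response options. Each option maps to a fixed weekly frequency
(times/week):

```{r}
ffq_levels()
```

The map is strictly monotone, so any analysis on weekly frequencies
preserves the ordering of responses. Portion sizes are not collected by the
instrument, so no energy or nutrient intake is derived — frequencies are the
only exposure currency.

A food group's weekly frequency is the **sum** of its member items' weekly
frequencies. The instrument's published description does not state the
within-group aggregation rule; summation is the convention of the index's
validation lineage, matches the interpretation "two vegetable items once a
week = vegetables twice a week", and makes aggregation additive over any
partition of a group's items (a property the test suite checks).

## The modified Healthy Food Intake Index

The index comprises 11 food-group components; each awards 0–1 or 0–2 points
and the total spans 0–18, higher meaning closer to Nordic food-based
dietary guidelines. Since there are 11 components and the total is 18, the
structure forces exactly seven 2-point and four 1-point components.
*Favourable* components (vegetables; fruits and berries; fibre-rich grains;
fish; milk; vegetable oil; nuts and seeds; fat spreads) award points for
reaching frequency cut-offs; *limiting* components (red and processed meat;
sugar-sweetened beverages; snacks) award points for staying below them.

Two conventions are deliberate package choices:

* **Boundary convention.** Published component tables of this kind rarely
  state whether cut-offs are open or closed. We use "at least" (≥) for
  favourable bands and "at most" (≤) for limiting bands, so a frequency
  exactly at a cut-off always earns the higher band's score. The convention
  is documented in the scoring-table schema and enforced identically in
  `score_component()` and in the brute-force oracle used by the tests.
* **Configuration, not code.** The component definitions — member items,
  direction, cut-offs, maximum points — live in a versioned YAML file
  (`inst/extdata/scoring_table.yaml`). The shipped table is the package's
  default reconstruction: its structure (component names, the 7/4 point
  split, the 0–18 range) follows the published index description, while the
  numeric cut-offs are expressed on the achievable weekly-frequency grid and
  chosen to reflect the guideline messages the components encode (e.g. fish
  at least twice a week for full points, vegetables at least twice daily,
  red and processed meat at most 1.5 times a week for full points). Any
  alternative component table — including a faithful transcription of a
  published one, or the original index without the added meat and nut
  components — is a config drop-in; `validate_scoring_table()` enforces the
  structural invariants.

Missing data policy: a component whose member items are *all* missing cannot
be scored; the participant is flagged incomplete and excluded from analyses
(listwise deletion). A partially observed component is scored on its
observed items — with frequency-sum scoring this treats unobserved items as
unconsumed, which slightly biases favourable components downward for
participants with item nonresponse; the flag and count of missing
components are always reported so stricter exclusion is a one-line filter.

## HFIAS categorisation

Each of the nine questions asks whether an access-related experience
occurred in the past 30 days and, if so, how often (rarely / sometimes /
often). The standard decision table assigns the most severe triggered
category:

* **severe** — Q5 or Q6 often; or any occurrence of Q7, Q8 or Q9;
* **moderate** — Q3 or Q4 sometimes/often; or Q5 or Q6 rarely/sometimes;
* **mild** — Q1 sometimes/often; or any occurrence of Q2; or Q3 or Q4
  rarely;
* **food secure** — otherwise (worrying rarely at most, nothing else).

The individual-level wording used in Finnish survey adaptations changes the
referent ("I" rather than "my household"), not the scoring; we assume the
trigger thresholds are unchanged, and record that assumption here and in the
cohort provenance block. The implementation is validated exhaustively: all
4⁹ = 262 144 complete response patterns are compared against an independent
per-pattern transcription of the decision table, and monotonicity (raising
any one item's frequency never lowers the category) is property-tested. The
continuous 0–27 sum is exported for convenience but unused by the analyses.

## The synthetic cohort generator

Survey microdata linking FFQ, HFIAS and register sociodemographics are
rarely shareable, so the package ships a generator that emulates the joint
structure such a cohort: it is first-class, tested code, and every
inference routine is exercised against it.

**What it draws.** For each of *n* participants (default 6435): age group
(18–29 / 30–44 / 45–59 / 60+, default shares 17/34/37/12 %), sex (80 %
female), education (8 % basic, 72 % upper secondary or vocational, 15 %
lower tertiary, 5 % postgraduate); an FI category; an mHFII total; 11
ordinal component scores; and optionally item-level FFQ responses and HFIAS
patterns consistent with them.

**Total-score model.** The total is a rounded, clamped linear model:
`round(min(max(b0 + age + sex + education + FI effect + ε, 0), 18))` with
ε ~ N(0, σ²). Confounder effects are +1.9 points for the oldest vs
youngest age group (monotone within: 0, 0.8, 1.5, 1.9), +0.4 for women and
+0.8 for postgraduate vs vocational education. The direct severe-FI effect
is ≈ −0.8 points; small direct mild/moderate effects (−0.12/−0.15) plus
confounding produce unadjusted mild/moderate gaps of roughly a third of the
severe gap. The residual dispersion σ = 2.2 points is a free parameter —
published group means do not identify within-group spread — chosen so that
the 0–18 score has realistic spread without noticeable boundary clamping
(the mean sits ≈ 4σ from both bounds); it is recorded in the provenance
block.

**Confounding.** FI categories are drawn from a multinomial whose
log-weights are tilted per FI level by the participant's block-centred
confounder effects (separate tilt coefficients for age, sex and education,
scaled by a severity profile). Negative tilts make younger, male and
less-educated participants more likely to be food insecure, opening a gap
between the unadjusted (−1.1) and adjusted (−0.8) severe-vs-secure
contrasts.

**Calibration is exact, not stochastic.** The confounders are fully
discrete — 4 × 2 × 4 = 32 cells — so `expected_margins()` computes, in
closed form: the FI prevalences after tilting; the expected rounded/clamped
total for every cell × FI combination (a sum of 19 normal-CDF terms); the
FI-group means; and the population weighted-least-squares limit of the
adjusted linear-model contrast. `calibrate_generator()` fixed-point iterates
four knobs (intercept, severe effect, a common tilt scale, FI base weights)
against the targets {secure mean 9.1, unadjusted gap −1.1, adjusted gap
−0.8, prevalences 35/14.5/14.5/36 %} to tolerance 10⁻⁶, typically in about
five iterations. The shipped `generator_config()` defaults *are* this
solution, so generated cohorts are unbiased draws around the targets and
replicate means converge to them at the Monte-Carlo rate. When the targeted
unadjusted and adjusted gaps coincide the calibrator returns zero tilt — no
confounding is needed. Infeasible targets leave a warning and the closest
achieved margins.

**Component model.** Each component score is drawn from a cumulative-logit
model with the configured severe-FI log odds (defaults: log of the target
odds ratios, e.g. vegetables ln 0.54, red/processed meat ln 1.15, fat
spreads and snacks 0), reduced effects for mild/moderate participants, and a
shared confounder term (0.25 log-odds per point of the confounder index).
Because that index is an additive function of the three categorical
covariates, a proportional-odds fit adjusting for them is correctly
specified, and coverage of the configured odds ratios is nominal — which is
exactly what the recovery tests check. The total-score and component-score
sub-generators are *not* forced to be mutually consistent (published group
means and per-component odds ratios are not linked analytically); each is
calibrated to its own targets, and the provenance block says so.

**Raw-instrument layers.** `scores_to_ffq()` enumerates, per component, all
member-item level combinations (≤ 7⁴) grouped by score band and samples
uniformly within the drawn score's band, so rescoring the generated FFQ
reproduces the component scores exactly (an identity the tests check
exhaustively on generated cohorts). Empty bands — possible only with a
misconfigured table — raise an error naming the component. HFIAS patterns
are sampled uniformly from the exhaustive enumeration of the drawn
category's patterns; uniformity over patterns is a simplicity choice, not a
claim about real response-pattern frequencies. Optional missingness knobs
blank items at configured rates to exercise the exclusion policies.

**Reproducibility.** Each block (sociodemographics, FI, totals, components,
FFQ, HFIAS, missingness) draws from its own deterministic sub-seed, so
identical (config, seed) reproduce a cohort exactly and enabling an optional
block never perturbs the others.

**What the generator does not emulate.** Item-level correlation structure
beyond what the score bands induce; realistic HFIAS pattern frequencies
within a category; survey nonresponse mechanisms (missingness is injected
completely at random); register-linkage variables such as income or
municipality; and any total-score/component coupling. Passing recovery tests
therefore demonstrate that the *pipeline* estimates what its inputs encode —
not that real FFQ data behave like the synthetic cohorts.

## Inference

* **One-way ANOVA** (`anova_oneway()`): omnibus F, then mean differences of
  each FI level against the food-secure reference. Pairwise confidence
  intervals and p-values are Bonferroni-corrected with family size equal to
  the number of reference contrasts (3 by default; configurable and
  reported).
* **Adjusted contrasts** (`anova_adjusted()`): a main-effects linear model
  of the total on FI plus categorical covariates — "multi-way ANOVA"
  interpreted without FI × covariate interactions, which is what a single
  adjusted contrast per FI level implies. Age enters as the grouped
  categorical variable, not continuous. Singular designs are reported with
  the aliased terms rather than silently dropped.
* **Confounder screening** (`screen_confounders()`): a candidate is
  retained if it associates with both FI (chi-square; ANOVA for numeric
  candidates) and the total score at α = 0.05, shifts the severe-FI
  estimate by more than 10 % (relative, configurable) when added alongside
  already-selected confounders, and is not collinear (Cramér's V or |r| <
  0.6) with them. The 10 % change-in-estimate default is the conventional
  epidemiological threshold, not a published value. Note an honest
  consequence of the calibrated defaults: sex and education shift the
  severe estimate by only a few percent (their score effects are small and
  their prevalence shifts modest), so strict screening at 10 % selects age
  but not necessarily sex or education. `run_full_analysis()` therefore
  adjusts for the full hypothesis-driven set {age group, sex, education}
  regardless, and emits the screening report as information — mirroring the
  combined hypothesis- and data-driven practice the screening models.
* **Proportional-odds models** (`fit_proportional_odds()`): restricted to
  the severe and food-secure groups, the component score (2–3 levels) is
  regressed on the exposure plus covariates by maximum likelihood
  (`MASS::polr`); binary outcomes go through logistic regression, to which
  the model reduces. Confidence intervals are Wald on the log-odds scale
  (the CI method is not dictated by the models' published use; Wald is the
  default reported by most software). With no covariates and a binary
  outcome the estimate equals the closed-form 2×2 cross-product ratio — the
  tests verify agreement to 10⁻⁶ against that closed form, and against a
  direct likelihood maximisation for 3-level outcomes. Quasi-separation
  (|log OR| > 10 or SE > 10) flags the fit and reports intervals as
  unavailable instead of fabricating them. Outcome levels unobserved in a
  draw are dropped with a warning.

Significance is assessed at 0.05 throughout; missing data are excluded
listwise per analysis, with exclusion counts reported.

## Numerical and testing choices

Monte-Carlo problem sizes in the test suite were chosen to balance
resolution against runtime, and are the package's own choices: mean-gap
recovery uses 150 replicate cohorts of n = 6435 (replicate means must sit
within 3-σ Monte-Carlo bands of the calibrated targets); odds-ratio
recovery uses 120 replicates with a ≥ 90 % CI-coverage requirement per
component; familywise type-I error under the global-null generator uses 500
replicates of n = 600 with a binomial 3-σ tolerance above the nominal 0.05.
The HFIAS oracle comparison is exhaustive (262 144 patterns), not sampled.

## Known limitations

* The shipped scoring table is a guideline-informed default, not a
  transcription of any single published component table; absolute totals
  depend on its cut-offs, though the structural properties (0–18 range,
  monotonicity, decomposition) do not.
* Partial-component scoring treats unobserved items as unconsumed (see
  above).
* The generator's independence of the total-score and component layers
  means joint statistics across the two (e.g. correlation between the drawn
  total and a drawn component score) are not meaningful.
* No survey weighting, multiple imputation, energy adjustment or mediation
  analysis; the instruments measure frequency only.
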