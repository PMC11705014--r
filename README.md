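# mhfii — diet quality and food insecurity with the modified Healthy Food Intake Index

`mhfii` is an R package for epidemiologists and nutrition researchers studying
how food insecurity relates to diet quality in survey cohorts. It implements
the full analysis chain for frequency-based diet-quality scoring:

1. **FFQ parsing and conversion** — 52-item food frequency questionnaire
   responses on a 7-level scale ("not at all" … "more than once a day") are
   converted to weekly consumption frequencies using the fixed map
   {0, 0.12, 0.47, 1.5, 4, 6, 8} times/week.
2. **mHFII scoring** — the modified Healthy Food Intake Index awards 0–2
   points per food group across 11 components (vegetables, fruits and
   berries, fibre-rich grains, fish, milk, vegetable oil, nuts and seeds,
   fat spreads, red and processed meat, sugar-sweetened beverages, snacks),
   reverse-scoring the limiting groups, for a total score of 0–18 where
   higher means closer to Nordic food-based dietary guidelines. Component
   definitions and cut-offs are declarative YAML configuration, not code.
3. **HFIAS categorisation** — the nine-item Household Food Insecurity Access
   Scale (30-day recall, individual-level wording) is scored into the four
   standard categories *food secure < mild < moderate < severe* with the
   Coates decision table.
4. **Inference** — one-way ANOVA with Bonferroni-corrected pairwise mean
   differences against the food-secure reference; covariate-adjusted
   (multi-way ANOVA) contrasts; change-in-estimate confounder screening; and
   per-component proportional-odds (cumulative logit) models comparing
   severely food-insecure with food-secure participants,

   P(score ≤ j | x) = logit⁻¹(ζⱼ − β·severe − γ′·covariates),

   where exp(β) is the odds ratio of a severely food-insecure participant
   achieving a *higher* (more optimal) food-group score.
5. **Synthetic cohorts** — because survey microdata of this kind are rarely
   shareable, a calibrated generator (`generate_cohort()`,
   `calibrate_generator()`) produces cohorts with controlled
   sociodemographic confounding whose FI prevalences, group means, adjusted
   and unadjusted mean gaps and per-component odds ratios match configured
   targets exactly in expectation, so every pipeline stage is testable end
   to end.

## Worked example

```r
library(mhfii)

cohort <- generate_cohort(generator_config(), seed = 2024)
res <- run_full_analysis(cohort)
print(res)
```

```
Food insecurity / diet quality analysis
  n = 6435 (0 excluded for missing data)

Unadjusted mean differences vs food secure (Bonferroni):
  comparison              estimate conf.low conf.high  p.value
1 mild vs food_secure       -0.264   -0.479   -0.0483 1.01e- 2
2 moderate vs food_secure   -0.445   -0.663   -0.227  3.18e- 6
3 severe vs food_secure     -0.976   -1.14    -0.811  2.19e-44

Adjusted for age_group, sex, education:
1 mild vs food_secure     -0.00457   -0.213    0.204  1   e+ 0
2 moderate vs food_secure -0.231     -0.442   -0.0206 2.58e- 2
3 severe vs food_secure   -0.705     -0.866   -0.543  5.42e-25

Proportional-odds ORs, severe FI vs food secure (adjusted):
   component          odds_ratio conf.low conf.high     n
 1 vegetables              0.571    0.510     0.638  4555
 2 fruits_berries          0.628    0.562     0.702  4555
 ...
10 ssb                     0.577    0.516     0.644  4555
11 snacks                  0.978    0.867     1.10   4555
```

Reading the output: in this simulated cohort of 6435 service workers,
severely food-insecure participants average about 1 mHFII point lower than
food-secure participants before adjustment and about 0.7 points lower after
adjusting for age group, sex and education (the default calibration targets
are −1.1 and −0.8; single cohorts scatter around them). The odds ratios
below 1 (vegetables 0.57, fruits/berries 0.63, …) mean severe food
insecurity lowers the odds of reaching a higher food-group score; values
near 1 (fat spreads, snacks) mean no association. The `n = 4555` rows use
only the severe and food-secure groups.

A complete simulate → score → categorise → analyse run, with CSV/JSON
reports and a reproducibility manifest, is one call:

```r
run_pipeline("report/", generator_config(n = 1000L), seed = 7)
```

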