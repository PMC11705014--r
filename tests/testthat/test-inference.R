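toy_groups <- function(a, b) {
  tibble::tibble(
    total_mhfii = c(a, b),
    fi_category = rep(c("food_secure", "severe"), c(length(a), length(b)))
  )
}

test_that("one-way ANOVA recovers the closed-form two-group toy", {
  # A: 8,9,10; B: 11,12,13 -> difference 3, F = t^2 = 13.5
  res <- anova_oneway(toy_groups(c(8, 9, 10), c(11, 12, 13)))
  expect_equal(res$contrasts$estimate, 3)
  expect_equal(res$omnibus$statistic, 13.5)
  # pooled t on 4 df: p of F(1,4) equals two-sided t p-value
  expect_equal(res$omnibus$p.value, 2 * pt(-sqrt(13.5), 4))
  expect_equal(res$group_means$mean, c(9, 12))
})

test_that("identical groups give zero differences with p = 1", {
  res <- anova_oneway(toy_groups(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(res$contrasts$estimate, 0)
  expect_equal(res$contrasts$p.value, 1)
})

test_that("listwise deletion and empty groups are handled explicitly", {
  d <- toy_groups(c(8, 9, 10), c(11, 12, 13))
  d$total_mhfii[2] <- NA
  res <- anova_oneway(d)
  expect_equal(res$n_excluded, 1)
  expect_equal(res$n_used, 5)
  d2 <- toy_groups(c(8, 9, 10), 11)
  expect_error(anova_oneway(d2), "fewer than 2")
})

test_that("Bonferroni widens intervals and inflates p-values by the family size", {
  cfg <- generator_config(n = 3000L)
  co <- generate_cohort(cfg, seed = 31, include_components = FALSE)
  res1 <- anova_oneway(co, family = 1)
  res3 <- anova_oneway(co, family = 3)
  expect_true(all(res3$contrasts$conf.low < res1$contrasts$conf.low))
  expect_true(all(res3$contrasts$p.value >=
                    pmin(1, res1$contrasts$p.value)))
  expect_equal(pmin(1, res1$contrasts$p.value * 3), res3$contrasts$p.value)
})

test_that("adjusted contrasts equal unadjusted when covariates are independent of FI", {
  cfg <- null_generator_config(n = 20000L)
  cfg$score_model$fi_effects["severe"] <- -1
  co <- generate_cohort(cfg, seed = 17, include_components = FALSE)
  un <- anova_oneway(co)$contrasts
  ad <- anova_adjusted(co)$contrasts
  sev <- un$comparison == "severe vs food_secure"
  expect_lt(abs(un$estimate[sev] - ad$estimate[sev]), 0.1)
  expect_lt(abs(un$estimate[sev] + 1), 0.12)
})

test_that("a confounder-driven gap vanishes after adjustment", {
  cfg <- generator_config(n = 30000L)
  cfg$score_model$fi_effects[] <- 0  # tilt remains: gap is pure confounding
  co <- generate_cohort(cfg, seed = 19, include_components = FALSE)
  un <- anova_oneway(co)$contrasts
  ad <- anova_adjusted(co)$contrasts
  sev <- un$comparison == "severe vs food_secure"
  expect_lt(un$estimate[sev], -0.2)      # confounding alone opens a gap
  expect_lt(abs(ad$estimate[sev]), 0.08) # adjustment closes it
})

test_that("proportional odds with no covariates equals the 2x2 cross-product ratio", {
  d <- tibble::tibble(
    score = rep(c(0, 1, 0, 1), c(30, 70, 50, 50)),
    fi_category = rep(c("food_secure", "severe"), c(100, 100))
  )
  fit <- fit_proportional_odds(d, "score")
  expect_equal(fit$odds_ratio, (50 * 30) / (50 * 70), tolerance = 1e-6)
  expect_false(fit$separation)

  set.seed(99)
  for (rep in 1:30) {
    cells <- sample(1:30, 4, replace = TRUE)
    d2 <- tibble::tibble(
      score = rep(c(0, 1, 0, 1), cells),
      fi_category = rep(c("food_secure", "food_secure", "severe", "severe"),
                        cells)
    )
    fit2 <- fit_proportional_odds(d2, "score")
    closed <- (cells[4] * cells[1]) / (cells[3] * cells[2])
    expect_equal(fit2$odds_ratio, closed, tolerance = 1e-6)
  }
})

test_that("three-level fits agree with direct likelihood maximisation", {
  cfg <- generator_config(n = 400L)
  co <- generate_cohort(cfg, seed = 41)
  fit <- fit_proportional_odds(co, "vegetables")
  sub <- co[as.character(co$fi_category) %in% c("food_secure", "severe"), ]
  y <- as.integer(sub$vegetables)
  x <- as.numeric(sub$fi_category == "severe")
  nll <- function(par) {
    z1 <- par[1]; z2 <- par[1] + exp(par[2]); b <- par[3]
    p1 <- plogis(z1 - b * x)
    p2 <- plogis(z2 - b * x)
    ll <- ifelse(y == 0, log(p1), ifelse(y == 1, log(p2 - p1), log(1 - p2)))
    -sum(ll)
  }
  opt <- optim(c(-1, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 500))
  expect_equal(unname(fit$odds_ratio), exp(opt$par[3]), tolerance = 1e-3)
})

test_that("null exposure gives OR near 1; unobserved levels are dropped with warning", {
  cfg <- null_generator_config(n = 20000L)
  co <- generate_cohort(cfg, seed = 43)
  fit <- fit_proportional_odds(co, "fish")
  expect_lt(abs(log(fit$odds_ratio)), 0.1)

  small <- co[1:60, ]
  small$vegetables[small$vegetables == 2] <- 1L
  small$vegetables <- factor(small$vegetables, levels = 0:2)
  expect_warning(fit_proportional_odds(small, "vegetables"), "dropped")
})

test_that("separation is flagged instead of fabricating intervals", {
  d <- tibble::tibble(
    score = rep(c(0, 1), c(40, 40)),
    fi_category = rep(c("severe", "food_secure"), c(40, 40))
  )
  fit <- suppressWarnings(fit_proportional_odds(d, "score"))
  expect_true(fit$separation)
  expect_true(is.na(fit$conf.low))
  expect_true(is.na(fit$conf.high))
})

test_that("confounder screening applies each criterion", {
  cfg <- generator_config(n = 6435L)
  co <- generate_cohort(cfg, seed = 51, include_components = FALSE)
  set.seed(51)
  co$noise_cand <- factor(sample(c("a", "b"), nrow(co), replace = TRUE))
  co$age_copy <- co$age_group  # perfectly collinear with age_group
  scr <- screen_confounders(
    co, c("age_group", "age_copy", "sex", "education", "noise_cand"))
  rep_tab <- scr$report
  # age passes everything; its copy fails only on collinearity
  expect_true("age_group" %in% scr$selected)
  expect_equal(rep_tab$reason[rep_tab$candidate == "age_copy"],
               "collinear with selected confounder")
  # a candidate independent of FI and outcome is excluded on association
  expect_false("noise_cand" %in% scr$selected)
  expect_match(rep_tab$reason[rep_tab$candidate == "noise_cand"],
               "not associated")
  # single-level candidates are skipped with a warning
  co$constant <- factor("x")
  expect_warning(screen_confounders(co, "constant"), "single level")
})

test_that("the full analysis bundles stages and accounts for exclusions", {
  cfg <- generator_config(n = 2500L)
  cfg$missing$sociodemo_rate <- 0.02
  co <- generate_cohort(cfg, seed = 61)
  res <- run_full_analysis(co)
  expect_s3_class(res, "fi_analysis")
  expect_equal(res$n$total, 2500)
  expect_gt(res$n$excluded, 0)
  expect_equal(res$n$used, res$n$total - res$n$excluded)
  expect_equal(nrow(res$ordinal_effects), 11)
  expect_equal(nrow(res$unadjusted$contrasts), 3)
  expect_true(all(res$adjusted$contrasts$adjusted))
  expect_true(all(res$ordinal_effects$odds_ratio > 0))
  expect_true(all(res$ordinal_effects$conf.low <=
                    res$ordinal_effects$odds_ratio, na.rm = TRUE))
  expect_output(print(res), "Proportional-odds")
})
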