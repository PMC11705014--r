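test_that("identical config and seed reproduce the cohort exactly", {
  cfg <- generator_config(n = 400L)
  a <- generate_cohort(cfg, seed = 9, include_ffq = TRUE,
                       include_hfias = TRUE)
  b <- generate_cohort(cfg, seed = 9, include_ffq = TRUE,
                       include_hfias = TRUE)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(as.data.frame(attr(a, "ffq")),
                   as.data.frame(attr(b, "ffq")))
  expect_identical(as.data.frame(attr(a, "hfias")),
                   as.data.frame(attr(b, "hfias")))
  c <- generate_cohort(cfg, seed = 10)
  expect_false(identical(a$total_mhfii, c$total_mhfii))
})

test_that("optional blocks draw from sub-streams without perturbing the rest", {
  cfg <- generator_config(n = 300L)
  plain <- generate_cohort(cfg, seed = 4)
  with_extras <- generate_cohort(cfg, seed = 4, include_ffq = TRUE,
                                 include_hfias = TRUE)
  shared <- names(plain)
  strip <- function(d) {
    d <- as.data.frame(d)
    attributes(d)[setdiff(names(attributes(d)),
                          c("names", "row.names", "class"))] <- NULL
    d
  }
  expect_identical(strip(plain[shared]), strip(with_extras[shared]))
})

test_that("empirical marginals converge to the configured values", {
  cfg <- generator_config(n = 100000L)
  co <- generate_cohort(cfg, seed = 2, include_components = FALSE)
  m <- expected_margins(cfg)
  emp_fi <- as.numeric(table(co$fi_category)) / nrow(co)
  tol <- 3 * sqrt(m$prevalence * (1 - m$prevalence) / nrow(co))
  expect_true(all(abs(emp_fi - m$prevalence) < tol))
  expect_lt(abs(mean(co$sex == "female") - cfg$sex_female), 0.005)
  emp_age <- as.numeric(table(co$age_group)) / nrow(co)
  expect_true(all(abs(emp_age - cfg$age_groups) < 0.006))
  # group means near their exact expectations
  mn <- tapply(co$total_mhfii, co$fi_category, mean)
  expect_lt(abs(mn[["food_secure"]] - m$secure_mean), 0.05)
  expect_lt(abs(mn[["severe"]] - m$severe_mean), 0.05)
})

test_that("the null configuration carries no FI-outcome association", {
  cfg <- null_generator_config(n = 20000L)
  co <- generate_cohort(cfg, seed = 3)
  mn <- tapply(co$total_mhfii, co$fi_category, mean)
  expect_lt(abs(mn[["severe"]] - mn[["food_secure"]]), 0.12)
  fit <- fit_proportional_odds(co, "vegetables",
                               covariates = c("age_group", "sex", "education"))
  # SE(log OR) ~ 0.027 at this n; 0.1 is a ~3.7 sigma band around the null
  expect_lt(abs(log(fit$odds_ratio)), 0.1)
})

test_that("FFQ responses derived from scores rescore to the same values", {
  cfg <- generator_config(n = 500L)
  co <- generate_cohort(cfg, seed = 12, include_ffq = TRUE)
  rescored <- score_mhfii(attr(co, "ffq"))
  comp <- names(default_scoring_table()$components)
  expect_identical(as.matrix(rescored[comp]), as.matrix(co[comp]))
  expect_false(any(rescored$incomplete))
  # max component scores imply frequencies in the top band by construction
  tab <- default_scoring_table()
  veg <- tab$components$vegetables
  at_max <- which(co$vegetables == veg$max_points)
  freq <- aggregate_group(attr(co, "ffq"), veg)
  expect_true(all(freq[at_max] >= max(veg$thresholds)))
})

test_that("generated HFIAS patterns reproduce the drawn FI categories", {
  cfg <- generator_config(n = 800L)
  co <- generate_cohort(cfg, seed = 21, include_components = FALSE,
                        include_hfias = TRUE)
  hf <- attr(co, "hfias")
  expect_identical(as.character(categorize_hfias(hf)),
                   as.character(co$fi_category))
})

test_that("calibration hits the target margins and degenerates gracefully", {
  cal <- calibrate_generator()
  info <- attr(cal, "calibration")
  expect_true(info$converged)
  expect_lt(abs(info$margins$secure_mean - 9.1), 1e-5)
  expect_lt(abs(info$margins$unadjusted_gap + 1.1), 1e-5)
  expect_lt(abs(info$margins$adjusted_gap + 0.8), 1e-5)
  expect_true(all(abs(info$margins$prevalence -
                        cal$fi_prevalence) < 1e-5))
  # shipped defaults are the calibrated solution
  m <- expected_margins(generator_config())
  expect_lt(abs(m$secure_mean - 9.1), 1e-4)
  expect_lt(abs(m$unadjusted_gap + 1.1), 1e-4)
  expect_lt(abs(m$adjusted_gap + 0.8), 1e-4)

  # equal unadjusted and adjusted targets need no confounding
  flat <- calibrate_generator(targets = list(secure_mean = 9.1,
                                             unadjusted_gap = -0.8,
                                             adjusted_gap = -0.8))
  expect_equal(flat$fi_confounder_association$age, 0)
  expect_equal(flat$fi_confounder_association$sex, 0)
  expect_equal(flat$fi_confounder_association$education, 0)
  mf <- expected_margins(flat)
  expect_lt(abs(mf$unadjusted_gap - mf$adjusted_gap), 1e-6)
})

test_that("missingness injection blanks items at the configured rates", {
  cfg <- generator_config(n = 2000L)
  cfg$missing$ffq_item_rate <- 0.05
  cfg$missing$hfias_item_rate <- 0.05
  co <- generate_cohort(cfg, seed = 8, include_ffq = TRUE,
                        include_hfias = TRUE)
  ffq <- attr(co, "ffq")
  rate <- mean(is.na(as.matrix(ffq[, -1])))
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
  hf <- attr(co, "hfias")
  expect_true(anyNA(as.matrix(hf[, -1])))
  expect_true(anyNA(categorize_hfias(hf)))
})

test_that("invalid configurations are rejected before sampling", {
  cfg <- generator_config()
  cfg$fi_prevalence <- c(food_secure = 0.5, mild = 0.5,
                         moderate = 0.5, severe = 0.5)
  expect_error(generate_cohort(cfg), "probabilities")
  cfg2 <- generator_config()
  cfg2$n <- 0L
  expect_error(generate_cohort(cfg2), "positive")
  expect_error(generator_config(not_a_field = 1), "unknown")
})
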