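# Synthetic survey-cohort generator.
#
# Two linked sub-generators share one drawn set of sociodemographics and
# food-insecurity (FI) categories:
#   (a) a total-score generator: mHFII total = round/clamp(intercept +
#       confounder effects + FI effect + normal noise);
#   (b) a component generator: each of the 11 component scores drawn from a
#       cumulative-logit (proportional-odds) model with a configured
#       severe-FI log-odds and a shared confounder term.
# FI categories are tilted by the sociodemographics so that the unadjusted
# severe-vs-secure mean gap exceeds the adjusted (direct) effect; the tilt,
# intercept, severe effect and FI base weights are calibrated against the
# target margins (see calibrate_generator()).
#
# Because the confounders are fully discrete (4 age x 2 sex x 4 education =
# 32 cells), all margins the calibration targets -- FI prevalences, group
# means of the rounded and clamped total, and the population limit of the
# covariate-adjusted contrast -- have closed forms; expected_margins()
# computes them exactly and the calibrator solves against them, so the only
# error left in a generated cohort is sampling error.

sex_labels <- c("male", "female")

#' Synthetic-cohort generator configuration
#'
#' Returns the default generator configuration, optionally overriding any
#' top-level field by name. Defaults encode the study conditions: cohort size
#' 6435; FI prevalences 35 % food secure, 14.5 % mild, 14.5 % moderate and
#' 36 % severe (the combined 29 % mild/moderate split evenly); 80 % women;
#' age-group shares 17/34/37/12 % for 18--29 / 30--44 / 45--59 / 60+;
#' education 8 % basic, 72 % upper secondary or vocational, 15 % lower
#' tertiary, 5 % postgraduate. The total-score model uses confounder effects
#' of +1.9 points for the oldest vs youngest age group, +0.4 for women and
#' +0.8 for postgraduate vs vocational education; the component model's
#' severe-FI log odds are the logarithms of the target odds ratios
#' (vegetables 0.54, fruits/berries 0.61, fibre-rich grains 0.79, fish 0.65,
#' milk 0.89, vegetable oil 0.80, nuts/seeds 0.66, red/processed meat 1.15,
#' SSB 0.67, fat spreads and snacks 1). The intercept, severe-FI total-score
#' effect, confounder tilt and FI base weights ship pre-calibrated so that the
#' food-secure mean is 9.1, the unadjusted severe-vs-secure gap -1.1 and the
#' adjusted gap -0.8 ([calibrate_generator()] reproduces them).
#'
#' @param ... Named top-level fields to override (e.g. `n = 500`,
#'   `seed = 42`).
#' @return A `generator_config` list.
#' @export
generator_config <- function(...) {
  cfg <- list(
    n = 6435L,
    seed = 1L,
    fi_prevalence = c(food_secure = 0.35, mild = 0.145,
                      moderate = 0.145, severe = 0.36),
    sex_female = 0.80,
    age_groups = c("18-29" = 0.17, "30-44" = 0.34,
                   "45-59" = 0.37, "60+" = 0.12),
    education = c(basic = 0.08, upper_secondary_vocational = 0.72,
                  lower_tertiary = 0.15, postgraduate = 0.05),
    score_model = list(
      # intercept and severe effect are calibrated; see calibrate_generator()
      intercept = 7.404428023137,
      fi_effects = c(food_secure = 0, mild = -0.12, moderate = -0.15,
                     severe = -0.800093642469),
      age_effects = c("18-29" = 0, "30-44" = 0.8, "45-59" = 1.5, "60+" = 1.9),
      sex_female_effect = 0.4,
      education_effects = c(basic = 0.3, upper_secondary_vocational = 0,
                            lower_tertiary = 0.5, postgraduate = 0.8),
      residual_sd = 2.2
    ),
    fi_confounder_association = list(
      # log-odds tilt per point of the (block-centred) confounder effect,
      # scaled per FI level by severity_scale; calibrated jointly
      age = -0.550999889101, sex = -1.796967758181,
      education = -1.174160241670,
      severity_scale = c(food_secure = 0, mild = 0.85,
                         moderate = 0.85, severe = 1)
    ),
    # multinomial base weights; calibrated so marginal prevalences match
    # fi_prevalence despite the tilt
    fi_base_weights = c(food_secure = 0.342232394331,
                        mild = 0.147734421953,
                        moderate = 0.147734421953,
                        severe = 0.362298761764),
    component_model = list(
      severe_log_or = c(
        vegetables = log(0.54), fruits_berries = log(0.61),
        fibre_grains = log(0.79), fish = log(0.65), milk = log(0.89),
        vegetable_oil = log(0.80), nuts_seeds = log(0.66), fat_spreads = 0,
        red_processed_meat = log(1.15), ssb = log(0.67), snacks = 0
      ),
      severity_scale = c(food_secure = 0, mild = 0.4, moderate = 0.55,
                         severe = 1),
      confounder_effect = 0.25,
      cutpoints = list(
        vegetables = c(-1.2, 0.7), fruits_berries = c(-1.0, 0.8),
        fibre_grains = c(-1.3, 0.5), fish = c(-0.6, 1.1),
        milk = c(-0.8, 0.9), vegetable_oil = -0.2, nuts_seeds = 0.3,
        fat_spreads = -0.5, red_processed_meat = c(-1.5, 0.4),
        ssb = c(-1.0, 0.3), snacks = 0.1
      )
    ),
    missing = list(ffq_item_rate = 0, hfias_item_rate = 0,
                   sociodemo_rate = 0)
  )
  dots <- list(...)
  if (length(dots) > 0) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown) > 0) {
      stop(sprintf("unknown generator_config field(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  structure(cfg, class = "generator_config")
}

#' Null-association generator configuration
#'
#' The default configuration with every FI effect removed: no total-score FI
#' effect, no component log odds, and no FI--confounder tilt (base weights
#' equal the prevalences). Confounders still affect the total score, but FI
#' is independent of both confounders and outcomes, so any detected
#' FI-outcome association is a false positive.
#'
#' @param ... Passed on to [generator_config()] overrides.
#' @return A `generator_config`.
#' @export
null_generator_config <- function(...) {
  cfg <- generator_config(...)
  cfg$score_model$fi_effects[] <- 0
  cfg$fi_confounder_association$age <- 0
  cfg$fi_confounder_association$sex <- 0
  cfg$fi_confounder_association$education <- 0
  cfg$fi_base_weights <- cfg$fi_prevalence
  cfg$component_model$severe_log_or[] <- 0
  cfg
}

check_probs <- function(p, what) {
  if (any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-6) {
    stop(sprintf("%s must be probabilities in [0,1] summing to 1", what),
         call. = FALSE)
  }
}

#' Validate a generator configuration
#'
#' @param config A `generator_config`.
#' @return `config`, invisibly; errors (before any sampling) on invalid
#'   fields.
#' @export
validate_generator_config <- function(config) {
  if (length(config$n) != 1 || is.na(config$n) || config$n < 1) {
    stop("n must be a positive integer", call. = FALSE)
  }
  check_probs(config$fi_prevalence, "fi_prevalence")
  check_probs(config$age_groups, "age_groups")
  check_probs(config$education, "education")
  if (config$sex_female < 0 || config$sex_female > 1) {
    stop("sex_female must be in [0,1]", call. = FALSE)
  }
  sm <- config$score_model
  if (sm$residual_sd <= 0) stop("residual_sd must be > 0", call. = FALSE)
  if (length(sm$fi_effects) != 4 || length(sm$age_effects) != 4 ||
      length(sm$education_effects) != 4) {
    stop("score_model effect vectors must have 4 entries", call. = FALSE)
  }
  if (any(config$fi_base_weights <= 0)) {
    stop("fi_base_weights must be positive", call. = FALSE)
  }
  cm <- config$component_model
  if (!identical(sort(names(cm$severe_log_or)), sort(names(cm$cutpoints)))) {
    stop("component_model severe_log_or and cutpoints must name the same components",
         call. = FALSE)
  }
  invisible(config)
}

# The 32 discrete confounder cells with joint probabilities, score-scale
# confounder effects (C), block-centred effects and the FI tilt index t.
confounder_cells <- function(config) {
  sm <- config$score_model
  fca <- config$fi_confounder_association
  sex_probs <- c(1 - config$sex_female, config$sex_female)
  sex_effects <- c(0, sm$sex_female_effect)
  grid <- expand.grid(age = 1:4, sex = 1:2, edu = 1:4,
                      KEEP.OUT.ATTRS = FALSE)
  prob <- config$age_groups[grid$age] * sex_probs[grid$sex] *
    config$education[grid$edu]
  z_age <- sm$age_effects - sum(config$age_groups * sm$age_effects)
  z_sex <- sex_effects - sum(sex_probs * sex_effects)
  z_edu <- sm$education_effects - sum(config$education * sm$education_effects)
  C <- sm$age_effects[grid$age] + sex_effects[grid$sex] +
    sm$education_effects[grid$edu]
  tilt <- fca$age * z_age[grid$age] + fca$sex * z_sex[grid$sex] +
    fca$education * z_edu[grid$edu]
  z_total <- z_age[grid$age] + z_sex[grid$sex] + z_edu[grid$edu]
  list(grid = grid, prob = as.numeric(prob), C = as.numeric(C),
       tilt = as.numeric(tilt), z_total = as.numeric(z_total))
}

# FI-category probabilities for a vector of tilt indices (rows sum to 1)
fi_probs_for_tilt <- function(config, tilt) {
  s <- config$fi_confounder_association$severity_scale
  w <- config$fi_base_weights
  logp <- outer(tilt, s) + rep(log(w), each = length(tilt))
  p <- exp(logp - apply(logp, 1, max))
  p / rowSums(p)
}

# E[round(clamp(X, 0, 18))] for X ~ N(mu, sd), exactly
expected_rounded_total <- function(mu, sd) {
  breaks <- c(-Inf, seq(0.5, 17.5, by = 1), Inf)
  cdf <- vapply(breaks, function(b) pnorm(b, mean = mu, sd = sd),
                numeric(length(mu)))
  if (length(mu) == 1) cdf <- matrix(cdf, nrow = 1)
  probs <- cdf[, -1, drop = FALSE] - cdf[, -ncol(cdf), drop = FALSE]
  as.numeric(probs %*% (0:18))
}

#' Exact expected margins of the total-score generator
#'
#' Computes, without simulation, the margins the calibration targets: FI
#' prevalences, FI-group means of the rounded/clamped total score, the
#' unadjusted severe-vs-secure mean difference, and the adjusted difference
#' (the population weighted-least-squares limit of a linear model with FI and
#' the three confounders as categorical main effects).
#'
#' @param config A `generator_config`.
#' @return A list with `prevalence`, `group_means`, `secure_mean`,
#'   `severe_mean`, `unadjusted_gap`, `adjusted_gap`.
#' @export
expected_margins <- function(config) {
  validate_generator_config(config)
  cells <- confounder_cells(config)
  P <- fi_probs_for_tilt(config, cells$tilt)       # 32 x 4
  joint <- cells$prob * P                           # cell x FI joint probs
  prevalence <- colSums(joint)
  names(prevalence) <- names(config$fi_prevalence)
  sm <- config$score_model
  n_cell <- length(cells$prob)
  # expected rounded totals for every (cell, FI) combination
  mu <- outer(cells$C + sm$intercept, sm$fi_effects, `+`)
  Ey <- matrix(expected_rounded_total(as.numeric(mu), sm$residual_sd),
               nrow = n_cell)
  group_means <- colSums(joint * Ey) / prevalence
  names(group_means) <- names(prevalence)
  # population WLS limit of lm(total ~ fi + age + sex + education)
  grid <- cells$grid
  rows <- expand.grid(cell = seq_len(n_cell), fi = 1:4)
  X <- cbind(
    1,
    outer(rows$fi, 2:4, `==`) * 1,
    outer(grid$age[rows$cell], 2:4, `==`) * 1,
    (grid$sex[rows$cell] == 2) * 1,
    outer(grid$edu[rows$cell], 2:4, `==`) * 1
  )
  wts <- joint[cbind(rows$cell, rows$fi)]
  y <- Ey[cbind(rows$cell, rows$fi)]
  XtW <- t(X * wts)
  beta <- solve(XtW %*% X, XtW %*% y)
  list(
    prevalence = prevalence,
    group_means = group_means,
    secure_mean = unname(group_means[1]),
    severe_mean = unname(group_means[4]),
    unadjusted_gap = unname(group_means[4] - group_means[1]),
    adjusted_gap = beta[4]
  )
}

#' Calibrate the generator against target margins
#'
#' Fixed-point search over the total-score intercept, severe-FI effect,
#' FI--confounder tilt scale and FI base weights so that the exact expected
#' margins (see [expected_margins()]) match the targets: food-secure mean,
#' adjusted severe-vs-secure difference, unadjusted difference, and FI
#' prevalences. When the targeted unadjusted and adjusted gaps coincide the
#' tilt is set to zero (no confounding is needed).
#'
#' @param targets List with `secure_mean`, `unadjusted_gap`, `adjusted_gap`
#'   (signed differences, severe minus secure) and optionally
#'   `fi_prevalence`.
#' @param config Starting configuration.
#' @param max_iter,tol Iteration control; convergence is declared when every
#'   margin is within `tol` of its target.
#' @param path Optional YAML path; when given, the calibrated configuration
#'   and the search trace are written there.
#' @return The calibrated `generator_config`, with attribute `calibration`
#'   (targets, trace, final margins, convergence flag). When the targets are
#'   infeasible within `max_iter`, the closest achieved configuration is
#'   returned with `converged = FALSE` and a warning.
#' @export
calibrate_generator <- function(targets = list(secure_mean = 9.1,
                                               unadjusted_gap = -1.1,
                                               adjusted_gap = -0.8),
                                config = generator_config(),
                                max_iter = 200, tol = 1e-6, path = NULL) {
  targets$fi_prevalence <- targets$fi_prevalence %||% config$fi_prevalence
  conf_target <- targets$unadjusted_gap - targets$adjusted_gap
  if (abs(conf_target) < 1e-12) {
    config$fi_confounder_association$age <- 0
    config$fi_confounder_association$sex <- 0
    config$fi_confounder_association$education <- 0
  }
  trace <- vector("list", max_iter)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    m <- expected_margins(config)
    err <- c(
      secure_mean = targets$secure_mean - m$secure_mean,
      adjusted_gap = targets$adjusted_gap - m$adjusted_gap,
      unadjusted_gap = targets$unadjusted_gap - m$unadjusted_gap,
      prevalence = max(abs(targets$fi_prevalence - m$prevalence))
    )
    trace[[it]] <- tibble::tibble(
      iter = it, secure_mean = m$secure_mean,
      unadjusted_gap = m$unadjusted_gap, adjusted_gap = m$adjusted_gap,
      max_abs_error = max(abs(err))
    )
    if (max(abs(err)) < tol) {
      converged <- TRUE
      break
    }
    config$score_model$intercept <- config$score_model$intercept +
      err["secure_mean"]
    config$score_model$fi_effects["severe"] <-
      config$score_model$fi_effects["severe"] + err["adjusted_gap"]
    conf_ach <- m$unadjusted_gap - m$adjusted_gap
    if (abs(conf_target) >= 1e-12) {
      fca <- config$fi_confounder_association
      if (abs(conf_ach) < 1e-10) {
        # no tilt yet: seed one proportional to the default block weights
        config$fi_confounder_association$age <- -0.5
        config$fi_confounder_association$sex <- -1.6
        config$fi_confounder_association$education <- -1.1
      } else {
        fac <- conf_target / conf_ach
        fac <- max(min(fac, 4), 0.25)  # damped update
        config$fi_confounder_association$age <- fca$age * fac
        config$fi_confounder_association$sex <- fca$sex * fac
        config$fi_confounder_association$education <- fca$education * fac
      }
    }
    w <- config$fi_base_weights * targets$fi_prevalence / m$prevalence
    config$fi_base_weights <- w / sum(w)
  }
  trace <- dplyr::bind_rows(trace[!vapply(trace, is.null, TRUE)])
  m_final <- expected_margins(config)
  if (!converged) {
    warning(sprintf(
      paste0("calibration did not converge within %d iterations; closest ",
             "margins: secure mean %.4f, unadjusted gap %.4f, adjusted gap %.4f"),
      max_iter, m_final$secure_mean, m_final$unadjusted_gap,
      m_final$adjusted_gap), call. = FALSE)
  }
  attr(config, "calibration") <- list(
    targets = targets, trace = trace, margins = m_final,
    converged = converged
  )
  if (!is.null(path)) {
    out <- unclass(config)
    out$calibration_trace <- lapply(
      seq_len(nrow(trace)), function(i) as.list(trace[i, ])
    )
    yaml::write_yaml(out, path)
  }
  config
}

sub_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 65521 * 19937 + k * 7919) %% 2147483587)
}

# enumerate all 4^9 HFIAS patterns once, categorised; cached per session
hfias_pattern_pool <- function() {
  if (!is.null(.mhfii_cache$hfias_pool)) return(.mhfii_cache$hfias_pool)
  grid <- as.matrix(expand.grid(rep(list(0:3), 9), KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- hfias_question_cols
  storage.mode(grid) <- "integer"
  categories <- categorize_hfias(grid)
  pool <- list(
    patterns = grid,
    index_by_cat = split(seq_len(nrow(grid)), categories)
  )
  .mhfii_cache$hfias_pool <- pool
  pool
}

#' Generate a synthetic cohort
#'
#' Draws sociodemographics, FI categories (tilted by the configured
#' confounder association), mHFII totals, 11 component scores, and optionally
#' item-level FFQ responses consistent with the component scores and HFIAS
#' response patterns consistent with the FI categories. Each block draws from
#' its own seeded sub-stream, so switching optional blocks on or off never
#' perturbs the others.
#'
#' The total-score and component-score sub-generators are intentionally not
#' mutually consistent: each is calibrated against its own target margins,
#' and an mHFII total recomputed from the generated FFQ responses will not
#' equal the drawn `total_mhfii` (the provenance attribute records this).
#'
#' @param config A `generator_config`.
#' @param seed RNG seed (defaults to `config$seed`).
#' @param include_components Draw the 11 ordinal component scores.
#' @param include_ffq Derive item-level FFQ responses from the component
#'   scores (attached as attribute `"ffq"`); implies `include_components`.
#' @param include_hfias Draw HFIAS response patterns whose categorisation
#'   reproduces the drawn FI category (attached as attribute `"hfias"`).
#' @param scoring_table,item_schema Used when `include_ffq = TRUE`.
#' @return A tibble of class `synthetic_cohort` with `participant_id`,
#'   `age_group`, `sex`, `education`, `fi_category`, `total_mhfii` and one
#'   column per component; attributes `provenance`, and `ffq` / `hfias` when
#'   requested.
#' @export
generate_cohort <- function(config = generator_config(),
                            seed = config$seed,
                            include_components = TRUE,
                            include_ffq = FALSE,
                            include_hfias = FALSE,
                            scoring_table = default_scoring_table(),
                            item_schema = default_item_schema()) {
  validate_generator_config(config)
  if (include_ffq) include_components <- TRUE
  n <- as.integer(config$n)
  sm <- config$score_model
  cm <- config$component_model

  # block 1: sociodemographics
  withr::with_seed(sub_seed(seed, 1L), {
    age_i <- sample.int(4L, n, replace = TRUE, prob = config$age_groups)
    sex_i <- sample.int(2L, n, replace = TRUE,
                        prob = c(1 - config$sex_female, config$sex_female))
    edu_i <- sample.int(4L, n, replace = TRUE, prob = config$education)
  })
  fca <- config$fi_confounder_association
  sex_probs <- c(1 - config$sex_female, config$sex_female)
  sex_effects <- c(0, sm$sex_female_effect)
  z_age <- sm$age_effects - sum(config$age_groups * sm$age_effects)
  z_sex <- sex_effects - sum(sex_probs * sex_effects)
  z_edu <- sm$education_effects - sum(config$education * sm$education_effects)
  C_i <- sm$age_effects[age_i] + sex_effects[sex_i] +
    sm$education_effects[edu_i]
  tilt_i <- fca$age * z_age[age_i] + fca$sex * z_sex[sex_i] +
    fca$education * z_edu[edu_i]
  z_total_i <- z_age[age_i] + z_sex[sex_i] + z_edu[edu_i]

  # block 2: FI category
  P <- fi_probs_for_tilt(config, tilt_i)
  c1 <- P[, 1]; c2 <- c1 + P[, 2]; c3 <- c2 + P[, 3]
  withr::with_seed(sub_seed(seed, 2L), u_fi <- runif(n))
  fi_i <- 1L + (u_fi > c1) + (u_fi > c2) + (u_fi > c3)

  # block 3: total score
  mu_i <- sm$intercept + C_i + sm$fi_effects[fi_i]
  withr::with_seed(sub_seed(seed, 3L), eps <- rnorm(n, 0, sm$residual_sd))
  total <- as.integer(pmin(pmax(round(mu_i + eps), 0), 18))

  cohort <- tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    age_group = factor(names(config$age_groups)[age_i],
                       levels = names(config$age_groups)),
    sex = factor(sex_labels[sex_i], levels = sex_labels),
    education = factor(names(config$education)[edu_i],
                       levels = names(config$education)),
    fi_category = fi_factor(fi_category_labels[fi_i]),
    total_mhfii = total
  )

  # block 4: component scores (cumulative-logit draws)
  if (include_components) {
    comp_names <- names(cm$severe_log_or)
    sev_scale_i <- cm$severity_scale[fi_i]
    withr::with_seed(sub_seed(seed, 4L), {
      for (comp in comp_names) {
        eta <- sev_scale_i * cm$severe_log_or[[comp]] +
          cm$confounder_effect * z_total_i
        cuts <- cm$cutpoints[[comp]]
        u <- runif(n)
        y <- integer(n)
        for (ct in cuts) y <- y + (u > plogis(ct - eta))
        cohort[[comp]] <- as.integer(y)
      }
    })
  }

  # block 5: FFQ responses consistent with component scores
  ffq <- NULL
  if (include_ffq) {
    ffq <- scores_to_ffq(cohort, table = scoring_table,
                         item_schema = item_schema,
                         seed = sub_seed(seed, 5L))
  }

  # block 6: HFIAS patterns consistent with the drawn FI category
  hfias <- NULL
  if (include_hfias) {
    pool <- hfias_pattern_pool()
    idx <- integer(n)
    withr::with_seed(sub_seed(seed, 6L), {
      for (k in seq_along(fi_category_labels)) {
        rows <- which(fi_i == k)
        if (length(rows) == 0) next
        bank <- pool$index_by_cat[[fi_category_labels[k]]]
        idx[rows] <- bank[sample.int(length(bank), length(rows),
                                     replace = TRUE)]
      }
    })
    hfias <- tibble::as_tibble(as.data.frame(pool$patterns[idx, ,
                                                           drop = FALSE]))
    hfias <- dplyr::bind_cols(
      tibble::tibble(participant_id = cohort$participant_id), hfias
    )
  }

  # block 7: optional missingness injection (exercises exclusion policies)
  withr::with_seed(sub_seed(seed, 7L), {
    if (!is.null(ffq) && config$missing$ffq_item_rate > 0) {
      items <- setdiff(names(ffq), "participant_id")
      for (it in items) {
        blank <- runif(n) < config$missing$ffq_item_rate
        ffq[[it]][blank] <- NA_integer_
      }
    }
    if (!is.null(hfias) && config$missing$hfias_item_rate > 0) {
      for (q in hfias_question_cols) {
        blank <- runif(n) < config$missing$hfias_item_rate
        hfias[[q]][blank] <- NA_integer_
      }
    }
    if (config$missing$sociodemo_rate > 0) {
      for (col in c("age_group", "sex", "education")) {
        blank <- runif(n) < config$missing$sociodemo_rate
        cohort[[col]][blank] <- NA
      }
    }
  })

  attr(cohort, "provenance") <- list(
    package = "mhfii",
    config = unclass(config),
    seed = seed,
    note = paste(
      "total-score and component-score sub-generators are calibrated",
      "independently and are not mutually consistent; HFIAS categorisation",
      "assumes the standard decision table"
    )
  )
  if (!is.null(ffq)) attr(cohort, "ffq") <- ffq
  if (!is.null(hfias)) attr(cohort, "hfias") <- hfias
  class(cohort) <- c("synthetic_cohort", class(cohort))
  cohort
}

# per-component enumeration of item-level combinations by score band, cached
component_band_index <- function(cmp) {
  key <- paste(cmp$name, cmp$direction, paste(cmp$items, collapse = ","),
               paste(cmp$thresholds, collapse = ","), sep = "|")
  cached <- .mhfii_cache$bands[[key]]
  if (!is.null(cached)) return(cached)
  k <- length(cmp$items)
  grid <- as.matrix(expand.grid(rep(list(0:6), k), KEEP.OUT.ATTRS = FALSE))
  storage.mode(grid) <- "integer"
  weekly <- matrix(ffq_weekly_values[grid + 1L], ncol = k)
  scores <- score_component(rowSums(weekly), cmp)
  bands <- lapply(0:cmp$max_points, function(s) which(scores == s))
  empty <- which(vapply(bands, length, 0L) == 0)
  if (length(empty) > 0) {
    stop(sprintf(
      "component '%s': no item-level combination achieves score %s",
      cmp$name, paste(empty - 1L, collapse = ", ")), call. = FALSE)
  }
  out <- list(grid = grid, bands = bands)
  if (is.null(.mhfii_cache$bands)) .mhfii_cache$bands <- list()
  .mhfii_cache$bands[[key]] <- out
  out
}

#' Derive item-level FFQ responses from component scores
#'
#' For every component, samples uniformly from the member items' frequency
#' level combinations whose aggregated weekly frequency falls in the drawn
#' score's band, so that rescoring the generated FFQ reproduces the component
#' scores exactly. Items outside every component are drawn from a fixed
#' low-frequency-skewed level distribution.
#'
#' @param scores Data frame with `participant_id` and one integer column per
#'   scoring-table component.
#' @param table A `scoring_table`.
#' @param item_schema Character vector of all FFQ items.
#' @param seed RNG seed.
#' @return An `ffq_tbl` of integer level codes.
#' @export
scores_to_ffq <- function(scores, table = default_scoring_table(),
                          item_schema = default_item_schema(), seed = 1L) {
  n <- nrow(scores)
  ffq <- tibble::tibble(participant_id = as.character(scores$participant_id))
  withr::with_seed(as.integer(seed), {
    for (cmp in table$components) {
      if (!cmp$name %in% names(scores)) {
        stop(sprintf("scores lack component column '%s'", cmp$name),
             call. = FALSE)
      }
      bi <- component_band_index(cmp)
      s <- scores[[cmp$name]]
      if (any(is.na(s)) || any(s < 0 | s > cmp$max_points)) {
        stop(sprintf("invalid scores for component '%s'", cmp$name),
             call. = FALSE)
      }
      idx <- integer(n)
      for (sc in 0:cmp$max_points) {
        rows <- which(s == sc)
        if (length(rows) == 0) next
        bank <- bi$bands[[sc + 1L]]
        idx[rows] <- bank[sample.int(length(bank), length(rows),
                                     replace = TRUE)]
      }
      for (j in seq_along(cmp$items)) {
        ffq[[cmp$items[j]]] <- bi$grid[idx, j]
      }
    }
    scored_items <- unlist(lapply(table$components, `[[`, "items"))
    for (it in setdiff(item_schema, scored_items)) {
      ffq[[it]] <- sample.int(7L, n, replace = TRUE,
                              prob = c(0.25, 0.15, 0.15, 0.15,
                                       0.12, 0.12, 0.06)) - 1L
    }
  })
  ffq <- ffq[, c("participant_id", item_schema)]
  class(ffq) <- c("ffq_tbl", class(ffq))
  ffq
}
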