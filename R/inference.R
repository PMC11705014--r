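# Statistical analyses: confounder screening, one-way ANOVA with pairwise
# contrasts against the food-secure reference, covariate-adjusted (multi-way
# ANOVA) contrasts, and per-component proportional-odds regression.

fi_model_factor <- function(x, reference = "food_secure") {
  f <- factor(as.character(x), levels = fi_category_labels)
  stats::relevel(droplevels(f), ref = reference)
}

contrast_rows <- function(fit, term_prefix, labels, conf_level, family) {
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  df_res <- stats::df.residual(fit)
  terms <- paste0(term_prefix, labels)
  alpha <- (1 - conf_level) / family
  crit <- qt(1 - alpha / 2, df_res)
  out <- lapply(seq_along(labels), function(i) {
    b <- est[[terms[i]]]
    s <- se[[terms[i]]]
    if (s == 0) {
      p <- as.numeric(b != 0)
    } else {
      p <- 2 * pt(-abs(b / s), df_res)
    }
    tibble::tibble(
      comparison = paste0(labels[i], " vs food_secure"),
      estimate = b,
      conf.low = b - crit * s,
      conf.high = b + crit * s,
      p.value = pmin(1, p * family)
    )
  })
  dplyr::bind_rows(out)
}

#' One-way ANOVA of mHFII totals across food-insecurity levels
#'
#' Omnibus F test followed by pairwise mean differences of each FI level
#' against the food-secure reference, with Bonferroni-corrected confidence
#' intervals and p-values (family = number of non-reference levels by
#' default). Rows missing the outcome or group are excluded first (listwise
#' deletion).
#'
#' @param data Data frame with the outcome and group columns.
#' @param outcome,group Column names (defaults `total_mhfii`,
#'   `fi_category`).
#' @param reference Reference group level.
#' @param conf_level Confidence level before correction.
#' @param family Bonferroni family size; defaults to the number of
#'   comparisons.
#' @return A list of class `fi_contrasts`: `contrasts` tibble (estimate,
#'   corrected CI and p per level), `omnibus` (F statistic, dfs, p),
#'   `group_means`, `n_used`, `n_excluded`, `adjusted = FALSE`.
#' @export
anova_oneway <- function(data, outcome = "total_mhfii",
                         group = "fi_category",
                         reference = "food_secure",
                         conf_level = 0.95, family = NULL) {
  keep <- !is.na(data[[outcome]]) & !is.na(data[[group]])
  n_excluded <- sum(!keep)
  df <- data[keep, , drop = FALSE]
  g <- fi_model_factor(df[[group]], reference)
  y <- as.numeric(df[[outcome]])
  counts <- table(g)
  if (length(counts) < 2) stop("need at least two groups", call. = FALSE)
  small <- names(counts)[counts < 2]
  if (length(small) > 0) {
    stop(sprintf("group(s) with fewer than 2 observations after deletion: %s",
                 paste(small, collapse = ", ")), call. = FALSE)
  }
  fit <- lm(y ~ g)
  an <- anova(fit)
  labels <- setdiff(levels(g), reference)
  family <- family %||% length(labels)
  contrasts <- contrast_rows(fit, "g", labels, conf_level, family)
  contrasts$n_reference <- as.integer(counts[[reference]])
  contrasts$n_comparison <- as.integer(counts[labels])
  contrasts$adjusted <- FALSE
  group_means <- tibble::tibble(
    group = names(counts),
    n = as.integer(counts),
    mean = as.numeric(tapply(y, g, mean)),
    sd = as.numeric(tapply(y, g, sd))
  )
  structure(list(
    contrasts = contrasts,
    omnibus = list(statistic = an$`F value`[1], df1 = an$Df[1],
                   df2 = an$Df[2], p.value = an$`Pr(>F)`[1]),
    group_means = group_means,
    n_used = nrow(df), n_excluded = n_excluded,
    adjusted = FALSE
  ), class = "fi_contrasts")
}

#' Covariate-adjusted (multi-way ANOVA) contrasts
#'
#' Linear model with the FI category and categorical covariates as main
#' effects (no interactions); adjusted mean differences of each FI level
#' against the food-secure reference with Bonferroni-corrected CIs.
#'
#' @inheritParams anova_oneway
#' @param covariates Character vector of categorical covariate columns
#'   (default age group, sex, education).
#' @return A list of class `fi_contrasts` (as [anova_oneway()], with
#'   `adjusted = TRUE` and a `covariates` field).
#' @export
anova_adjusted <- function(data, outcome = "total_mhfii",
                           group = "fi_category",
                           covariates = c("age_group", "sex", "education"),
                           reference = "food_secure",
                           conf_level = 0.95, family = NULL) {
  used <- c(outcome, group, covariates)
  keep <- complete.cases(data[, used, drop = FALSE])
  n_excluded <- sum(!keep)
  df <- data[keep, , drop = FALSE]
  g <- fi_model_factor(df[[group]], reference)
  y <- as.numeric(df[[outcome]])
  model_df <- data.frame(y = y, g = g)
  for (cv in covariates) model_df[[cv]] <- droplevels(factor(df[[cv]]))
  fml <- stats::as.formula(paste("y ~ g +", paste(covariates, collapse = " + ")))
  fit <- lm(fml, data = model_df)
  if (anyNA(coef(fit))) {
    stop(sprintf("singular design; aliased term(s): %s",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
         call. = FALSE)
  }
  counts <- table(g)
  labels <- setdiff(levels(g), reference)
  family <- family %||% length(labels)
  contrasts <- contrast_rows(fit, "g", labels, conf_level, family)
  contrasts$n_reference <- as.integer(counts[[reference]])
  contrasts$n_comparison <- as.integer(counts[labels])
  contrasts$adjusted <- TRUE
  structure(list(
    contrasts = contrasts,
    omnibus = NULL,
    group_means = NULL,
    covariates = covariates,
    n_used = nrow(df), n_excluded = n_excluded,
    adjusted = TRUE
  ), class = "fi_contrasts")
}

#' Proportional-odds regression of a food-group score on severe food
#' insecurity
#'
#' Restricts the sample to the severe-FI and food-secure groups and fits a
#' cumulative-logit proportional-odds model of the ordinal component score
#' (2--3 levels) on the exposure, optionally adjusted for categorical
#' covariates. The exponentiated exposure coefficient is the odds ratio of a
#' severely food-insecure participant achieving a *higher* (more optimal)
#' score. Binary outcomes are fitted by logistic regression, to which the
#' proportional-odds model reduces. Wald 95 % confidence intervals on the
#' log-odds scale. Quasi-separated fits are flagged and their CIs reported as
#' unavailable rather than fabricated.
#'
#' @param data Data frame containing the component score and exposure.
#' @param component Column name of the ordinal outcome.
#' @param exposure FI-category column (default `fi_category`).
#' @param covariates Character vector of categorical covariates (possibly
#'   empty).
#' @param exposure_levels The two groups compared (reference first).
#' @param conf_level Confidence level.
#' @return A one-row tibble of class `ordinal_effect`: `component`,
#'   `odds_ratio`, `conf.low`, `conf.high`, `p.value`, `n`, `n_levels`,
#'   `separation`.
#' @export
fit_proportional_odds <- function(data, component,
                                  exposure = "fi_category",
                                  covariates = character(),
                                  exposure_levels = c("food_secure", "severe"),
                                  conf_level = 0.95) {
  used <- c(component, exposure, covariates)
  keep <- complete.cases(data[, used, drop = FALSE]) &
    as.character(data[[exposure]]) %in% exposure_levels
  df <- data[keep, , drop = FALSE]
  x <- factor(as.character(df[[exposure]]), levels = exposure_levels)
  y <- if (is.factor(df[[component]])) df[[component]] else
    factor(df[[component]])
  observed <- levels(droplevels(y))
  if (length(observed) < length(levels(y))) {
    warning(sprintf("component '%s': unobserved outcome level(s) dropped",
                    component), call. = FALSE)
  }
  y <- droplevels(y)
  if (nlevels(y) < 2) {
    stop(sprintf("component '%s': outcome has fewer than 2 observed levels",
                 component), call. = FALSE)
  }
  model_df <- data.frame(.y = y, .x = x)
  for (cv in covariates) model_df[[cv]] <- droplevels(factor(df[[cv]]))
  rhs <- paste(c(".x", covariates), collapse = " + ")
  if (nlevels(y) == 2) {
    fml <- stats::as.formula(paste(".y ~", rhs))
    fit <- stats::glm(fml, data = model_df, family = stats::binomial())
    term <- paste0(".x", exposure_levels[2])
    beta <- coef(fit)[[term]]
    se <- sqrt(diag(vcov(fit)))[[term]]
  } else {
    fml <- stats::as.formula(paste("ordered(.y) ~", rhs))
    fit <- MASS::polr(fml, data = model_df, Hess = TRUE)
    term <- paste0(".x", exposure_levels[2])
    beta <- coef(fit)[[term]]
    se <- sqrt(diag(vcov(fit)))[[term]]
  }
  separation <- !is.finite(se) || se > 10 || abs(beta) > 10
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- tibble::tibble(
    component = component,
    odds_ratio = exp(beta),
    conf.low = if (separation) NA_real_ else exp(beta - z * se),
    conf.high = if (separation) NA_real_ else exp(beta + z * se),
    p.value = if (separation) NA_real_ else 2 * pnorm(-abs(beta / se)),
    n = nrow(df),
    n_levels = nlevels(y),
    separation = separation
  )
  class(out) <- c("ordinal_effect", class(out))
  out
}

cramers_v <- function(a, b) {
  tab <- table(a, b)
  if (min(dim(tab)) < 2) return(NA_real_)
  chi <- suppressWarnings(chisq.test(tab, correct = FALSE))
  sqrt(as.numeric(chi$statistic) / (sum(tab) * (min(dim(tab)) - 1)))
}

assoc_p <- function(x, y_factor) {
  # association p-value between a candidate (factor or numeric) and a factor
  if (is.numeric(x)) {
    fit <- lm(x ~ y_factor)
    stats::anova(fit)$`Pr(>F)`[1]
  } else {
    suppressWarnings(chisq.test(table(x, y_factor))$p.value)
  }
}

#' Screen candidate confounders
#'
#' Retains candidates that (i) are associated with both the FI category
#' (chi-square for categorical candidates, ANOVA for numeric) and the mHFII
#' total (ANOVA / correlation test) at `alpha`; (ii) change the severe-FI
#' mean-difference estimate by more than `change_threshold` (relative) when
#' added to the model alongside already-selected confounders; and (iii) have
#' association below `correlation_threshold` (Cramer's V, or |r| for numeric
#' pairs) with every already-selected confounder. Candidates are examined in
#' the given order; a per-criterion report is returned.
#'
#' @param data Data frame.
#' @param candidates Character vector of candidate columns.
#' @param fi,outcome FI-category and outcome columns.
#' @param severe_level FI level whose estimate the change criterion tracks.
#' @param alpha Significance level for the association criteria.
#' @param change_threshold Relative change-in-estimate threshold.
#' @param correlation_threshold Maximum pairwise association with selected
#'   confounders.
#' @return A list with `selected` (character) and `report` (tibble, one row
#'   per candidate with each criterion's value and verdict).
#' @export
screen_confounders <- function(data, candidates, fi = "fi_category",
                               outcome = "total_mhfii",
                               severe_level = "severe", alpha = 0.05,
                               change_threshold = 0.10,
                               correlation_threshold = 0.6) {
  keep <- complete.cases(data[, c(fi, outcome, candidates), drop = FALSE])
  df <- data[keep, , drop = FALSE]
  g <- fi_model_factor(df[[fi]])
  y <- as.numeric(df[[outcome]])
  severe_term <- paste0("g", severe_level)
  selected <- character()
  model_df <- data.frame(y = y, g = g)
  base_fit <- lm(y ~ g, data = model_df)
  rows <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    cand <- candidates[i]
    x <- df[[cand]]
    if (!is.numeric(x)) x <- droplevels(factor(x))
    n_levels <- if (is.numeric(x)) Inf else nlevels(x)
    if (!is.numeric(x) && n_levels < 2) {
      warning(sprintf("candidate '%s' has a single level; skipped", cand),
              call. = FALSE)
      rows[[i]] <- tibble::tibble(
        candidate = cand, p_fi = NA_real_, p_outcome = NA_real_,
        change_in_estimate = NA_real_, max_assoc_selected = NA_real_,
        selected = FALSE, reason = "single level"
      )
      next
    }
    p_fi <- assoc_p(x, g)
    p_out <- if (is.numeric(x)) {
      stats::cor.test(x, y)$p.value
    } else {
      stats::anova(lm(y ~ x))$`Pr(>F)`[1]
    }
    model_df[[cand]] <- x
    base_terms <- c("g", selected)
    fit0 <- lm(stats::as.formula(
      paste("y ~", paste(base_terms, collapse = " + "))), data = model_df)
    fit1 <- lm(stats::as.formula(
      paste("y ~", paste(c(base_terms, cand), collapse = " + "))),
      data = model_df)
    b0 <- coef(fit0)[[severe_term]]
    b1 <- coef(fit1)[[severe_term]]
    change <- abs(b1 - b0) / max(abs(b0), 1e-12)
    max_assoc <- if (length(selected) == 0) 0 else {
      max(vapply(selected, function(s) {
        xs <- model_df[[s]]
        if (is.numeric(x) && is.numeric(xs)) {
          abs(cor(x, xs))
        } else if (!is.numeric(x) && !is.numeric(xs)) {
          cramers_v(x, xs)
        } else {
          num <- if (is.numeric(x)) x else xs
          fac <- if (is.numeric(x)) xs else x
          sqrt(max(summary(lm(num ~ fac))$r.squared, 0))
        }
      }, 0))
    }
    pass <- !is.na(p_fi) && p_fi < alpha && p_out < alpha &&
      change > change_threshold &&
      (is.na(max_assoc) || max_assoc < correlation_threshold)
    reason <- if (pass) "selected" else if (is.na(p_fi) || p_fi >= alpha) {
      "not associated with FI"
    } else if (p_out >= alpha) {
      "not associated with outcome"
    } else if (!is.na(max_assoc) && max_assoc >= correlation_threshold) {
      "collinear with selected confounder"
    } else {
      "change in estimate below threshold"
    }
    if (pass) selected <- c(selected, cand)
    rows[[i]] <- tibble::tibble(
      candidate = cand, p_fi = p_fi, p_outcome = p_out,
      change_in_estimate = change, max_assoc_selected = max_assoc,
      selected = pass, reason = reason
    )
  }
  list(selected = selected, report = dplyr::bind_rows(rows))
}

#' Run the full food-insecurity / diet-quality analysis
#'
#' Executes the analysis pipeline on a scored cohort: listwise exclusion of
#' missing data, optional confounder screening report, one-way ANOVA with
#' pairwise contrasts against the food-secure reference, covariate-adjusted
#' contrasts, and one proportional-odds model per index component comparing
#' severe FI with food security, adjusted for the covariates.
#'
#' @param cohort Data frame with `fi_category`, `total_mhfii`, the covariate
#'   columns and one column per component.
#' @param scoring_table Scoring table naming the components to model.
#' @param covariates Adjustment set for the multi-way ANOVA and the
#'   proportional-odds models (default age group, sex, education -- the
#'   hypothesis-driven key confounders; the screening report is informational).
#' @param screen_candidates Optional candidate columns for
#'   [screen_confounders()].
#' @param conf_level Confidence level (significance level 0.05).
#' @return A list of class `fi_analysis`: `unadjusted`, `adjusted`
#'   (`fi_contrasts`), `ordinal_effects` (one row per component; a Fig.-1
#'   style forest-plot table), `screening`, and an `n` block (total, excluded,
#'   used).
#' @export
run_full_analysis <- function(cohort,
                              scoring_table = default_scoring_table(),
                              covariates = c("age_group", "sex", "education"),
                              screen_candidates = NULL,
                              conf_level = 0.95) {
  comp_names <- names(scoring_table$components)
  missing_cols <- setdiff(c("fi_category", "total_mhfii", covariates,
                            comp_names), names(cohort))
  if (length(missing_cols) > 0) {
    stop(sprintf("cohort lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  required <- c("fi_category", "total_mhfii", covariates)
  keep <- complete.cases(cohort[, required, drop = FALSE])
  analysed <- cohort[keep, , drop = FALSE]
  screening <- NULL
  if (!is.null(screen_candidates)) {
    screening <- screen_confounders(analysed, screen_candidates)
  }
  unadj <- anova_oneway(analysed, conf_level = conf_level)
  adj <- anova_adjusted(analysed, covariates = covariates,
                        conf_level = conf_level)
  ord <- dplyr::bind_rows(lapply(comp_names, function(cn) {
    fit_proportional_odds(analysed, cn, covariates = covariates,
                          conf_level = conf_level)
  }))
  structure(list(
    unadjusted = unadj,
    adjusted = adj,
    ordinal_effects = ord,
    screening = screening,
    covariates = covariates,
    n = list(total = nrow(cohort), excluded = sum(!keep),
             used = nrow(analysed))
  ), class = "fi_analysis")
}

#' @export
print.fi_analysis <- function(x, ...) {
  cat("Food insecurity / diet quality analysis\n")
  cat(sprintf("  n = %d (%d excluded for missing data)\n",
              x$n$used, x$n$excluded))
  cat("\nUnadjusted mean differences vs food secure (Bonferroni):\n")
  print(x$unadjusted$contrasts[, c("comparison", "estimate", "conf.low",
                                   "conf.high", "p.value")])
  cat(sprintf("\nAdjusted for %s:\n", paste(x$covariates, collapse = ", ")))
  print(x$adjusted$contrasts[, c("comparison", "estimate", "conf.low",
                                 "conf.high", "p.value")])
  cat("\nProportional-odds ORs, severe FI vs food secure (adjusted):\n")
  print(x$ordinal_effects[, c("component", "odds_ratio", "conf.low",
                              "conf.high", "n")])
  invisible(x)
}
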