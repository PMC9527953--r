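#' Configuration for the synthetic cohort generator
#'
#' The defaults state a hospital-employee world calibrated to the cohort the
#' package is designed for: ~79% women, 35% part-time, eight occupational
#' groups dominated by nurses, an overall sickness absence rate of 4% of fixed
#' working hours decomposing 37/32/31 into short-, intermediate- and long-term
#' hours, and ~15.3% of employees with incomplete exposure data under a
#' missing-at-random mechanism. Default true effects are multiplicative
#' most-vs-least-desirable rate ratios per factor (bullying 0.86, perceived
#' stress 0.90, skill discretion 0.91, all other factors 0.97; product ~0.46).
#'
#' @param n_employees cohort size.
#' @param true_effects named vector of per-factor most-vs-least-desirable rate
#'   ratios (strictly positive). Unnamed scalar recycles to every factor;
#'   factors not named default to 1 (no effect); `NULL` uses the calibrated
#'   defaults above.
#' @param baseline_rate target expected absence-hours per fixed working hour.
#' @param term_split nonnegative shares of expected absence *hours* falling in
#'   the short/intermediate/long terms; must sum to 1.
#' @param covariate_mix distribution settings for the sociodemographic and
#'   employment covariates (see Details in the package vignette).
#' @param exposure_structure latent structure of the ordinal items:
#'   `latent_correlation` (inter-item correlation within a factor, in `[0,1)`),
#'   `covariate_loading` (loading of the factor latent on the adversity
#'   composite of covariates), `binary_prevalence` (named Yes-prevalences for
#'   the binary adversities), `binary_loading`.
#' @param outcome_effects log-rate covariate coefficients of the generating
#'   model, plus `workplace_sd` for random workplace effects.
#' @param spell_durations within-term duration means (days): intermediate and
#'   long spells are offset + truncated-geometric; short spells are uniform on
#'   1-3 days. Long spells are capped at 365 days.
#' @param hours `full_time_daily` contracted hours/day (default 7.4),
#'   `working_days` in the one-year follow-up, `part_time_range` of the
#'   part-time hours fraction.
#' @param missingness MAR mechanism: `target_share` of incomplete employees
#'   and logistic `coefficients` on covariates (names among `part_time`,
#'   `men`, `married`, `age_z`, `income_z`, `seniority_z`); the intercept is
#'   calibrated to the target share by [inject_missingness()].
#' @param prior_absence prevalences and severity slope for prior-year absence
#'   indicators (used by the prior-absence sensitivity adjustment).
#' @param factors named list of [factor_definition()]s (default all 17).
#' @param seed integer master seed.
#' @return object of class `sa_config`.
#' @export
cohort_config <- function(n_employees = 25000,
                          true_effects = NULL,
                          baseline_rate = 0.04,
                          term_split = c(short = 0.37, intermediate = 0.32, long = 0.31),
                          covariate_mix = list(),
                          exposure_structure = list(),
                          outcome_effects = list(),
                          spell_durations = list(),
                          hours = list(),
                          missingness = list(),
                          prior_absence = list(),
                          factors = default_factor_definitions(),
                          seed = 1L) {
  assert_that(is_scalar_number(n_employees) && n_employees >= 1,
              "n_employees must be a positive count")
  assert_that(abs(sum(term_split) - 1) < 1e-12, "term_split must sum to 1")
  assert_that(all(term_split >= 0), "term_split shares must be nonnegative")
  ids <- factor_ids(factors)

  te <- rep(1, length(ids)); names(te) <- ids
  if (is.null(true_effects)) {
    te[] <- 0.97
    for (nm in c("bullying", "perceived_stress", "skill_discretion")) {
      if (nm %in% ids) te[nm] <- c(bullying = 0.86, perceived_stress = 0.90,
                                   skill_discretion = 0.91)[nm]
    }
  } else if (is.null(names(true_effects))) {
    assert_that(length(true_effects) == 1 || length(true_effects) == length(ids),
                "unnamed true_effects must be scalar or one per factor")
    te[] <- true_effects
  } else {
    unknown <- setdiff(names(true_effects), ids)
    assert_that(length(unknown) == 0,
                paste0("true_effects name(s) not among factors: ",
                       paste(unknown, collapse = ", ")))
    te[names(true_effects)] <- true_effects
  }
  assert_that(all(te > 0), "all true_effects must be strictly positive")

  defaults <- function(user, def) utils::modifyList(def, user)
  cm <- defaults(covariate_mix, list(
    sex_women = 0.79, age_mean = 45, age_sd = 11, age_range = c(18, 69),
    marital_married = 0.56, income_meanlog = log(300), income_sdlog = 0.35,
    occ_groups = c("Physicians" = 0.11, "Nurses" = 0.34,
                   "Social and health care" = 0.07, "Other health care" = 0.16,
                   "Pedagogical" = 0.03, "Service and technical" = 0.10,
                   "Administrative leaders" = 0.02, "Administrative employees" = 0.17),
    seniority_mean = 8, part_time_share = 0.35, n_workplaces = 20L))
  ex <- defaults(exposure_structure, list(
    latent_correlation = 0.5, covariate_loading = 0.3,
    binary_prevalence = c(bullying = 0.08, sexual_harassment = 0.03,
                          threats = 0.07, violence = 0.06),
    binary_loading = 0.8))
  assert_that(ex$latent_correlation >= 0 && ex$latent_correlation < 1,
              "latent_correlation must be in [0,1)")
  oe <- defaults(outcome_effects, list(
    women = 0.25, age_z = 0.05, married = -0.15, income_z = -0.15,
    seniority_z = -0.03, part_time = 0.30,
    occ = c("Physicians" = -0.55, "Nurses" = 0.05, "Social and health care" = 0.35,
            "Other health care" = -0.05, "Pedagogical" = 0.20,
            "Service and technical" = 0.15, "Administrative leaders" = -0.70,
            "Administrative employees" = -0.05),
    workplace_sd = 0.10))
  sd_ <- defaults(spell_durations, list(intermediate_mean = 8, long_mean = 45))
  hr <- defaults(hours, list(full_time_daily = 7.4, working_days = 226,
                             part_time_range = c(0.4, 0.95)))
  ms <- defaults(missingness, list(
    target_share = 0.153,
    coefficients = c(part_time = 0.4, men = 0.2, age_z = -0.1)))
  pa <- defaults(prior_absence, list(
    base_prev = c(short = 0.45, intermediate = 0.20, long = 0.08), slope = 0.5))

  structure(list(n_employees = as.integer(n_employees), true_effects = te,
                 baseline_rate = baseline_rate, term_split = term_split,
                 covariate_mix = cm, exposure_structure = ex,
                 outcome_effects = oe, spell_durations = sd_, hours = hr,
                 missingness = ms, prior_absence = pa, factors = factors,
                 seed = as.integer(seed)),
            class = "sa_config")
}

#' @export
print.sa_config <- function(x, ...) {
  cat(sprintf("<cohort config> n = %d, %d factors, baseline rate %.3f, seed %d\n",
              x$n_employees, length(x$factors), x$baseline_rate, x$seed))
  invisible(x)
}

# truncated geometric on 0..max_extra -----------------------------------------
tg_probs <- function(mean_extra, max_extra) {
  p <- 1 / (1 + mean_extra)
  pr <- stats::dgeom(0:max_extra, p)
  pr / sum(pr)
}
# exact mean of the truncated geometric support
tg_mean <- function(probs) sum((seq_along(probs) - 1) * probs)

#' Generate a synthetic employee cohort with recorded ground truth
#'
#' Draws covariates per the configured mix; generates ordinal exposure items
#' by thresholding correlated Gaussian latents (Gaussian-copula style, equal
#' probability bins) shifted by a covariate adversity composite; generates the
#' four binary adversities as Bernoulli with covariate-dependent logits;
#' scores and categorizes factors exactly as the analysis does; and draws
#' absence spells from a compound-Poisson process whose expected hours follow
#' the log-linear model `fixed_hours x baseline_rate x exp(covariate effects)
#' x prod(RR_f ^ s_f)` where `s_f` is the desirability score of the employee's
#' realized level (High/No = 1, Medium = 0.5, Low/Yes = 0). Expected absence
#' hours split across terms by `term_split`; spell durations are drawn within
#' the term's 1-3 / 4-28 / 29-365 day support, so spells always classify into
#' the intended term and per-employee term hours sum exactly to total hours.
#'
#' The generating intercept is calibrated so the *expected* overall rate
#' equals `baseline_rate` exactly; the ground-truth object records everything
#' needed to compute any scenario contrast analytically.
#'
#' @param config an [cohort_config()] object.
#' @return list with elements `cohort` (class `sa_cohort`: `employees`,
#'   `spells`, `factors`, `config`) and `truth` (class `sa_truth`).
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "sa_config"), "config must come from cohort_config()")
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_employees
  cm <- config$covariate_mix
  ex <- config$exposure_structure
  oe <- config$outcome_effects

  # --- covariates ------------------------------------------------------------
  sex <- factor(ifelse(stats::runif(n) < cm$sex_women, "Women", "Men"),
                levels = c("Women", "Men"))
  age <- pmin(pmax(stats::rnorm(n, cm$age_mean, cm$age_sd), cm$age_range[1]),
              cm$age_range[2])
  marital <- factor(ifelse(stats::runif(n) < cm$marital_married,
                           "Married", "Unmarried"),
                    levels = c("Married", "Unmarried"))
  income <- stats::rlnorm(n, cm$income_meanlog, cm$income_sdlog)
  occ <- factor(sample(names(cm$occ_groups), n, replace = TRUE,
                       prob = cm$occ_groups), levels = names(cm$occ_groups))
  seniority <- pmin(stats::rexp(n, 1 / cm$seniority_mean), pmax(age - 18, 0.5))
  part_time <- stats::runif(n) < cm$part_time_share
  employment <- factor(ifelse(part_time, "Part-time", "Full-time"),
                       levels = c("Full-time", "Part-time"))
  workplace <- factor(sprintf("W%02d", sample.int(cm$n_workplaces, n, replace = TRUE)),
                      levels = sprintf("W%02d", seq_len(cm$n_workplaces)))
  daily_hours <- ifelse(part_time,
                        config$hours$full_time_daily *
                          stats::runif(n, config$hours$part_time_range[1],
                                       config$hours$part_time_range[2]),
                        config$hours$full_time_daily)
  fixed_hours <- config$hours$working_days * daily_hours

  age_z <- (age - cm$age_mean) / cm$age_sd
  income_z <- (log(income) - cm$income_meanlog) / cm$income_sdlog
  seniority_z <- (seniority - cm$seniority_mean) / cm$seniority_mean

  # adversity composite driving both exposures and missingness realism
  occ_sev <- c("Physicians" = -0.5, "Nurses" = 0, "Social and health care" = 0.6,
               "Other health care" = 0, "Pedagogical" = 0.3,
               "Service and technical" = 0.4, "Administrative leaders" = -0.6,
               "Administrative employees" = -0.1)
  comp <- 0.5 * part_time + occ_sev[as.character(occ)] - 0.3 * income_z
  comp <- as.numeric(scale(comp))

  employees <- data.frame(id = seq_len(n), age = age, sex = sex,
                          marital = marital, income = income, occ_group = occ,
                          seniority = seniority, employment = employment,
                          workplace = workplace, daily_hours = daily_hours,
                          fixed_hours = fixed_hours, complete = TRUE)

  # --- exposure items --------------------------------------------------------
  rho <- ex$latent_correlation
  a <- ex$covariate_loading
  for (f in config$factors) {
    if (f$kind == "binary") {
      prev <- ex$binary_prevalence[[f$id]] %||% 0.05
      p_yes <- stats::plogis(stats::qlogis(prev) + ex$binary_loading * comp)
      employees[[f$items[[1]]]] <- stats::rbinom(n, 1, p_yes)
    } else {
      u <- -a * comp + sqrt(1 - a^2) * stats::rnorm(n)  # high latent = desirable
      for (j in seq_along(f$items)) {
        K <- f$points[j]
        z <- sqrt(rho) * u + sqrt(1 - rho) * stats::rnorm(n)
        resp <- findInterval(stats::pnorm(z), (1:(K - 1)) / K) + 1L
        if (f$reversed[j]) resp <- K + 1L - resp
        employees[[f$items[j]]] <- resp
      }
    }
  }

  # --- realized exposure levels & desirability scores ------------------------
  exposure <- build_exposure_matrix(employees, config$factors)
  s <- desirability_scores(exposure$levels, config$factors)

  # --- generating rates ------------------------------------------------------
  wp_eff <- stats::rnorm(cm$n_workplaces, 0, oe$workplace_sd)
  cov_lp <- oe$women * (sex == "Women") + oe$age_z * age_z +
    oe$married * (marital == "Married") + oe$income_z * income_z +
    oe$seniority_z * seniority_z + oe$part_time * part_time +
    oe$occ[as.character(occ)] + wp_eff[as.integer(workplace)]
  log_rr <- log(config$true_effects)
  rel <- exp(cov_lp + as.numeric(s %*% log_rr))
  norm <- sum(fixed_hours) / sum(fixed_hours * rel)
  base_rate <- config$baseline_rate * exp(cov_lp) * norm  # excl. factor terms
  mu_rate <- base_rate * exp(as.numeric(s %*% log_rr))    # expected hours per fixed-hour
  mu_hours <- mu_rate * fixed_hours

  # --- spells ----------------------------------------------------------------
  sdur <- config$spell_durations
  p_int <- tg_probs(sdur$intermediate_mean - 4, 24)
  p_long <- tg_probs(sdur$long_mean - 29, 336)
  term_mean_days <- c(short = 2,
                      intermediate = 4 + tg_mean(p_int),
                      long = 29 + tg_mean(p_long))
  spells <- list()
  for (tt in names(config$term_split)) {
    exp_hours_t <- mu_hours * config$term_split[[tt]]
    lam <- exp_hours_t / (term_mean_days[[tt]] * daily_hours)
    k <- stats::rpois(n, lam)
    tot <- sum(k)
    if (tot == 0) next
    dur <- switch(tt,
      short = sample(1:3, tot, replace = TRUE),
      intermediate = 4L + sample(0:24, tot, replace = TRUE, prob = p_int),
      long = 29L + sample(0:336, tot, replace = TRUE, prob = p_long))
    ids <- rep(employees$id, k)
    spells[[tt]] <- data.frame(id = ids, duration_days = dur,
                               hours = dur * rep(daily_hours, k))
  }
  spells <- if (length(spells)) do.call(rbind, spells) else
    data.frame(id = integer(), duration_days = integer(), hours = numeric())
  spells <- spells[order(spells$id, spells$duration_days), , drop = FALSE]
  rownames(spells) <- NULL

  # --- prior-year absence indicators (sensitivity adjustment) ----------------
  pa <- config$prior_absence
  sev <- as.numeric(scale(log(mu_rate)))
  for (tt in names(pa$base_prev)) {
    p <- stats::plogis(stats::qlogis(pa$base_prev[[tt]]) + pa$slope * sev)
    employees[[paste0("prior_", tt)]] <- stats::rbinom(n, 1, p)
  }

  truth <- structure(list(
    factor_ids = factor_ids(config$factors),
    terms = c("total", "short", "intermediate", "long"),
    rr = matrix(rep(config$true_effects, 4), ncol = 4,
                dimnames = list(names(config$true_effects),
                                c("total", "short", "intermediate", "long"))),
    s = s, base_rate = base_rate, fixed_hours = fixed_hours,
    term_split = config$term_split,
    coefficients = list(covariates = unlist(oe[c("women", "age_z", "married",
                                                 "income_z", "seniority_z",
                                                 "part_time")]),
                        occ = oe$occ, workplace = wp_eff,
                        baseline_rate = config$baseline_rate,
                        normalization = norm),
    missingness = NULL), class = "sa_truth")

  cohort <- structure(list(employees = employees, spells = spells,
                           factors = config$factors, config = config),
                      class = "sa_cohort")
  list(cohort = cohort, truth = truth)
}

#' @export
print.sa_cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d employees, %d spells, %d factors; %d (%.1f%%) incomplete\n",
              nrow(x$employees), nrow(x$spells), length(x$factors),
              sum(!x$employees$complete), 100 * mean(!x$employees$complete)))
  invisible(x)
}

#' @export
print.sa_truth <- function(x, ...) {
  cat(sprintf("<ground truth> %d factors x %d terms; joint etiologic RR (total) = %.4f\n",
              nrow(x$rr), ncol(x$rr), prod(x$rr[, "total"])))
  invisible(x)
}

#' Desirability scores of realized exposure levels
#'
#' High/No = 1, Medium = 0.5, Low/Yes = 0 per factor.
#' @noRd
desirability_scores <- function(levels_df, factors) {
  s <- sapply(factors, function(f) {
    v <- levels_df[[f$id]]
    if (f$kind == "binary") ifelse(v == "No", 1, 0)
    else ifelse(v == "High", 1, ifelse(v == "Medium", 0.5, 0))
  })
  s <- matrix(s, nrow = nrow(levels_df),
              dimnames = list(NULL, factor_ids(factors)))
  s
}

#' Inject missing-at-random exposure data
#'
#' Selects employees for incompleteness with probability
#' `plogis(intercept + coefficients . covariates)`, where the intercept is
#' calibrated by root finding so the expected incomplete share equals the
#' configured target; sets *all* their exposure items to missing (all-or-none
#' missingness, matching a person-level complete-case definition) and updates
#' the completeness flag. A zero target returns the cohort unchanged.
#'
#' @param generated output of [generate_cohort()] (list with `cohort`,
#'   `truth`) or an `sa_cohort`.
#' @param config optional [cohort_config()]; defaults to the cohort's own.
#' @return same shape as the input, with missingness injected and the solved
#'   logistic model recorded in `truth$missingness` (when truth is present).
#' @export
inject_missingness <- function(generated, config = NULL) {
  has_truth <- !inherits(generated, "sa_cohort")
  cohort <- if (has_truth) generated$cohort else generated
  config <- config %||% cohort$config
  ms <- config$missingness
  item_cols <- unlist(lapply(cohort$factors, `[[`, "items"))
  assert_that(!anyNA(cohort$employees[item_cols]),
              "cohort already has missing exposure items")
  if (ms$target_share <= 0) return(generated)

  set.seed(derive_seed(config$seed, 2L))
  lp <- missingness_lp(cohort$employees, ms$coefficients, config)
  f <- function(a) mean(stats::plogis(a + lp)) - ms$target_share
  intercept <- stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
  p_inc <- stats::plogis(intercept + lp)
  inc <- stats::runif(nrow(cohort$employees)) < p_inc

  cohort$employees[inc, item_cols] <- NA
  cohort$employees$complete <- !inc
  model <- list(intercept = intercept, coefficients = ms$coefficients,
                target_share = ms$target_share)
  if (has_truth) {
    generated$cohort <- cohort
    generated$truth$missingness <- model
    generated
  } else cohort
}

#' @noRd
missingness_lp <- function(emp, coefs, config) {
  cm <- config$covariate_mix
  X <- cbind(part_time = as.numeric(emp$employment == "Part-time"),
             men = as.numeric(emp$sex == "Men"),
             married = as.numeric(emp$marital == "Married"),
             age_z = (emp$age - cm$age_mean) / cm$age_sd,
             income_z = (log(emp$income) - cm$income_meanlog) / cm$income_sdlog,
             seniority_z = (emp$seniority - cm$seniority_mean) / cm$seniority_mean)
  unknown <- setdiff(names(coefs), colnames(X))
  assert_that(length(unknown) == 0,
              paste0("unknown missingness covariate(s): ",
                     paste(unknown, collapse = ", ")))
  if (length(coefs) == 0) return(rep(0, nrow(emp)))
  as.numeric(X[, names(coefs), drop = FALSE] %*% coefs)
}

#' Ground-truth rate ratio between two scenarios
#'
#' Computes the generating-model rate ratio between two intervention
#' scenarios by exact enumeration over the generated cohort: each employee's
#' counterfactual rate is `base_rate x prod(RR_f ^ s'_f)` with `s'_f` set to 1
#' (most desirable), 0 (least desirable) or the observed desirability score,
#' standardized by fixed working hours. For pure most-vs-least contrasts this
#' reduces to the analytic product of per-factor RRs.
#'
#' @param truth an `sa_truth` object.
#' @param scenario_pair list of two [intervention_scenario()]s
#'   (numerator, denominator).
#' @param term one of `"total"`, `"short"`, `"intermediate"`, `"long"`.
#' @return the true rate ratio, with attributes `method` and `n`.
#' @export
ground_truth_rr <- function(truth, scenario_pair, term = "total") {
  assert_that(inherits(truth, "sa_truth"), "truth must be an sa_truth")
  assert_that(term %in% truth$terms, "unknown outcome term")
  rate <- function(scn) {
    sprime <- truth$s
    for (fid in names(scn$rules)) {
      assert_that(fid %in% truth$factor_ids, paste0("unknown factor: ", fid))
      sprime[, fid] <- switch(scn$rules[[fid]],
                              most_desirable = 1,
                              least_desirable = 0,
                              observed = truth$s[, fid])
    }
    lr <- log(truth$rr[, term])
    sum(truth$fixed_hours * truth$base_rate * exp(as.numeric(sprime %*% lr))) /
      sum(truth$fixed_hours)
  }
  out <- rate(scenario_pair[[1]]) / rate(scenario_pair[[2]])
  attr(out, "method") <- "exact_enumeration"
  attr(out, "n") <- length(truth$fixed_hours)
  out
}
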