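#' Configuration of an end-to-end pipeline run
#'
#' Exactly one input mode: `synthetic` (the generator settings state the
#' cohort) or `files` (a directory written by [write_cohort()] or matching
#' its layout). One master `seed` deterministically derives all stage seeds
#' (generation, missingness, CV folds, BLB), so a run is reproducible from
#' its configuration alone.
#'
#' @param mode `"synthetic"` or `"files"`.
#' @param generator an [cohort_config()] (synthetic mode).
#' @param input_dir cohort directory (files mode).
#' @param factors optional character vector restricting the factor set
#'   (validated against [default_factor_definitions()]).
#' @param penalty `"cv"` or a fixed nonnegative penalty.
#' @param cv_grid,cv_folds,cv_rule cross-validation settings (see
#'   [select_penalty()]; the pipeline defaults to the one-standard-error
#'   rule).
#' @param blb an [blb_settings()], or `NULL` to skip confidence intervals.
#' @param blb_refit_ipw refit the completeness model inside each BLB resample
#'   so weight-estimation uncertainty propagates (default TRUE).
#' @param reactions_adjust_conditions see [outcome_model_specs()].
#' @param prior_absence adjust for prior-year absence indicators
#'   (sensitivity analysis).
#' @param stratify `"none"`, `"sex"` or `"occ_group"`: refit everything
#'   within each stratum.
#' @param na_rule scale-score missingness rule.
#' @param weight_truncation IPW truncation percentile (`NULL` = off).
#' @param output_dir optional directory for result artifacts.
#' @param seed master seed (mandatory).
#' @return object of class `sa_run_config`.
#' @export
run_config <- function(mode = c("synthetic", "files"), generator = NULL,
                       input_dir = NULL, factors = NULL, penalty = "cv",
                       cv_grid = NULL, cv_folds = 5L, cv_rule = "1se",
                       blb = blb_settings(),
                       blb_refit_ipw = TRUE, reactions_adjust_conditions = TRUE,
                       prior_absence = FALSE,
                       stratify = c("none", "sex", "occ_group"),
                       na_rule = "half", weight_truncation = 0.99,
                       output_dir = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stratify <- match.arg(stratify)
  if (!is.null(factors)) default_factor_definitions(factors)  # validates names
  if (mode == "synthetic") {
    assert_that(!is.null(seed) || !is.null(generator),
                "synthetic mode requires a seed (or a generator carrying one)")
    if (is.null(generator)) {
      generator <- cohort_config(
        factors = if (is.null(factors)) default_factor_definitions()
                  else default_factor_definitions(factors),
        seed = seed)
    }
    seed <- seed %||% generator$seed
    generator$seed <- as.integer(seed)
  } else {
    assert_that(!is.null(input_dir), "files mode requires input_dir")
    seed <- seed %||% 1L
  }
  assert_that(identical(penalty, "cv") ||
                (is_scalar_number(penalty) && penalty >= 0),
              "penalty must be \"cv\" or a nonnegative number")
  structure(list(mode = mode, generator = generator, input_dir = input_dir,
                 penalty = penalty, cv_grid = cv_grid,
                 cv_folds = as.integer(cv_folds), cv_rule = cv_rule, blb = blb,
                 blb_refit_ipw = blb_refit_ipw,
                 reactions_adjust_conditions = reactions_adjust_conditions,
                 prior_absence = prior_absence, stratify = stratify,
                 na_rule = na_rule, weight_truncation = weight_truncation,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "sa_run_config")
}

#' Validate cohort input tables
#'
#' Checks column presence, id uniqueness, Likert ranges against the factor
#' definitions, 0/1 coding of binary items, positive fixed hours, nonnegative
#' spell hours and >= 1 day durations, and orphan spell ids. Violations are
#' returned with row/column context; an empty table means a valid input.
#'
#' @param employees employee data frame (or a path readable by
#'   [utils::read.csv()]).
#' @param spells spell data frame (or a path).
#' @param factors factor definitions the items must conform to.
#' @return data frame of violations (class `sa_validation`).
#' @export
validate_cohort_schema <- function(employees, spells, factors) {
  if (is.character(employees)) employees <- utils::read.csv(employees, na.strings = "")
  if (is.character(spells)) spells <- utils::read.csv(spells, na.strings = "")
  v <- list()
  note <- function(table, row, column, message)
    v[[length(v) + 1L]] <<- data.frame(table = table, row = row,
                                       column = column, message = message,
                                       stringsAsFactors = FALSE)
  need <- c("id", "fixed_hours")
  for (col in setdiff(need, names(employees)))
    note("employees", NA_integer_, col, "required column missing")
  if ("id" %in% names(employees)) {
    dup <- which(duplicated(employees$id))
    for (r in dup) note("employees", r, "id",
                        sprintf("duplicate employee id %s", employees$id[r]))
  }
  if ("fixed_hours" %in% names(employees)) {
    bad <- which(!is.na(employees$fixed_hours) & employees$fixed_hours <= 0)
    for (r in bad) note("employees", r, "fixed_hours", "fixed hours must be positive")
  }
  for (f in factors) {
    for (j in seq_along(f$items)) {
      it <- f$items[j]
      if (!it %in% names(employees)) {
        note("employees", NA_integer_, it, "item column missing")
        next
      }
      x <- employees[[it]]
      if (f$kind == "binary") {
        bad <- which(!is.na(x) & !x %in% c(0, 1))
      } else {
        bad <- which(!is.na(x) & (x < 1 | x > f$points[j] | x != round(x)))
      }
      for (r in bad) note("employees", r, it,
                          sprintf("employee %s: value %s outside %s", employees$id[r],
                                  x[r], if (f$kind == "binary") "0/1"
                                        else paste0("1..", f$points[j])))
    }
  }
  for (col in setdiff(c("id", "duration_days", "hours"), names(spells)))
    note("spells", NA_integer_, col, "required column missing")
  if (all(c("id", "duration_days", "hours") %in% names(spells)) && nrow(spells)) {
    bad <- which(spells$duration_days < 1 | spells$duration_days != round(spells$duration_days))
    for (r in bad) note("spells", r, "duration_days", "duration must be a positive integer")
    bad <- which(spells$hours < 0)
    for (r in bad) note("spells", r, "hours", "hours must be nonnegative")
    if ("id" %in% names(employees)) {
      orphan <- which(!spells$id %in% employees$id)
      for (r in orphan) note("spells", r, "id",
                             sprintf("spell references unknown employee id %s", spells$id[r]))
    }
  }
  out <- if (length(v)) do.call(rbind, v) else
    data.frame(table = character(), row = integer(), column = character(),
               message = character(), stringsAsFactors = FALSE)
  class(out) <- c("sa_validation", class(out))
  out
}

#' @export
print.sa_validation <- function(x, ...) {
  if (nrow(x) == 0) cat("<validation> no violations\n")
  else {
    cat(sprintf("<validation> %d violation(s)\n", nrow(x)))
    print.data.frame(utils::head(x, 20))
  }
  invisible(x)
}

#' Run the end-to-end g-formula analysis
#'
#' Generate-or-load -> exposure scales -> outcome aggregation -> inverse
#' probability weights -> eight ridge Poisson models -> 144 counterfactual
#' contrasts -> Bag of Little Bootstraps confidence intervals. Attrition
#' (eligible vs. complete) is logged at every step; the result carries an
#' exact echo of the effective configuration and, in synthetic mode, the
#' generator's ground truth.
#'
#' @param config an [run_config()].
#' @return object of class `sa_run`: list with `contrasts` (144 rows with
#'   CIs), `models`, `weights`, `completeness`, `summary` (top factors by
#'   total-term realistic RR), `truth` (synthetic mode), `log`, `config`;
#'   stratified runs return one such element per stratum in `$strata`.
#' @export
run_pipeline <- function(config) {
  assert_that(inherits(config, "sa_run_config"), "config must come from run_config()")
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
  }

  truth <- NULL
  if (config$mode == "synthetic") {
    gen <- generate_cohort(config$generator)
    say("generated synthetic cohort: n = %d", nrow(gen$cohort$employees))
    gen <- inject_missingness(gen)
    cohort <- gen$cohort
    truth <- gen$truth
  } else {
    cohort <- read_cohort(config$input_dir)
    viol <- validate_cohort_schema(cohort$employees, cohort$spells, cohort$factors)
    if (nrow(viol) > 0) {
      print(viol)
      stop(sprintf("cohort input failed validation with %d violation(s)", nrow(viol)))
    }
    say("loaded cohort from %s: n = %d", config$input_dir, nrow(cohort$employees))
  }
  say("eligible responders: %d; complete on work factors: %d (%.1f%%)",
      nrow(cohort$employees), sum(cohort$employees$complete),
      100 * mean(cohort$employees$complete))

  if (config$stratify != "none") {
    strata_var <- if (config$stratify == "sex") "sex" else "occ_group"
    levels_ <- levels(cohort$employees[[strata_var]])
    strata <- lapply(levels_, function(lv) {
      sub <- cohort
      keep <- sub$employees[[strata_var]] == lv
      sub$employees <- sub$employees[keep, , drop = FALSE]
      sub$spells <- sub$spells[sub$spells$id %in% sub$employees$id, , drop = FALSE]
      run_pipeline_core(sub, config, NULL, paste0(strata_var, "=", lv))
    })
    names(strata) <- levels_
    return(structure(list(strata = strata, config = config, log = log_lines),
                     class = "sa_run"))
  }

  out <- run_pipeline_core(cohort, config, truth, "all")
  out$log <- c(log_lines, out$log)
  if (!is.null(config$output_dir)) write_run(out, config$output_dir)
  out
}

#' @noRd
run_pipeline_core <- function(cohort, config, truth, stratum_label) {
  log_lines <- character()
  say <- function(fmt, ...) log_lines <<- c(log_lines, sprintf(fmt, ...))

  analysis <- build_analysis_table(cohort, na_rule = config$na_rule)
  factors <- attr(analysis, "factors")

  if (all(analysis$complete)) {
    wts <- structure(list(weights = rep(1, nrow(analysis)), truncation = NA,
                          diagnostics = list(min = 1, max = 1, mean = 1,
                                             sum = nrow(analysis),
                                             ess = nrow(analysis),
                                             n_complete = nrow(analysis),
                                             n_eligible = nrow(analysis))),
                     class = "sa_weights")
    completeness <- NULL
    say("no incomplete employees; unit weights")
  } else {
    completeness <- fit_completeness_model(analysis)
    wts <- compute_weights(completeness$probabilities, analysis$complete,
                           config$weight_truncation)
    say("IPW: %d complete cases reweighted to %d eligible (sum of weights %.1f)",
        wts$diagnostics$n_complete, wts$diagnostics$n_eligible,
        wts$diagnostics$sum)
  }

  models <- fit_outcome_models(analysis, factors, wts,
                               penalty = config$penalty, grid = config$cv_grid,
                               folds = config$cv_folds, cv_rule = config$cv_rule,
                               seed = derive_seed(config$seed, 3L),
                               reactions_adjust_conditions =
                                 config$reactions_adjust_conditions,
                               prior_absence = config$prior_absence)
  bad <- unlist(lapply(models$models, function(b)
    vapply(b, function(m) !m$converged, TRUE)))
  if (any(bad)) stop("non-convergent outcome model(s): ",
                     paste(names(bad)[bad], collapse = ", "))
  say("fitted 8 outcome models (penalties %s)",
      paste(signif(models$penalties, 3), collapse = ", "))

  contrasts <- run_all_contrasts(models, analysis, factors, wts)

  if (!is.null(config$blb)) {
    blb_cfg <- config$blb
    blb_cfg$seed <- derive_seed(config$seed, 4L)
    blb_cfg$log_scale <- TRUE
    est <- pipeline_blb_estimator(config, factors, models$penalties)
    ci <- blb_ci(est, analysis, blb_cfg)
    key <- with(contrasts, paste(factor_set, contrast_type, term, sep = "|"))
    idx <- match(key, ci$intervals$component)
    contrasts$ci_low <- ci$intervals$lower[idx]
    contrasts$ci_high <- ci$intervals$upper[idx]
    say("BLB intervals: b = %d, s = %d, r = %d", ci$b, blb_cfg$s, blb_cfg$r)
  }
  contrasts$penalty <- models$penalties[paste(contrasts$model_block,
                                              contrasts$term, sep = ".")]
  contrasts$n <- models$n_complete
  contrasts$seed <- config$seed
  contrasts$stratum <- stratum_label

  top <- contrasts[contrasts$contrast_type == "realistic" &
                     contrasts$term == "total" &
                     contrasts$factor_set != "all_factors", ]
  top <- top[order(top$rr), c("factor_set", "rr", "ci_low", "ci_high")]
  structure(list(contrasts = contrasts, models = models, weights = wts,
                 completeness = completeness, summary = top, truth = truth,
                 log = log_lines, config = config), class = "sa_run")
}

#' @noRd
pipeline_blb_estimator <- function(config, factors, penalties) {
  function(sub, mult) {
    mult <- as.numeric(mult)
    if (any(!sub$complete) && config$blb_refit_ipw) {
      cm <- fit_completeness_model(sub, weights = mult)
      wts <- compute_weights(cm$probabilities, sub$complete,
                             config$weight_truncation)
      w <- wts$weights * mult
    } else {
      w <- as.numeric(sub$complete) * mult
    }
    m <- fit_outcome_models(sub, factors, w, penalty = penalties,
                            reactions_adjust_conditions =
                              config$reactions_adjust_conditions,
                            prior_absence = config$prior_absence)
    ctr <- run_all_contrasts(m, sub, factors, w)
    stats::setNames(ctr$rr, paste(ctr$factor_set, ctr$contrast_type, ctr$term,
                                  sep = "|"))
  }
}

#' @export
print.sa_run <- function(x, ...) {
  if (!is.null(x$strata)) {
    cat(sprintf("<g-formula run> %d strata\n", length(x$strata)))
    return(invisible(x))
  }
  cat("<g-formula run>\n")
  for (l in x$log) cat(" ", l, "\n")
  cat("Top factors by total-term realistic RR:\n")
  print(utils::head(x$summary, 5), row.names = FALSE)
  invisible(x)
}

#' Write run artifacts to a directory
#'
#' `contrasts.csv` (the tidy 144-row results table), `models.json`,
#' `weights.csv`, `log.txt` and `config.txt` (an exact echo via [dput()]
#' syntax of the effective configuration).
#'
#' @param run an `sa_run`.
#' @param dir output directory.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$contrasts, file.path(dir, "contrasts.csv"),
                   row.names = FALSE)
  write_models(run$models, file.path(dir, "models.json"))
  writeLines(run$log, file.path(dir, "log.txt"))
  cfg <- run$config
  cfg_txt <- utils::capture.output(dput(cfg[setdiff(names(cfg), "generator")]))
  writeLines(c(cfg_txt, "", "generator:",
               utils::capture.output(utils::str(cfg$generator, max.level = 2))),
             file.path(dir, "config.txt"))
  invisible(dir)
}
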