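#' Default sociodemographic / workplace / employment covariates
#' @export
sa_default_covariates <- c("age", "sex", "marital", "income", "seniority",
                           "employment", "occ_group", "workplace")

#' Assemble the per-employee analysis table
#'
#' Joins the covariates, the categorized exposure matrix (cutpoints fitted on
#' the analysis sample unless supplied) and the term-specific outcome records
#' into one table, keeping incomplete employees (flagged, weight 0 downstream)
#' so that missingness models and bootstrap subsets can see them.
#'
#' @param cohort an `sa_cohort`.
#' @param na_rule item-missingness rule for scale scores.
#' @param cutpoints optional named list of reference `sa_cutpoints`.
#' @return data frame with attributes `cutpoints` and `factors`.
#' @export
build_analysis_table <- function(cohort, na_rule = "half", cutpoints = NULL) {
  assert_that(inherits(cohort, "sa_cohort"), "cohort must be an sa_cohort")
  emp <- cohort$employees
  exposure <- build_exposure_matrix(cohort, cohort$factors,
                                    cutpoints = cutpoints, na_rule = na_rule)
  outcomes <- aggregate_outcomes(cohort$spells,
                                 emp[, c("id", "fixed_hours")])
  keep <- intersect(c("id", sa_default_covariates, "daily_hours",
                      grep("^prior_", names(emp), value = TRUE)),
                    names(emp))
  out <- merge(emp[, keep, drop = FALSE], exposure$levels, by = "id")
  out <- merge(out, outcomes[, setdiff(names(outcomes), "fixed_hours")], by = "id")
  out <- merge(out, emp[, c("id", "fixed_hours")], by = "id")
  out$complete <- !exposure$incomplete[match(out$id, exposure$levels$id)]
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cutpoints") <- exposure$cutpoints
  attr(out, "factors") <- cohort$factors
  out
}

#' Enumerate the eight outcome model specifications
#'
#' Two exposure blocks x four outcome terms. The working-conditions block
#' regresses absence hours on the 15 psychosocial working conditions plus the
#' sociodemographic/workplace/employment covariates; the reactions block adds
#' the two cognitive and emotional reactions and, by default, also adjusts for
#' the 15 working conditions (so one model contains all 17 factors - the model
#' that serves the all-factors-simultaneously scenario; set
#' `reactions_adjust_conditions = FALSE` for the narrow reading that adjusts
#' for the shared covariates only).
#'
#' @param factors named list of factor definitions.
#' @param covariates covariate column names.
#' @param reactions_adjust_conditions see above.
#' @param prior_absence append the three prior-year absence indicators
#'   (sensitivity adjustment).
#' @return list of 8 specs (class `sa_model_spec`), named `block.term`.
#' @export
outcome_model_specs <- function(factors, covariates = sa_default_covariates,
                                reactions_adjust_conditions = TRUE,
                                prior_absence = FALSE) {
  ids <- factor_ids(factors)
  blocks <- vapply(factors, `[[`, "", "block")
  wc <- ids[blocks == "working_conditions"]
  re <- ids[blocks == "reactions"]
  extra <- if (prior_absence) c("prior_short", "prior_intermediate", "prior_long")
           else character()
  specs <- list()
  for (blk in c("working_conditions", "reactions")) {
    rhs <- if (blk == "working_conditions") c(covariates, extra, wc)
           else c(covariates, extra, if (reactions_adjust_conditions) wc, re)
    for (term in c("total", "short", "intermediate", "long")) {
      specs[[paste(blk, term, sep = ".")]] <-
        structure(list(term = term, block = blk, rhs = rhs),
                  class = "sa_model_spec")
    }
  }
  specs
}

#' Fit the eight weighted ridge Poisson outcome models
#'
#' Fits, for each exposure block and each outcome term, a weighted
#' ridge-penalized Poisson regression of term-specific absence hours with log
#' fixed working hours as offset, on complete cases weighted by the inverse
#' probability weights. The penalty is either a fixed value or selected per
#' model by seeded cross-validation (`penalty = "cv"`). By default the
#' penalty acts on the exposure-factor coefficients only (`penalize =
#' "factors"`): the ridge exists to stabilize the mutually correlated work
#' factors, while confounder adjustment stays unpenalized - shrinking the
#' covariate coefficients would trade confounding bias for nothing. Set
#' `penalize = "all"` to shrink every slope.
#'
#' @param data analysis table from [build_analysis_table()].
#' @param factors factor definitions (default: the table's own).
#' @param weights `sa_weights` object or a numeric vector aligned with `data`
#'   (0 for incomplete employees).
#' @param penalty `"cv"`, a nonnegative number, or a named vector with one
#'   entry per `block.term` (as produced in `$penalties`; used when refitting
#'   inside bootstrap resamples at the penalties selected on the full data).
#' @param grid penalty grid for CV (default [default_penalty_grid()]).
#' @param folds CV folds.
#' @param cv_rule penalty-selection rule, see [select_penalty()]; the
#'   conservative `"1se"` default guards against under-shrinkage when the
#'   hours response is overdispersed.
#' @param penalize `"factors"` (default) penalizes only the exposure-level
#'   dummy columns; `"all"` penalizes every slope.
#' @param seed seed for CV fold assignment.
#' @param specs optional pre-built [outcome_model_specs()].
#' @param ... passed to [outcome_model_specs()] when `specs` is NULL.
#' @return object of class `sa_outcome_models`: `models[[block]][[term]]`,
#'   each an `sa_poisson_fit` with `$term`, `$block`; plus `penalties`.
#' @export
fit_outcome_models <- function(data, factors = attr(data, "factors"),
                               weights, penalty = "cv", grid = NULL,
                               folds = 5L, cv_rule = "1se", seed = 1L,
                               penalize = c("factors", "all"),
                               specs = NULL, ...) {
  penalize <- match.arg(penalize)
  w_all <- if (inherits(weights, "sa_weights")) weights$weights else weights
  assert_that(length(w_all) == nrow(data), "weights must align with data")
  specs <- specs %||% outcome_model_specs(factors, ...)
  cc <- data$complete & w_all > 0
  dat <- data[cc, , drop = FALSE]
  w <- w_all[cc]
  off <- log(dat$fixed_hours)
  grid <- grid %||% default_penalty_grid(nrow(dat))

  models <- list(working_conditions = list(), reactions = list())
  penalties <- numeric()
  for (blk in c("working_conditions", "reactions")) {
    blk_specs <- Filter(function(s) s$block == blk, specs)
    if (length(blk_specs) == 0) next
    design <- build_design(dat, stats::reformulate(blk_specs[[1]]$rhs), w)
    unpen <- if (penalize == "factors") {
      pen_cols <- unlist(lapply(factors, function(f)
        paste0(f$id, setdiff(factor_levels(f), factor_levels(f)[1]))))
      setdiff(colnames(design$X), c("(Intercept)", pen_cols))
    } else NULL
    for (s in blk_specs) {
      y <- dat[[paste0(s$term, "_hours")]]
      lam <- if (identical(penalty, "cv")) {
        as.numeric(select_penalty(design, y, off, w, grid = grid, folds = folds,
                                  rule = cv_rule, unpenalized = unpen,
                                  seed = derive_seed(seed, match(s$term, c(
                                    "total", "short", "intermediate", "long")) +
                                    10L * (blk == "reactions"))))
      } else if (length(penalty) > 1) {
        as.numeric(penalty[[paste(blk, s$term, sep = ".")]])
      } else penalty
      fit <- fit_ridge_poisson(design, y, off, w, penalty = lam,
                               unpenalized = unpen)
      fit$term <- s$term
      fit$block <- blk
      models[[blk]][[s$term]] <- fit
      penalties[paste(blk, s$term, sep = ".")] <- lam
    }
  }
  structure(list(models = models, penalties = penalties,
                 n_complete = nrow(dat)), class = "sa_outcome_models")
}

#' @export
print.sa_outcome_models <- function(x, ...) {
  cat(sprintf("<outcome models> %d fits on %d complete cases\n",
              sum(lengths(x$models)), x$n_complete))
  for (nm in names(x$penalties)) cat(sprintf("  %-30s lambda = %.4g\n", nm, x$penalties[[nm]]))
  invisible(x)
}
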