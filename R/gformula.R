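#' Define a counterfactual intervention scenario
#'
#' A scenario assigns each targeted factor one of three rules:
#' `most_desirable` (everyone set to High, or No for the binary adversities),
#' `least_desirable` (Low / Yes), or `observed` (left at reported levels).
#' Factors not named keep their observed levels, so the empty scenario is the
#' identity (the observed world).
#'
#' @param rules named character vector, names = factor ids, values among
#'   `most_desirable`, `least_desirable`, `observed`.
#' @param label optional label.
#' @return object of class `sa_scenario`.
#' @export
intervention_scenario <- function(rules = character(), label = NULL) {
  if (length(rules)) {
    assert_that(!is.null(names(rules)) && all(nzchar(names(rules))),
                "rules must be named by factor id")
    assert_that(all(rules %in% c("most_desirable", "least_desirable", "observed")),
                "rules must be most_desirable / least_desirable / observed")
  }
  structure(list(rules = rules,
                 label = label %||% if (length(rules)) paste0(
                   unique(rules), " on ", length(rules), " factor(s)")[1]
                 else "observed"),
            class = "sa_scenario")
}

#' @export
print.sa_scenario <- function(x, ...) {
  cat(sprintf("<scenario> %s\n", x$label))
  invisible(x)
}

#' @noRd
scenario_on <- function(factor_set, rule) {
  intervention_scenario(stats::setNames(rep(rule, length(factor_set)), factor_set))
}

#' Apply a scenario to an exposure-level table
#'
#' Sets each targeted factor's column to its desirable or least-desirable
#' level; `observed` and non-targeted factors are untouched. Covariates and
#' the offset are never modified (static point-exposure g-formula).
#'
#' @param data data frame containing the factor-level columns.
#' @param scenario an [intervention_scenario()].
#' @param factors factor definitions covering the targeted ids.
#' @return the modified data frame.
#' @export
apply_scenario <- function(data, scenario, factors) {
  ids <- factor_ids(factors)
  for (fid in names(scenario$rules)) {
    assert_that(fid %in% ids, paste0("scenario rule for unknown factor: ", fid))
    rule <- scenario$rules[[fid]]
    if (rule == "observed") next
    f <- factors[[match(fid, ids)]]
    lev <- if (rule == "most_desirable") f$desirable_level else f$least_desirable_level
    data[[fid]] <- factor(rep(lev, nrow(data)), levels = levels(data[[fid]]))
  }
  data
}

#' Standardized sickness absence rate under a scenario
#'
#' The parametric g-formula standardization step: modify the exposure columns
#' per the scenario, re-encode through the model's frozen design metadata,
#' predict each employee's expected absence hours, and pool:
#' `sum(w * yhat) / sum(w * fixed_hours)`. Covariates are always held at
#' their observed values.
#'
#' @param model an `sa_poisson_fit` carrying design metadata.
#' @param data analysis table (complete cases are used: rows with positive
#'   weight).
#' @param scenario an [intervention_scenario()].
#' @param weights `sa_weights` or numeric vector aligned with `data`.
#' @param factors factor definitions.
#' @return the standardized rate (scalar).
#' @export
standardized_rate <- function(model, data, scenario, weights = NULL,
                              factors = attr(data, "factors")) {
  w_all <- if (inherits(weights, "sa_weights")) weights$weights else
    weights %||% rep(1, nrow(data))
  use <- if ("complete" %in% names(data)) data$complete & w_all > 0 else w_all > 0
  dat <- data[use, , drop = FALSE]
  w <- w_all[use]
  mod_dat <- apply_scenario(dat, scenario, factors)
  yhat <- predict_expected_hours(model, mod_dat, log(dat$fixed_hours))
  sum(w * yhat) / sum(w * dat$fixed_hours)
}

#' @noRd
contrast_row <- function(factor_set_label, type, term, num, den, block) {
  data.frame(factor_set = factor_set_label, contrast_type = type, term = term,
             rate_num = num, rate_den = den, rr = num / den,
             ci_low = NA_real_, ci_high = NA_real_, model_block = block,
             stringsAsFactors = FALSE)
}

#' Etiologic contrast: most vs. least desirable levels
#'
#' Rate ratio of the standardized rates with every employee set to the most
#' desirable levels of the targeted factors versus everyone at the least
#' desirable levels, non-targeted exposures held at observed values. This is
#' the all-treated vs. none-treated contrast, independent of the observed
#' exposure distribution.
#'
#' @inheritParams standardized_rate
#' @param factor_set character vector of factor ids to intervene on.
#' @param term outcome term label recorded in the result.
#' @return one-row data frame (ContrastResult).
#' @export
etiologic_rr <- function(model, data, factor_set, term = model$term %||% "total",
                         weights = NULL, factors = attr(data, "factors")) {
  num <- standardized_rate(model, data, scenario_on(factor_set, "most_desirable"),
                           weights, factors)
  den <- standardized_rate(model, data, scenario_on(factor_set, "least_desirable"),
                           weights, factors)
  contrast_row(paste(factor_set, collapse = "+"), "etiologic", term, num, den,
               model$block %||% NA_character_)
}

#' Realistic contrast: most desirable vs. observed levels
#'
#' Rate ratio of the standardized rates with everyone at the most desirable
#' levels of the targeted factors versus everyone at their observed levels -
#' the population-attributable-fraction-style contrast; `1 - RR` is the
#' prevented fraction of the absence rate.
#'
#' @inheritParams etiologic_rr
#' @return one-row data frame (ContrastResult).
#' @export
realistic_rr <- function(model, data, factor_set, term = model$term %||% "total",
                         weights = NULL, factors = attr(data, "factors")) {
  num <- standardized_rate(model, data, scenario_on(factor_set, "most_desirable"),
                           weights, factors)
  den <- standardized_rate(model, data, intervention_scenario(), weights, factors)
  contrast_row(paste(factor_set, collapse = "+"), "realistic", term, num, den,
               model$block %||% NA_character_)
}

#' Run the full contrast enumeration
#'
#' For each of the 17 single factors plus the all-factors set, both contrast
#' types (etiologic, realistic), and all four outcome terms: 18 x 2 x 4 = 144
#' rows. Single working-condition factors are evaluated on the
#' working-conditions-block models; single reaction factors and the joint set
#' on the reactions-block (all-17) models. Designs are rebuilt once per
#' (factor set, scenario, block) and shared across the four terms.
#'
#' @param models an `sa_outcome_models` (all 8 fits present).
#' @param data analysis table.
#' @param factors factor definitions.
#' @param weights `sa_weights` or numeric vector.
#' @return data frame of 144 ContrastResult rows (CI columns `NA`, filled by
#'   the BLB step).
#' @export
run_all_contrasts <- function(models, data, factors = attr(data, "factors"),
                              weights = NULL) {
  terms <- c("total", "short", "intermediate", "long")
  for (blk in c("working_conditions", "reactions")) {
    missing_terms <- setdiff(terms, names(models$models[[blk]]))
    assert_that(length(missing_terms) == 0,
                paste0("missing ", blk, " model(s) for term(s): ",
                       paste(missing_terms, collapse = ", ")))
  }
  w_all <- if (inherits(weights, "sa_weights")) weights$weights else
    weights %||% rep(1, nrow(data))
  use <- data$complete & w_all > 0
  dat <- data[use, , drop = FALSE]
  w <- w_all[use]
  off <- log(dat$fixed_hours)
  denomT <- sum(w * dat$fixed_hours)
  ids <- factor_ids(factors)
  blocks <- vapply(factors, `[[`, "", "block")

  rate_for <- function(blk, scn) {
    meta <- models$models[[blk]][["total"]]$design_meta
    X <- rebuild_design(meta, apply_scenario(dat, scn, factors))
    vapply(terms, function(tt) {
      fit <- models$models[[blk]][[tt]]
      sum(w * exp(off + as.numeric(X %*% fit$coef_std))) / denomT
    }, numeric(1))
  }
  obs_rates <- list(working_conditions = rate_for("working_conditions",
                                                  intervention_scenario()),
                    reactions = rate_for("reactions", intervention_scenario()))

  sets <- c(stats::setNames(as.list(ids), ids), list(all_factors = ids))
  rows <- vector("list", 0L)
  for (nm in names(sets)) {
    set <- sets[[nm]]
    blk <- if (length(set) == 1 && blocks[match(set, ids)] == "working_conditions")
      "working_conditions" else "reactions"
    most <- rate_for(blk, scenario_on(set, "most_desirable"))
    least <- rate_for(blk, scenario_on(set, "least_desirable"))
    for (tt in terms) {
      rows[[length(rows) + 1L]] <-
        contrast_row(nm, "etiologic", tt, most[[tt]], least[[tt]], blk)
      rows[[length(rows) + 1L]] <-
        contrast_row(nm, "realistic", tt, most[[tt]], obs_rates[[blk]][[tt]], blk)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
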