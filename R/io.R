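# Plain-text I/O: cohorts as delimited tables (missing values as empty
# fields), factor definitions / ground truth / fitted models as JSON.

#' Write a cohort to a directory of delimited tables
#'
#' `employees.csv` (one row per employee, missing values as empty fields),
#' `spells.csv`, `factors.json`, and `truth.json` when ground truth is given.
#'
#' @param cohort an `sa_cohort`.
#' @param dir output directory (created if needed).
#' @param truth optional `sa_truth` saved alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$employees, file.path(dir, "employees.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$spells, file.path(dir, "spells.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(lapply(cohort$factors, function(f)
    f[c("name", "kind", "items", "points", "reversed", "block")]),
    file.path(dir, "factors.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    tr <- truth
    tr$s <- NULL  # bulky per-employee matrix; regenerate from config instead
    jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `employees.csv`, `spells.csv`,
#'   `factors.json`.
#' @return an `sa_cohort` (with `config = NULL`).
#' @export
read_cohort <- function(dir) {
  emp <- utils::read.csv(file.path(dir, "employees.csv"), na.strings = "")
  spells <- utils::read.csv(file.path(dir, "spells.csv"), na.strings = "")
  fdefs <- jsonlite::read_json(file.path(dir, "factors.json"),
                               simplifyVector = TRUE)
  factors <- lapply(fdefs, function(f)
    factor_definition(f$name, f$kind, f$items, f$points %||% 5L,
                      f$reversed %||% FALSE, f$block))
  names(factors) <- vapply(factors, `[[`, "", "id")
  for (col in c("sex", "marital", "occ_group", "employment", "workplace")) {
    if (col %in% names(emp)) emp[[col]] <- factor(emp[[col]])
  }
  if (!"complete" %in% names(emp)) emp$complete <- TRUE
  structure(list(employees = emp, spells = spells, factors = factors,
                 config = NULL), class = "sa_cohort")
}

#' Serialize fitted outcome models to JSON
#'
#' Stores, per model, the standardized and back-transformed coefficients, the
#' penalty, convergence diagnostics, and the full encoding metadata (formula,
#' frozen factor levels, column set, standardization constants) - sufficient
#' for exact re-prediction after [read_models()].
#'
#' @param models an `sa_outcome_models`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path) {
  ser <- lapply(models$models, function(blk) lapply(blk, function(fit) {
    m <- fit$design_meta
    list(coef_std = as.list(fit$coef_std), coef = as.list(fit$coef),
         penalty = fit$penalty, deviance = fit$deviance,
         iterations = fit$iterations, converged = fit$converged,
         term = fit$term, block = fit$block, n = fit$n,
         meta = list(formula = paste(deparse(stats::formula(m$terms)),
                                     collapse = " "),
                     xlev = m$xlev, columns = m$columns,
                     center = as.list(m$center), scale = as.list(m$scale),
                     standardize = m$standardize, dropped = m$dropped))
  }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore fitted outcome models from JSON
#'
#' @param path path written by [write_models()].
#' @return an `sa_outcome_models`.
#' @export
read_models <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  models <- lapply(ser, function(blk) lapply(blk, function(x) {
    meta <- list(
      terms = stats::delete.response(stats::terms(stats::as.formula(x$meta$formula))),
      xlev = lapply(x$meta$xlev, unlist),
      columns = unlist(x$meta$columns),
      center = unlist(x$meta$center), scale = unlist(x$meta$scale),
      standardize = x$meta$standardize, dropped = unlist(x$meta$dropped))
    structure(list(coef_std = unlist(x$coef_std), coef = unlist(x$coef),
                   penalty = x$penalty, deviance = x$deviance,
                   iterations = x$iterations, converged = x$converged,
                   design_meta = meta, term = x$term, block = x$block,
                   n = x$n), class = "sa_poisson_fit")
  }))
  penalties <- unlist(lapply(names(models), function(blk)
    stats::setNames(vapply(models[[blk]], `[[`, 0, "penalty"),
                    paste(blk, names(models[[blk]]), sep = "."))))
  structure(list(models = models, penalties = penalties,
                 n_complete = models[[1]][[1]]$n), class = "sa_outcome_models")
}

#' Write IPW weights as a two-column delimited table
#' @param weights an `sa_weights`.
#' @param ids employee ids aligned with the weights.
#' @param path output path.
#' @export
write_weights <- function(weights, ids, path) {
  utils::write.csv(data.frame(id = ids, weight = weights$weights), path,
                   row.names = FALSE)
  invisible(path)
}
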