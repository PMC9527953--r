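#' Fit the complete-case probability model
#'
#' Logistic regression of the person-level completeness flag on
#' sociodemographic, workplace and employment covariates, fitted on *all*
#' eligible responders (complete and incomplete). The in-sample predicted
#' probabilities of being complete feed [compute_weights()]. Under separation
#' (fitted probabilities numerically 0/1 or a non-converged fit) the model
#' falls back to a lightly ridge-stabilized logistic fit.
#'
#' @param data employee data frame with a logical/0-1 `complete` column and
#'   the covariates.
#' @param covariates character vector of covariate column names.
#' @param ridge penalty used only by the separation fallback.
#' @param weights optional nonnegative case weights (e.g. bootstrap
#'   multiplicities inside a resample).
#' @return object of class `sa_completeness`: list with `probabilities`
#'   (P(complete | X) per row), `coefficients`, `fallback` flag.
#' @export
fit_completeness_model <- function(data,
                                   covariates = c("age", "sex", "marital",
                                                  "income", "seniority",
                                                  "employment", "occ_group",
                                                  "workplace"),
                                   ridge = 1e-3, weights = NULL) {
  assert_that("complete" %in% names(data), "data needs a `complete` column")
  y <- as.numeric(data$complete)
  w <- weights %||% rep(1, nrow(data))
  assert_that(length(unique(y[w > 0])) == 2,
              "completeness is constant; no model identifiable")
  covariates <- intersect(covariates, names(data))
  form <- stats::reformulate(covariates, response = "complete")
  df <- transform(data, complete = y)
  df$.w <- w
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                     data = df, weights = .w))
  p <- as.numeric(stats::predict(fit, type = "response"))
  coefs <- stats::coef(fit)
  separated <- !fit$converged || anyNA(coefs) || any(abs(coefs) > 15) ||
    any(p < 1e-8) || any(p > 1 - 1e-8)
  fallback <- FALSE
  if (separated) {
    # ridge-stabilized refit on the same design
    X <- stats::model.matrix(form, data)
    rf <- ridge_glm_irls(X, y, offset = rep(0, length(y)), weights = w,
                         penalty = ridge * nrow(X), family = "binomial")
    p <- as.numeric(stats::plogis(X %*% rf$beta))
    coefs <- stats::setNames(rf$beta, colnames(X))
    fallback <- TRUE
  }
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  structure(list(probabilities = p, coefficients = coefs,
                 formula = form, fallback = fallback),
            class = "sa_completeness")
}

#' @export
print.sa_completeness <- function(x, ...) {
  cat(sprintf("<completeness model> %d coefficients; fitted P(complete) in [%.3f, %.3f]%s\n",
              length(x$coefficients), min(x$probabilities), max(x$probabilities),
              if (x$fallback) " (ridge fallback)" else ""))
  invisible(x)
}

#' Inverse probability weights for complete-case analysis
#'
#' Complete cases receive weight `1 / P(complete | X)` (>= 1), truncated at
#' the given upper percentile of the complete-case weight distribution
#' (`NULL` disables truncation); incomplete employees receive weight 0 and
#' are excluded from the outcome models. The weighted complete cases then
#' stand in for the full eligible sample under missing-at-random.
#'
#' @param probabilities P(complete | X) per employee, in (0, 1).
#' @param complete logical completeness flags.
#' @param truncation upper percentile (default 0.99) or `NULL`.
#' @return object of class `sa_weights`: list with `weights`, `truncation`
#'   (the bound applied, or `NA`), and `diagnostics` (min/max/mean weight over
#'   complete cases, effective sample size, sum of weights).
#' @export
compute_weights <- function(probabilities, complete, truncation = 0.99) {
  assert_that(length(probabilities) == length(complete),
              "probabilities and flags must align")
  assert_that(all(probabilities[complete] > 0),
              "zero completeness probability for a complete case")
  w <- ifelse(complete, 1 / probabilities, 0)
  bound <- NA_real_
  if (!is.null(truncation)) {
    bound <- as.numeric(stats::quantile(w[complete], truncation, names = FALSE))
    w[complete] <- pmin(w[complete], bound)
  }
  wc <- w[complete]
  structure(list(weights = w, truncation = bound,
                 diagnostics = list(min = min(wc), max = max(wc),
                                    mean = mean(wc), sum = sum(wc),
                                    ess = sum(wc)^2 / sum(wc^2),
                                    n_complete = sum(complete),
                                    n_eligible = length(complete))),
            class = "sa_weights")
}

#' @export
print.sa_weights <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<IPW weights> %d complete of %d eligible; weights %.3f-%.3f (mean %.3f), ESS %.0f\n",
              d$n_complete, d$n_eligible, d$min, d$max, d$mean, d$ess))
  invisible(x)
}
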