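#' Weighted Poisson deviance
#'
#' `2 * sum(w * (y * log(y / mu) - (y - mu)))` with the `y log y` term taken
#' as 0 at `y = 0`. Valid as a quasi-likelihood discrepancy for nonnegative
#' continuous responses such as absence hours.
#'
#' @param y nonnegative responses.
#' @param mu positive fitted means.
#' @param w nonnegative weights.
#' @return scalar deviance.
#' @export
poisson_deviance <- function(y, mu, w = rep(1, length(y))) {
  ylogy <- ifelse(y > 0, y * log(y / mu), 0)
  2 * sum(w * (ylogy - (y - mu)))
}

# Core penalized IRLS for log/logit links. Maximizes the weighted
# log-likelihood minus penalty/2 * ||beta[-intercept]||^2 (intercept column,
# named "(Intercept)" or the first column, is never penalized). Convergence:
# relative penalized-deviance change < tol, then polished until the Newton
# step is numerically zero (quadratic convergence makes this 1-3 extra
# iterations); hard cap maxit.
#' @noRd
ridge_glm_irls <- function(X, y, offset, weights, penalty,
                           family = c("poisson", "binomial"),
                           beta0 = NULL, tol = 1e-8, maxit = 100L,
                           pen_mask = NULL) {
  family <- match.arg(family)
  assert_that(penalty >= 0, "penalty must be nonnegative")
  assert_that(all(weights >= 0), "weights must be nonnegative")
  assert_that(all(is.finite(offset)), "offsets must be finite")
  if (family == "poisson") assert_that(all(y >= 0), "negative response")
  p <- ncol(X)
  if (is.null(pen_mask)) pen_mask <- rep(1, p)
  icol <- if ("(Intercept)" %in% colnames(X)) which(colnames(X) == "(Intercept)") else 1L
  pen_mask[icol] <- 0
  D <- penalty * pen_mask
  # Exempted slope columns (pen_mask 0, not the intercept) get a negligible
  # stabilizing ridge (1e-4 of the information scale) so quasi-separated
  # resamples have a finite optimum; inactive when every slope shares the
  # penalty or the fit is fully unpenalized.
  if (penalty > 0 && any(pen_mask[-icol] == 0)) {
    info <- if (family == "poisson") sum(weights * y) + 1 else
      0.25 * sum(weights) + 1
    stab <- rep(0, p)
    stab[pen_mask == 0] <- 1e-4 * info
    stab[icol] <- 0
    D <- D + stab
  }

  mu_fun <- if (family == "poisson") exp else stats::plogis
  dev_fun <- if (family == "poisson") {
    function(mu) poisson_deviance(y, mu, weights)
  } else {
    function(mu) -2 * sum(weights * (y * log(mu) + (1 - y) * log(1 - mu)))
  }

  beta <- beta0 %||% numeric(p)
  if (is.null(beta0) && family == "poisson") {
    beta[icol] <- log(max(wmean(y, weights * exp(offset) / mean(exp(offset))), 1e-8) + 1e-8) -
      log(mean(exp(offset)))
    if (!is.finite(beta[icol])) beta[icol] <- 0
  }
  eta <- as.numeric(X %*% beta)
  mu <- mu_fun(eta + offset)
  pdev <- dev_fun(mu) + sum(D * beta^2)
  converged <- FALSE
  polish <- 0L
  for (it in seq_len(maxit)) {
    V <- if (family == "poisson") mu else mu * (1 - mu)
    V <- pmax(V, 1e-12)
    W <- weights * V
    z <- eta + (y - mu) / V
    XtW <- t(X * W)
    A <- XtW %*% X
    diag(A) <- diag(A) + D
    b <- XtW %*% z
    beta_new <- tryCatch(solve(A, b), error = function(e) {
      diag(A) <- diag(A) + 1e-10 * mean(diag(A))
      solve(A, b)
    })
    beta_new <- as.numeric(beta_new)
    # step-halving if the penalized deviance worsens; coefficients are boxed
    # at +/-30 on the standardized scale (beyond that the cell is separated
    # and the fitted mean is numerically 0/1 anyway)
    step <- 1
    repeat {
      bt <- pmin(pmax(beta + step * (beta_new - beta), -30), 30)
      eta_t <- as.numeric(X %*% bt)
      mu_t <- mu_fun(eta_t + offset)
      pdev_t <- dev_fun(mu_t) + sum(D * bt^2)
      if (is.finite(pdev_t) && (pdev_t <= pdev + 1e-8 || step < 1e-4)) break
      step <- step / 2
    }
    delta <- max(abs(bt - beta))
    rel <- abs(pdev - pdev_t) / (abs(pdev_t) + 0.1)
    beta <- bt; eta <- eta_t; mu <- mu_t; pdev <- pdev_t
    if (rel < tol) {
      polish <- polish + 1L
      if (delta < 1e-11 * (1 + max(abs(beta))) || polish >= 3L) {
        converged <- TRUE
        break
      }
    } else polish <- 0L
  }
  list(beta = stats::setNames(beta, colnames(X)), deviance = dev_fun(mu),
       penalized_deviance = pdev, iterations = it, converged = converged,
       fitted = mu)
}

#' Fit a weighted ridge-penalized Poisson regression with offset
#'
#' Maximizes the weighted Poisson log-likelihood minus
#' `penalty/2 * ||slopes||^2` (the intercept is never penalized) by
#' iteratively reweighted least squares. Absence hours are treated as a
#' nonnegative response under a log link - a quasi-likelihood estimating
#' equation that is valid for non-integer hours; only the mean predictions
#' feed the g-formula, and uncertainty comes from the Bag of Little
#' Bootstraps, not model-based standard errors. Non-convergence is flagged,
#' never silent.
#'
#' @param design an `sa_design` from [build_design()] or a plain numeric
#'   matrix whose first/`"(Intercept)"` column is the intercept.
#' @param hours nonnegative response (absence hours).
#' @param offset_log_fixed_hours log fixed working hours per row.
#' @param weights nonnegative observation weights (IPW, possibly times
#'   bootstrap multiplicities).
#' @param penalty ridge penalty `lambda >= 0` on the standardized slopes.
#' @param unpenalized optional character vector of column names exempted from
#'   the penalty in addition to the intercept (e.g. confounder columns when
#'   only the exposure-factor coefficients should be shrunk).
#' @param beta0 optional warm-start coefficients.
#' @return object of class `sa_poisson_fit`: coefficients on the
#'   standardized scale (`coef_std`) and back-transformed to the original
#'   scale (`coef`), deviance, iteration count, `converged` flag, penalty and
#'   (when available) the design metadata for re-prediction.
#' @export
fit_ridge_poisson <- function(design, hours, offset_log_fixed_hours, weights = NULL,
                              penalty = 0, unpenalized = NULL, beta0 = NULL) {
  X <- if (inherits(design, "sa_design")) design$X else design
  meta <- if (inherits(design, "sa_design")) design$meta else NULL
  w <- weights %||% rep(1, nrow(X))
  fit <- ridge_glm_irls(X, hours, offset_log_fixed_hours, w, penalty,
                        family = "poisson", beta0 = beta0,
                        pen_mask = penalty_mask(colnames(X), unpenalized))
  if (!fit$converged)
    warning("ridge Poisson IRLS did not converge in 100 iterations")
  coef_std <- fit$beta
  coef_orig <- coef_std
  if (!is.null(meta) && meta$standardize) {
    sl <- setdiff(names(coef_std), "(Intercept)")
    coef_orig[sl] <- coef_std[sl] / meta$scale[sl]
    coef_orig["(Intercept)"] <- coef_std["(Intercept)"] -
      sum(coef_std[sl] * meta$center[sl] / meta$scale[sl])
  }
  structure(list(coef_std = coef_std, coef = coef_orig, penalty = penalty,
                 deviance = fit$deviance, iterations = fit$iterations,
                 converged = fit$converged, design_meta = meta,
                 unpenalized = unpenalized,
                 n = nrow(X)), class = "sa_poisson_fit")
}

#' @export
print.sa_poisson_fit <- function(x, ...) {
  cat(sprintf("<ridge Poisson fit> %d coefficients, lambda = %.4g, deviance = %.4g, %d iterations%s\n",
              length(x$coef_std), x$penalty, x$deviance, x$iterations,
              if (x$converged) "" else " (NOT CONVERGED)"))
  invisible(x)
}

#' Predict expected absence hours
#'
#' `exp(offset + x'beta)` per row; strictly positive. `design_rows` may be a
#' standardized matrix matching the fit's encoding, or a data frame which is
#' re-encoded through the fit's own design metadata.
#'
#' @param model an `sa_poisson_fit`.
#' @param design_rows matrix or data frame.
#' @param offset_log_fixed_hours log fixed hours per row.
#' @return expected hours per row.
#' @export
predict_expected_hours <- function(model, design_rows, offset_log_fixed_hours) {
  X <- if (is.data.frame(design_rows)) {
    assert_that(!is.null(model$design_meta),
                "model carries no design metadata; pass a matrix")
    rebuild_design(model$design_meta, design_rows)
  } else design_rows
  assert_that(ncol(X) == length(model$coef_std), "encoding mismatch")
  as.numeric(exp(offset_log_fixed_hours + X %*% model$coef_std))
}

#' Select the ridge penalty by cross-validated Poisson deviance
#'
#' Seeded k-fold cross-validation minimizing held-out weighted Poisson
#' deviance over a penalty grid; ties (within numerical fuzz) resolve to the
#' larger penalty. Folds are assigned by shuffling row indices; a fold with
#' zero total weight is an error. Fits are warm-started along the grid.
#'
#' @param design `sa_design` or matrix.
#' @param hours,offset_log_fixed_hours,weights as in [fit_ridge_poisson()].
#' @param grid nonempty vector of candidate penalties.
#' @param folds number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @param unpenalized columns exempt from the penalty, as in
#'   [fit_ridge_poisson()].
#' @param rule `"min"` returns the grid argmin (ties to the larger penalty);
#'   `"1se"` returns the largest penalty whose CV deviance is within one
#'   standard error (across folds) of the minimum - the conservative choice
#'   used by the pipeline, which is markedly more stable when the hours
#'   response is overdispersed relative to the Poisson working model.
#' @return the selected penalty, with the CV table in attribute `"cv"`.
#' @export
select_penalty <- function(design, hours, offset_log_fixed_hours, weights = NULL,
                           grid, folds = 5L, seed = 1L,
                           rule = c("min", "1se"), unpenalized = NULL) {
  rule <- match.arg(rule)
  assert_that(length(grid) >= 1, "empty penalty grid")
  assert_that(folds >= 2, "need at least 2 folds")
  X <- if (inherits(design, "sa_design")) design$X else design
  w <- weights %||% rep(1, nrow(X))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(folds), nrow(X)))
  for (k in seq_len(folds)) {
    assert_that(sum(w[fold == k]) > 0, "degenerate fold with zero total weight")
  }
  grid <- sort(grid)
  cv <- matrix(0, folds, length(grid))
  for (k in seq_len(folds)) {
    tr <- fold != k
    beta_prev <- NULL
    for (g in rev(seq_along(grid))) {  # large -> small, warm-started
      fit <- ridge_glm_irls(X[tr, , drop = FALSE], hours[tr],
                            offset_log_fixed_hours[tr], w[tr], grid[g],
                            family = "poisson", beta0 = beta_prev,
                            pen_mask = penalty_mask(colnames(X), unpenalized))
      beta_prev <- fit$beta
      mu_te <- exp(offset_log_fixed_hours[!tr] +
                     as.numeric(X[!tr, , drop = FALSE] %*% fit$beta))
      cv[k, g] <- poisson_deviance(hours[!tr], mu_te, w[!tr])
    }
  }
  cvm <- colSums(cv)
  best <- max(which(cvm <= min(cvm) * (1 + 1e-12)))
  if (rule == "1se") {
    se <- stats::sd(cv[, best]) * sqrt(folds)  # SE of the summed deviance
    best <- max(which(cvm <= cvm[best] + se))
  }
  structure(grid[best],
            cv = data.frame(penalty = grid, cv_deviance = cvm,
                            cv_se = apply(cv, 2, stats::sd) * sqrt(folds)))
}

#' Default penalty grid
#'
#' 20 log-spaced penalties scaled by the number of observations, spanning
#' effectively-unpenalized to effectively-intercept-only fits.
#' @param n number of observations.
#' @param length grid size.
#' @return numeric vector.
#' @export
default_penalty_grid <- function(n, length = 20L) {
  n * 10^seq(-6, 3, length.out = length)
}

#' @noRd
penalty_mask <- function(colnames_, unpenalized) {
  if (is.null(unpenalized)) return(NULL)
  as.numeric(!colnames_ %in% unpenalized)
}
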