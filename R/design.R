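#' Build a standardized design matrix with reusable encoding metadata
#'
#' One-hot encodes categoricals against their reference level (first level;
#' exposure levels are stored with Medium/No first) via [stats::model.matrix()]
#' and standardizes every non-intercept column to weighted mean 0, sd 1 using
#' the supplied weights, so that ridge penalization is scale-equivariant.
#' Factor levels and the standardization constants are frozen in the metadata,
#' which [rebuild_design()] uses to reproduce the *identical* encoding on
#' scenario-modified data (an unseen category at rebuild time is an error).
#' Columns with zero weighted variance are dropped and recorded.
#'
#' @param data data frame of covariates and exposure-level columns.
#' @param formula right-hand-side formula naming the model terms.
#' @param weights nonnegative observation weights (default unit); used for
#'   the standardization moments.
#' @param standardize standardize columns (default TRUE).
#' @return object of class `sa_design`: list with the matrix `X` (intercept
#'   first) and `meta`.
#' @export
build_design <- function(data, formula, weights = NULL, standardize = TRUE) {
  w <- weights %||% rep(1, nrow(data))
  trm <- stats::delete.response(stats::terms(formula, data = data))
  vars <- all.vars(trm)
  fac_cols <- vars[vapply(data[vars], function(v) is.factor(v) || is.character(v), TRUE)]
  xlev <- lapply(data[fac_cols], function(v) levels(as.factor(v)))
  mf <- stats::model.frame(trm, data, xlev = xlev, na.action = stats::na.fail)
  X <- stats::model.matrix(trm, mf)
  keep <- colnames(X) != "(Intercept)"
  center <- rep(0, ncol(X)); scale_ <- rep(1, ncol(X))
  names(center) <- names(scale_) <- colnames(X)
  dropped <- character()
  if (standardize) {
    for (j in which(keep)) {
      cj <- colnames(X)[j]
      center[cj] <- wmean(X[, j], w)
      s <- wsd(X[, j], w)
      if (s < 1e-10) { dropped <- c(dropped, cj); next }
      scale_[cj] <- s
      X[, j] <- (X[, j] - center[cj]) / s
    }
  } else {
    zero_var <- vapply(which(keep), function(j) stats::var(X[, j]) < 1e-20, TRUE)
    dropped <- colnames(X)[which(keep)[zero_var]]
  }
  if (length(dropped)) X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  meta <- list(terms = trm, xlev = xlev, columns = colnames(X),
               center = center[colnames(X)], scale = scale_[colnames(X)],
               standardize = standardize, dropped = dropped)
  structure(list(X = X, meta = meta), class = "sa_design")
}

#' Rebuild a design matrix on new (e.g. scenario-modified) data
#'
#' Applies the frozen factor levels, column set and standardization constants
#' from a previous [build_design()] call, guaranteeing that predictions on
#' counterfactual data use exactly the training encoding.
#'
#' @param meta the `meta` element of an `sa_design` (or the `design_meta` of a
#'   fitted model).
#' @param newdata data frame with the same variables.
#' @return numeric design matrix.
#' @export
rebuild_design <- function(meta, newdata) {
  for (v in names(meta$xlev)) {
    lv <- meta$xlev[[v]]
    bad <- setdiff(unique(as.character(newdata[[v]])), c(lv, NA))
    assert_that(length(bad) == 0,
                paste0("unseen category in `", v, "`: ", paste(bad, collapse = ", ")))
  }
  mf <- stats::model.frame(meta$terms, newdata, xlev = meta$xlev,
                           na.action = stats::na.fail)
  X <- stats::model.matrix(meta$terms, mf)
  missing_cols <- setdiff(meta$columns, colnames(X))
  assert_that(length(missing_cols) == 0,
              paste0("encoding mismatch; missing column(s): ",
                     paste(missing_cols, collapse = ", ")))
  X <- X[, meta$columns, drop = FALSE]
  if (meta$standardize) {
    X <- sweep(X, 2, meta$center, `-`)
    X <- sweep(X, 2, meta$scale, `/`)
    if ("(Intercept)" %in% colnames(X)) X[, "(Intercept)"] <- 1
  }
  X
}
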