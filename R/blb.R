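#' Bag of Little Bootstraps settings
#'
#' Defaults follow standard BLB practice: subset size `b = ceiling(n^gamma)`
#' with `gamma = 0.7`, 10 disjoint subsets, 50 multinomial resamples per
#' subset, 95% percentile intervals.
#'
#' @param gamma subset-size exponent in `[0.5, 1]`.
#' @param s number of disjoint subsets (>= 1).
#' @param r resamples per subset (>= 2).
#' @param ci_level confidence level.
#' @param seed integer seed; the whole BLB run is reproducible from it.
#' @param log_scale compute percentile intervals on the log scale and
#'   exponentiate when averaging across subsets (appropriate for
#'   bounded-positive estimands such as rate ratios).
#' @return object of class `sa_blb_settings`.
#' @export
blb_settings <- function(gamma = 0.7, s = 10L, r = 50L, ci_level = 0.95,
                         seed = 1L, log_scale = FALSE) {
  assert_that(gamma >= 0.5 && gamma <= 1, "gamma must be in [0.5, 1]")
  assert_that(s >= 1, "need at least one subset")
  assert_that(r >= 2, "need at least two resamples per subset")
  structure(list(gamma = gamma, s = as.integer(s), r = as.integer(r),
                 ci_level = ci_level, seed = as.integer(seed),
                 log_scale = log_scale),
            class = "sa_blb_settings")
}

#' Multinomial bootstrap multiplicity weights
#'
#' One inner BLB resample: nonnegative integer counts of length `b` summing
#' exactly to `n`, drawn uniformly-multinomially, i.e. a size-`n` bootstrap of
#' the `b` subset units expressed as case multiplicities.
#'
#' @param b subset size.
#' @param n full-sample size (`b <= n`).
#' @param seed optional seed (omit to use the current RNG stream).
#' @return integer vector of length `b` summing to `n`.
#' @export
multinomial_resample_weights <- function(b, n, seed = NULL) {
  assert_that(b <= n, "subset size b must not exceed n")
  if (!is.null(seed)) set.seed(seed)
  as.integer(stats::rmultinom(1, n, rep(1 / b, b)))
}

#' Bag of Little Bootstraps confidence intervals
#'
#' Partitions the data into `s` disjoint subsets of size `b = ceiling(n^gamma)`
#' (drawn without replacement), draws `r` multinomial weight vectors of total
#' mass `n` per subset, evaluates the estimator on each weighted resample,
#' takes the within-subset percentile interval, and averages the bounds
#' across subsets. With `gamma = 1, s = 1` this reduces to the ordinary
#' percentile bootstrap. Estimators may return a scalar or a named vector
#' (e.g. all 144 contrast RRs at once); intervals are computed per component.
#'
#' A resample on which the estimator fails is recorded; a subset with more
#' than 20% failed resamples is dropped, and the run aborts if any subset is
#' dropped (conservative default).
#'
#' @param estimator `function(data_subset, mult_weights) -> numeric`; the
#'   multiplicity weights must be multiplied into any analysis (e.g. IPW)
#'   weights by the estimator.
#' @param data data frame of units (rows).
#' @param settings an [blb_settings()].
#' @return object of class `sa_blb_ci`: data frame `intervals` (component,
#'   lower, upper), the per-subset replicate array in `replicates`, and the
#'   failure count.
#' @export
blb_ci <- function(estimator, data, settings = blb_settings()) {
  n <- nrow(data)
  b <- ceiling(n^settings$gamma)
  assert_that(settings$s * b <= n,
              sprintf("cannot draw %d disjoint subsets of size %d from n = %d",
                      settings$s, b, n))
  set.seed(derive_seed(settings$seed, 0L))
  perm <- sample.int(n)
  alpha <- 1 - settings$ci_level
  lowers <- list(); uppers <- list()
  replicates <- list()
  n_fail <- 0L
  for (j in seq_len(settings$s)) {
    idx <- perm[((j - 1) * b + 1):(j * b)]
    sub <- data[idx, , drop = FALSE]
    set.seed(derive_seed(settings$seed, j))
    ests <- vector("list", settings$r)
    fails <- 0L
    for (k in seq_len(settings$r)) {
      wk <- multinomial_resample_weights(b, n)
      res <- tryCatch(estimator(sub, wk), error = function(e) {
        warning(sprintf("BLB resample failed (subset %d, resample %d): %s",
                        j, k, conditionMessage(e)))
        NULL
      })
      if (is.null(res)) fails <- fails + 1L
      ests[k] <- list(res)
    }
    n_fail <- n_fail + fails
    if (fails > 0.2 * settings$r) {
      stop(sprintf("BLB subset %d dropped (%d/%d resamples failed); aborting",
                   j, fails, settings$r))
    }
    em <- do.call(rbind, Filter(Negate(is.null), ests))
    if (settings$log_scale) em <- log(em)
    qs <- apply(em, 2, stats::quantile, probs = c(alpha / 2, 1 - alpha / 2),
                names = FALSE)
    lowers[[j]] <- qs[1, ]
    uppers[[j]] <- qs[2, ]
    replicates[[j]] <- em
  }
  lo <- Reduce(`+`, lowers) / settings$s
  hi <- Reduce(`+`, uppers) / settings$s
  if (settings$log_scale) { lo <- exp(lo); hi <- exp(hi) }
  comp <- colnames(replicates[[1]]) %||% as.character(seq_along(lo))
  structure(list(intervals = data.frame(component = comp, lower = lo,
                                        upper = hi, stringsAsFactors = FALSE),
                 replicates = replicates, n_failed = n_fail, b = b,
                 settings = settings),
            class = "sa_blb_ci")
}

#' @export
print.sa_blb_ci <- function(x, ...) {
  cat(sprintf("<BLB CI> %d component(s), b = %d, s = %d, r = %d, level %.0f%%\n",
              nrow(x$intervals), x$b, x$settings$s, x$settings$r,
              100 * x$settings$ci_level))
  if (nrow(x$intervals) <= 6) print(x$intervals)
  invisible(x)
}
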