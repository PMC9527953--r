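# small simulated regression fixture
sim_poisson <- function(n = 150, p = 3, seed = 1, beta = NULL) {
  set.seed(seed)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (p > 0) {
    X <- cbind(X, matrix(stats::rnorm(n * p), n, p,
                         dimnames = list(NULL, paste0("v", seq_len(p)))))
  }
  if (is.null(beta)) beta <- c(-3, stats::runif(p, -0.3, 0.3))
  off <- log(stats::runif(n, 800, 1800))
  y <- stats::rpois(n, exp(off + as.numeric(X %*% beta)))
  w <- stats::runif(n, 0.5, 2)
  list(X = X, y = y, off = off, w = w, beta = beta)
}

test_that("intercept-only fit equals the closed-form weighted rate", {
  s <- sim_poisson(n = 80, p = 0, seed = 2)
  fit <- fit_ridge_poisson(s$X, s$y, s$off, s$w, penalty = 0)
  expect_equal(unname(fit$coef_std[1]),
               log(sum(s$w * s$y) / sum(s$w * exp(s$off))), tolerance = 1e-10)
})

test_that("penalty 0 satisfies the weighted score equation", {
  s <- sim_poisson(n = 200, p = 4, seed = 3)
  fit <- fit_ridge_poisson(s$X, s$y, s$off, s$w, penalty = 0)
  mu <- predict_expected_hours(fit, s$X, s$off)
  expect_lt(abs(sum(s$w * mu) - sum(s$w * s$y)) / sum(s$w * s$y), 1e-6)
})

test_that("an extreme penalty shrinks every slope to numerical zero", {
  s <- sim_poisson(n = 150, p = 4, seed = 4)
  fit <- fit_ridge_poisson(s$X, s$y, s$off, s$w, penalty = 1e8)
  expect_lt(max(abs(fit$coef_std[-1])), 1e-4)
  expect_true(fit$converged)
})

test_that("IRLS matches an independent optimizer of the same objective", {
  s <- sim_poisson(n = 120, p = 3, seed = 5)
  for (lam in c(0, 5)) {
    obj <- function(b) {
      eta <- s$off + as.numeric(s$X %*% b)
      -(sum(s$w * (s$y * eta - exp(eta)))) + lam / 2 * sum(b[-1]^2)
    }
    oracle <- stats::optim(rep(0, ncol(s$X)), obj, method = "BFGS",
                           control = list(maxit = 5000, reltol = 1e-15))
    fit <- fit_ridge_poisson(s$X, s$y, s$off, s$w, penalty = lam)
    expect_equal(unname(fit$coef_std), oracle$par, tolerance = 1e-6)
  }
})

test_that("slopes are monotonically shrunk as the penalty grows", {
  s <- sim_poisson(n = 200, p = 5, seed = 6)
  norms <- vapply(c(0, 1, 10, 100, 1e4, 1e6), function(lam) {
    sqrt(sum(fit_ridge_poisson(s$X, s$y, s$off, s$w, penalty = lam)$coef_std[-1]^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-10))
})

test_that("fits are invariant to row order and jointly scale-equivariant in
           (weights, penalty)", {
  s <- sim_poisson(n = 150, p = 3, seed = 7)
  fit <- fit_ridge_poisson(s$X, s$y, s$off, s$w, penalty = 2)
  perm <- sample(nrow(s$X))
  fit_p <- fit_ridge_poisson(s$X[perm, ], s$y[perm], s$off[perm], s$w[perm],
                             penalty = 2)
  expect_equal(fit$coef_std, fit_p$coef_std, tolerance = 1e-8)
  # rescaling weights by c with penalty scaled by c reproduces the fit;
  # at penalty 0 weight rescaling alone is neutral
  fit_c <- fit_ridge_poisson(s$X, s$y, s$off, 3.7 * s$w, penalty = 2 * 3.7)
  expect_equal(fit$coef_std, fit_c$coef_std, tolerance = 1e-8)
  f0 <- fit_ridge_poisson(s$X, s$y, s$off, s$w, penalty = 0)
  f0c <- fit_ridge_poisson(s$X, s$y, s$off, 5 * s$w, penalty = 0)
  expect_equal(f0$coef_std, f0c$coef_std, tolerance = 1e-8)
})

test_that("predictions respect the offset and the encoding", {
  X <- matrix(1, 1, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- structure(list(coef_std = c("(Intercept)" = log(0.04)),
                        design_meta = NULL), class = "sa_poisson_fit")
  expect_equal(predict_expected_hours(fit, X, log(1000)), 40)
  expect_equal(predict_expected_hours(fit, X, log(2000)), 80)
  expect_error(predict_expected_hours(fit, cbind(X, X), log(1000)),
               "encoding mismatch")
})

test_that("penalty selection returns the grid argmin with seeded folds", {
  s <- sim_poisson(n = 200, p = 3, seed = 8)
  expect_equal(as.numeric(select_penalty(s$X, s$y, s$off, s$w,
                                         grid = 3.14, folds = 3, seed = 1)),
               3.14)
  lam1 <- select_penalty(s$X, s$y, s$off, s$w, grid = c(1, 100, 1e4),
                         folds = 4, seed = 9)
  lam2 <- select_penalty(s$X, s$y, s$off, s$w, grid = c(1, 100, 1e4),
                         folds = 4, seed = 9)
  expect_identical(as.numeric(lam1), as.numeric(lam2))
  expect_s3_class(attr(lam1, "cv"), "data.frame")
  # degenerate folds: zero-weight fold is an error
  w0 <- c(1, 1, rep(0, 198))
  expect_error(select_penalty(s$X, s$y, s$off, w0, grid = c(1, 10), folds = 5,
                              seed = 1), "zero total weight")
})

test_that("under pure-noise slopes CV picks the largest penalty almost always", {
  hits <- 0L
  for (rep in 1:50) {
    set.seed(rep + 100)
    n <- 150
    X <- cbind("(Intercept)" = 1,
               matrix(stats::rnorm(n * 4), n, 4,
                      dimnames = list(NULL, paste0("v", 1:4))))
    off <- log(stats::runif(n, 800, 1800))
    y <- stats::rpois(n, exp(off - 3))  # intercept-only truth
    lam <- select_penalty(X, y, off, grid = c(1, 100, 1e7), folds = 3,
                          seed = rep)
    if (as.numeric(lam) == 1e7) hits <- hits + 1L
  }
  expect_gte(hits, 40L)  # >= 80% of 50 repetitions
})

test_that("with strong signal CV beats the heaviest penalty out of sample", {
  set.seed(11)
  n <- 2000
  X <- cbind("(Intercept)" = 1,
             matrix(stats::rnorm(n * 3), n, 3,
                    dimnames = list(NULL, paste0("v", 1:3))))
  off <- log(stats::runif(n, 800, 1800))
  y <- stats::rpois(n, exp(off - 3 + X[, 2] * 0.5 - X[, 3] * 0.4))
  grid <- c(0.01, 1, 100, 1e7)
  lam <- select_penalty(X, y, off, grid = grid, folds = 5, seed = 3)
  cv <- attr(lam, "cv")
  expect_lte(cv$cv_deviance[cv$penalty == as.numeric(lam)],
             cv$cv_deviance[cv$penalty == 1e7])
  expect_lt(as.numeric(lam), 1e7)
})

test_that("outcome-model fitting recovers generating factor effects at penalty 0", {
  g <- generate_cohort(small_config(n = 20000, seed = 51,
                                    effects = c(skill_discretion = 0.8)))
  an <- build_analysis_table(g$cohort)
  w <- rep(1, nrow(an))
  specs <- outcome_model_specs(attr(an, "factors"))
  m <- fit_outcome_models(an, weights = w, penalty = 0,
                          specs = specs["working_conditions.total"])
  fit <- m$models$working_conditions$total
  est <- fit$coef["skill_discretionHigh"] - fit$coef["skill_discretionLow"]
  expect_lt(abs(unname(est) - log(0.8)), 3 * 0.02 + 0.02)
  expect_true(fit$converged)
  expect_equal(length(m$penalties), 1L)
})

test_that("eight model specifications enumerate blocks x terms", {
  specs <- outcome_model_specs(default_factor_definitions())
  expect_length(specs, 8L)
  expect_length(Filter(function(s) s$block == "reactions", specs), 4L)
  # working-conditions block excludes the reactions
  expect_false("perceived_stress" %in% specs$working_conditions.total$rhs)
  expect_true("perceived_stress" %in% specs$reactions.total$rhs)
  expect_true("skill_discretion" %in% specs$reactions.total$rhs)
  narrow <- outcome_model_specs(default_factor_definitions(),
                                reactions_adjust_conditions = FALSE)
  expect_false("skill_discretion" %in% narrow$reactions.total$rhs)
  pa <- outcome_model_specs(default_factor_definitions(), prior_absence = TRUE)
  expect_true(all(c("prior_short", "prior_long") %in% pa$reactions.total$rhs))
})
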