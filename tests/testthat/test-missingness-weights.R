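test_that("intercept-only limit: random completeness gives flat probabilities", {
  set.seed(1)
  n <- 4000
  d <- data.frame(complete = stats::runif(n) < 0.85,
                  age = stats::rnorm(n, 45, 11),
                  sex = factor(sample(c("Women", "Men"), n, TRUE)))
  m <- fit_completeness_model(d, covariates = c("age", "sex"))
  expect_lt(max(abs(m$probabilities - 0.85)), 0.05)
  expect_false(m$fallback)
  expect_error(fit_completeness_model(transform(d, complete = TRUE),
                                      covariates = "age"), "constant")
})

test_that("weights invert completeness probabilities with truncation", {
  w <- compute_weights(c(0.5, 0.8, 0.9), c(TRUE, TRUE, FALSE),
                       truncation = NULL)
  expect_equal(w$weights, c(2, 1.25, 0))
  expect_true(all(w$weights[c(1, 2)] >= 1))
  # all complete at probability 1 -> unit weights
  w1 <- compute_weights(rep(1, 5), rep(TRUE, 5))
  expect_equal(w1$weights, rep(1, 5))
  # truncation caps the heaviest weights at the stated percentile
  set.seed(2)
  p <- stats::runif(1000, 0.2, 1)
  wt <- compute_weights(p, rep(TRUE, 1000), truncation = 0.9)
  expect_equal(wt$truncation,
               as.numeric(stats::quantile(1 / p, 0.9, names = FALSE)))
  expect_lte(max(wt$weights), wt$truncation)
  expect_error(compute_weights(c(0, 0.5), c(TRUE, TRUE)), "zero completeness")
})

test_that("the completeness model recovers the generating MAR coefficients", {
  g <- generate_cohort(cohort_config(
    n_employees = 20000, seed = 41,
    missingness = list(target_share = 0.15,
                       coefficients = c(part_time = 0.6, men = 0.3))))
  g <- inject_missingness(g)
  an <- build_analysis_table(g$cohort)
  m <- fit_completeness_model(an)
  # P(complete) logit carries the negated incompleteness coefficients
  expect_equal(unname(m$coefficients["employmentPart-time"]), -0.6,
               tolerance = 0.15)
  expect_equal(unname(m$coefficients["sexMen"]), -0.3, tolerance = 0.15)
})

test_that("IPW balances complete-case covariates to the eligible sample", {
  g <- generate_cohort(cohort_config(
    n_employees = 20000, seed = 42,
    missingness = list(target_share = 0.153,
                       coefficients = c(part_time = 0.8))))
  g <- inject_missingness(g)
  an <- build_analysis_table(g$cohort)
  m <- fit_completeness_model(an)
  w <- compute_weights(m$probabilities, an$complete)
  pt <- as.numeric(an$employment == "Part-time")
  cc <- an$complete
  eligible_mean <- mean(pt)
  unweighted <- mean(pt[cc])
  weighted <- sum(w$weights[cc] * pt[cc]) / sum(w$weights[cc])
  expect_gt(abs(unweighted - eligible_mean), 0.02)   # injected selection bias
  expect_lt(abs(weighted - eligible_mean), 0.012)    # removed by IPW
  # sum of weights recovers the eligible count within truncation slack
  expect_lt(abs(w$diagnostics$sum - nrow(an)) / nrow(an), 0.02)
})

test_that("separation falls back to a ridge-stabilized fit", {
  set.seed(7)
  n <- 300
  d <- data.frame(z = factor(rep(c("a", "b"), each = n / 2)),
                  complete = rep(c(TRUE, FALSE), each = n / 2))
  d$complete[1:10] <- FALSE  # constant-within-level otherwise
  m <- suppressWarnings(fit_completeness_model(d, covariates = "z"))
  expect_true(m$fallback)
  expect_true(all(is.finite(m$probabilities)))
  expect_true(all(m$probabilities > 0 & m$probabilities < 1))
})
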