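test_that("Likert-to-score mapping is the stated linear map with reversal", {
  expect_equal(likert_to_score(1, 5), 0)
  expect_equal(likert_to_score(5, 5), 100)
  expect_equal(likert_to_score(3, 5), 50)
  expect_equal(likert_to_score(2, 7, reversed = TRUE), 100 * 5 / 6)
  expect_true(is.na(likert_to_score(NA, 5)))
  expect_error(likert_to_score(6, 5), "out of")
  expect_error(likert_to_score(0, 7), "out of")
  expect_error(likert_to_score(3, 1), ">= 2")
})

test_that("likert_to_score is a bijection and double reversal is identity", {
  for (K in c(5, 7)) {
    fwd <- likert_to_score(1:K, K)
    expect_equal(length(unique(fwd)), K)
    expect_equal(sort(fwd), fwd)  # monotone
    rev2 <- 100 - likert_to_score(1:K, K, reversed = TRUE)
    expect_equal(rev2, fwd)
  }
})

test_that("scale scores average non-missing items under the half-items rule", {
  expect_equal(scale_score(c(0, 50, 100)), 50)
  expect_equal(scale_score(100), 100)
  expect_true(is.na(scale_score(c(NA, NA, 50))))     # 1 of 3 < half
  expect_equal(scale_score(c(NA, 25, 75)), 50)       # 2 of 3 >= half
  expect_true(is.na(scale_score(c(NA, 25, 75), na_rule = "strict")))
  expect_error(scale_score(numeric(0)), "empty")
  # item-order invariance
  set.seed(3)
  x <- c(stats::runif(4, 0, 100), NA)
  expect_equal(scale_score(x), scale_score(rev(x)))
})

test_that("cutpoints sit at the quartiles or as close as possible", {
  cp <- fit_cutpoints(1:100)
  expect_equal(cp$achieved_low_share, 0.25)
  expect_equal(cp$achieved_high_share, 0.25)
  expect_equal(cp$lower_cut, 25)
  expect_equal(cp$upper_cut, 76)

  # spiky distribution: the smaller deviation wins on each side
  s <- c(rep(0, 10), rep(50, 80), rep(100, 10))
  cp <- fit_cutpoints(s)
  expect_equal(cp$lower_cut, 0)
  expect_equal(cp$upper_cut, 100)
  expect_equal(cp$achieved_low_share, 0.10)
  expect_equal(cp$achieved_high_share, 0.10)

  expect_error(fit_cutpoints(c(rep(1, 9), 2)), "distinct")
})

test_that("categorization respects boundary rules and reproduces achieved shares", {
  cp <- fit_cutpoints(1:100)
  expect_equal(as.character(categorize(cp$lower_cut, cp)), "Low")
  expect_equal(as.character(categorize(cp$upper_cut, cp)), "High")
  expect_equal(as.character(categorize((cp$lower_cut + cp$upper_cut) / 2, cp)),
               "Medium")
  expect_true(is.na(categorize(NA, cp)))

  set.seed(9)
  s <- stats::runif(500, 0, 100)
  cp <- fit_cutpoints(s)
  lev <- categorize(s, cp)
  expect_equal(mean(lev == "Low"), cp$achieved_low_share)
  expect_equal(mean(lev == "High"), cp$achieved_high_share)
  expect_equal(sum(table(lev)), 500)  # exhaustive, mutually exclusive
  # with continuous scores the achieved shares are 0.25 within 1/n
  expect_lt(abs(cp$achieved_low_share - 0.25), 1 / 500 + 1e-12)
  expect_lt(abs(cp$achieved_high_share - 0.25), 1 / 500 + 1e-12)
})

test_that("exposure matrix covers all factors and tracks completeness exactly", {
  gen <- generate_cohort(small_config(n = 800, seed = 4))
  ex <- build_exposure_matrix(gen$cohort, gen$cohort$factors)
  expect_equal(ncol(ex$levels) - 1L, 5L)
  expect_equal(sum(ex$incomplete), 0L)
  expect_setequal(levels(ex$levels$skill_discretion), c("Low", "Medium", "High"))
  expect_setequal(levels(ex$levels$bullying), c("No", "Yes"))

  # after injection the incomplete share matches the injected share exactly
  gen2 <- generate_cohort(small_config(n = 2000, seed = 4,
                                       miss = list(target_share = 0.15)))
  gen2 <- inject_missingness(gen2)
  ex2 <- build_exposure_matrix(gen2$cohort, gen2$cohort$factors)
  expect_equal(mean(ex2$incomplete), mean(!gen2$cohort$employees$complete))

  # unknown item id is a contract error
  bad <- factor_definition("Ghost factor", "scale",
                           items = c("nope_1", "nope_2"), points = c(5, 5),
                           reversed = c(FALSE, FALSE))
  expect_error(build_exposure_matrix(gen$cohort, list(bad)), "unknown item")
})
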