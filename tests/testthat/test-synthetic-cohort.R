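test_that("generation is deterministic under config + seed", {
  g1 <- generate_cohort(small_config(n = 500, seed = 17))
  g2 <- generate_cohort(small_config(n = 500, seed = 17))
  expect_identical(g1$cohort$employees, g2$cohort$employees)
  expect_identical(g1$cohort$spells, g2$cohort$spells)
  g3 <- generate_cohort(small_config(n = 500, seed = 18))
  expect_false(identical(g1$cohort$spells, g3$cohort$spells))
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_employees = 0), "positive")
  expect_error(cohort_config(term_split = c(short = 0.5, intermediate = 0.4,
                                            long = 0.2)), "sum to 1")
  expect_error(cohort_config(true_effects = c(skill_discretion = -1),
                             factors = small_factors()), "strictly positive")
  expect_error(cohort_config(true_effects = c(nonexistent = 0.8),
                             factors = small_factors()), "not among factors")
})

test_that("spell hours split exactly into terms and classify as intended", {
  g <- generate_cohort(small_config(n = 1500, seed = 5))
  sp <- g$cohort$spells
  expect_true(all(sp$duration_days >= 1 & sp$duration_days <= 365))
  expect_equal(sp$hours,
               sp$duration_days *
                 g$cohort$employees$daily_hours[match(sp$id, g$cohort$employees$id)])
  out <- aggregate_outcomes(sp, g$cohort$employees[, c("id", "fixed_hours")])
  expect_equal(out$total_hours,
               out$short_hours + out$intermediate_hours + out$long_hours)
})

test_that("ground-truth rate ratios follow the generating coefficients", {
  # null effects: every contrast is exactly 1
  g0 <- generate_cohort(small_config(n = 400, effects = 1, seed = 2))
  most <- intervention_scenario(stats::setNames(
    rep("most_desirable", 5), names(g0$truth$rr[, 1])))
  least <- intervention_scenario(stats::setNames(
    rep("least_desirable", 5), names(g0$truth$rr[, 1])))
  obs <- intervention_scenario()
  for (term in c("total", "short", "intermediate", "long")) {
    expect_equal(as.numeric(ground_truth_rr(g0$truth, list(most, least), term)), 1)
  }
  # multiplicative effects: joint RR is the product of per-factor RRs
  g <- generate_cohort(small_config(
    n = 400, effects = c(bullying = 0.8, skill_discretion = 0.9), seed = 2))
  expect_equal(as.numeric(ground_truth_rr(g$truth, list(most, least))), 0.72,
               tolerance = 1e-12)
  expect_equal(prod(g$truth$rr[, "total"]), 0.72, tolerance = 1e-12)
  # observed vs observed is the identity contrast
  expect_equal(as.numeric(ground_truth_rr(g$truth, list(obs, obs))), 1)
  expect_equal(attr(ground_truth_rr(g$truth, list(most, obs)), "method"),
               "exact_enumeration")
  expect_error(ground_truth_rr(g$truth, list(
    intervention_scenario(c(ghost = "most_desirable")), obs)), "unknown factor")
})

test_that("realized overall rate is near the configured baseline", {
  g <- generate_cohort(cohort_config(n_employees = 20000, seed = 31,
                                     missingness = list(target_share = 0)))
  out <- aggregate_outcomes(g$cohort$spells,
                            g$cohort$employees[, c("id", "fixed_hours")])
  rate <- population_rate(out)[["total"]]
  expect_lt(abs(rate - 0.04), 0.2 * 0.04)
})

test_that("realized per-term hour shares converge to term_split", {
  g <- generate_cohort(cohort_config(n_employees = 50000, seed = 32,
                                     missingness = list(target_share = 0)))
  out <- aggregate_outcomes(g$cohort$spells,
                            g$cohort$employees[, c("id", "fixed_hours")])
  r <- population_rate(out)
  shares <- r[c("short", "intermediate", "long")] / r[["total"]]
  expect_true(all(abs(shares - c(0.37, 0.32, 0.31)) < 0.03))
})

test_that("missingness injection hits the target share under MAR", {
  g <- generate_cohort(cohort_config(n_employees = 20000, seed = 33))
  g <- inject_missingness(g)
  inc_share <- mean(!g$cohort$employees$complete)
  expect_lt(abs(inc_share - 0.153), 0.02)
  item_cols <- unlist(lapply(g$cohort$factors, `[[`, "items"))
  inc <- !g$cohort$employees$complete
  expect_true(all(is.na(g$cohort$employees[inc, item_cols])))
  expect_true(!anyNA(g$cohort$employees[!inc, item_cols]))
  expect_false(is.null(g$truth$missingness$intercept))

  # zero target leaves the cohort unchanged
  g0 <- generate_cohort(small_config(n = 300, seed = 2))
  expect_identical(inject_missingness(g0)$cohort$employees,
                   g0$cohort$employees)

  # a strong part-time coefficient raises incompleteness among part-timers
  gpt <- generate_cohort(small_config(
    n = 8000, seed = 34,
    miss = list(target_share = 0.15, coefficients = c(part_time = 1.5))))
  gpt <- inject_missingness(gpt)
  emp <- gpt$cohort$employees
  pt <- emp$employment == "Part-time"
  expect_gt(mean(!emp$complete[pt]), mean(!emp$complete[!pt]))
})
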