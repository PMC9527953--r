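bullying_def <- function() list(bullying = factor_definition("Bullying", "binary",
                                                             items = "bullying"))

test_that("scenarios rewrite exposure columns and nothing else", {
  g <- generate_cohort(small_config(n = 300, seed = 8))
  an <- build_analysis_table(g$cohort)
  factors <- attr(an, "factors")
  # observed scenario is the identity
  expect_identical(apply_scenario(an, intervention_scenario(), factors), an)
  mod <- apply_scenario(an, intervention_scenario(
    c(bullying = "most_desirable", skill_discretion = "least_desirable")),
    factors)
  expect_true(all(mod$bullying == "No"))
  expect_true(all(mod$skill_discretion == "Low"))
  expect_identical(mod$justice, an$justice)        # non-targeted untouched
  expect_identical(mod$age, an$age)                # covariates untouched
  expect_error(apply_scenario(an, intervention_scenario(
    c(ghost = "most_desirable")), factors), "unknown factor")
})

test_that("standardized observed rate equals the weighted observed rate at
           penalty 0", {
  g <- generate_cohort(small_config(n = 3000, seed = 9,
                                    effects = c(bullying = 0.85)))
  an <- build_analysis_table(g$cohort)
  w <- stats::runif(nrow(an), 0.5, 2)
  m <- fit_outcome_models(an, weights = w, penalty = 0)
  obs <- standardized_rate(m$models$reactions$total, an,
                           intervention_scenario(), w)
  expect_equal(obs, sum(w * an$total_hours) / sum(w * an$fixed_hours),
               tolerance = 1e-8)
})

test_that("standardization agrees with the exhaustive stratum-wise oracle", {
  d <- make_discrete_cohort(n = 400, k = 3, seed = 5)
  cell <- do.call(interaction, c(unname(d[paste0("x", 1:3)]), list(d$bullying)))
  expect_true(all(table(cell) > 0))  # oracle precondition
  w <- stats::runif(nrow(d), 0.5, 2)
  design <- build_design(d, ~ x1 * x2 * x3 * bullying, w)
  fit <- fit_ridge_poisson(design, d$total_hours, log(d$fixed_hours), w,
                           penalty = 0)
  fit$term <- "total"; fit$block <- "saturated"
  for (scn in list(c(bullying = "most_desirable"),
                   c(bullying = "least_desirable"))) {
    got <- standardized_rate(fit, d, intervention_scenario(scn), w,
                             bullying_def())
    want <- brute_force_rate(d, w, if (scn == "most_desirable") "No" else "Yes")
    expect_equal(got, want, tolerance = 1e-8)
  }
  got_obs <- standardized_rate(fit, d, intervention_scenario(), w,
                               bullying_def())
  expect_equal(got_obs, brute_force_rate(d, w, NULL), tolerance = 1e-8)
})

test_that("contrasting a scenario with itself gives RR exactly 1", {
  g <- generate_cohort(small_config(n = 1000, seed = 10))
  an <- build_analysis_table(g$cohort)
  w <- rep(1, nrow(an))
  m <- fit_outcome_models(an, weights = w, penalty = 50)
  fit <- m$models$working_conditions$short
  scn <- intervention_scenario(c(justice = "most_desirable"))
  r1 <- standardized_rate(fit, an, scn, w)
  expect_identical(r1 / r1, 1)
  # zero-coefficient factor: RR exactly 1
  fit0 <- fit
  zcols <- grep("^justice", names(fit0$coef_std))
  fit0$coef_std[zcols] <- 0
  rr <- etiologic_rr(fit0, an, "justice", weights = w)
  expect_equal(rr$rr, 1)
})

test_that("realistic contrasts sit between etiologic contrasts and 1 under a
           monotone protective fit", {
  g <- generate_cohort(small_config(n = 1500, seed = 12))
  an <- build_analysis_table(g$cohort)
  w <- rep(1, nrow(an))
  m <- fit_outcome_models(an, weights = w, penalty = 100)
  fit <- m$models$reactions$total
  # force a deterministic monotone protective effect: High < Medium < Low
  for (f in attr(an, "factors")) {
    lvls <- grep(paste0("^", f$id), names(fit$coef_std), value = TRUE)
    fit$coef_std[lvls] <- 0
    if (f$kind == "binary") {
      fit$coef_std[paste0(f$id, "Yes")] <- 0.2
    } else {
      fit$coef_std[paste0(f$id, "Low")] <- 0.2
      fit$coef_std[paste0(f$id, "High")] <- -0.2
    }
  }
  for (fid in names(attr(an, "factors"))) {
    et <- etiologic_rr(fit, an, fid, weights = w)
    re <- realistic_rr(fit, an, fid, weights = w)
    expect_lt(et$rr, 1)
    expect_gte(re$rr, et$rr)
    expect_lte(re$rr, 1)
  }
})

test_that("the full contrast table enumerates 18 sets x 2 types x 4 terms", {
  g <- generate_cohort(cohort_config(n_employees = 1500, seed = 13,
                                     missingness = list(target_share = 0)))
  an <- build_analysis_table(g$cohort)
  w <- rep(1, nrow(an))
  m <- fit_outcome_models(an, weights = w, penalty = 500)
  ctr <- run_all_contrasts(m, an, weights = w)
  expect_equal(nrow(ctr), 144L)
  key <- with(ctr, paste(factor_set, contrast_type, term))
  expect_equal(anyDuplicated(key), 0L)
  expect_true(all(ctr$rr > 0))
  expect_equal(ctr$rr, ctr$rate_num / ctr$rate_den)
  # model routing: wc singles on the wc block, reactions + joint on reactions
  expect_equal(unique(ctr$model_block[ctr$factor_set == "bullying"]),
               "working_conditions")
  expect_equal(unique(ctr$model_block[ctr$factor_set == "perceived_stress"]),
               "reactions")
  expect_equal(unique(ctr$model_block[ctr$factor_set == "all_factors"]),
               "reactions")
  # missing model for a term fails loudly
  m2 <- m
  m2$models$reactions$long <- NULL
  expect_error(run_all_contrasts(m2, an, weights = w), "missing")
})
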