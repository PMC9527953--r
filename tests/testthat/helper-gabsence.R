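# Shared fixtures: everything is generated in code at test time.

# A reduced five-factor world (two binaries, two working-condition scales,
# one reaction scale) for fast pipeline-level tests.
small_factors <- function() {
  default_factor_definitions(c("Bullying", "Skill discretion", "Justice",
                               "Work demands", "Perceived stress"))
}

small_config <- function(n = 2000, effects = 1, seed = 1,
                         miss = list(target_share = 0), ...) {
  cohort_config(n_employees = n, true_effects = effects,
                missingness = miss, factors = small_factors(),
                seed = seed, ...)
}

# Discrete-cohort fixture for brute-force standardization oracles:
# `k` binary covariates plus one binary exposure ("bullying"), hours drawn
# from cell-specific rates so a saturated model reproduces cell means.
make_discrete_cohort <- function(n = 400, k = 3, seed = 5) {
  set.seed(seed)
  d <- data.frame(id = seq_len(n))
  for (j in seq_len(k)) d[[paste0("x", j)]] <- factor(sample(c("a", "b"), n, TRUE))
  d$bullying <- factor(sample(c("No", "Yes"), n, TRUE, prob = c(0.7, 0.3)),
                       levels = c("No", "Yes"))
  d$fixed_hours <- sample(c(1200, 1600), n, TRUE)
  cell <- do.call(interaction, c(unname(d[paste0("x", seq_len(k))]),
                                 list(d$bullying), drop = FALSE))
  rate <- stats::runif(nlevels(cell), 0.01, 0.08)[as.integer(cell)]
  d$total_hours <- stats::rpois(n, rate * d$fixed_hours)
  d$complete <- TRUE
  d
}

# Direct stratum-wise standardization: sum_x P_hat(x) * rate(x, e) with
# weighted empirical cell rates and covariate shares - the independent oracle
# for standardized_rate().
brute_force_rate <- function(d, w, exposure_level = NULL) {
  covs <- grep("^x", names(d), value = TRUE)
  strata <- do.call(interaction, c(unname(d[covs]), drop = FALSE))
  tot <- sum(w * d$fixed_hours)
  out <- 0
  for (s in levels(strata)) {
    in_s <- strata == s
    if (!any(in_s)) next
    p_s <- sum(w[in_s] * d$fixed_hours[in_s]) / tot
    if (is.null(exposure_level)) {
      rate_s <- sum(w[in_s] * d$total_hours[in_s]) /
        sum(w[in_s] * d$fixed_hours[in_s])
    } else {
      in_se <- in_s & d$bullying == exposure_level
      rate_s <- sum(w[in_se] * d$total_hours[in_se]) /
        sum(w[in_se] * d$fixed_hours[in_se])
    }
    out <- out + p_s * rate_s
  }
  out
}
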