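#' Classify an absence spell by duration
#'
#' Spells of 1-3 days are short-term, 4-28 days intermediate-term, and 29 days
#' or more long-term. Each spell belongs to exactly one term (terms are
#' mutually exclusive). Vectorized.
#'
#' @param duration_days positive integer day count(s).
#' @return factor with levels `short`, `intermediate`, `long`.
#' @export
#' @examples
#' classify_spell(c(1, 3, 4, 28, 29))
classify_spell <- function(duration_days) {
  assert_that(all(duration_days >= 1), "spell duration must be >= 1 day")
  factor(ifelse(duration_days <= 3, "short",
         ifelse(duration_days <= 28, "intermediate", "long")),
         levels = c("short", "intermediate", "long"))
}

#' Aggregate absence spells into per-employee term-specific hours
#'
#' Sums each employee's absence hours by spell term. Employees without spells
#' get all-zero hours; employees with non-positive fixed working hours are
#' excluded (the rate offset is undefined for them) and their count recorded
#' in the `"excluded"` attribute.
#'
#' @param spells data frame with columns `id`, `duration_days`, `hours`.
#' @param fixed_hours data frame with columns `id`, `fixed_hours` (one row per
#'   employee).
#' @return data frame (`id`, `fixed_hours`, `total_hours`, `short_hours`,
#'   `intermediate_hours`, `long_hours`), one row per included employee.
#' @export
aggregate_outcomes <- function(spells, fixed_hours) {
  assert_that(all(c("id", "fixed_hours") %in% names(fixed_hours)),
              "fixed_hours needs columns id, fixed_hours")
  orphans <- setdiff(spells$id, fixed_hours$id)
  assert_that(length(orphans) == 0,
              paste0("spells reference unknown employee id(s): ",
                     paste(utils::head(orphans, 5), collapse = ", ")))
  out <- data.frame(id = fixed_hours$id, fixed_hours = fixed_hours$fixed_hours,
                    total_hours = 0, short_hours = 0,
                    intermediate_hours = 0, long_hours = 0)
  if (nrow(spells) > 0) {
    assert_that(all(spells$hours >= 0), "spell hours must be nonnegative")
    term <- classify_spell(spells$duration_days)
    for (tt in levels(term)) {
      sel <- term == tt
      agg <- tapply(spells$hours[sel], spells$id[sel], sum)
      col <- paste0(tt, "_hours")
      idx <- match(names(agg), out$id)
      out[[col]][idx] <- as.numeric(agg)
    }
    out$total_hours <- out$short_hours + out$intermediate_hours + out$long_hours
  }
  excluded <- sum(out$fixed_hours <= 0)
  out <- out[out$fixed_hours > 0, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Population sickness absence rates
#'
#' Weighted pooled rates: for each term, the weighted sum of absence hours
#' divided by the weighted sum of fixed working hours. With unit weights this
#' is the cohort rate of the paper-style decomposition (term rates sum to the
#' total rate exactly). Invariant to a common rescaling of the weights.
#'
#' @param records outcome records from [aggregate_outcomes()].
#' @param weights nonnegative per-record weights (default: unit).
#' @return named numeric vector `total`, `short`, `intermediate`, `long`.
#' @export
population_rate <- function(records, weights = NULL) {
  w <- weights %||% rep(1, nrow(records))
  assert_that(length(w) == nrow(records), "weights must align with records")
  assert_that(all(w >= 0) && sum(w) > 0, "weights must be nonnegative with a positive sum")
  denom <- sum(w * records$fixed_hours)
  c(total = sum(w * records$total_hours) / denom,
    short = sum(w * records$short_hours) / denom,
    intermediate = sum(w * records$intermediate_hours) / denom,
    long = sum(w * records$long_hours) / denom)
}
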