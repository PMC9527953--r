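#' Convert a Likert response to a 0-100 score
#'
#' Linear map of a response on a K-point Likert item onto `[0, 100]`:
#' `100 * (response - 1) / (K - 1)`, or `100 * (K - response) / (K - 1)` for
#' reversed items (raw high response = less desirable), so that higher scores
#' are always more desirable. Vectorized over `response`.
#'
#' @param response integer response(s) in `1..points`; `NA` passes through.
#' @param points Likert cardinality K (>= 2).
#' @param reversed flip the item's polarity.
#' @return numeric score(s) in `[0, 100]`.
#' @export
#' @examples
#' likert_to_score(1, 5)          # 0
#' likert_to_score(5, 5)          # 100
#' likert_to_score(2, 7, TRUE)    # 83.33
likert_to_score <- function(response, points, reversed = FALSE) {
  assert_that(is_scalar_number(points) && points >= 2, "points must be >= 2")
  ok <- is.na(response) | (response >= 1 & response <= points & response == round(response))
  assert_that(all(ok), "response out of 1..points range")
  if (reversed) 100 * (points - response) / (points - 1)
  else 100 * (response - 1) / (points - 1)
}

#' Average item scores into a factor scale score
#'
#' Arithmetic mean of the non-missing item scores. Under the default COPSOQ
#' convention (`na_rule = "half"`) the scale score is computed when at least
#' half the items are non-missing and is missing otherwise; under
#' `na_rule = "strict"` any missing item makes the scale missing.
#'
#' @param item_scores numeric vector of 0-100 item scores (may contain `NA`).
#' @param na_rule `"half"` or `"strict"`.
#' @return the scale score, or `NA` under the missingness rule.
#' @export
scale_score <- function(item_scores, na_rule = c("half", "strict")) {
  na_rule <- match.arg(na_rule)
  assert_that(length(item_scores) >= 1, "empty item list")
  n_ok <- sum(!is.na(item_scores))
  if (na_rule == "strict" && n_ok < length(item_scores)) return(NA_real_)
  if (n_ok < length(item_scores) / 2 || n_ok == 0) return(NA_real_)
  mean(item_scores, na.rm = TRUE)
}

#' Fit quartile cutpoints for a factor score
#'
#' Chooses the Low/High category boundaries at the 25th and 75th percentile
#' "or as close as possible": among candidate cuts at observed unique score
#' values, `lower_cut` minimizes `|share(score <= cut) - target_low|` and
#' `upper_cut` minimizes `|share(score >= cut) - target_high|`, subject to
#' `lower_cut < upper_cut`. Ties are broken toward the cut giving the smaller
#' extreme group, so the intervention target (the top quartile) is never
#' inflated. The achieved shares are recorded in the result.
#'
#' @param scores numeric scores; `NA` ignored. Needs >= 3 distinct values.
#' @param target_low,target_high target tail shares (default 0.25 each).
#' @return object of class `sa_cutpoints` with elements `lower_cut`,
#'   `upper_cut`, `achieved_low_share`, `achieved_high_share`.
#' @export
fit_cutpoints <- function(scores, target_low = 0.25, target_high = 0.25) {
  s <- scores[!is.na(scores)]
  u <- sort(unique(s))
  assert_that(length(u) >= 3,
              "fewer than 3 distinct score values; declare the factor binary or exclude it")
  n <- length(s)
  share_le <- cumsum(tabulate(match(s, u), length(u))) / n
  share_ge <- rev(cumsum(rev(tabulate(match(s, u), length(u))))) / n

  pick <- function(dev, size) {
    # smallest deviation; ties (within numerical fuzz) -> smaller extreme group
    cand <- which(dev <= min(dev) + 1e-12)
    cand[which.min(size[cand])]
  }
  i_low <- pick(abs(share_le - target_low), share_le)
  i_up <- pick(abs(share_ge - target_high), share_ge)
  if (u[i_low] >= u[i_up]) {
    # degenerate spacing: joint search over admissible pairs (few unique values)
    best <- NULL; best_obj <- Inf
    for (i in seq_len(length(u) - 1)) {
      for (j in seq(i + 1, length(u))) {
        obj <- abs(share_le[i] - target_low) + abs(share_ge[j] - target_high)
        tie <- share_le[i] + share_ge[j]
        if (obj < best_obj - 1e-12 ||
            (obj < best_obj + 1e-12 && !is.null(best) && tie < best$tie - 1e-12)) {
          best <- list(i = i, j = j, tie = tie); best_obj <- obj
        }
      }
    }
    i_low <- best$i; i_up <- best$j
  }
  structure(list(lower_cut = u[i_low], upper_cut = u[i_up],
                 achieved_low_share = share_le[i_low],
                 achieved_high_share = share_ge[i_up],
                 target_low = target_low, target_high = target_high,
                 n = n), class = "sa_cutpoints")
}

#' @export
print.sa_cutpoints <- function(x, ...) {
  cat(sprintf("<cutpoints> low <= %.3g (share %.3f), high >= %.3g (share %.3f)\n",
              x$lower_cut, x$achieved_low_share, x$upper_cut, x$achieved_high_share))
  invisible(x)
}

#' Categorize scores into Low/Medium/High
#'
#' `score <= lower_cut` is Low, `score >= upper_cut` is High, everything
#' strictly in between is Medium; missing stays missing. Cutpoints should be
#' fitted on the reference (analysis) population with [fit_cutpoints()].
#'
#' @param scores numeric scores.
#' @param cutpoints an `sa_cutpoints` object.
#' @return factor with levels `Medium`, `Low`, `High` (reference level first).
#' @export
categorize <- function(scores, cutpoints) {
  assert_that(inherits(cutpoints, "sa_cutpoints"), "cutpoints must come from fit_cutpoints()")
  lab <- ifelse(is.na(scores), NA_character_,
         ifelse(scores <= cutpoints$lower_cut, "Low",
         ifelse(scores >= cutpoints$upper_cut, "High", "Medium")))
  factor(lab, levels = c("Medium", "Low", "High"))
}

#' Compute per-factor 0-100 scores for a cohort table
#'
#' @param data data frame containing the factor's item columns.
#' @param f an `sa_factor` (scale kind).
#' @param na_rule passed to [scale_score()].
#' @return numeric vector of scale scores.
#' @export
factor_scores <- function(data, f, na_rule = "half") {
  assert_that(f$kind == "scale", "factor_scores applies to scale factors")
  missing_items <- setdiff(f$items, names(data))
  assert_that(length(missing_items) == 0,
              paste0("unknown item id(s): ", paste(missing_items, collapse = ", ")))
  sc <- mapply(function(it, K, rev) likert_to_score(data[[it]], K, rev),
               f$items, f$points, f$reversed, SIMPLIFY = TRUE)
  sc <- matrix(sc, nrow = nrow(data))
  # vectorized equivalent of applying scale_score() row-wise
  n_ok <- rowSums(!is.na(sc))
  out <- rowMeans(sc, na.rm = TRUE)
  min_ok <- if (na_rule == "strict") ncol(sc) else ncol(sc) / 2
  out[n_ok < min_ok | n_ok == 0] <- NA_real_
  out
}

#' Build the per-employee exposure matrix of categorical factor levels
#'
#' Converts raw Likert items into 0-100 scale scores, categorizes them at the
#' quartile cutpoints (fitted on the supplied data unless `cutpoints` are
#' given, e.g. when re-applying reference cutpoints to scenario data), maps
#' binary adversity items to Yes/No, and flags employees with any missing
#' factor as incomplete.
#'
#' @param cohort an `sa_cohort` (see [generate_cohort()]) or a plain employee
#'   data frame containing `id` and the item columns.
#' @param factors named list of [factor_definition()]s.
#' @param cutpoints optional named list of pre-fitted `sa_cutpoints`.
#' @param na_rule item-missingness rule for [scale_score()].
#' @return object of class `sa_exposure`: list with `levels` (data frame of
#'   `id` + one factor-level column per factor id), `cutpoints`, `scores`,
#'   and logical `incomplete`.
#' @export
build_exposure_matrix <- function(cohort, factors, cutpoints = NULL,
                                  na_rule = "half") {
  data <- if (inherits(cohort, "sa_cohort")) cohort$employees else cohort
  out <- data.frame(id = data$id)
  cps <- list()
  scores <- data.frame(id = data$id)
  for (f in factors) {
    if (f$kind == "binary") {
      it <- f$items[[1]]
      assert_that(it %in% names(data), paste0("unknown item id: ", it))
      v <- data[[it]]
      assert_that(all(v %in% c(0, 1) | is.na(v)),
                  paste0("binary item ", it, " must be coded 0/1"))
      out[[f$id]] <- factor(ifelse(is.na(v), NA_character_,
                                   ifelse(v == 1, "Yes", "No")),
                            levels = c("No", "Yes"))
    } else {
      sc <- factor_scores(data, f, na_rule)
      cp <- if (!is.null(cutpoints) && !is.null(cutpoints[[f$id]]))
        cutpoints[[f$id]] else fit_cutpoints(sc)
      cps[[f$id]] <- cp
      scores[[f$id]] <- sc
      out[[f$id]] <- categorize(sc, cp)
    }
  }
  incomplete <- rowSums(is.na(out[, setdiff(names(out), "id"), drop = FALSE])) > 0
  structure(list(levels = out, cutpoints = cps, scores = scores,
                 incomplete = incomplete),
            class = "sa_exposure")
}

#' @export
print.sa_exposure <- function(x, ...) {
  cat(sprintf("<exposure matrix> %d employees x %d factors; %d (%.1f%%) incomplete\n",
              nrow(x$levels), ncol(x$levels) - 1L, sum(x$incomplete),
              100 * mean(x$incomplete)))
  invisible(x)
}
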