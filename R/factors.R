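#' Define a psychosocial work factor
#'
#' A factor is either a multi-item Likert *scale* (scored 0-100, averaged,
#' categorized Low/Medium/High at the quartiles) or a single-item *binary*
#' adversity (bullying, sexual harassment, threats, violence; Yes/No). All
#' scales are polarity-oriented at definition time so that higher scores are
#' always more desirable; items whose raw high response is *less* desirable
#' are flagged `reversed` and flipped during scoring. The most desirable level
#' is therefore always `"High"` for scales and `"No"` for binary factors, and
#' the least desirable level the reverse (`"Low"` / `"Yes"`).
#'
#' @param name display name, e.g. `"Skill discretion"`.
#' @param kind `"scale"` or `"binary"`.
#' @param items character vector of item identifiers (columns of the cohort
#'   table). Binary factors have exactly one item coded 0 = No, 1 = Yes.
#' @param points integer vector, Likert cardinality per item (5 or 7);
#'   ignored for binary factors.
#' @param reversed logical vector per item; `TRUE` when a high raw response is
#'   less desirable.
#' @param block `"working_conditions"` or `"reactions"` (cognitive and
#'   emotional reactions).
#' @return an object of class `sa_factor`.
#' @export
factor_definition <- function(name, kind = c("scale", "binary"), items,
                              points = rep(5L, length(items)),
                              reversed = rep(FALSE, length(items)),
                              block = c("working_conditions", "reactions")) {
  kind <- match.arg(kind)
  block <- match.arg(block)
  assert_that(length(items) >= 1, "a factor needs at least one item")
  if (kind == "binary") {
    assert_that(length(items) == 1, "binary factors have exactly one item")
  } else {
    assert_that(all(points %in% c(5L, 7L)), "Likert items must have 5 or 7 points")
    assert_that(length(points) == length(items) && length(reversed) == length(items),
                "points/reversed must align with items")
  }
  structure(list(
    name = name,
    id = factor_id(name),
    kind = kind,
    items = items,
    points = as.integer(points),
    reversed = reversed,
    block = block,
    desirable_level = if (kind == "binary") "No" else "High",
    least_desirable_level = if (kind == "binary") "Yes" else "Low"
  ), class = "sa_factor")
}

#' @noRd
factor_id <- function(name) gsub("[^a-z0-9]+", "_", tolower(name))

#' @export
print.sa_factor <- function(x, ...) {
  cat(sprintf("<%s factor> %s [%s]: %d item(s); desirable = %s\n",
              x$kind, x$name, x$block, length(x$items), x$desirable_level))
  invisible(x)
}

#' Default definitions of the 17 psychosocial work factors
#'
#' Fifteen psychosocial working conditions (eleven Likert scales and the four
#' binary adversities bullying, sexual harassment, threats and violence) plus
#' two cognitive and emotional reactions (job satisfaction, perceived stress).
#' The survey instrument's item-to-scale map is not public, so this default
#' uses a synthetic 40-item map with the field-typical structure: 2-3 items
#' per scale, a mix of 5- and 7-point response formats, and reversed items for
#' the negatively worded dimensions (work demands, perceived stress).
#'
#' @param which optional character vector of factor names (or ids) to keep,
#'   e.g. for small test cohorts.
#' @return named list of [factor_definition()] objects, keyed by factor id.
#' @export
default_factor_definitions <- function(which = NULL) {
  mk <- function(name, n_items, points = 5L, reversed = FALSE,
                 block = "working_conditions", kind = "scale") {
    id <- factor_id(name)
    if (kind == "binary") {
      factor_definition(name, "binary", items = id, block = block)
    } else {
      factor_definition(name, "scale",
                        items = sprintf("%s_%d", id, seq_len(n_items)),
                        points = rep(as.integer(points), n_items),
                        reversed = rep(reversed, length.out = n_items),
                        block = block)
    }
  }
  defs <- list(
    mk("Bullying", 1, kind = "binary"),
    mk("Collaboration", 3),
    mk("Inclusiveness", 2),
    mk("Influence on work", 3),
    mk("Influence on schedule", 2),
    mk("Justice", 3),
    mk("Leadership quality", 3),
    mk("Predictability", 3),
    mk("Role clarity", 3),
    mk("Sexual harassment", 1, kind = "binary"),
    mk("Skill discretion", 3),
    mk("Trust", 3),
    mk("Threats", 1, kind = "binary"),
    mk("Violence", 1, kind = "binary"),
    mk("Work demands", 3, points = 7L, reversed = TRUE),
    mk("Job satisfaction", 3, points = 7L, block = "reactions"),
    mk("Perceived stress", 2, points = 7L, reversed = TRUE, block = "reactions")
  )
  names(defs) <- vapply(defs, `[[`, "", "id")
  if (!is.null(which)) {
    keys <- ifelse(which %in% names(defs), which, factor_id(which))
    missing <- setdiff(keys, names(defs))
    assert_that(length(missing) == 0,
                paste0("unknown factor(s): ", paste(missing, collapse = ", ")))
    defs <- defs[keys]
  }
  defs
}

#' @noRd
factor_ids <- function(factors) vapply(factors, `[[`, "", "id")

#' @noRd
factor_levels <- function(f) {
  if (f$kind == "binary") c("No", "Yes") else c("Medium", "Low", "High")
}
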