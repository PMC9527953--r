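# Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Weighted mean with zero-weight protection
#' @noRd
wmean <- function(x, w) {
  sw <- sum(w)
  assert_that(sw > 0, "all weights are zero")
  sum(w * x) / sw
}

#' Weighted standard deviation (population form, matching the standardization
#' used for penalized design columns).
#' @noRd
wsd <- function(x, w) {
  m <- wmean(x, w)
  sqrt(wmean((x - m)^2, w))
}

#' Derive a stage seed from a master seed.
#'
#' One master seed deterministically yields the seeds of every stochastic
#' stage (generation, missingness injection, CV folds, BLB subsets) so a run
#' is reproducible from its configuration alone. Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stage small integer identifying the stage.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  assert_that(is.numeric(seed) && length(seed) == 1, "seed must be a single number")
  as.integer((abs(as.numeric(seed)) * 48271 + 1000003 * as.numeric(stage)) %% 2147483647)
}

#' @noRd
is_scalar_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
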