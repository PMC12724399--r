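# Small epidemiological and annotation utilities: case-control risk ratios
# with log-normal confidence intervals, and SpliceAI score aggregation.

#' Case-control risk ratio with confidence interval
#'
#' Risk ratio `(a / (a + c)) / (b / (b + d))` where `a`/`b` are cases and
#' controls carrying the variant class and `c`/`d` those without. The
#' confidence interval uses the Katz log-normal method:
#' `exp(log RR +- z * sqrt(1/a - 1/(a+c) + 1/b - 1/(b+d)))`.
#'
#' @param a Cases with the variant class.
#' @param b Controls with the variant class.
#' @param c_ Cases without.
#' @param d Controls without.
#' @param ci_level Confidence level (default 0.95).
#' @return List with `rr`, `ci_low`, `ci_high`, `one_sided` (TRUE when
#'   `a = 0`, where the interval is one-sided).
#' @export
risk_ratio <- function(a, b, c_, d, ci_level = 0.95) {
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  if (a + c_ <= 0 || b + d <= 0) stop2("each arm must contain subjects")
  if (b == 0) stop2("risk ratio undefined with no exposed controls (b = 0)")
  rr <- (a / (a + c_)) / (b / (b + d))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  if (a == 0) {
    # One-sided bound: substitute a = 0.5 for the upper limit only.
    se <- sqrt(1 / 0.5 - 1 / (0.5 + c_) + 1 / b - 1 / (b + d))
    rr_half <- (0.5 / (0.5 + c_)) / (b / (b + d))
    return(list(rr = 0, ci_low = 0, ci_high = rr_half * exp(z * se),
                one_sided = TRUE))
  }
  se <- sqrt(1 / a - 1 / (a + c_) + 1 / b - 1 / (b + d))
  list(rr = rr, ci_low = rr * exp(-z * se), ci_high = rr * exp(z * se),
       one_sided = FALSE)
}

#' Aggregate SpliceAI sub-scores into one splice-disruption probability
#'
#' Combines the four SpliceAI delta scores (acceptor gain/loss, donor
#' gain/loss) as the probability that at least one splice alteration occurs:
#' `1 - (1-AG)(1-AL)(1-DG)(1-DL)`. Setting `as_product = TRUE` instead
#' returns the bare product `(1-AG)(1-AL)(1-DG)(1-DL)` — the probability of
#' no disruption — for comparison with sources that print the formula in
#' that form.
#'
#' @param ag,al,dg,dl Probabilities in `[0, 1]` (vectorized).
#' @param as_product Return the no-disruption product instead of its
#'   complement.
#' @return Aggregate probability vector.
#' @export
spliceai_aggregate <- function(ag, al, dg, dl, as_product = FALSE) {
  for (v in list(ag, al, dg, dl)) {
    if (any(v < 0 | v > 1, na.rm = TRUE)) stop2("sub-scores must be in [0, 1]")
  }
  prod_none <- (1 - ag) * (1 - al) * (1 - dg) * (1 - dl)
  if (as_product) prod_none else 1 - prod_none
}

#' Per-variant maximum aggregate SpliceAI score
#'
#' Computes the aggregate splice-disruption probability for every row (one
#' row per transcript/coordinate alternative) and returns the maximum per
#' variant.
#'
#' @param df `data.frame` with columns `variant_id`, `AG`, `AL`, `DG`, `DL`.
#' @return `data.frame` with `variant_id`, `spliceai_max`.
#' @export
spliceai_aggregate_max <- function(df) {
  agg <- spliceai_aggregate(df$AG, df$AL, df$DG, df$DL)
  mx <- tapply(agg, df$variant_id, max)
  data.frame(variant_id = names(mx), spliceai_max = as.numeric(mx),
             stringsAsFactors = FALSE, row.names = NULL)
}
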