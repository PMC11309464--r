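# Effect sizes, correlations, Cronbach-alpha ICC for test-retest analysis,
# and the prognostic quadrant summary.

#' Hedges' g standardized mean difference
#'
#' `g = J * (mean_a - mean_b) / s_pooled`, with the pooled SD
#' `s_pooled = sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a+n_b-2))` and the
#' small-sample correction `J = 1 - 3 / (4 (n_a+n_b) - 9)`.
#'
#' @param a,b numeric samples (each of length >= 2).
#' @return Hedges' g (sign: positive when `mean(a) > mean(b)`).
#' @export
#' @examples
#' hedges_g(c(1, 2, 3), c(4, 5, 6))  # -2.4
hedges_g <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stopf("need at least 2 observations per sample")
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2))
  if (sp == 0) stopf("zero pooled variance")
  j <- 1 - 3 / (4 * (na + nb) - 9)
  j * (mean(a) - mean(b)) / sp
}

#' Cronbach-alpha intraclass correlation for two visits
#'
#' Internal-consistency ICC of paired measurements computed from Cronbach's
#' alpha at k = 2 items: `alpha = 2 * (1 - (s1^2 + s2^2) / s_sum^2)` with
#' `s_sum^2` the variance of per-subject sums (the consistency-type form,
#' equivalent to ICC(3,k)).
#'
#' @param v1,v2 numeric vectors of the measure at visits 1 and 2, matched by
#'   subject (length >= 3).
#' @return the ICC (1 for exact repetition, ~0 under independence).
#' @export
icc_alpha <- function(v1, v2) {
  if (length(v1) != length(v2)) stopf("visits must have equal length")
  if (length(v1) < 3) stopf("need at least 3 subjects")
  s_sum <- stats::var(v1 + v2)
  if (s_sum == 0) stopf("zero total variance")
  2 * (1 - (stats::var(v1) + stats::var(v2)) / s_sum)
}

#' Pearson correlation with two-sided p value
#'
#' @param v1,v2 paired numeric vectors (length >= 3).
#' @return list with `r` and `p` (t-based, two-sided).
#' @export
pearson_r <- function(v1, v2) {
  if (length(v1) < 3) stopf("need at least 3 pairs")
  ct <- stats::cor.test(v1, v2, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Prognostic quadrant summary
#'
#' Cross-tabulates baseline classification (score > 0 = classified MCI)
#' against subsequent cognitive decline (outcome change below the threshold)
#' into the four quadrants -- Q1: classified healthy, no decline; Q2:
#' classified healthy, decline; Q3: classified MCI, decline; Q4: classified
#' MCI, no decline -- and correlates the baseline score with the outcome
#' change.
#'
#' @param baseline_scores numeric classifier scores at baseline.
#' @param outcome_change change in the cognitive outcome (follow-up minus
#'   baseline; negative = decline).
#' @param decline_threshold decline is `outcome_change < decline_threshold`
#'   (default 0).
#' @return list with `fractions_pct` (named Q1..Q4, summing to 100), `r`, `p`,
#'   `n`.
#' @export
prognostic_quadrants <- function(baseline_scores, outcome_change,
                                 decline_threshold = 0) {
  stopifnot(length(baseline_scores) == length(outcome_change))
  n <- length(baseline_scores)
  if (n == 0) stopf("empty input")
  mci <- baseline_scores > 0
  decline <- outcome_change < decline_threshold
  fr <- 100 * c(Q1 = sum(!mci & !decline), Q2 = sum(!mci & decline),
                Q3 = sum(mci & decline), Q4 = sum(mci & !decline)) / n
  ct <- if (n >= 3 && stats::sd(baseline_scores) > 0 && stats::sd(outcome_change) > 0) {
    pearson_r(baseline_scores, outcome_change)
  } else list(r = NA_real_, p = NA_real_)
  list(fractions_pct = fr, r = ct$r, p = ct$p, n = n)
}
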