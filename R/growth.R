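# Growth-rate formulas, tolerance normalisation, log transformation, and the
# mutant-versus-wild-type comparisons with Bonferroni-adjusted t-tests.

#' Relative growth rate in percent
#'
#' `(final - initial) * 100 / initial`; negative values indicate shrinkage or
#' death of the rosette.
#'
#' @param initial,final areas (same units); `initial` must be positive.
#' @return growth rate(s) in percent.
#' @export
growth_rate_percent <- function(initial, final) {
  if (any(initial <= 0)) abort("`initial` must be > 0.")
  (final - initial) * 100 / initial
}

#' Ecotype growth rate under cold stress
#'
#' Growth on the final (30th) day of cold treatment expressed as a percent of
#' growth on day 0: `day30 * 100 / day0`.
#'
#' @param day0,day30 areas at the start and end of the cold treatment.
#' @return percent value(s).
#' @export
ecotype_growth_rate <- function(day0, day30) {
  if (any(day0 <= 0)) abort("`day0` must be > 0.")
  day30 * 100 / day0
}

#' Proportionate tolerance across a panel
#'
#' Each ecotype's growth rate as a percent of the summed growth rate of the
#' whole panel; the output always sums to 100.
#'
#' @param rates numeric vector of per-ecotype growth rates (non-zero sum).
#' @return vector of percents summing to 100.
#' @export
proportionate_tolerance <- function(rates) {
  s <- sum(rates)
  if (s == 0) abort("Sum of growth rates is zero; proportionate tolerance undefined.")
  rates * 100 / s
}

#' Natural-log transform of pixel areas
#'
#' @param values numeric vector; `values + offset` must be positive.
#' @param offset additive offset applied before the log (default 0); use a
#'   small offset when zero areas occur.
#' @return `log(values + offset)`.
#' @export
log_transform <- function(values, offset = 0) {
  shifted <- values + offset
  bad <- which(!(shifted > 0))
  if (length(bad)) {
    abort(sprintf("Non-positive value(s) after offset at index: %s",
                  paste(head(bad, 10L), collapse = ", ")))
  }
  log(shifted)
}

#' Mutant growth ratio relative to wild type
#'
#' `mean(mutant) / mean(wt)`; negative ratios are meaningful (yellowing and
#' death under cold stress yields a negative growth rate).
#'
#' @param mutant,wt numeric vectors of growth rates.
#' @return single ratio.
#' @export
mutant_growth_ratio <- function(mutant, wt) {
  mw <- base::mean(wt)
  if (mw == 0) abort("Wild-type mean growth is zero; ratio undefined.")
  base::mean(mutant) / mw
}

#' Compare a mutant against wild type with a Bonferroni-adjusted t-test
#'
#' Two-sided two-sample t-test (Welch by default; pooled-variance optional),
#' declared significant when `p < alpha / m`.
#'
#' @param mutant,wt numeric samples (n >= 2 each).
#' @param alpha family-wise error level (default 0.05).
#' @param m number of comparisons in the family (Bonferroni divisor).
#' @param pooled use the pooled-variance (classic Student) test instead of
#'   Welch.
#' @param mutant_id,wt_id,treatment labels copied into the output.
#' @return one-row tibble: ids, `ratio` (mean mutant / mean wt), `t`, `df`,
#'   `p_value`, `alpha_adjusted`, `significant`.
#' @export
compare_mutant <- function(mutant, wt, alpha = 0.05, m = 1,
                           pooled = FALSE, mutant_id = "mutant",
                           wt_id = "Col-0", treatment = "cold") {
  if (length(mutant) < 2L || length(wt) < 2L) {
    abort("Each sample needs at least two observations.")
  }
  if (var(mutant) == 0 && var(wt) == 0 && base::mean(mutant) == base::mean(wt)) {
    tt <- list(statistic = 0, parameter = length(mutant) + length(wt) - 2L,
               p.value = 1)
  } else {
    tt <- t.test(mutant, wt, var.equal = pooled)
  }
  thr <- alpha / m
  tibble(mutant_id = mutant_id, wt_id = wt_id, treatment = treatment,
         ratio = base::mean(mutant) / base::mean(wt),
         t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, alpha_adjusted = thr,
         significant = tt$p.value < thr)
}

#' Pearson validation correlation
#'
#' Sample Pearson correlation with a two-sided t-based p-value, as used to
#' benchmark pipeline areas against an independent measurement.
#'
#' @param x,y numeric vectors (n >= 3, non-constant).
#' @return one-row tibble: `r`, `t`, `df`, `p_value`, `n`.
#' @export
pearson_validation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  if (sd(x) == 0 || sd(y) == 0) abort("Constant vector: correlation undefined.")
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), t = unname(ct$statistic),
         df = unname(ct$parameter), p_value = ct$p.value, n = length(x))
}
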