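# Dose-response analysis: bin subjects by standard-deviate categories of the
# inverse-normalized exposure, compute design-corrected prevalence per bin,
# and test for a linear trend in proportions (Cochran-Armitage).

#' Bin standard-normal exposure scores by standard deviates
#'
#' Partitions inverse-normalized scores into four ordered categories with
#' boundaries at -1, 0 and +1 SD; intervals are left-open and right-closed
#' except the first, so a score of exactly 0 falls in `(-1, 0]`.
#'
#' @param z Numeric vector of standard-normal scores.
#' @return Ordered factor with levels `<=-1 SD`, `(-1,0] SD`, `(0,1] SD`,
#'   `>+1 SD`.
#' @export
bin_by_sd <- function(z) {
  cut(z, breaks = c(-Inf, -1, 0, 1, Inf),
      labels = c("<=-1 SD", "(-1,0] SD", "(0,1] SD", ">+1 SD"),
      right = TRUE, ordered_result = TRUE)
}

#' Cochran-Armitage test for linear trend in proportions
#'
#' Signed trend statistic for ordered binomial categories with linear scores:
#' `z = sum(s_i (r_i - n_i p)) / sqrt(p (1 - p) (sum(n_i s_i^2) -
#' (sum(n_i s_i))^2 / N))`, where `r_i`/`n_i` are positives/totals in
#' category `i`, `p` the pooled proportion, and `s_i` the scores. The
#' chi-square statistic is `z^2` with 1 df; the two-sided p-value comes from
#' its upper tail. Zero-total categories are dropped with a warning. The
#' statistic is invariant to affine rescaling of the scores, and reversing
#' the category order flips the sign of `z` but not the p-value.
#'
#' @param positives Counts of outcome-positive subjects per ordered category.
#' @param totals Total counts per category.
#' @param scores Numeric scores, default `1:k`.
#' @return List with `z` (signed), `statistic` (chi-square, 1 df), `p_value`,
#'   `scores`, `proportions`.
#' @export
cochran_armitage <- function(positives, totals, scores = seq_along(positives)) {
  k <- length(positives)
  if (k < 2L) stop("need at least 2 ordered categories")
  if (length(totals) != k || length(scores) != k) {
    stop("positives, totals and scores must have equal length")
  }
  if (any(positives < 0) || any(totals < positives)) {
    stop("counts must satisfy 0 <= positives <= totals")
  }
  empty <- totals == 0
  if (any(empty)) {
    warning("dropping ", sum(empty), " zero-total categor",
            if (sum(empty) == 1) "y" else "ies")
    positives <- positives[!empty]
    totals <- totals[!empty]
    scores <- scores[!empty]
    if (length(totals) < 2L) stop("fewer than 2 nonempty categories remain")
  }
  N <- sum(totals)
  p <- sum(positives) / N
  if (p == 0 || p == 1) stop("all outcomes identical; trend undefined")
  num <- sum(scores * (positives - totals * p))
  den <- p * (1 - p) * (sum(totals * scores^2) - sum(totals * scores)^2 / N)
  z <- num / sqrt(den)
  list(z = z, statistic = z^2,
       p_value = stats::pchisq(z^2, df = 1, lower.tail = FALSE),
       scores = scores, proportions = positives / totals)
}

#' Dose-response analysis of an exposure against a binary outcome
#'
#' Bins the inverse-normalized exposure by standard deviates, computes raw
#' counts and design-corrected prevalences per bin, runs the Cochran-Armitage
#' trend test on the unweighted counts (scores 1..4), and, as a
#' design-consistent companion, fits a survey-weighted logistic regression of
#' the outcome on the bin index.
#'
#' @param z Inverse-normalized exposure scores.
#' @param outcome Binary 0/1 outcome.
#' @param design A [survey_design()] aligned with the inputs.
#' @param single_psu Passed to the design-based estimators.
#' @return A `trend_result` list: `table` (data frame with bin, n, positives,
#'   prevalence_raw, prevalence_weighted, prevalence_se), `trend` (the
#'   [cochran_armitage()] output), and `weighted_trend` (per-bin-index OR,
#'   CI, p from the weighted logistic fit).
#' @export
dose_response <- function(z, outcome, design,
                          single_psu = c("fail", "center")) {
  single_psu <- match.arg(single_psu)
  stopifnot(inherits(design, "survey_design_spec"))
  bins <- bin_by_sd(z)
  lev <- levels(bins)
  tab <- data.frame(
    bin = lev,
    n = as.integer(table(bins)[lev]),
    positives = vapply(lev, function(b) sum(outcome[bins == b]), numeric(1)),
    row.names = NULL
  )
  tab$prevalence_raw <- ifelse(tab$n > 0, tab$positives / tab$n, NA_real_)
  wprev <- lapply(lev, function(b) {
    idx <- bins == b
    if (!any(idx)) return(list(estimate = NA_real_, se = NA_real_))
    sub_design <- survey_design(design$stratum[idx], design$psu[idx],
                                design$weight[idx])
    tryCatch(design_proportion(outcome[idx], sub_design,
                               single_psu = "center"),
             error = function(e) list(estimate = NA_real_, se = NA_real_))
  })
  tab$prevalence_weighted <- vapply(wprev, `[[`, numeric(1), "estimate")
  tab$prevalence_se <- vapply(wprev, `[[`, numeric(1), "se")
  trend <- cochran_armitage(tab$positives, tab$n)
  bin_index <- as.integer(bins)
  wfit <- fit_weighted_logistic(outcome, data.frame(bin_index = bin_index),
                                design, single_psu = single_psu)
  structure(
    list(table = tab, trend = trend,
         weighted_trend = list(or = wfit$or[["bin_index"]],
                               ci_lower = wfit$ci_lower[["bin_index"]],
                               ci_upper = wfit$ci_upper[["bin_index"]],
                               p_value = wfit$p_value[["bin_index"]])),
    class = "trend_result"
  )
}

#' @export
print.trend_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("Cochran-Armitage trend: chi2(1) = %.3f, p = %.4g\n",
              x$trend$statistic, x$trend$p_value))
  invisible(x)
}
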