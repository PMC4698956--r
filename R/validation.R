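# Validation of the self-reported outcome against the 4-level imaging grade:
# cross-tabulation with design-corrected row proportions, collapse to a 2x2
# (positive imaging = moderate/severe NPR or PR), percent agreement, Cohen's
# kappa with large-sample SE/p, and extraction of the misclassification rates
# fed to the Monte Carlo sensitivity analysis.

imaging_grades <- function() c("none", "mild", "modsev", "PR")

#' Cross-tabulate self-report against the imaging grade
#'
#' Builds the 4 (imaging grade) x 2 (self-report) count table on the
#' validation subsample, the collapsed 2x2 (no/mild vs moderate/severe NPR or
#' PR), and within-row design-weighted proportions of self-report positives.
#'
#' @param selfreport Binary 0/1 self-reported outcome.
#' @param imaging_grade Character vector with levels none/mild/modsev/PR
#'   (`NA` rows are excluded with the matching design rows).
#' @param design Optional [survey_design()] aligned with the inputs; when
#'   omitted, weighted proportions equal the raw ones.
#' @return An `agreement_table` list: `counts4` (4x2), `counts2` (2x2,
#'   rows no_mild / modsev_pr, columns selfreport 0/1), `row_prop_weighted`,
#'   `row_prop_raw` (per-row share self-report positive), `n_total`.
#' @export
crosstab <- function(selfreport, imaging_grade, design = NULL) {
  keep <- !is.na(imaging_grade) & !is.na(selfreport)
  if (!any(keep)) stop("validation subsample is empty")
  sr <- selfreport[keep]
  gr <- factor(imaging_grade[keep], levels = imaging_grades())
  if (anyNA(gr)) stop("imaging_grade contains unknown levels")
  w <- if (is.null(design)) rep(1, sum(keep)) else design$weight[keep]
  counts4 <- table(grade = gr, selfreport = factor(sr, levels = 0:1))
  counts4 <- unclass(counts4)
  collapse <- rbind(
    no_mild = counts4["none", ] + counts4["mild", ],
    modsev_pr = counts4["modsev", ] + counts4["PR", ]
  )
  wsum <- function(rows, srval) sum(w[gr %in% rows & sr == srval])
  row_sets <- list(none = "none", mild = "mild", modsev = "modsev", PR = "PR",
                   no_mild = c("none", "mild"), modsev_pr = c("modsev", "PR"))
  row_prop_weighted <- vapply(row_sets, function(rs) {
    tot <- wsum(rs, 0) + wsum(rs, 1)
    if (tot == 0) NA_real_ else wsum(rs, 1) / tot
  }, numeric(1))
  row_prop_raw <- vapply(row_sets, function(rs) {
    tot <- sum(gr %in% rs)
    if (tot == 0) NA_real_ else sum(sr[gr %in% rs]) / tot
  }, numeric(1))
  structure(
    list(counts4 = counts4, counts2 = collapse,
         row_prop_weighted = row_prop_weighted, row_prop_raw = row_prop_raw,
         weights = w, grade = gr, selfreport = sr, n_total = sum(keep)),
    class = "agreement_table"
  )
}

#' @export
print.agreement_table <- function(x, ...) {
  cat("Imaging grade x self-report (n =", x$n_total, ")\n")
  print(x$counts4)
  cat("\nCollapsed (positive imaging = moderate/severe NPR or PR):\n")
  print(x$counts2)
  invisible(x)
}

#' Cohen's kappa for a 2x2 agreement table
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` between two
#' binary classifications, with the large-sample standard error under
#' independence and a two-sided p-value for `H0: kappa = 0`. With a cell
#' weight matrix (sums of design weights instead of counts) the same formulas
#' give a design-weighted variant; with equal weights the two coincide.
#'
#' @param table 2x2 numeric matrix of counts (rows: gold standard, columns:
#'   comparison outcome) or an `agreement_table`, in which case both the
#'   unweighted and design-weighted variants are computed.
#' @return An `agreement_result` list: `percent_agreement` (in %),
#'   `expected_agreement`, `kappa`, `kappa_se`, `kappa_z`, `kappa_p`, `n`;
#'   for an `agreement_table` input also `weighted` (the design-weighted
#'   variant) and the misclassification rates of
#'   [extract_misclass_rates()].
#' @export
cohens_kappa <- function(table) {
  if (inherits(table, "agreement_table")) {
    raw <- kappa_from_counts(table$counts2, n_eff = sum(table$counts2))
    wtab <- weighted_counts2(table)
    wt <- kappa_from_counts(wtab, n_eff = sum(table$counts2))
    raw$weighted <- wt
    raw$rates <- extract_misclass_rates(table)
    return(raw)
  }
  kappa_from_counts(as.matrix(table), n_eff = sum(table))
}

weighted_counts2 <- function(at) {
  pos <- at$grade %in% c("modsev", "PR")
  rbind(
    no_mild = c(sum(at$weights[!pos & at$selfreport == 0]),
                sum(at$weights[!pos & at$selfreport == 1])),
    modsev_pr = c(sum(at$weights[pos & at$selfreport == 0]),
                  sum(at$weights[pos & at$selfreport == 1]))
  )
}

kappa_from_counts <- function(tab, n_eff) {
  if (!all(dim(tab) == c(2L, 2L))) stop("kappa needs a 2x2 table")
  n <- sum(tab)
  if (n <= 0) stop("table total must be positive")
  rowm <- rowSums(tab) / n
  colm <- colSums(tab) / n
  if (any(rowm == 0) || any(colm == 0)) {
    stop("degenerate margin (all observations in one category); ",
         "kappa undefined")
  }
  po <- sum(diag(tab)) / n
  pe <- sum(rowm * colm)
  kappa <- (po - pe) / (1 - pe)
  # large-sample SE under H0 (Fleiss), evaluated with the unweighted n
  se0 <- sqrt((pe + pe^2 - sum(rowm * colm * (rowm + colm))) /
                (n_eff * (1 - pe)^2))
  z <- kappa / se0
  structure(
    list(percent_agreement = 100 * po, expected_agreement = pe,
         kappa = kappa, kappa_se = se0, kappa_z = z,
         kappa_p = 2 * stats::pnorm(-abs(z)), n = n_eff),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Agreement %.2f%%, kappa = %.4f (SE %.4f, p = %.3g), n = %d\n",
              x$percent_agreement, x$kappa, x$kappa_se, x$kappa_p, x$n))
  if (!is.null(x$weighted)) {
    cat(sprintf("Design-weighted: agreement %.2f%%, kappa = %.4f\n",
                x$weighted$percent_agreement, x$weighted$kappa))
  }
  invisible(x)
}

#' Extract outcome misclassification rates from a validation table
#'
#' The false-positive rate is the share of self-report positives without
#' positive imaging (no or mild NPR only), and the false-negative rate the
#' share of self-report negatives with positive imaging (moderate/severe NPR
#' or PR). Both design-weighted and unweighted variants are returned; the
#' weighted ones are the rates the misclassification Monte Carlo consumes.
#'
#' @param table An `agreement_table` from [crosstab()], or a 2x2 count matrix
#'   (rows no_mild / modsev_pr, columns selfreport 0/1).
#' @return List with `fp_rate`, `fn_rate` (design-weighted when weights are
#'   available) and `fp_rate_raw`, `fn_rate_raw`.
#' @export
extract_misclass_rates <- function(table) {
  if (inherits(table, "agreement_table")) {
    raw <- rates_from_counts(table$counts2)
    wt <- rates_from_counts(weighted_counts2(table))
    return(list(fp_rate = wt$fp_rate_raw, fn_rate = wt$fn_rate_raw,
                fp_rate_raw = raw$fp_rate_raw, fn_rate_raw = raw$fn_rate_raw))
  }
  rates_from_counts(as.matrix(table))
}

rates_from_counts <- function(tab) {
  pos_total <- sum(tab[, 2])
  neg_total <- sum(tab[, 1])
  if (pos_total == 0 || neg_total == 0) {
    stop("zero denominator: one self-report margin is empty")
  }
  list(fp_rate_raw = unname(tab[1, 2] / pos_total),
       fn_rate_raw = unname(tab[2, 1] / neg_total))
}

#' Run the full validation stage on a cohort
#'
#' Restricts to the imaging substudy, cross-tabulates, computes raw and
#' design-weighted agreement/kappa and misclassification rates.
#'
#' @param cohort Cohort with `selfreport_outcome` and `imaging_grade`.
#' @param design A [survey_design()] aligned with `cohort`.
#' @return List with `table` (`agreement_table`) and `agreement`
#'   (`agreement_result` including the weighted variant and rates).
#' @export
validate_selfreport <- function(cohort, design) {
  at <- crosstab(cohort$selfreport_outcome, cohort$imaging_grade, design)
  list(table = at, agreement = cohens_kappa(at))
}
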