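# Exposure transformation: LOD substitution, creatinine dilution correction,
# and rank-based inverse normal transformation.

#' Substitute concentrations below the limit of detection
#'
#' Assay values flagged as below the limit of detection (LOD) are replaced by
#' LOD/2, the conventional single-value substitution for left-censored urinary
#' biomarker concentrations. Values at or above the LOD are returned unchanged.
#'
#' @param concentration Numeric vector of measured concentrations (ng/mL).
#' @param lod Numeric vector (or scalar) of detection limits (ng/mL), `> 0`.
#' @param below_lod Logical vector flagging censored readings.
#' @return Numeric vector with censored entries replaced by `lod/2`.
#' @examples
#' substitute_lod(c(0.84, 5), lod = 0.84, below_lod = c(TRUE, FALSE))
#' @export
substitute_lod <- function(concentration, lod, below_lod) {
  lod <- rep_len(lod, length(concentration))
  below_lod <- rep_len(as.logical(below_lod), length(concentration))
  if (anyNA(below_lod)) stop("below_lod flags must be TRUE/FALSE")
  if (any(below_lod & (is.na(lod) | lod <= 0))) {
    stop("a value is flagged below LOD but its LOD is missing or nonpositive")
  }
  out <- concentration
  out[below_lod] <- lod[below_lod] / 2
  out
}

#' Correct a urinary concentration for dilution
#'
#' Returns the natural log of the ratio of analyte concentration to urinary
#' creatinine, the standard adjustment for urine dilution. The ratio mixes
#' units (ng/mL over mg/dL); because the downstream inverse normal transform
#' depends only on ranks, the constant unit factor is irrelevant.
#'
#' @param concentration Positive analyte concentration (ng/mL).
#' @param creatinine Positive urinary creatinine (mg/dL).
#' @return `log(concentration / creatinine)`, dimensionless up to an additive
#'   unit constant.
#' @export
dilution_correct <- function(concentration, creatinine) {
  if (any(!is.finite(concentration)) || any(!is.finite(creatinine))) {
    stop("concentration and creatinine must be finite")
  }
  if (any(concentration <= 0) || any(creatinine <= 0)) {
    stop("concentration and creatinine must be strictly positive")
  }
  log(concentration / creatinine)
}

#' Rank-based inverse normal transformation
#'
#' Maps a numeric vector to standard-normal quantiles via its ranks: values are
#' ranked (average ranks for ties), converted to empirical CDF points, and
#' passed through the standard-normal quantile function, yielding a variable
#' distributed as N(0, 1). The default CDF convention is `rank / (n + 1)`,
#' which keeps all quantiles finite; Blom `(rank - 3/8)/(n + 1/4)` and
#' van der Waerden-like `(rank - 1/2)/n` offsets are available.
#'
#' The output is invariant under any strictly increasing transformation of the
#' input, so upstream unit or base-of-logarithm choices do not matter.
#'
#' @param values Numeric vector with at least 2 non-missing values.
#' @param offset CDF convention, one of `"rank"` (`r/(n+1)`, default),
#'   `"blom"`, `"halved"`.
#' @return Numeric vector of standard-normal scores; `NA` preserved.
#' @examples
#' inverse_normal(c(10, 20, 30))  # -0.6745, 0, 0.6745
#' @export
inverse_normal <- function(values, offset = c("rank", "blom", "halved")) {
  offset <- match.arg(offset)
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2L) stop("inverse_normal needs at least 2 non-missing values")
  x <- values[ok]
  if (length(unique(x)) == 1L) {
    warning("all values identical; inverse normal scores set to 0")
    out <- rep(NA_real_, length(values))
    out[ok] <- 0
    return(out)
  }
  r <- rank(x, ties.method = "average")
  u <- switch(offset,
    rank   = r / (n + 1),
    blom   = (r - 3 / 8) / (n + 1 / 4),
    halved = (r - 0.5) / n
  )
  out <- rep(NA_real_, length(values))
  out[ok] <- stats::qnorm(u)
  out
}

#' Transform metabolite concentrations to standard-normal exposure scores
#'
#' Applies the full two-step exposure transformation to each metabolite column
#' of a cohort table: below-LOD readings are replaced by LOD/2, concentrations
#' are dilution-corrected as the log ratio to urinary creatinine, and the log
#' ratios are inverse-normalized. Adds one `z_<metabolite>` column per
#' metabolite.
#'
#' @param cohort A cohort `data.frame` with one concentration column per
#'   metabolite, matching `below_lod_<name>` flag columns, and a `creatinine`
#'   column (mg/dL).
#' @param metabolites Character vector of metabolite column names.
#' @param lods Named numeric vector of detection limits, one per metabolite.
#' @param offset CDF convention passed to [inverse_normal()].
#' @return `cohort` with added `z_<metabolite>` columns.
#' @export
transform_exposures <- function(cohort, metabolites, lods,
                                offset = c("rank", "blom", "halved")) {
  offset <- match.arg(offset)
  stopifnot(is.data.frame(cohort), "creatinine" %in% names(cohort))
  missing_cols <- setdiff(metabolites, names(cohort))
  if (length(missing_cols)) {
    stop("metabolite columns absent from cohort: ",
         paste(missing_cols, collapse = ", "))
  }
  for (m in metabolites) {
    flag_col <- paste0("below_lod_", m)
    flags <- if (flag_col %in% names(cohort)) cohort[[flag_col]] else {
      cohort[[m]] < lods[[m]]
    }
    conc <- substitute_lod(cohort[[m]], lods[[m]], flags)
    lr <- dilution_correct(conc, cohort$creatinine)
    cohort[[paste0("z_", m)]] <- inverse_normal(lr, offset = offset)
  }
  cohort
}
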