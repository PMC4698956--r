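# Association scan: univariate per-metabolite logistic models with Bonferroni
# correction, the nested multivariable model sequence, and the DnOP molar-sum
# specificity analysis.

#' Molecular weights used for the DnOP molar sum
#'
#' Mono-n-octyl phthalate (MOP, C16H22O4) and mono-(3-carboxypropyl)
#' phthalate (MCPP, C12H12O6), computed from their molecular formulas with
#' standard atomic weights.
#' @format Named numeric vector, g/mol.
#' @export
dnop_molecular_weights <- c(MOP = 278.34, MCPP = 252.22)

#' Univariate metabolite scan with Bonferroni correction
#'
#' Fits one survey-weighted logistic regression per metabolite (outcome on a
#' single inverse-normalized exposure) and applies a Bonferroni correction
#' with the family size fixed at the number of metabolites scanned. Fit
#' failures for individual metabolites are flagged and the scan continues.
#'
#' @param cohort Cohort data frame carrying `z_<metabolite>` columns and the
#'   outcome column.
#' @param design A [survey_design()] object aligned with `cohort` rows.
#' @param metabolites Metabolite names (default the standard 12).
#' @param outcome Name of the binary outcome column
#'   (default `"selfreport_outcome"`).
#' @param m Bonferroni family size; defaults to `length(metabolites)`.
#' @param level Confidence level.
#' @return A `data.frame` (class `scan_result`) with one row per metabolite:
#'   `metabolite`, `coef`, `se`, `or`, `ci_lower`, `ci_upper`, `p_value`,
#'   `p_bonferroni`, `error` (NA when the fit succeeded).
#' @export
univariate_scan <- function(cohort, design, metabolites = default_metabolites(),
                            outcome = "selfreport_outcome",
                            m = length(metabolites), level = 0.95) {
  zcols <- paste0("z_", metabolites)
  missing_cols <- setdiff(c(zcols, outcome), names(cohort))
  if (length(missing_cols)) {
    stop("columns absent from cohort: ", paste(missing_cols, collapse = ", "))
  }
  y <- cohort[[outcome]]
  rows <- lapply(seq_along(metabolites), function(i) {
    met <- metabolites[i]
    X <- cohort[, zcols[i], drop = FALSE]
    names(X) <- met
    fit <- tryCatch(fit_weighted_logistic(y, X, design, level = level),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      data.frame(metabolite = met, coef = NA_real_, se = NA_real_,
                 or = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
                 p_value = NA_real_, error = conditionMessage(fit))
    } else {
      data.frame(metabolite = met, coef = fit$coefficients[[met]],
                 se = fit$se[[met]], or = fit$or[[met]],
                 ci_lower = fit$ci_lower[[met]],
                 ci_upper = fit$ci_upper[[met]],
                 p_value = fit$p_value[[met]], error = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni_adjust(out$p_value, m = m)
  out <- out[, c("metabolite", "coef", "se", "or", "ci_lower", "ci_upper",
                 "p_value", "p_bonferroni", "error")]
  class(out) <- c("scan_result", "data.frame")
  out
}

#' The default nested (cumulative) multivariable model sequence
#'
#' Sixteen cumulative models for the exposure of interest: Model 1 adjusts
#' for the other eleven metabolites; Models 2-16 add, one at a time, age,
#' sex, Hispanic ethnicity, marital status, educational attainment, poverty
#' income ratio, physical activity, HbA1c strata, total cholesterol strata,
#' HDL strata, triglyceride strata, hypertension, diabetes duration, calorie
#' quartiles, and obesity.
#'
#' @param exposure The metabolite of interest (default `"MOP"`).
#' @param metabolites Full metabolite panel.
#' @return Named list of character vectors; each element lists the adjustment
#'   variables (metabolite z-columns by `z_<name>`, covariates by code name)
#'   added up to that model.
#' @export
default_model_sequence <- function(exposure = "MOP",
                                   metabolites = default_metabolites()) {
  others <- setdiff(metabolites, exposure)
  steps <- c("age", "sex", "hispanic", "married", "education", "pir",
             "activity", "hba1c_cat", "tchol", "hdl", "trig", "htn",
             "duration", "calories", "obesity")
  seq_list <- vector("list", length(steps) + 1L)
  seq_list[[1L]] <- paste0("z_", others)
  for (i in seq_along(steps)) {
    seq_list[[i + 1L]] <- c(seq_list[[i]], steps[i])
  }
  names(seq_list) <- paste0("model_", seq_along(seq_list))
  seq_list
}

#' Nested multivariable models for one exposure
#'
#' Fits the cumulative sequence of survey-weighted logistic models and
#' reports the exposure coefficient from each. Models whose fit fails (e.g.
#' collinearity) are flagged and skipped.
#'
#' @param cohort Cohort with `z_` exposure columns and coded covariates.
#' @param design A [survey_design()] object.
#' @param exposure Metabolite of interest (default `"MOP"`).
#' @param model_sequence List of adjustment-variable vectors, as produced by
#'   [default_model_sequence()].
#' @param outcome Outcome column name.
#' @param level Confidence level.
#' @return A `data.frame` with one row per model: `model`, `n_covariates`,
#'   exposure `coef`, `se`, `or`, `ci_lower`, `ci_upper`, `p_value`, `error`;
#'   the full fits are attached as the `"fits"` attribute.
#' @export
nested_models <- function(cohort, design, exposure = "MOP",
                          model_sequence = default_model_sequence(exposure),
                          outcome = "selfreport_outcome", level = 0.95) {
  zexp <- paste0("z_", exposure)
  if (!zexp %in% names(cohort)) stop("exposure column ", zexp, " absent")
  y <- cohort[[outcome]]
  fits <- vector("list", length(model_sequence))
  rows <- lapply(seq_along(model_sequence), function(i) {
    vars <- model_sequence[[i]]
    missing_cols <- setdiff(vars, names(cohort))
    if (length(missing_cols)) {
      return(data.frame(model = names(model_sequence)[i],
                        n_covariates = length(vars), coef = NA_real_,
                        se = NA_real_, or = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p_value = NA_real_,
                        error = paste("missing columns:",
                                      paste(missing_cols, collapse = ", "))))
    }
    X <- cohort[, c(zexp, vars), drop = FALSE]
    names(X)[1] <- exposure
    fit <- tryCatch(fit_weighted_logistic(y, X, design, level = level),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      data.frame(model = names(model_sequence)[i], n_covariates = length(vars),
                 coef = NA_real_, se = NA_real_, or = NA_real_,
                 ci_lower = NA_real_, ci_upper = NA_real_, p_value = NA_real_,
                 error = conditionMessage(fit))
    } else {
      fits[[i]] <<- fit
      data.frame(model = names(model_sequence)[i], n_covariates = length(vars),
                 coef = fit$coefficients[[exposure]], se = fit$se[[exposure]],
                 or = fit$or[[exposure]], ci_lower = fit$ci_lower[[exposure]],
                 ci_upper = fit$ci_upper[[exposure]],
                 p_value = fit$p_value[[exposure]], error = NA_character_)
    }
  })
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}

#' Molar sum of the DnOP metabolites MOP and MCPP
#'
#' Converts the mass concentrations of the two di-n-octyl phthalate
#' derivatives to a molar sum: `mop/278.34 + mcpp/252.22` with concentrations
#' in ng/mL, giving nmol/mL, numerically equal to umol/L.
#'
#' @param mop_conc,mcpp_conc Nonnegative concentrations (ng/mL).
#' @return Molar sum in umol/L.
#' @export
molar_sum_dnop <- function(mop_conc, mcpp_conc) {
  if (any(mop_conc < 0, na.rm = TRUE) || any(mcpp_conc < 0, na.rm = TRUE)) {
    stop("concentrations must be nonnegative")
  }
  mop_conc / dnop_molecular_weights[["MOP"]] +
    mcpp_conc / dnop_molecular_weights[["MCPP"]]
}

#' Fit the DnOP molar-sum exposure like any metabolite
#'
#' Builds the molar sum from LOD/2-substituted MOP and MCPP concentrations,
#' pushes it through the standard dilution-correction and inverse normal
#' transform, and fits the univariate survey-weighted logistic model.
#'
#' @inheritParams univariate_scan
#' @param lods Named LODs including `MOP` and `MCPP`.
#' @return A one-row data frame in the [univariate_scan()] layout (no
#'   Bonferroni column).
#' @export
dnop_molar_sum_fit <- function(cohort, design, lods = default_lods(),
                               outcome = "selfreport_outcome", level = 0.95) {
  sub <- function(met) {
    flag_col <- paste0("below_lod_", met)
    flags <- if (flag_col %in% names(cohort)) cohort[[flag_col]] else
      cohort[[met]] < lods[[met]]
    substitute_lod(cohort[[met]], lods[[met]], flags)
  }
  ms <- molar_sum_dnop(sub("MOP"), sub("MCPP"))
  z <- inverse_normal(dilution_correct(ms, cohort$creatinine))
  fit <- fit_weighted_logistic(cohort[[outcome]],
                               data.frame(dnop_molar = z), design,
                               level = level)
  data.frame(metabolite = "DnOP_molar_sum",
             coef = fit$coefficients[["dnop_molar"]],
             se = fit$se[["dnop_molar"]], or = fit$or[["dnop_molar"]],
             ci_lower = fit$ci_lower[["dnop_molar"]],
             ci_upper = fit$ci_upper[["dnop_molar"]],
             p_value = fit$p_value[["dnop_molar"]])
}
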