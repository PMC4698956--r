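# Table-1-style covariate coding: every confounder maps to small integer
# codes, with missing/unknown always coded 0 so that no subject is dropped
# from the multivariable models.

#' Default covariate coding map
#'
#' Returns the coding scheme used for the confounders: each entry is a
#' function mapping a raw value (possibly `NA`) to its integer code. Missing
#' or unknown values always code to 0.
#'
#' * `sex`: male 1, female 0
#' * `hispanic`: Mexican American / other Hispanic 1, else 0
#' * `married`: married 1, all other statuses 0
#' * `education`: <9th grade 1 ... college graduate 5, unknown 0
#' * `pir`: poverty income ratio, raw value, unknown 0
#' * `calories`: daily kcal quartile, cutpoints 1200.5 / 1648.5 / 2191,
#'   codes 0-3
#' * `obesity`: BMI >= 30 code 2, < 30 code 1, unmeasured 0
#' * `activity`: > 6 METs 2, 3-6 METs 1, < 3 or unknown 0
#' * `hba1c_cat`: >= 6.5% 2, < 6.5% 1, unknown 0
#' * `tchol`: total cholesterol >= 240 mg/dL 2, < 240 1, unknown 0
#' * `hdl`: low HDL (male < 40 / female < 50 mg/dL) 2, otherwise 1, unknown 0
#' * `trig`: triglycerides >= 150 mg/dL 2, < 150 1, unknown 0
#' * `htn`: hypertension yes 2, no 1, unknown 0
#' * `duration`: diabetes duration >= 14 y 4, 8-13 y 3, 3-7 y 2, < 3 y 1,
#'   unknown 0
#'
#' @return Named list of coding functions.
#' @export
default_covariate_coding <- function() {
  band <- function(x, cuts, codes_asc) {
    # cuts ascending; codes_asc[i] for x < cuts[i], last code for x >= max
    if (is.na(x)) return(0L)
    codes_asc[findInterval(x, cuts) + 1L]
  }
  yesno <- function(x, yes_code = 2L, no_code = 1L) {
    if (is.na(x)) return(0L)
    if (is.character(x)) {
      if (x == "yes") yes_code else if (x == "no") no_code else 0L
    } else if (x %in% c(0, 1)) {
      if (x == 1) yes_code else no_code
    } else 0L
  }
  list(
    age = function(x) if (is.na(x)) 0 else as.numeric(x),
    sex = function(x) {
      if (is.na(x)) return(0L)
      if (is.character(x)) as.integer(tolower(x) %in% c("male", "m")) else
        as.integer(x == 1)
    },
    hispanic = function(x) {
      if (is.na(x)) return(0L)
      if (is.character(x)) {
        as.integer(tolower(x) %in% c("mexican american", "other hispanic",
                                     "hispanic"))
      } else as.integer(x == 1)
    },
    married = function(x) {
      if (is.na(x)) return(0L)
      if (is.character(x)) as.integer(tolower(x) == "married") else
        as.integer(x == 1)
    },
    education = function(x) {
      if (is.na(x) || (is.numeric(x) && !(x %in% 1:5))) 0L else as.integer(x)
    },
    pir = function(x) if (is.na(x)) 0 else as.numeric(x),
    calories = function(x) band(x, c(1200.5, 1648.5, 2191), 0:3),
    obesity = function(x) band(x, 30, 1:2),
    activity = function(x) band(x, c(3, 6 + 1e-9), 0:2),
    hba1c_cat = function(x) band(x, 6.5, 1:2),
    tchol = function(x) band(x, 240, 1:2),
    hdl = NULL, # handled jointly with sex; see encode_covariates
    trig = function(x) band(x, 150, 1:2),
    htn = function(x) yesno(x),
    duration = function(x) band(x, c(3, 8, 14), 1:4)
  )
}

#' Encode raw confounders to analysis codes
#'
#' Applies the Table-1-style coding map to a data frame of raw confounder
#' measurements (BMI in kg/m2, activity in METs, HbA1c in %, cholesterol /
#' HDL / triglycerides in mg/dL, daily calories in kcal, diabetes duration in
#' years, hypertension as yes/no, plus demographics). Missing values always
#' code to 0, so the encoded matrix is complete. Low HDL depends on sex
#' (male < 40, female < 50 mg/dL), so `hdl` is coded from the `hdl_mgdl` and
#' `sex` columns jointly.
#'
#' @param raw Data frame of raw values; recognized columns are `age`, `sex`,
#'   `hispanic`, `married`, `education`, `pir`, `calories_kcal`, `bmi`,
#'   `activity_mets`, `hba1c`, `tchol_mgdl`, `hdl_mgdl`, `trig_mgdl`,
#'   `hypertension`, `duration_years`.
#' @param coding Coding map as produced by [default_covariate_coding()].
#' @return Data frame of numeric codes with columns named as in
#'   [default_covariate_spec()] (`age`, `sex`, `hispanic`, `married`,
#'   `education`, `pir`, `calories`, `obesity`, `activity`, `hba1c_cat`,
#'   `tchol`, `hdl`, `trig`, `htn`, `duration`).
#' @export
encode_covariates <- function(raw, coding = default_covariate_coding()) {
  stopifnot(is.data.frame(raw))
  col_map <- c(age = "age", sex = "sex", hispanic = "hispanic",
               married = "married", education = "education", pir = "pir",
               calories = "calories_kcal", obesity = "bmi",
               activity = "activity_mets", hba1c_cat = "hba1c",
               tchol = "tchol_mgdl", trig = "trig_mgdl",
               htn = "hypertension", duration = "duration_years")
  out <- list()
  for (code_name in names(col_map)) {
    src <- col_map[[code_name]]
    if (!src %in% names(raw)) next
    f <- coding[[code_name]]
    if (is.null(f)) stop("no coding rule for ", code_name)
    out[[code_name]] <- vapply(raw[[src]], f, numeric(1))
  }
  if ("hdl_mgdl" %in% names(raw)) {
    sex_code <- if (!is.null(out$sex)) out$sex else {
      if (!"sex" %in% names(raw)) stop("hdl coding requires a sex column")
      vapply(raw$sex, coding$sex, numeric(1))
    }
    thr <- ifelse(sex_code == 1, 40, 50)
    out$hdl <- ifelse(is.na(raw$hdl_mgdl), 0L,
                      ifelse(raw$hdl_mgdl < thr, 2L, 1L))
  }
  as.data.frame(out)
}

#' Bonferroni adjustment with a fixed test count
#'
#' `min(1, m * p)`, with the family size `m` fixed (default 12, the number of
#' metabolites in the scan) regardless of how many fits succeeded.
#'
#' @param p Numeric vector of nominal p-values.
#' @param m Family size.
#' @return Corrected p-values, capped at 1.
#' @export
bonferroni_adjust <- function(p, m = 12L) {
  if (m < 1) stop("m must be >= 1")
  stats::p.adjust(p, method = "bonferroni", n = m)
}
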