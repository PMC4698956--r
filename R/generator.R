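# Synthetic NHANES-like cohort generator with known ground truth: stratified
# two-PSU-per-stratum design with unequal weights, correlated log-normal
# metabolite concentrations censored at the LOD, a logistic outcome model on
# the inverse-normalized exposures, self-report misclassification against an
# imaging gold standard available in a subsample, and eligibility fields that
# exercise the inclusion criteria.

#' The twelve urinary phthalate metabolites analyzed by the pipeline
#'
#' @return Character vector of metabolite abbreviations (MBP, MCP, MEP, MEHP,
#'   MNP, MOP, MBzP, MNM, MCPP, MEHHP, MEOHP, MiBP).
#' @export
default_metabolites <- function() {
  c("MBP", "MCP", "MEP", "MEHP", "MNP", "MOP",
    "MBzP", "MNM", "MCPP", "MEHHP", "MEOHP", "MiBP")
}

#' Default detection limits (ng/mL) per metabolite
#'
#' MOP's LOD of 0.84 ng/mL is the assay detection limit for mono-n-octyl
#' phthalate; the others are typical tandem-MS urinary phthalate LODs.
#'
#' @return Named numeric vector of LODs.
#' @export
default_lods <- function() {
  stats::setNames(
    c(0.40, 0.26, 0.53, 0.90, 0.77, 0.84, 0.22, 0.55, 0.20, 0.32, 0.37, 0.30),
    default_metabolites()
  )
}

# Log-normal parameters per metabolite. Means target the observed arithmetic
# means of urinary concentrations in diabetic adults; MOP uses a tighter
# spread calibrated so that roughly 73% of readings exceed its 0.84 ng/mL LOD
# while keeping the arithmetic mean near 1.13 ng/mL.
default_conc_params <- function() {
  means <- c(MBP = 47.30, MCP = 0.41, MEP = 464.77, MEHP = 6.44, MNP = 1.54,
             MOP = 1.13, MBzP = 12.59, MNM = 3.85, MCPP = 5.38,
             MEHHP = 42.34, MEOHP = 25.66, MiBP = 9.00)
  sdlog <- stats::setNames(rep(1, 12), names(means))
  meanlog <- log(means) - sdlog^2 / 2
  sdlog["MOP"] <- 0.371
  meanlog["MOP"] <- log(1.13) - 0.371^2 / 2
  list(meanlog = meanlog, sdlog = sdlog)
}

# Exchangeable correlation 0.3 among metabolites, with the three DEHP
# oxidation products (MEHP, MEHHP, MEOHP) correlated at 0.8, mirroring the
# strong within-parent clustering seen in urinary phthalate panels.
default_conc_correlation <- function() {
  m <- default_metabolites()
  R <- matrix(0.3, 12, 12, dimnames = list(m, m))
  dehp <- c("MEHP", "MEHHP", "MEOHP")
  R[dehp, dehp] <- 0.8
  diag(R) <- 1
  R
}

# Category probabilities for the Table-1-style coded confounders (code 0 is
# always the unknown/unmeasured stratum).
default_covariate_spec <- function() {
  list(
    age       = list(dist = "normal", mean = 60, sd = 13, min = 18, max = 90),
    sex       = list(codes = 0:1, probs = c(0.506, 0.494)),
    hispanic  = list(codes = 0:1, probs = c(0.872, 0.128)),
    married   = list(codes = 0:1, probs = c(0.414, 0.586)),
    education = list(codes = 0:5,
                     probs = c(0.001, 0.215, 0.190, 0.218, 0.252, 0.124)),
    pir       = list(dist = "gamma", shape = 4, rate = 4 / 2.87,
                     zero_prob = 0.08),
    calories  = list(codes = 0:3, probs = rep(0.25, 4)),
    activity  = list(codes = 0:2, probs = c(0.484, 0.349, 0.167)),
    hba1c_cat = list(codes = 0:2, probs = c(0.391, 0.177, 0.432)),
    tchol     = list(codes = 0:2, probs = c(0.048, 0.812, 0.140)),
    hdl       = list(codes = 0:2, probs = c(0.046, 0.526, 0.428)),
    trig      = list(codes = 0:2, probs = c(0.516, 0.247, 0.237)),
    htn       = list(codes = 0:2, probs = c(0.046, 0.670, 0.284)),
    duration  = list(codes = 0:4, probs = c(0.174, 0.190, 0.255, 0.190, 0.191)),
    obesity   = list(codes = 0:2, probs = c(0.026, 0.414, 0.560))
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Collects every data-generating assumption: the stratified two-stage survey
#' design, correlated log-normal metabolite concentrations with censoring at
#' the limit of detection, urinary creatinine, Table-1-style coded
#' confounders, a logistic outcome model on the inverse-normalized exposure
#' scale, self-report misclassification rates defined on the self-report
#' margin (the fraction of self-reported cases without gold-standard disease,
#' and of self-reported controls with it), and the fraction of subjects with
#' an imaging-graded outcome.
#'
#' @param n_subjects Number of subjects.
#' @param n_strata Number of design strata (default 15).
#' @param psus_per_stratum PSUs per stratum, `>= 2` (default 2).
#' @param weight_law Distribution spec for sampling weights.
#' @param metabolite_names Character vector of 12 metabolite labels.
#' @param log_conc_means,log_conc_sds Log-scale mean/SD per metabolite.
#' @param conc_correlation 12x12 correlation matrix (symmetric PSD, unit
#'   diagonal).
#' @param lods Named detection limits (ng/mL), all `> 0`.
#' @param creatinine_law Distribution spec for urinary creatinine (mg/dL).
#' @param covariate_spec Per-covariate coding/distribution spec.
#' @param true_log_or Named vector of true log odds ratios per 1-SD of
#'   inverse-normalized exposure (default all 0).
#' @param covariate_log_or Optional named vector of covariate effects on the
#'   log-odds scale (default none).
#' @param intercept Model intercept on the log-odds scale; the default gives
#'   an outcome prevalence near 13.9% under null exposure effects.
#' @param substudy_fraction Fraction of subjects with imaging grades.
#' @param selfreport_fp_rate,selfreport_fn_rate Misclassification rates on the
#'   self-report margin, in `[0, 1]` (defaults 0.112 and 0.0492).
#' @param grade_probs Multinomial grade assignment given the true outcome;
#'   the default maps true cases to moderate/severe NPR or PR and true
#'   controls to none/mild, so imaging positivity coincides with the latent
#'   truth.
#' @param inclusion_noise Fraction of subjects given eligibility fields that
#'   fail the inclusion criteria (exercises the selection flow).
#' @param seed Master seed; every stage uses a derived substream.
#' @return A `generator_config` list, validated.
#' @export
generator_config <- function(n_subjects = 1000L,
                             n_strata = 15L,
                             psus_per_stratum = 2L,
                             weight_law = list(dist = "lognormal",
                                               meanlog = log(20000),
                                               sdlog = 0.7),
                             metabolite_names = default_metabolites(),
                             log_conc_means = default_conc_params()$meanlog,
                             log_conc_sds = default_conc_params()$sdlog,
                             conc_correlation = default_conc_correlation(),
                             lods = default_lods(),
                             creatinine_law = list(dist = "lognormal",
                                                   meanlog = log(110),
                                                   sdlog = 0.6),
                             covariate_spec = default_covariate_spec(),
                             true_log_or = stats::setNames(rep(0, 12),
                                                           default_metabolites()),
                             covariate_log_or = NULL,
                             intercept = stats::qlogis(0.1387),
                             substudy_fraction = 285 / 1004,
                             selfreport_fp_rate = 0.112,
                             selfreport_fn_rate = 0.0492,
                             grade_probs = list(
                               case = c(none = 0, mild = 0,
                                        modsev = 0.8, PR = 0.2),
                               control = c(none = 0.75, mild = 0.25,
                                           modsev = 0, PR = 0)
                             ),
                             inclusion_noise = 0.05,
                             seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_strata = as.integer(n_strata),
    psus_per_stratum = as.integer(psus_per_stratum), weight_law = weight_law,
    metabolite_names = metabolite_names, log_conc_means = log_conc_means,
    log_conc_sds = log_conc_sds, conc_correlation = conc_correlation,
    lods = lods, creatinine_law = creatinine_law,
    covariate_spec = covariate_spec, true_log_or = true_log_or,
    covariate_log_or = covariate_log_or, intercept = intercept,
    substudy_fraction = substudy_fraction,
    selfreport_fp_rate = selfreport_fp_rate,
    selfreport_fn_rate = selfreport_fn_rate,
    grade_probs = grade_probs, inclusion_noise = inclusion_noise,
    seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  structure(cfg, class = "generator_config")
}

validate_generator_config <- function(cfg) {
  m <- length(cfg$metabolite_names)
  if (cfg$psus_per_stratum < 2L) stop("psus_per_stratum must be >= 2")
  n_cells <- cfg$n_strata * cfg$psus_per_stratum
  if (cfg$n_subjects < 2L * n_cells) {
    stop("n_subjects too small to place >= 2 subjects in every stratum/PSU ",
         "cell (need at least ", 2L * n_cells, ")")
  }
  R <- cfg$conc_correlation
  if (!is.matrix(R) || nrow(R) != m || ncol(R) != m) {
    stop("conc_correlation must be a ", m, "x", m, " matrix")
  }
  if (max(abs(R - t(R))) > 1e-10 || max(abs(diag(R) - 1)) > 1e-10) {
    stop("conc_correlation must be symmetric with unit diagonal")
  }
  if (!is_psd(R)) stop("conc_correlation is not positive semi-definite")
  if (length(cfg$log_conc_means) != m || length(cfg$log_conc_sds) != m) {
    stop("log-scale concentration parameters must match metabolite_names")
  }
  if (length(cfg$lods) != m || any(cfg$lods <= 0)) {
    stop("lods must be one positive value per metabolite")
  }
  for (r in c(cfg$selfreport_fp_rate, cfg$selfreport_fn_rate,
              cfg$substudy_fraction, cfg$inclusion_noise)) {
    if (!is.finite(r) || r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  if (length(cfg$true_log_or) != m) {
    stop("true_log_or must have one entry per metabolite")
  }
  invisible(cfg)
}

draw_covariate <- function(spec, n) {
  if (!is.null(spec$codes)) {
    sample(spec$codes, n, replace = TRUE, prob = spec$probs)
  } else if (identical(spec$dist, "normal")) {
    x <- stats::rnorm(n, spec$mean, spec$sd)
    pmin(pmax(x, spec$min %||% -Inf), spec$max %||% Inf)
  } else {
    x <- draw_positive(spec, n)
    if (!is.null(spec$zero_prob)) {
      x[stats::runif(n) < spec$zero_prob] <- 0
    }
    x
  }
}

# Invert self-report misclassification rates (defined on the self-report
# margin) into truth-conditional reporting probabilities, given the realized
# truth prevalence pi: with s = P(S=1) = (pi - fn)/(1 - fp - fn),
# P(S=1 | T=1) = (1-fp) s / pi and P(S=1 | T=0) = fp s / (1-pi).
selfreport_probs <- function(pi, fp, fn) {
  if (fp == 0 && fn == 0) return(list(p_report_case = 1, p_report_ctrl = 0))
  if (fp + fn >= 1) stop("selfreport fp + fn rates must sum to < 1")
  s <- (pi - fn) / (1 - fp - fn)
  p1 <- (1 - fp) * s / pi
  p0 <- fp * s / (1 - pi)
  if (s <= 0 || s >= 1 || p1 < 0 || p1 > 1 || p0 < 0 || p0 > 1) {
    stop("selfreport rates are incompatible with the realized outcome ",
         "prevalence (", signif(pi, 3), "); reduce fn_rate or raise prevalence")
  }
  list(p_report_case = p1, p_report_ctrl = p0)
}

#' Generate a synthetic NHANES-like diabetic cohort
#'
#' Draws a full subject-level cohort from the data-generating model described
#' in [generator_config()]: design cells are filled with at least two subjects
#' each, weights and creatinine follow the configured positive laws,
#' metabolite concentrations follow a correlated log-normal and are censored
#' at the LOD (the stored concentration is the LOD itself with the
#' `below_lod_*` flag set; uncensored draws are retained in the
#' `"raw_concentrations"` attribute for oracle checks), the true outcome is
#' drawn from the logistic model on the inverse-normalized (LOD/2-substituted,
#' dilution-corrected) exposures plus covariates, the self-reported outcome is
#' a misclassified copy of the truth calibrated to the configured
#' self-report-margin rates, and imaging grades are assigned in the substudy.
#'
#' Deterministic given `config$seed`; each generation stage uses its own
#' derived substream.
#'
#' @param config A [generator_config()].
#' @return A `data.frame` (class `cohort_table`) with design variables,
#'   concentrations and flags, creatinine, coded covariates, eligibility
#'   fields, `true_outcome`, `selfreport_outcome`, `in_substudy`, and
#'   `imaging_grade` (one of none/mild/modsev/PR, `NA` outside the substudy).
#' @export
generate_cohort <- function(config) {
  validate_generator_config(config)
  n <- config$n_subjects
  mets <- config$metabolite_names
  seed <- config$seed

  # --- survey design ----------------------------------------------------
  design_vars <- with_substream(seed, "design", {
    cells <- expand.grid(
      stratum = sprintf("S%02d", seq_len(config$n_strata)),
      psu = sprintf("P%d", seq_len(config$psus_per_stratum)),
      stringsAsFactors = FALSE
    )
    n_cells <- nrow(cells)
    # uneven cell sizes with a floor of 2 per cell
    sizes <- rep(2L, n_cells)
    extra <- stats::rmultinom(1, n - 2L * n_cells,
                              prob = stats::runif(n_cells, 0.5, 1.5))[, 1]
    sizes <- sizes + extra
    idx <- sample(rep.int(seq_len(n_cells), sizes))
    data.frame(
      stratum_label = cells$stratum[idx],
      psu_label = cells$psu[idx],
      sampling_weight = draw_positive(config$weight_law, n),
      stringsAsFactors = FALSE
    )
  })

  # --- exposures --------------------------------------------------------
  raw_conc <- with_substream(seed, "exposure", {
    Z <- MASS::mvrnorm(n, mu = rep(0, length(mets)),
                       Sigma = config$conc_correlation)
    conc <- exp(sweep(sweep(Z, 2L, config$log_conc_sds, `*`),
                      2L, config$log_conc_means, `+`))
    colnames(conc) <- mets
    conc
  })
  below <- sweep(raw_conc, 2L, config$lods[mets], `<`)
  conc <- raw_conc
  for (j in seq_along(mets)) conc[below[, j], j] <- config$lods[[mets[j]]]

  creatinine <- with_substream(seed, "creatinine",
                               draw_positive(config$creatinine_law, n))

  # --- covariates -------------------------------------------------------
  covars <- with_substream(seed, "covariates", {
    as.data.frame(lapply(config$covariate_spec, draw_covariate, n = n))
  })

  cohort <- cbind(
    data.frame(subject_id = seq_len(n)),
    design_vars,
    as.data.frame(conc),
    stats::setNames(as.data.frame(below), paste0("below_lod_", mets)),
    data.frame(creatinine = creatinine),
    covars
  )

  # --- true outcome on the analysis scale -------------------------------
  cohort <- transform_exposures(cohort, mets, config$lods)
  eta <- config$intercept +
    as.matrix(cohort[, paste0("z_", mets)]) %*% config$true_log_or[mets]
  if (!is.null(config$covariate_log_or)) {
    cv <- names(config$covariate_log_or)
    missing_cv <- setdiff(cv, names(covars))
    if (length(missing_cv)) stop("covariate_log_or names not generated: ",
                                 paste(missing_cv, collapse = ", "))
    eta <- eta + as.matrix(covars[, cv, drop = FALSE]) %*%
      config$covariate_log_or[cv]
  }
  true_outcome <- with_substream(seed, "outcome", {
    as.integer(stats::runif(n) < stats::plogis(drop(eta)))
  })
  cohort$true_outcome <- true_outcome

  # --- self-report misclassification ------------------------------------
  pi_hat <- mean(true_outcome)
  pr <- selfreport_probs(pi_hat, config$selfreport_fp_rate,
                         config$selfreport_fn_rate)
  cohort$selfreport_outcome <- with_substream(seed, "selfreport", {
    u <- stats::runif(n)
    as.integer(ifelse(true_outcome == 1, u < pr$p_report_case,
                      u < pr$p_report_ctrl))
  })

  # --- imaging substudy -------------------------------------------------
  grades <- c("none", "mild", "modsev", "PR")
  substudy <- with_substream(seed, "substudy", {
    sample(c(TRUE, FALSE), n, replace = TRUE,
           prob = c(config$substudy_fraction, 1 - config$substudy_fraction))
  })
  cohort$in_substudy <- substudy
  cohort$imaging_grade <- NA_character_
  imaging <- with_substream(seed, "imaging", {
    vapply(true_outcome, function(t) {
      p <- if (t == 1) config$grade_probs$case else config$grade_probs$control
      sample(grades, 1L, prob = p[grades])
    }, character(1))
  })
  cohort$imaging_grade[substudy] <- imaging[substudy]

  # --- eligibility fields ------------------------------------------------
  elig <- with_substream(seed, "eligibility", {
    noise <- config$inclusion_noise
    age_screening <- covars$age
    diagnosed <- stats::runif(n) < 0.88
    dm_selfreport <- ifelse(diagnosed, "yes", "no")
    bad <- stats::runif(n) < noise / 3
    dm_selfreport[bad] <- sample(c("refused", "dont_know", "missing"),
                                 sum(bad), replace = TRUE)
    insulin <- ifelse(diagnosed & stats::runif(n) < 0.3, "yes", "no")
    pills <- ifelse(diagnosed & stats::runif(n) < 0.55, "yes", "no")
    hba1c <- round(stats::rnorm(n, 7.4, 1.4), 1)
    hba1c[stats::runif(n) < 0.10] <- NA_real_
    # undiagnosed subjects qualify (mostly) through HbA1c
    undx <- which(!diagnosed)
    hba1c[undx] <- ifelse(stats::runif(length(undx)) < 0.75,
                          round(stats::runif(length(undx), 6.5, 9.5), 1),
                          round(stats::runif(length(undx), 5.0, 6.4), 1))
    age_diagnosis <- ifelse(diagnosed,
                            pmax(age_screening -
                                   stats::rexp(n, 1 / 8) * (covars$duration + 1),
                                 5),
                            NA_real_)
    young_dx <- stats::runif(n) < noise / 3
    age_diagnosis[diagnosed & young_dx] <-
      stats::runif(sum(diagnosed & young_dx), 5, 19)
    data.frame(age_screening = age_screening,
               age_diagnosis = round(age_diagnosis, 1),
               dm_selfreport = dm_selfreport, insulin = insulin,
               pills = pills, hba1c = hba1c, stringsAsFactors = FALSE)
  })
  elig$age_screening <- NULL  # already present as covars$age
  cohort <- cbind(cohort, elig)
  cohort$age_screening <- cohort$age

  attr(cohort, "raw_concentrations") <- raw_conc
  attr(cohort, "config") <- config
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

#' Apply the diabetic-cohort inclusion criteria
#'
#' Keeps subjects who qualify as having diabetes either by questionnaire (a
#' "yes" to self-reported diabetes, current insulin use, or diabetic pills;
#' refused/don't-know/missing answers never qualify) or by a glycated
#' hemoglobin value of at least 6.5% (undiagnosed diabetes), and then requires
#' age at screening of at least 20 years and, where a diagnosis age exists,
#' age at diagnosis of at least 20 years (restricting to adult-onset, type-2
#' disease). Subjects qualifying only through HbA1c have no diagnosis age and
#' pass that filter.
#'
#' @param cohort A cohort `data.frame` with columns `dm_selfreport`, `insulin`,
#'   `pills` (character, "yes"/"no"/other), `hba1c` (numeric or `NA`),
#'   `age_screening`, `age_diagnosis`.
#' @return The filtered cohort; the attribute `"selection_flow"` holds a named
#'   count vector tracing the selection (total, questionnaire-diagnosed,
#'   HbA1c-qualified additions, with-diabetes, adult-onset kept, final).
#' @export
apply_inclusion_criteria <- function(cohort) {
  req <- c("dm_selfreport", "insulin", "pills", "hba1c",
           "age_screening", "age_diagnosis")
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols)) {
    stop("eligibility fields absent: ", paste(missing_cols, collapse = ", "))
  }
  yes <- function(x) !is.na(x) & x == "yes"
  questionnaire <- yes(cohort$dm_selfreport) | yes(cohort$insulin) |
    yes(cohort$pills)
  hba1c_dx <- !questionnaire & !is.na(cohort$hba1c) & cohort$hba1c >= 6.5
  diabetes <- questionnaire | hba1c_dx
  adult <- !is.na(cohort$age_screening) & cohort$age_screening >= 20 &
    (is.na(cohort$age_diagnosis) | cohort$age_diagnosis >= 20)
  keep <- diabetes & adult
  flow <- c(
    total = nrow(cohort),
    questionnaire_diabetes = sum(questionnaire),
    hba1c_additions = sum(hba1c_dx),
    with_diabetes = sum(diabetes),
    excluded_age = sum(diabetes & !adult),
    included = sum(keep)
  )
  out <- cohort[keep, , drop = FALSE]
  raw <- attr(cohort, "raw_concentrations")
  if (!is.null(raw)) attr(out, "raw_concentrations") <- raw[keep, , drop = FALSE]
  attr(out, "config") <- attr(cohort, "config")
  attr(out, "selection_flow") <- flow
  class(out) <- class(cohort)
  out
}

#' Randomly misclassify a binary outcome vector
#'
#' Flips each observed case (1) to a control with probability `fp_rate` and
#' each observed control (0) to a case with probability `fn_rate`,
#' independently across subjects. This is the reshuffling step of the outcome
#' misclassification Monte Carlo.
#'
#' @param outcome Binary 0/1 vector.
#' @param fp_rate,fn_rate Flip probabilities in `[0, 1]`.
#' @param seed Optional seed; when supplied the flip is deterministic.
#' @return Binary vector of the same length.
#' @export
inject_misclassification <- function(outcome, fp_rate, fn_rate, seed = NULL) {
  if (!all(outcome %in% c(0, 1))) stop("outcome must be binary 0/1")
  for (r in c(fp_rate, fn_rate)) {
    if (!is.finite(r) || r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  flip <- function() {
    u <- stats::runif(length(outcome))
    out <- as.integer(outcome)
    out[outcome == 1 & u < fp_rate] <- 0L
    out[outcome == 0 & u < fn_rate] <- 1L
    out
  }
  if (is.null(seed)) flip() else with_substream(seed, "misclass", flip())
}

#' Write / read a cohort table as CSV
#'
#' Plain-CSV round trip for cohort tables (column dictionary in the package
#' README). Generator-internal attributes (raw concentrations, config) are not
#' serialized.
#'
#' @param cohort A cohort `data.frame`.
#' @param path File path.
#' @return `read_cohort_csv` returns a `cohort_table` data frame.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  flag_cols <- grep("^below_lod_", names(out))
  for (j in flag_cols) out[[j]] <- as.logical(out[[j]])
  class(out) <- c("cohort_table", "data.frame")
  out
}
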