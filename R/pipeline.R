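# End-to-end orchestration: inclusion -> transform -> univariate scan ->
# nested models -> validation -> misclassification MC -> dose-response, with
# stage CSV outputs and a plain-text summary report.

#' Configuration for the end-to-end pipeline
#'
#' @param cohort A cohort `data.frame`, or a path to a cohort CSV readable by
#'   [read_cohort_csv()].
#' @param output_dir Directory for stage outputs (created if absent).
#' @param metabolites Metabolite column names.
#' @param lods Named detection limits.
#' @param exposure Metabolite of interest for the nested models, the
#'   misclassification MC and the dose-response analysis.
#' @param outcome Outcome column name.
#' @param stratum_col,psu_col,weight_col Design column names.
#' @param cycle_count Pooled-cycle divisor for the weights (see
#'   [pool_cycle_weights()]); default 1.
#' @param model_sequence Nested-model adjustment sets.
#' @param mc Either an [mc_config()] or `NULL` to derive rates from the
#'   validation stage.
#' @param n_mc_replicates Replicate count used when `mc` is `NULL`.
#' @param stages Subset of
#'   `c("include", "transform", "scan", "nested", "validate", "misclass_mc",
#'   "trend")` to run; later stages depending on earlier ones pull what they
#'   need automatically.
#' @param seed Master seed recorded in every output.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort, output_dir,
                            metabolites = default_metabolites(),
                            lods = default_lods(),
                            exposure = "MOP",
                            outcome = "selfreport_outcome",
                            stratum_col = "stratum_label",
                            psu_col = "psu_label",
                            weight_col = "sampling_weight",
                            cycle_count = 1L,
                            model_sequence = default_model_sequence(exposure,
                                                                    metabolites),
                            mc = NULL,
                            n_mc_replicates = 500L,
                            stages = c("include", "transform", "scan",
                                       "nested", "validate", "misclass_mc",
                                       "trend"),
                            seed = 1L) {
  structure(
    list(cohort = cohort, output_dir = output_dir, metabolites = metabolites,
         lods = lods, exposure = exposure, outcome = outcome,
         stratum_col = stratum_col, psu_col = psu_col,
         weight_col = weight_col, cycle_count = cycle_count,
         model_sequence = model_sequence, mc = mc,
         n_mc_replicates = as.integer(n_mc_replicates),
         stages = stages, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

# Histogram bin data per metabolite at the three transformation stages
# (raw concentration, dilution-corrected log ratio, inverse-normalized),
# for external plotting of before/after distributions.
transform_histograms <- function(cohort, metabolites, lods) {
  rows <- lapply(metabolites, function(m) {
    flags <- cohort[[paste0("below_lod_", m)]]
    conc <- substitute_lod(cohort[[m]], lods[[m]], flags)
    stages <- list(raw = cohort[[m]],
                   dilution_corrected = dilution_correct(conc,
                                                         cohort$creatinine),
                   inverse_normalized = cohort[[paste0("z_", m)]])
    do.call(rbind, lapply(names(stages), function(s) {
      h <- graphics::hist(stages[[s]], plot = FALSE)
      data.frame(metabolite = m, stage = s, mid = h$mids, count = h$counts)
    }))
  })
  do.call(rbind, rows)
}

pipeline_log <- function(...) {
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
}

write_stage_csv <- function(df, config, name) {
  path <- file.path(config$output_dir, paste0(name, ".csv"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# seed: ", config$seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order, writing one CSV per stage plus a
#' plain-text report that restates (never recomputes) the stage outputs.
#' Deterministic given the config seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of stage results (`included`, `cohort`, `scan`,
#'   `nested`, `validation`, `misclass_mc`, `trend`, `selection_flow`,
#'   `dnop`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- if (is.character(config$cohort)) {
    read_cohort_csv(config$cohort)
  } else {
    config$cohort
  }
  stages <- config$stages
  res <- list()

  if ("include" %in% stages) {
    pipeline_log("stage include: applying inclusion criteria")
    cohort <- apply_inclusion_criteria(cohort)
    res$selection_flow <- attr(cohort, "selection_flow")
    write_stage_csv(
      data.frame(step = names(res$selection_flow),
                 count = as.integer(res$selection_flow)),
      config, "selection_flow")
  }
  res$included <- cohort

  design <- survey_design(cohort[[config$stratum_col]],
                          cohort[[config$psu_col]],
                          cohort[[config$weight_col]],
                          cycle_count = config$cycle_count)

  needs_z <- any(c("transform", "scan", "nested", "misclass_mc", "trend")
                 %in% stages)
  if (needs_z) {
    pipeline_log("stage transform: LOD/2, dilution correction, inverse normal")
    cohort <- transform_exposures(cohort, config$metabolites, config$lods)
    if ("transform" %in% stages) {
      write_stage_csv(cohort[, c("subject_id",
                                 paste0("z_", config$metabolites))],
                      config, "transformed_exposures")
      write_stage_csv(transform_histograms(cohort, config$metabolites,
                                           config$lods),
                      config, "transform_histograms")
    }
  }
  res$cohort <- cohort

  if ("scan" %in% stages) {
    pipeline_log("stage scan: univariate metabolite scan")
    res$scan <- univariate_scan(cohort, design, config$metabolites,
                                outcome = config$outcome)
    write_stage_csv(as.data.frame(res$scan), config, "univariate_scan")
    res$dnop <- tryCatch(
      dnop_molar_sum_fit(cohort, design, config$lods,
                         outcome = config$outcome),
      error = function(e) NULL
    )
    if (!is.null(res$dnop)) write_stage_csv(res$dnop, config, "dnop_molar_sum")
  }

  if ("nested" %in% stages) {
    pipeline_log("stage nested: cumulative multivariable models")
    res$nested <- nested_models(cohort, design, config$exposure,
                                config$model_sequence,
                                outcome = config$outcome)
    write_stage_csv(as.data.frame(res$nested), config, "nested_models")
  }

  if ("validate" %in% stages) {
    pipeline_log("stage validate: self-report vs imaging grade")
    res$validation <- validate_selfreport(cohort, design)
    at <- res$validation$table
    ag <- res$validation$agreement
    tab4 <- data.frame(
      grade = rownames(at$counts4),
      selfreport_no = at$counts4[, 1], selfreport_yes = at$counts4[, 2],
      prop_selfreport_weighted =
        at$row_prop_weighted[rownames(at$counts4)],
      prop_selfreport_raw = at$row_prop_raw[rownames(at$counts4)],
      row.names = NULL
    )
    tab2 <- data.frame(
      grade = rownames(at$counts2),
      selfreport_no = at$counts2[, 1], selfreport_yes = at$counts2[, 2],
      prop_selfreport_weighted =
        at$row_prop_weighted[rownames(at$counts2)],
      prop_selfreport_raw = at$row_prop_raw[rownames(at$counts2)],
      row.names = NULL
    )
    write_stage_csv(rbind(tab4, tab2), config, "validation_crosstab")
    write_stage_csv(
      data.frame(
        quantity = c("percent_agreement_raw", "kappa_raw", "kappa_p_raw",
                     "percent_agreement_weighted", "kappa_weighted",
                     "fp_rate_weighted", "fn_rate_weighted",
                     "fp_rate_raw", "fn_rate_raw"),
        value = c(ag$percent_agreement, ag$kappa, ag$kappa_p,
                  ag$weighted$percent_agreement, ag$weighted$kappa,
                  ag$rates$fp_rate, ag$rates$fn_rate,
                  ag$rates$fp_rate_raw, ag$rates$fn_rate_raw)
      ),
      config, "validation_agreement")
  }

  if ("misclass_mc" %in% stages) {
    pipeline_log("stage misclass_mc: outcome-misclassification Monte Carlo")
    mcc <- config$mc
    if (is.null(mcc)) {
      rates <- if (!is.null(res$validation)) {
        res$validation$agreement$rates
      } else {
        list(fp_rate = 0.112, fn_rate = 0.0492)
      }
      mcc <- mc_config(fp_rate = rates$fp_rate, fn_rate = rates$fn_rate,
                       n_replicates = config$n_mc_replicates,
                       seed = config$seed, exposure = config$exposure)
    }
    res$misclass_mc <- run_misclass_mc(cohort, design, mcc,
                                       outcome = config$outcome)
    mc <- res$misclass_mc
    write_stage_csv(data.frame(replicate = seq_along(mc$betas),
                               beta = mc$betas),
                    config, "misclass_mc_replicates")
    write_stage_csv(
      data.frame(quantity = c("mean_beta", "sd_beta", "or", "ci_lower",
                              "ci_upper", "base_beta", "n_failed",
                              "fp_rate", "fn_rate"),
                 value = c(mc$mean_beta, mc$sd_beta, mc$or, mc$ci_lower,
                           mc$ci_upper, mc$base_beta, mc$n_failed,
                           mcc$fp_rate, mcc$fn_rate)),
      config, "misclass_mc_summary")
    write_stage_csv(mc$histogram, config, "misclass_mc_histogram")
  }

  if ("trend" %in% stages) {
    pipeline_log("stage trend: dose-response and Cochran-Armitage test")
    res$trend <- dose_response(cohort[[paste0("z_", config$exposure)]],
                               cohort[[config$outcome]], design)
    tr <- res$trend
    write_stage_csv(tr$table, config, "dose_response_bins")
    write_stage_csv(
      data.frame(quantity = c("trend_z", "trend_chisq", "trend_p",
                              "weighted_or_per_bin", "weighted_p"),
                 value = c(tr$trend$z, tr$trend$statistic, tr$trend$p_value,
                           tr$weighted_trend$or, tr$weighted_trend$p_value)),
      config, "dose_response_trend")
  }

  write_pipeline_report(res, config)
  invisible(res)
}

write_pipeline_report <- function(res, config) {
  lines <- c(
    "# Phthalate / retinopathy association pipeline report",
    paste0("seed: ", config$seed),
    paste0("stages: ", paste(config$stages, collapse = ", ")),
    paste0("subjects analyzed: ", nrow(res$included)),
    ""
  )
  if (!is.null(res$selection_flow)) {
    lines <- c(lines, "## Selection flow",
               paste0(names(res$selection_flow), ": ", res$selection_flow), "")
  }
  if (!is.null(res$scan)) {
    sig <- res$scan$metabolite[!is.na(res$scan$p_bonferroni) &
                                 res$scan$p_bonferroni < 0.05]
    lines <- c(lines, "## Univariate scan",
               paste0("metabolites significant after Bonferroni: ",
                      if (length(sig)) paste(sig, collapse = ", ") else "none"),
               "(full table: univariate_scan.csv)", "")
  }
  if (!is.null(res$validation)) {
    ag <- res$validation$agreement
    lines <- c(lines, "## Outcome validation",
               sprintf("raw agreement: %.2f%%, raw kappa: %.4f (p = %.3g)",
                       ag$percent_agreement, ag$kappa, ag$kappa_p),
               sprintf("design-weighted agreement: %.2f%%, kappa: %.4f",
                       ag$weighted$percent_agreement, ag$weighted$kappa),
               paste0("note: raw (count-based) and design-weighted values ",
                      "differ whenever sampling weights are unequal; both ",
                      "are reported."),
               sprintf("misclassification rates (weighted): fp %.4f, fn %.4f",
                       ag$rates$fp_rate, ag$rates$fn_rate), "")
  }
  if (!is.null(res$misclass_mc)) {
    mc <- res$misclass_mc
    lines <- c(lines, "## Misclassification Monte Carlo",
               sprintf("mean beta %.4f (SD %.4f), OR %.2f (CI %.2f-%.2f)",
                       mc$mean_beta, mc$sd_beta, mc$or, mc$ci_lower,
                       mc$ci_upper), "")
  }
  if (!is.null(res$trend)) {
    lines <- c(lines, "## Dose-response",
               sprintf("Cochran-Armitage chi2(1) = %.3f, p = %.4g",
                       res$trend$trend$statistic, res$trend$trend$p_value), "")
  }
  writeLines(lines, file.path(config$output_dir, "report.md"))
  invisible(NULL)
}
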