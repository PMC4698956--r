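# Monte Carlo outcome-misclassification sensitivity analysis: reshuffle the
# observed cases/controls at the validation-derived rates, refit the full
# survey-weighted model per replicate, and summarize the distribution of the
# exposure coefficient.

#' Configuration for the misclassification Monte Carlo
#'
#' @param fp_rate Probability that an observed case is flipped to control
#'   (default 0.112, the validation false-positive rate).
#' @param fn_rate Probability that an observed control is flipped to case
#'   (default 0.0492).
#' @param n_replicates Number of replicates (default 5000).
#' @param seed Seed controlling all replicate flips.
#' @param model_covariates Adjustment set for the refitted full model; default
#'   the final model of [default_model_sequence()] (all other metabolites plus
#'   every coded confounder).
#' @param exposure Metabolite of interest (default `"MOP"`).
#' @param ci_level Confidence level (default 0.95).
#' @return An `mc_config` list.
#' @export
mc_config <- function(fp_rate = 0.112, fn_rate = 0.0492,
                      n_replicates = 5000L, seed = 1L,
                      model_covariates = NULL, exposure = "MOP",
                      ci_level = 0.95) {
  for (r in c(fp_rate, fn_rate)) {
    if (!is.finite(r) || r < 0 || r > 1) stop("rates must lie in [0, 1]")
  }
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(
    list(fp_rate = fp_rate, fn_rate = fn_rate,
         n_replicates = as.integer(n_replicates), seed = as.integer(seed),
         model_covariates = model_covariates, exposure = exposure,
         ci_level = ci_level),
    class = "mc_config"
  )
}

#' Monte Carlo sensitivity analysis for outcome misclassification
#'
#' For each replicate the observed binary outcome is reshuffled by
#' [inject_misclassification()] at the configured false-positive and
#' false-negative rates and the full survey-weighted logistic model is refit;
#' the exposure coefficient is recorded. Replicates whose fit fails are
#' excluded (more than 5% failures aborts). The base fit's coefficients are
#' used as warm starts, which leaves the results identical to cold starts
#' because the iterations run to the same tolerance.
#'
#' @param cohort Cohort with `z_` columns, coded covariates and the outcome.
#' @param design A [survey_design()] object.
#' @param config An [mc_config()].
#' @param outcome Outcome column name.
#' @param warm_start Use the base fit's coefficients as starting values
#'   (default `TRUE`).
#' @return An `mc_summary` from [summarize_mc()], with the replicate
#'   coefficients in `$betas`, the base fit in `$base_fit`, and the failure
#'   count in `$n_failed`.
#' @export
run_misclass_mc <- function(cohort, design, config = mc_config(),
                            outcome = "selfreport_outcome",
                            warm_start = TRUE) {
  stopifnot(inherits(config, "mc_config"))
  covs <- config$model_covariates %||%
    default_model_sequence(config$exposure)[[16L]]
  zexp <- paste0("z_", config$exposure)
  X <- cohort[, c(zexp, covs), drop = FALSE]
  names(X)[1] <- config$exposure
  y <- cohort[[outcome]]
  base_fit <- fit_weighted_logistic(y, X, design, level = config$ci_level)
  start <- if (warm_start) base_fit$coefficients else NULL

  betas <- rep(NA_real_, config$n_replicates)
  n_failed <- 0L
  with_substream(config$seed, "misclass_mc", {
    for (r in seq_len(config$n_replicates)) {
      y_r <- inject_misclassification(y, config$fp_rate, config$fn_rate)
      if (all(y_r == y)) {
        # no flips: the refit is the base fit
        betas[r] <- base_fit$coefficients[[config$exposure]]
        next
      }
      fit <- tryCatch(
        fit_weighted_logistic(y_r, X, design, level = config$ci_level,
                              start = start),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        n_failed <- n_failed + 1L
      } else {
        betas[r] <- fit$coefficients[[config$exposure]]
      }
    }
  })
  if (n_failed > 0.05 * config$n_replicates) {
    stop("more than 5% of misclassification replicates failed to fit (",
         n_failed, "/", config$n_replicates, ")")
  }
  out <- summarize_mc(betas[!is.na(betas)], ci_level = config$ci_level)
  out$base_fit <- base_fit
  out$base_beta <- base_fit$coefficients[[config$exposure]]
  out$n_failed <- n_failed
  out$config <- config
  out
}

#' Summarize replicate coefficients from the misclassification Monte Carlo
#'
#' Normal-theory summary of the replicate coefficient distribution: mean, SD,
#' odds ratio `exp(mean)`, and the CI `exp(mean +/- z * sd)` (a percentile CI
#' is also reported). Histogram bin data with the overlaid normal density
#' parameters are included for plotting.
#'
#' @param betas Numeric vector of replicate log-odds coefficients (>= 2).
#' @param ci_level Confidence level.
#' @return An `mc_summary` list: `betas`, `n_replicates`, `mean_beta`,
#'   `sd_beta`, `or`, `ci_lower`, `ci_upper`, `ci_percentile`, `skewness`,
#'   `histogram` (data frame of bin mids/density), `normal_overlay`
#'   (mean/sd).
#' @export
summarize_mc <- function(betas, ci_level = 0.95) {
  if (length(betas) < 2L) stop("need at least 2 replicate coefficients")
  m <- mean(betas)
  s <- stats::sd(betas)
  zq <- stats::qnorm(1 - (1 - ci_level) / 2)
  h <- graphics::hist(betas, plot = FALSE)
  g1 <- if (s == 0) 0 else mean((betas - m)^3) / (mean((betas - m)^2))^1.5
  structure(
    list(
      betas = betas, n_replicates = length(betas),
      mean_beta = m, sd_beta = s, or = exp(m),
      ci_lower = exp(m - zq * s), ci_upper = exp(m + zq * s),
      ci_percentile = exp(unname(stats::quantile(
        betas, c((1 - ci_level) / 2, 1 - (1 - ci_level) / 2)))),
      skewness = g1,
      histogram = data.frame(mid = h$mids, density = h$density,
                             count = h$counts),
      normal_overlay = c(mean = m, sd = s),
      ci_level = ci_level
    ),
    class = "mc_summary"
  )
}

#' @export
print.mc_summary <- function(x, ...) {
  cat(sprintf(
    "Misclassification MC: %d replicates, mean beta = %.4f (SD %.4f)\n",
    x$n_replicates, x$mean_beta, x$sd_beta))
  cat(sprintf("OR = %.2f (%d%% CI %.2f-%.2f)\n", x$or, round(100 * x$ci_level),
              x$ci_lower, x$ci_upper))
  invisible(x)
}
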