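test_that("covariate coding matches the documented scheme", {
  raw <- data.frame(
    age = c(61, NA),
    sex = c("male", "female"),
    hispanic = c("Mexican American", "non-Hispanic white"),
    married = c("married", "widowed"),
    education = c(4, NA),
    pir = c(2.5, NA),
    calories_kcal = c(1700, 1200.5),
    bmi = c(32, NA),
    activity_mets = c(7, NA),
    hba1c = c(6.5, 6.4),
    tchol_mgdl = c(239, 240),
    hdl_mgdl = c(39, 49),
    trig_mgdl = c(150, NA),
    hypertension = c(NA, "no"),
    duration_years = c(14, 2)
  )
  got <- encode_covariates(raw)
  expect_equal(got$age, c(61, 0))
  expect_equal(got$sex, c(1, 0))
  expect_equal(got$hispanic, c(1, 0))
  expect_equal(got$married, c(1, 0))
  expect_equal(got$education, c(4, 0))
  expect_equal(got$pir, c(2.5, 0))
  expect_equal(got$calories, c(2, 1))
  expect_equal(got$obesity, c(2, 0))        # BMI 32 -> 2, unmeasured -> 0
  expect_equal(got$activity, c(2, 0))       # > 6 METs -> 2, unknown -> 0
  expect_equal(got$hba1c_cat, c(2, 1))
  expect_equal(got$tchol, c(1, 2))
  expect_equal(got$hdl, c(2, 2))            # male < 40, female < 50 -> low
  expect_equal(got$trig, c(2, 0))
  expect_equal(got$htn, c(0, 1))            # unknown hypertension -> 0
  expect_equal(got$duration, c(4, 1))
  # every missing value codes to 0, never NA
  expect_false(anyNA(got))
})

test_that("Bonferroni correction is monotone, capped and uses fixed m", {
  expect_equal(bonferroni_adjust(0.004, m = 12), 0.048)
  expect_equal(bonferroni_adjust(0.053, m = 12), 0.636)
  expect_equal(bonferroni_adjust(0.285, m = 12), 1.000)
  expect_equal(bonferroni_adjust(1 / 12, m = 12), 1.000)
  set.seed(2)
  for (i in 1:20) {
    m <- sample(2:30, 1)
    p <- sort(runif(m))
    pc <- bonferroni_adjust(p, m = m)
    expect_true(all(pc >= p))
    expect_true(all(diff(pc) >= 0))
    expect_true(all(pc <= 1))
  }
})

test_that("univariate scan fits each metabolite separately", {
  coh <- generate_cohort(test_config(n = 500, true_log_or = stats::setNames(
    c(rep(0, 5), log(2), rep(0, 6)), default_metabolites())))
  coh <- transform_exposures(coh, default_metabolites(), default_lods())
  d <- survey_design(coh$stratum_label, coh$psu_label, coh$sampling_weight)
  sc <- univariate_scan(coh, d, outcome = "selfreport_outcome")
  expect_equal(nrow(sc), 12)
  expect_true(all(is.na(sc$error)))
  expect_equal(sc$p_bonferroni, pmin(1, 12 * sc$p_value))
  expect_equal(sc$or, exp(sc$coef))
  # a metabolite's estimate ignores the other columns: permuting them is a no-op
  coh_perm <- coh
  perm <- sample(nrow(coh))
  for (m in setdiff(default_metabolites(), "MOP")) {
    coh_perm[[paste0("z_", m)]] <- coh[[paste0("z_", m)]][perm]
  }
  sc_perm <- univariate_scan(coh_perm, d)
  expect_equal(sc_perm[sc_perm$metabolite == "MOP", c("coef", "se")],
               sc[sc$metabolite == "MOP", c("coef", "se")], tolerance = 1e-12)
  # failed fits are flagged without killing the scan, m stays fixed
  coh_bad <- coh
  coh_bad$z_MCP <- 0
  sc_bad <- univariate_scan(coh_bad, d)
  expect_false(is.na(sc_bad$error[sc_bad$metabolite == "MCP"]))
  expect_equal(sc_bad$p_bonferroni[sc_bad$metabolite == "MOP"],
               min(1, 12 * sc_bad$p_value[sc_bad$metabolite == "MOP"]))
})

test_that("nested model sequence is cumulative and reports the exposure", {
  seq16 <- default_model_sequence("MOP")
  expect_length(seq16, 16)
  expect_equal(seq16$model_1, paste0("z_", setdiff(default_metabolites(),
                                                   "MOP")))
  for (i in 2:16) {
    expect_true(all(seq16[[i - 1]] %in% seq16[[i]]))
    expect_length(seq16[[i]], length(seq16[[i - 1]]) + 1L)
  }
  expect_equal(tail(seq16$model_16, 1), "obesity")

  coh <- generate_cohort(test_config(n = 600, true_log_or = stats::setNames(
    c(rep(0, 5), log(2), rep(0, 6)), default_metabolites())))
  coh <- transform_exposures(coh, default_metabolites(), default_lods())
  d <- survey_design(coh$stratum_label, coh$psu_label, coh$sampling_weight)
  nm <- nested_models(coh, d, "MOP", seq16[1:4])
  expect_equal(nrow(nm), 4)
  expect_true(all(is.na(nm$error)))
  expect_true(all(nm$or > 0))
  fits <- attr(nm, "fits")
  expect_length(fits[[1]]$coefficients, 13) # intercept + MOP + 11 others
})

test_that("independent exposures make adjusted and univariate MOP agree", {
  cfg <- generator_config(
    n_subjects = 4000, seed = 55,
    conc_correlation = diag(12),
    true_log_or = stats::setNames(c(rep(0, 5), log(1.8), rep(0, 6)),
                                  default_metabolites())
  )
  coh <- generate_cohort(cfg)
  coh <- transform_exposures(coh, default_metabolites(), default_lods())
  d <- survey_design(coh$stratum_label, coh$psu_label, coh$sampling_weight)
  uni <- univariate_scan(coh, d)
  m1 <- nested_models(coh, d, "MOP", default_model_sequence("MOP")[1])
  # with mutually independent exposures the adjusted estimate matches the
  # univariate one within a few standard errors
  expect_lt(abs(m1$coef[1] - uni$coef[uni$metabolite == "MOP"]),
            2 * sqrt(m1$se[1]^2 + uni$se[uni$metabolite == "MOP"]^2))
})

test_that("DnOP molar sum converts mass to micromoles correctly", {
  expect_equal(molar_sum_dnop(278.34, 0), 1.0)
  expect_equal(molar_sum_dnop(0, 252.22), 1.0)
  expect_equal(molar_sum_dnop(0, 0), 0)
  expect_equal(molar_sum_dnop(139.17, 126.11), 1.0)
  expect_error(molar_sum_dnop(-1, 0), "nonnegative")

  coh <- generate_cohort(test_config(n = 400))
  d <- survey_design(coh$stratum_label, coh$psu_label, coh$sampling_weight)
  ms <- dnop_molar_sum_fit(coh, d)
  expect_equal(ms$metabolite, "DnOP_molar_sum")
  expect_true(ms$ci_lower < ms$or && ms$or < ms$ci_upper)
})
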