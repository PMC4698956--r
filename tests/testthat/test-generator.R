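test_that("cohort generation is deterministic and respects the design", {
  cfg <- test_config(n = 300)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- generate_cohort(test_config(n = 300, seed = 100))
  expect_false(identical(c1$MOP, c3$MOP))
  # every stratum/PSU cell populated with >= 2 subjects
  cell <- table(c1$stratum_label, c1$psu_label)
  expect_true(all(cell >= 2))
  expect_true(all(c1$sampling_weight > 0))
  # imaging grades exist only in the substudy
  expect_true(all(is.na(c1$imaging_grade[!c1$in_substudy])))
  expect_true(all(!is.na(c1$imaging_grade[c1$in_substudy])))
})

test_that("LOD censoring flags are consistent and never touch detects", {
  coh <- generate_cohort(test_config(n = 300))
  raw <- attr(coh, "raw_concentrations")
  lods <- default_lods()
  for (m in default_metabolites()) {
    flag <- coh[[paste0("below_lod_", m)]]
    expect_equal(flag, unname(raw[, m] < lods[[m]]))
    # detects are passed through unchanged; censored values hold the LOD
    expect_equal(coh[[m]][!flag], unname(raw[!flag, m]))
    expect_true(all(coh[[m]][flag] == lods[[m]]))
  }
  # MOP detection fraction near its calibrated 73%
  expect_gt(mean(!coh$below_lod_MOP), 0.6)
  expect_lt(mean(!coh$below_lod_MOP), 0.85)
})

test_that("generated outcome prevalence matches the logistic model", {
  cfg <- generator_config(n_subjects = 8000, seed = 17)
  coh <- generate_cohort(cfg)
  # null exposure effects: expected prevalence = plogis(intercept)
  expect_equal(mean(coh$true_outcome), plogis(cfg$intercept),
               tolerance = 3 * sqrt(0.14 * 0.86 / 8000) / 0.12)
  d <- survey_design(coh$stratum_label, coh$psu_label, coh$sampling_weight)
  wp <- design_proportion(coh$true_outcome, d)
  expect_lt(abs(wp$estimate - plogis(cfg$intercept)), 4 * wp$se)
})

test_that("self-report misclassification is calibrated on the report margin", {
  cfg <- generator_config(n_subjects = 20000, seed = 23)
  coh <- generate_cohort(cfg)
  s <- coh$selfreport_outcome
  t <- coh$true_outcome
  fp_hat <- mean(t[s == 1] == 0)
  fn_hat <- mean(t[s == 0] == 1)
  se_fp <- sqrt(0.112 * 0.888 / sum(s == 1))
  se_fn <- sqrt(0.0492 * 0.9508 / sum(s == 0))
  expect_lt(abs(fp_hat - 0.112), 3 * se_fp)
  expect_lt(abs(fn_hat - 0.0492), 3 * se_fn)
  # zero rates reproduce the truth exactly
  c0 <- generate_cohort(generator_config(n_subjects = 500,
                                         selfreport_fp_rate = 0,
                                         selfreport_fn_rate = 0, seed = 5))
  expect_identical(c0$selfreport_outcome, c0$true_outcome)
})

test_that("invalid generator configurations are rejected", {
  expect_error(generator_config(psus_per_stratum = 1), "psus_per_stratum")
  expect_error(generator_config(n_subjects = 20), "too small")
  badR <- default_conc_correlation()
  badR[1, 2] <- 0.99
  expect_error(generator_config(conc_correlation = badR), "symmetric")
  badR <- matrix(0.999, 12, 12) + diag(0.001, 12)
  badR[1, 2] <- badR[2, 1] <- -0.999
  expect_error(generator_config(conc_correlation = badR),
               "positive semi-definite")
  expect_error(generator_config(selfreport_fp_rate = 1.2), "rates")
})

test_that("inclusion criteria implement the diabetes/age rules", {
  base <- data.frame(
    dm_selfreport = c("no", "yes", "missing", "refused", "yes", "no"),
    insulin = c("no", "no", "no", "no", "no", "yes"),
    pills = c("no", "no", "no", "no", "no", "no"),
    hba1c = c(6.5, NA, NA, 7.2, 8, NA),
    age_screening = c(55, 60, 50, 45, 62, 19),
    age_diagnosis = c(NA, 40, NA, NA, 19, 10)
  )
  out <- apply_inclusion_criteria(base)
  # row 1: undiagnosed via HbA1c exactly 6.5 -> in
  # row 2: questionnaire yes, adult onset -> in
  # row 3: no qualifying criterion -> out
  # row 4: refused questionnaire but HbA1c 7.2 -> in (undiagnosed route)
  # row 5: diagnosed at 19 -> out
  # row 6: insulin yes but screened under 20 -> out
  expect_identical(rownames(out), c("1", "2", "4"))
  flow <- attr(out, "selection_flow")
  expect_equal(unname(flow["total"]), 6)
  expect_equal(unname(flow["included"]), 3)
  expect_equal(unname(flow["hba1c_additions"]), 2)
  # empty output allowed
  none <- apply_inclusion_criteria(base[3, , drop = FALSE])
  expect_equal(nrow(none), 0)
})

test_that("misclassification injection follows the configured flip law", {
  y <- c(rep(1, 6), rep(0, 4))
  expect_identical(inject_misclassification(y, 0, 0, seed = 1), as.integer(y))
  expect_identical(inject_misclassification(y, 1, 1, seed = 1),
                   as.integer(1 - y))
  expect_identical(inject_misclassification(y, 0.3, 0.2, seed = 9),
                   inject_misclassification(y, 0.3, 0.2, seed = 9))
  expect_error(inject_misclassification(y, -0.1, 0), "rates")
  expect_error(inject_misclassification(c(0, 2), 0.1, 0.1), "binary")
  # realized flip fractions obey the binomial law at large n
  set.seed(8)
  y <- rbinom(1e5, 1, 0.5)
  z <- inject_misclassification(y, 0.112, 0.0492, seed = 44)
  fp_real <- mean(z[y == 1] == 0)
  fn_real <- mean(z[y == 0] == 1)
  expect_lt(abs(fp_real - 0.112), 3 * sqrt(0.112 * 0.888 / sum(y == 1)))
  expect_lt(abs(fn_real - 0.0492), 3 * sqrt(0.0492 * 0.9508 / sum(y == 0)))
  expect_length(z, length(y))
})

test_that("cohort CSV round trip preserves analysis columns", {
  coh <- generate_cohort(test_config(n = 120))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, path)
  back <- read_cohort_csv(path)
  expect_equal(back$MOP, coh$MOP)
  expect_identical(back$below_lod_MOP, coh$below_lod_MOP)
  expect_equal(back$sampling_weight, coh$sampling_weight)
  expect_identical(back$imaging_grade, coh$imaging_grade)
})
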