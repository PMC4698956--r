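test_that("crosstab collapses the four imaging grades additively", {
  counts <- table4_counts()
  # expand the published validation counts into subject-level vectors
  gr <- rep(rep(rownames(counts), 2),
            times = c(counts[, 1], counts[, 2]))
  sr <- rep(rep(c(0, 1), each = 4), times = c(counts[, 1], counts[, 2]))
  at <- crosstab(sr, gr)
  expect_equal(at$n_total, 285)
  expect_equal(unname(at$counts4), unname(counts))
  expect_equal(unname(at$counts2["no_mild", ]), c(216, 33))
  expect_equal(unname(at$counts2["modsev_pr", ]), c(19, 17))
  expect_equal(colSums(at$counts2), colSums(at$counts4))
  # collapsing is order-independent
  perm <- sample(length(sr))
  at2 <- crosstab(sr[perm], gr[perm])
  expect_equal(at2$counts2, at$counts2)
  # raw row proportions of self-report positives
  expect_equal(unname(at$row_prop_raw["no_mild"]), 33 / 249)
  expect_equal(unname(at$row_prop_raw["modsev_pr"]), 17 / 36)
  expect_error(crosstab(numeric(0), character(0)), "empty")
})

test_that("Cohen's kappa follows its defining identity", {
  tab <- matrix(c(216, 19, 33, 17), 2,
                dimnames = list(c("no_mild", "modsev_pr"), c("0", "1")))
  k <- cohens_kappa(tab)
  po <- 233 / 285
  pe <- (249 * 235 + 36 * 50) / 285^2
  expect_equal(k$percent_agreement, 100 * po, tolerance = 1e-12)
  expect_equal(k$kappa, (po - pe) / (1 - pe), tolerance = 1e-12)
  expect_lt(k$kappa_p, 0.001)
  # cross-check against an independent implementation
  skip_if_not_installed("e1071")
  expect_equal(k$kappa, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
})

test_that("kappa hits its boundary and invariance cases", {
  diag_tab <- matrix(c(40, 0, 0, 60), 2)
  expect_equal(cohens_kappa(diag_tab)$kappa, 1)
  # rows proportional to column margins -> chance agreement only
  indep <- outer(c(30, 70), c(0.2, 0.8))
  expect_equal(cohens_kappa(indep)$kappa, 0, tolerance = 1e-12)
  # swapping both axis labels simultaneously leaves kappa unchanged
  tab <- matrix(c(50, 9, 12, 29), 2)
  expect_equal(cohens_kappa(tab[2:1, 2:1])$kappa, cohens_kappa(tab)$kappa,
               tolerance = 1e-12)
  expect_error(cohens_kappa(matrix(c(10, 5, 0, 0), 2)), "degenerate")
  # equal weights: design-weighted variant equals the raw one exactly
  set.seed(12)
  n <- 80
  gr <- sample(c("none", "mild", "modsev", "PR"), n, replace = TRUE,
               prob = c(0.55, 0.25, 0.14, 0.06))
  sr <- as.integer(gr %in% c("modsev", "PR"))
  sr[sample(n, 12)] <- 1 - sr[sample(n, 12)]
  d <- survey_design(rep("s", n), rep(c("p1", "p2"), n / 2), rep(2.5, n))
  k <- cohens_kappa(crosstab(sr, gr, d))
  expect_equal(k$weighted$kappa, k$kappa, tolerance = 1e-12)
  expect_equal(k$weighted$percent_agreement, k$percent_agreement,
               tolerance = 1e-12)
})

test_that("misclassification rates come from the right denominators", {
  counts2 <- rbind(no_mild = c(216, 33), modsev_pr = c(19, 17))
  r <- extract_misclass_rates(counts2)
  expect_equal(r$fp_rate_raw, 33 / 50)
  expect_equal(r$fn_rate_raw, 19 / 235)
  perfect <- rbind(no_mild = c(100, 0), modsev_pr = c(0, 20))
  rp <- extract_misclass_rates(perfect)
  expect_equal(rp$fp_rate_raw, 0)
  expect_equal(rp$fn_rate_raw, 0)
  expect_error(extract_misclass_rates(rbind(c(5, 0), c(3, 0))),
               "denominator")
})

test_that("generator round trip recovers the configured rates", {
  cfg <- generator_config(n_subjects = 12000, substudy_fraction = 1, seed = 31)
  coh <- generate_cohort(cfg)
  d <- survey_design(coh$stratum_label, coh$psu_label, coh$sampling_weight)
  v <- validate_selfreport(coh, d)
  r <- v$agreement$rates
  n_pos <- sum(coh$selfreport_outcome == 1)
  n_neg <- sum(coh$selfreport_outcome == 0)
  expect_lt(abs(r$fp_rate_raw - 0.112), 3 * sqrt(0.112 * 0.888 / n_pos))
  expect_lt(abs(r$fn_rate_raw - 0.0492), 3 * sqrt(0.0492 * 0.9508 / n_neg))
})
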