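test_that("weighted proportion is the Horvitz-Thompson ratio", {
  d <- survey_design(rep("s", 3), c("p1", "p2", "p1"), c(2, 1, 1))
  expect_equal(design_proportion(c(1, 0, 1), d)$estimate, 0.75)
  # equal weights reduce to the sample proportion
  d2 <- survey_design(rep("s", 4), rep(c("p1", "p2"), 2), rep(1, 4))
  expect_equal(design_proportion(c(1, 1, 0, 0), d2)$estimate, 0.5)
})

test_that("linearized proportion SE matches the brute-force oracle", {
  fx <- fixture12()
  d <- survey_design(fx$stratum, fx$psu, fx$w)
  got <- design_proportion(fx$y, d)
  expect_equal(got$se,
               oracle_design_proportion_se(fx$y, fx$w, fx$stratum, fx$psu),
               tolerance = 1e-10)
  expect_equal(got$df, 4)  # 6 PSUs - 2 strata
})

test_that("weight scale and cycle pooling leave ratio estimates unchanged", {
  fx <- fixture12()
  d1 <- survey_design(fx$stratum, fx$psu, fx$w)
  d5 <- survey_design(fx$stratum, fx$psu, fx$w, cycle_count = 5)
  dk <- survey_design(fx$stratum, fx$psu, fx$w * 137.2)
  for (d in list(d5, dk)) {
    expect_equal(design_proportion(fx$y, d)$estimate,
                 design_proportion(fx$y, d1)$estimate, tolerance = 1e-12)
    expect_equal(design_proportion(fx$y, d)$se,
                 design_proportion(fx$y, d1)$se, tolerance = 1e-12)
  }
  expect_identical(pool_cycle_weights(c(5, 10), 1), c(5, 10))
  expect_equal(pool_cycle_weights(c(5, 10), 5), c(1, 2))
})

test_that("singleton-PSU strata error unless centering is requested", {
  y <- c(1, 0, 1, 0)
  d <- survey_design(c("a", "a", "b", "b"), c("p1", "p2", "p1", "p1"),
                     rep(1, 4))
  expect_error(design_proportion(y, d), "single PSU")
  expect_silent(design_proportion(y, d, single_psu = "center"))
})

test_that("pseudo-MLE coefficients reduce to classical ML under SRS", {
  set.seed(21)
  n <- 200
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.8 * x))
  d <- survey_design(rep("s1", n), paste0("p", rep(1:4, length.out = n)),
                     rep(1, n))
  fit <- fit_weighted_logistic(y, data.frame(x = x), d)
  ref <- glm(y ~ x, family = binomial)
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
  expect_true(fit$converged)
})

test_that("logistic sandwich SEs match the brute-force oracle", {
  fx <- fixture16()
  d <- survey_design(fx$stratum, fx$psu, fx$w)
  fit <- fit_weighted_logistic(fx$y, fx[, c("x1", "x2")], d)
  X <- cbind(1, fx$x1, fx$x2)
  V <- oracle_sandwich_vcov(fx$y, X, fx$w, fx$stratum, fx$psu,
                            fit$coefficients)
  expect_equal(unname(fit$se), sqrt(diag(V)), tolerance = 1e-8)
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-8)
  # coefficients agree with an independent weighted fit
  ref <- suppressWarnings(glm(y ~ x1 + x2, data = fx, weights = w,
                              family = quasibinomial,
                              control = glm.control(epsilon = 1e-12)))
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-8)
  # sandwich is PSD and symmetric; OR/CI consistency
  expect_true(all(eigen(fit$vcov, symmetric = TRUE)$values > 0))
  expect_equal(fit$or, exp(fit$coefficients))
  tcrit <- qt(0.975, df = fit$df)
  expect_equal(fit$ci_upper,
               exp(fit$coefficients + tcrit * fit$se), tolerance = 1e-12)
  # scale invariance of the whole fit
  dk <- survey_design(fx$stratum, fx$psu, fx$w * 9.3)
  fit2 <- fit_weighted_logistic(fx$y, fx[, c("x1", "x2")], dk)
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-9)
  expect_equal(fit2$se, fit$se, tolerance = 1e-9)
  expect_equal(fit2$p_value, fit$p_value, tolerance = 1e-9)
})

test_that("degenerate fits fail loudly", {
  fx <- fixture16()
  d <- survey_design(fx$stratum, fx$psu, fx$w)
  expect_error(fit_weighted_logistic(fx$y, data.frame(c1 = rep(2, 16)), d),
               "constant")
  expect_error(fit_weighted_logistic(rep(1, 16),
                                     fx[, c("x1", "x2")], d))
  # complete separation diverges and is detected
  xs <- c(rep(-1, 8), rep(1, 8))
  ys <- c(rep(0, 8), rep(1, 8))
  expect_error(fit_weighted_logistic(ys, data.frame(x = xs), d),
               "separation|converge")
})

test_that("null CIs achieve near-nominal coverage under the design", {
  set.seed(77)
  reps <- 300
  n <- 400
  covered <- logical(reps)
  strat <- rep(sprintf("s%d", 1:5), each = n / 5)
  psu <- rep(rep(c("p1", "p2"), each = n / 10), 5)
  for (r in seq_len(reps)) {
    x <- rnorm(n)
    y <- rbinom(n, 1, 0.3)  # independent of x
    w <- rlnorm(n, 0, 0.5)
    d <- survey_design(strat, psu, w)
    fit <- fit_weighted_logistic(y, data.frame(x = x), d)
    covered[r] <- fit$ci_lower[["x"]] < 1 && fit$ci_upper[["x"]] > 1
  }
  mc_se <- sqrt(0.95 * 0.05 / reps)
  expect_gt(mean(covered), 0.95 - 3 * mc_se)
})
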