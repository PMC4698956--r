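# Brute-force oracles, written independently of the package's vectorized
# estimators: plain loops over strata and PSUs following the textbook
# formulas for Taylor-linearized (with-replacement) design variance.

# Between-PSU covariance of per-subject contributions u (matrix or vector),
# looping explicitly over strata and PSUs.
oracle_strat_psu_var <- function(u, stratum, psu) {
  u <- as.matrix(u)
  k <- ncol(u)
  V <- matrix(0, k, k)
  for (h in unique(stratum)) {
    in_h <- stratum == h
    psus <- unique(psu[in_h])
    nh <- length(psus)
    z <- matrix(0, nh, k)
    for (j in seq_along(psus)) {
      rows <- in_h & psu == psus[j]
      z[j, ] <- colSums(u[rows, , drop = FALSE])
    }
    zbar <- colMeans(z)
    for (j in seq_len(nh)) {
      d <- z[j, ] - zbar
      V <- V + nh / (nh - 1) * (d %o% d)
    }
  }
  V
}

# Linearized SE of the weighted proportion sum(w*y)/sum(w).
oracle_design_proportion_se <- function(y, w, stratum, psu) {
  est <- sum(w * y) / sum(w)
  u <- w * (y - est) / sum(w)
  sqrt(oracle_strat_psu_var(u, stratum, psu)[1, 1])
}

# Sandwich covariance of a weighted logistic fit, evaluated at the supplied
# coefficients (intercept-first design matrix X built by the caller).
oracle_sandwich_vcov <- function(y, X, w, stratum, psu, beta) {
  p <- 1 / (1 + exp(-drop(X %*% beta)))
  k <- ncol(X)
  info <- matrix(0, k, k)
  for (i in seq_len(nrow(X))) {
    info <- info + w[i] * p[i] * (1 - p[i]) * (X[i, ] %o% X[i, ])
  }
  bread <- solve(info)
  score <- X * (w * (y - p))
  meat <- oracle_strat_psu_var(score, stratum, psu)
  bread %*% meat %*% bread
}

# Cochran-Armitage trend chi-square via the textbook formula, scalar loops.
oracle_trend_chisq <- function(pos, tot, s = seq_along(pos)) {
  N <- sum(tot)
  pbar <- sum(pos) / N
  num <- 0
  for (i in seq_along(pos)) num <- num + s[i] * (pos[i] - tot[i] * pbar)
  den <- pbar * (1 - pbar) * (sum(tot * s^2) - sum(tot * s)^2 / N)
  num^2 / den
}

# Small fixed two-stratum fixtures used across design tests.
fixture12 <- function() {
  data.frame(
    stratum = rep(c("a", "b"), each = 6),
    psu = rep(c("p1", "p1", "p2", "p2", "p3", "p3"), 2),
    w = c(2, 1, 3, 1.5, 2.5, 1, 1.2, 0.8, 2.2, 1.8, 0.5, 3),
    y = c(1, 0, 1, 1, 0, 0, 1, 1, 0, 1, 0, 1)
  )
}

fixture16 <- function() {
  set.seed(404)
  data.frame(
    stratum = rep(c("a", "b"), each = 8),
    psu = rep(rep(c("p1", "p2"), each = 4), 2),
    w = round(runif(16, 0.5, 4), 2),
    x1 = round(rnorm(16), 3),
    x2 = round(runif(16, -1, 1), 3),
    y = c(1, 0, 1, 1, 0, 1, 0, 0, 1, 1, 0, 1, 0, 0, 1, 0)
  )
}

# Tiny default-style generator config scaled for unit tests.
test_config <- function(n = 400, seed = 99, ...) {
  generator_config(n_subjects = n, n_strata = 5, seed = seed, ...)
}

null_log_or <- function() {
  stats::setNames(rep(0, 12), default_metabolites())
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "phthalret", mustWork = TRUE)
}

table4_counts <- function() {
  tab <- utils::read.csv(fixture_path("validation_subsample_counts.csv"))
  m <- as.matrix(tab[, c("selfreport_no", "selfreport_yes")])
  rownames(m) <- tab$grade
  m
}
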