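# Design-based estimation: Horvitz-Thompson ratio means/proportions with
# Taylor-linearized standard errors, and pseudo-maximum-likelihood logistic
# regression with a stratified between-PSU sandwich covariance. This follows
# the "with replacement" first-stage approximation used for public-release
# NHANES designs (no finite-population correction, no replicate weights).

#' Describe a stratified multistage survey design
#'
#' Bundles the per-subject stratum, primary sampling unit (PSU) and sampling
#' weight into a design object used by all design-based estimators. Variance
#' is estimated from between-PSU variation within strata, so every stratum
#' must contain at least two PSUs unless singleton handling is overridden at
#' estimation time. PSU labels are nested within strata (the same PSU label in
#' two strata denotes two distinct PSUs).
#'
#' @param stratum Vector of stratum labels, one per subject.
#' @param psu Vector of PSU labels, one per subject.
#' @param weight Positive sampling weights, one per subject.
#' @param cycle_count Number of pooled survey cycles; weights are divided by
#'   this (see [pool_cycle_weights()]). Default 1 (no pooling).
#' @return An object of class `survey_design_spec` with elements `stratum`,
#'   `psu` (nested labels), `weight`, `n_strata`, `n_psu`, and `df`
#'   (design degrees of freedom, `n_psu - n_strata`).
#' @export
survey_design <- function(stratum, psu, weight, cycle_count = 1L) {
  n <- length(weight)
  if (length(stratum) != n || length(psu) != n) {
    stop("stratum, psu and weight must have the same length")
  }
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    stop("sampling weights must be positive and finite")
  }
  weight <- pool_cycle_weights(weight, cycle_count)
  stratum <- as.character(stratum)
  psu_nested <- paste(stratum, as.character(psu), sep = "\r")
  structure(
    list(
      stratum = stratum,
      psu = psu_nested,
      weight = weight,
      n = n,
      n_strata = length(unique(stratum)),
      n_psu = length(unique(psu_nested)),
      df = length(unique(psu_nested)) - length(unique(stratum))
    ),
    class = "survey_design_spec"
  )
}

#' @export
print.survey_design_spec <- function(x, ...) {
  cat("Stratified survey design:", x$n, "subjects,", x$n_strata, "strata,",
      x$n_psu, "PSUs (design df =", x$df, ")\n")
  invisible(x)
}

#' Divide pooled multi-cycle sampling weights
#'
#' When several survey cycles are pooled into one analytic dataset, each
#' subject's cycle-specific weight is divided by the number of cycles so the
#' pooled weights still sum to one population. Ratio estimates (means,
#' proportions, regression coefficients) are invariant to this rescaling; only
#' estimated population totals change.
#'
#' @param weights Positive sampling weights.
#' @param cycle_count Integer `>= 1`.
#' @return Rescaled weights.
#' @export
pool_cycle_weights <- function(weights, cycle_count = 1L) {
  if (length(cycle_count) != 1L || !is.finite(cycle_count) || cycle_count < 1) {
    stop("cycle_count must be a single number >= 1")
  }
  weights / cycle_count
}

# Stratified between-PSU covariance of per-subject linearized contributions
# u (n x k matrix): sum over strata h of n_h/(n_h - 1) * sum_j (z_hj - zbar_h)
# (z_hj - zbar_h)', where z_hj are PSU totals of u. Singleton-PSU strata are a
# hard error unless single_psu = "center", in which case the lone PSU total is
# centered at the grand mean of all PSU totals (contributing with factor 1).
strat_psu_covariance <- function(u, design, single_psu = c("fail", "center")) {
  single_psu <- match.arg(single_psu)
  u <- as.matrix(u)
  k <- ncol(u)
  psu_tot <- rowsum(u, group = design$psu, reorder = FALSE)
  # recover the stratum label of each PSU row
  psu_stratum <- vapply(rownames(psu_tot), function(p) {
    design$stratum[match(p, design$psu)]
  }, character(1))
  V <- matrix(0, k, k)
  grand_mean <- colMeans(psu_tot)
  for (h in unique(psu_stratum)) {
    idx <- which(psu_stratum == h)
    nh <- length(idx)
    if (nh < 2L) {
      if (single_psu == "fail") {
        stop("stratum '", h, "' has a single PSU; variance not estimable ",
             "(use single_psu = \"center\" to center at the grand mean)")
      }
      d <- psu_tot[idx, , drop = FALSE] -
        matrix(grand_mean, 1L, k, byrow = TRUE)
      V <- V + crossprod(d)
    } else {
      zh <- psu_tot[idx, , drop = FALSE]
      d <- sweep(zh, 2L, colMeans(zh))
      V <- V + nh / (nh - 1) * crossprod(d)
    }
  }
  V
}

#' Design-based proportion or mean with linearized standard error
#'
#' Computes the Horvitz-Thompson ratio estimate `sum(w * y) / sum(w)` with a
#' Taylor-linearized standard error from between-PSU variation of the
#' linearized residuals within strata. With a binary `y` this is the
#' design-corrected prevalence.
#'
#' @param y Numeric (or logical) response vector.
#' @param design A [survey_design()] object.
#' @param single_psu Handling of single-PSU strata: `"fail"` (default) or
#'   `"center"` (center the lone PSU total at the grand mean).
#' @return A list with `estimate`, `se`, `df`, and `n`.
#' @export
design_proportion <- function(y, design, single_psu = c("fail", "center")) {
  single_psu <- match.arg(single_psu)
  stopifnot(inherits(design, "survey_design_spec"))
  y <- as.numeric(y)
  if (length(y) != design$n) stop("response length does not match design")
  if (anyNA(y)) stop("design_proportion requires complete responses")
  w <- design$weight
  wsum <- sum(w)
  est <- sum(w * y) / wsum
  u <- w * (y - est) / wsum
  V <- strat_psu_covariance(matrix(u, ncol = 1L), design, single_psu)
  list(estimate = est, se = sqrt(V[1, 1]), df = design$df, n = design$n)
}

#' @rdname design_proportion
#' @export
design_mean <- design_proportion

#' Survey-weighted logistic regression with sandwich variance
#'
#' Fits a logistic regression by pseudo-maximum likelihood: coefficients
#' maximize the sampling-weighted log-likelihood via iteratively reweighted
#' least squares (convergence on maximum absolute coefficient change,
#' tolerance `1e-10`, at most 100 iterations). The covariance is the Taylor-
#' linearized sandwich: `bread %*% meat %*% bread` with bread the inverse
#' weighted information and meat the stratified between-PSU covariance of the
#' weighted score contributions. Confidence intervals and p-values use a t
#' reference distribution with `n_psu - n_strata` degrees of freedom (the
#' Stata `svy` convention), and odds ratios are exponentiated coefficients
#' with CI limits computed on the log-odds scale.
#'
#' @param response Binary (0/1) response vector.
#' @param predictors Numeric matrix or data frame of predictors (no intercept
#'   column; one is added and reported as `(Intercept)`).
#' @param design A [survey_design()] object.
#' @param level Confidence level, default 0.95.
#' @param start Optional starting coefficient vector (intercept first), e.g. a
#'   previous fit's coefficients as a warm start. Results are identical to a
#'   cold start because IRLS is run to the same tolerance.
#' @param tol Convergence tolerance on the coefficient change. Default 1e-10.
#' @param max_iter Maximum IRLS iterations. Default 100.
#' @param single_psu Handling of single-PSU strata (see [design_proportion()]).
#' @return A `logistic_fit` object: `coefficients`, `vcov`, `se`, `or`,
#'   `ci_lower`, `ci_upper`, `statistic` (t), `p_value`, `df`, `iterations`,
#'   `converged`, `n`, `level`.
#' @export
fit_weighted_logistic <- function(response, predictors, design, level = 0.95,
                                  start = NULL, tol = 1e-10, max_iter = 100L,
                                  single_psu = c("fail", "center")) {
  single_psu <- match.arg(single_psu)
  stopifnot(inherits(design, "survey_design_spec"))
  y <- as.numeric(response)
  if (!all(y %in% c(0, 1))) stop("response must be binary 0/1")
  X <- as.matrix(cbind(`(Intercept)` = 1, as.data.frame(predictors)))
  storage.mode(X) <- "double"
  if (nrow(X) != design$n || length(y) != design$n) {
    stop("response/predictor dimensions do not match the design")
  }
  if (anyNA(X)) {
    stop("predictors contain missing values; code missing covariate levels ",
         "upstream (encode_covariates maps missing to 0)")
  }
  w <- design$weight
  k <- ncol(X)
  # non-constant check after weighting
  sds <- apply(X[, -1, drop = FALSE], 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant predictor(s): ",
         paste(colnames(X)[-1][sds == 0], collapse = ", "))
  }

  beta <- if (is.null(start)) rep(0, k) else {
    if (length(start) != k) stop("start has wrong length")
    as.numeric(start)
  }
  pseudo_ll <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(w * (y * log(p) + (1 - y) * log1p(-p)))
  }
  converged <- FALSE
  iter <- 0L
  ll <- pseudo_ll(beta)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    p <- stats::plogis(eta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    wirls <- w * p * (1 - p)
    z <- eta + (y - p) / (p * (1 - p))
    XtW <- t(X * wirls)
    info <- XtW %*% X
    beta_new <- tryCatch(
      drop(solve(info, XtW %*% z)),
      error = function(e) stop("weighted information is singular ",
                               "(collinear predictors?): ", conditionMessage(e))
    )
    # Newton steps can overshoot when the likelihood is nearly separated or
    # the start is far from the optimum; halve the step until the weighted
    # log-likelihood no longer decreases
    ll_new <- pseudo_ll(beta_new)
    halvings <- 0L
    while (!is.finite(ll_new) || ll_new < ll - 1e-12) {
      halvings <- halvings + 1L
      if (halvings > 40L) break
      beta_new <- (beta + beta_new) / 2
      ll_new <- pseudo_ll(beta_new)
    }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    ll <- ll_new
    if (!all(is.finite(beta)) || sqrt(sum(beta^2)) > 1e4) {
      stop("coefficient norm diverged; likely complete separation")
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) stop("IRLS did not converge in ", max_iter, " iterations")

  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  info <- t(X * (w * p * (1 - p))) %*% X
  bread <- solve(info)
  score <- X * (w * (y - p))            # per-subject weighted score
  meat <- strat_psu_covariance(score, design, single_psu)
  vcov <- bread %*% meat %*% bread
  vcov <- (vcov + t(vcov)) / 2
  se <- sqrt(diag(vcov))
  df <- design$df
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df = df)
  tcrit <- stats::qt(1 - (1 - level) / 2, df = df)
  names(beta) <- colnames(X)
  structure(
    list(
      coefficients = beta,
      vcov = vcov,
      se = stats::setNames(se, colnames(X)),
      or = exp(beta),
      ci_lower = exp(beta - tcrit * se),
      ci_upper = exp(beta + tcrit * se),
      statistic = tstat,
      p_value = stats::setNames(pval, colnames(X)),
      df = df,
      iterations = iter,
      converged = converged,
      n = design$n,
      level = level
    ),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, digits = 4, ...) {
  cat("Survey-weighted logistic regression (n =", x$n,
      ", design df =", x$df, ")\n")
  tab <- data.frame(
    coef = x$coefficients,
    se = x$se,
    OR = x$or,
    ci_lower = x$ci_lower,
    ci_upper = x$ci_upper,
    p = x$p_value
  )
  print(round(tab, digits))
  invisible(x)
}

#' Tidy a logistic fit into a one-row-per-term data frame
#'
#' @param fit A `logistic_fit` object.
#' @return A `data.frame` with columns `term`, `coef`, `se`, `or`,
#'   `ci_lower`, `ci_upper`, `p_value`.
#' @export
tidy_logistic_fit <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  data.frame(
    term = names(fit$coefficients),
    coef = unname(fit$coefficients),
    se = unname(fit$se),
    or = unname(fit$or),
    ci_lower = unname(fit$ci_lower),
    ci_upper = unname(fit$ci_upper),
    p_value = unname(fit$p_value),
    row.names = NULL
  )
}
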