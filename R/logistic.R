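#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood logistic fit with Wald inference, written for the
#' mortality risk-factor models: odds ratios with 95% Wald confidence
#' intervals `exp(beta +/- 1.96 * SE)` per term. Convergence requires the
#' deviance change to fall below `tol` (default 1e-8) within `max_iter`
#' iterations. Non-convergence and (quasi-)complete separation are flagged
#' on the result, never silent; separated fits carry no confidence
#' intervals.
#'
#' @param formula model formula; the response must be binary (logical,
#'   0/1, or a two-level factor).
#' @param data data.frame.
#' @param tol deviance-change convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @param conf_level confidence level of the Wald intervals.
#' @return object of class `csaki_logit`: list with `coefficients`
#'   (data.table: term, estimate, se, or, ci_lo, ci_hi, z, p_value), `n`,
#'   `deviance`, `null_deviance`, `iter`, `converged`, `separation`,
#'   `formula`.
#' @export
logistic_fit <- function(formula, data, tol = 1e-8, max_iter = 100L,
                         conf_level = 0.95) {
  mf <- stats::model.frame(formula, data = data, drop.unused.levels = TRUE)
  y <- stats::model.response(mf)
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary", call. = FALSE)
  X <- stats::model.matrix(formula, mf)
  n <- length(y); p <- ncol(X)
  beta <- numeric(p)
  dev_old <- Inf
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(max_iter)) {
    iter <- it
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    fit <- tryCatch(
      solve(crossprod(X, w * X), crossprod(X, w * z)),
      error = function(e) NULL)
    if (is.null(fit)) break
    beta <- drop(fit)
    mu <- plogis(drop(X %*% beta))
    mu_c <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    dev <- -2 * sum(y * log(mu_c) + (1 - y) * log(1 - mu_c))
    if (abs(dev - dev_old) < tol) { converged <- TRUE; dev_old <- dev; break }
    dev_old <- dev
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  ## separation diagnostic: fitted probabilities collapsing to 0/1 at data
  ## points, or runaway coefficients
  separation <- any(y == 1 & mu > 1 - 1e-8) ||
    any(y == 0 & mu < 1e-8) || max(abs(beta)) > 20
  w <- pmax(mu * (1 - mu), 1e-10)
  vcov <- tryCatch(solve(crossprod(X, w * X)), error = function(e) NULL)
  se <- if (is.null(vcov)) rep(NA_real_, p) else sqrt(diag(vcov))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.table(term = colnames(X), estimate = beta, se = se)
  coefs[, `:=`(or = exp(estimate),
               ci_lo = exp(estimate - zq * se),
               ci_hi = exp(estimate + zq * se),
               z = estimate / se)]
  coefs[, p_value := 2 * pnorm(-abs(z))]
  if (separation) coefs[, `:=`(ci_lo = NA_real_, ci_hi = NA_real_)]
  p_bar <- mean(y)
  null_dev <- -2 * sum(y * log(p_bar) + (1 - y) * log(1 - p_bar))
  out <- list(coefficients = coefs, n = n, deviance = dev_old,
              null_deviance = null_dev, iter = iter, converged = converged,
              separation = separation, formula = formula)
  class(out) <- "csaki_logit"
  out
}

#' @export
print.csaki_logit <- function(x, ...) {
  cat("Logistic regression (IRLS), n =", x$n, "\n")
  if (!x$converged) cat("** did not converge **\n")
  if (x$separation) cat("** separation detected: no confidence intervals **\n")
  y <- copy(x$coefficients)
  y[, `:=`(estimate = round(estimate, 4), se = round(se, 4),
           or = round(or, 2), ci_lo = round(ci_lo, 2),
           ci_hi = round(ci_hi, 2), z = round(z, 2),
           p_value = signif(p_value, 3))]
  print(as.data.table(y))
  invisible(x)
}

#' Mortality risk model for first or maximum AKI stage
#'
#' Convenience wrapper that fits the in-hospital-death logistic model with
#' AKI stage entered as three indicator terms against the no-AKI reference,
#' plus any further covariates.
#'
#' @param assessments data.table with `patient_id` and `first_stage` /
#'   `max_stage` (from [assess_cohort()]).
#' @param outcomes data.frame with `patient_id`, `death` (logical) and any
#'   covariates.
#' @param stage_encoding `"max"` or `"first"`.
#' @param covariates character vector of additional covariate columns.
#' @return a [logistic_fit()] result.
#' @export
aki_mortality_model <- function(assessments, outcomes,
                                stage_encoding = c("max", "first"),
                                covariates = character()) {
  stage_encoding <- match.arg(stage_encoding)
  col <- if (stage_encoding == "max") "max_stage" else "first_stage"
  d <- merge(as.data.table(assessments)[, c("patient_id", col), with = FALSE],
             as.data.table(outcomes), by = "patient_id")
  d[, aki_stage := factor(get(col), levels = 0:3,
                          labels = c("none", "stage1", "stage2", "stage3"))]
  ## constant columns (e.g. no AKI at all in a degenerate cohort) carry no
  ## information and would break the factor contrasts
  terms <- Filter(function(v) length(unique(d[[v]])) > 1L,
                  c("aki_stage", covariates))
  rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
  f <- stats::as.formula(paste("death ~", rhs))
  logistic_fit(f, d)
}
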