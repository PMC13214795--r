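#' Simulation-based power for a binary-exposure mortality model
#'
#' Monte-Carlo post hoc power for detecting an exposure odds ratio in a
#' logistic mortality model. The intercept is calibrated so the *marginal*
#' mortality matches `overall_mortality` given the exposure prevalence and
#' odds ratio. Each replicate draws exposure ~ Bernoulli(prevalence) and
#' the outcome from the calibrated model, then performs the two-sided Wald
#' test of the exposure term. For a single binary covariate the logistic
#' Wald statistic has the closed form `log(ad/bc) / sqrt(1/a+1/b+1/c+1/d)`
#' (the model is saturated), which is what is computed; replicates with an
#' empty cell cannot reject.
#'
#' @param n cohort size per replicate.
#' @param exposure_prev exposure prevalence (e.g. AKI incidence).
#' @param overall_mortality target marginal outcome rate.
#' @param or exposure odds ratio under the alternative (1 = null).
#' @param alpha significance level of the Wald test.
#' @param reps Monte-Carlo replicates.
#' @param seed integer seed.
#' @return list of class `power_result`: inputs plus `power` and
#'   `mc_se` (= `sqrt(power * (1 - power) / reps)`).
#' @export
power_simulation <- function(n, exposure_prev, overall_mortality, or,
                             alpha = 0.005, reps = 2000L, seed = 1L) {
  stopifnot(n >= 4, exposure_prev > 0, exposure_prev < 1,
            overall_mortality > 0, overall_mortality < 1, or > 0,
            alpha > 0, alpha < 1, reps >= 1)
  lor <- log(or)
  ## calibrate the unexposed rate p0 so that
  ## prev * plogis(qlogis(p0) + lor) + (1 - prev) * p0 = overall_mortality
  f <- function(l0) {
    exposure_prev * plogis(l0 + lor) + (1 - exposure_prev) * plogis(l0) -
      overall_mortality
  }
  l0 <- uniroot(f, c(-30, 30), tol = 1e-12)$root
  p0 <- plogis(l0)
  p1 <- plogis(l0 + lor)
  res <- with_seed(seed, {
    n1 <- rbinom(reps, n, exposure_prev)
    n0 <- n - n1
    a <- rbinom(reps, n1, p1)          # exposed deaths
    c_ <- rbinom(reps, n0, p0)         # unexposed deaths
    b <- n1 - a
    d <- n0 - c_
    ok <- a > 0 & b > 0 & c_ > 0 & d > 0
    z <- rep(0, reps)
    z[ok] <- (log(a[ok]) - log(b[ok]) - log(c_[ok]) + log(d[ok])) /
      sqrt(1 / a[ok] + 1 / b[ok] + 1 / c_[ok] + 1 / d[ok])
    2 * pnorm(-abs(z)) < alpha
  })
  power <- mean(res)
  out <- list(n = n, exposure_prev = exposure_prev,
              overall_mortality = overall_mortality, or = or, alpha = alpha,
              reps = reps, seed = seed, p_unexposed = p0, p_exposed = p1,
              power = power, mc_se = sqrt(power * (1 - power) / reps))
  class(out) <- "power_result"
  out
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "Simulated power: %.1f%% (MC SE %.2f%%)\n  n = %d, prevalence %.3f, marginal mortality %.3f, OR %.2f, alpha %.3g, %d reps\n",
    100 * x$power, 100 * x$mc_se, x$n, x$exposure_prev, x$overall_mortality,
    x$or, x$alpha, x$reps))
  invisible(x)
}
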