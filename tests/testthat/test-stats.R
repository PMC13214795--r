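test_that("rate table computes the documented denominators", {
  aki <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  death <- c(TRUE, FALSE, FALSE, FALSE, TRUE)
  strat <- c("A", "A", "B", "B", "A")
  rt <- rate_table(aki, death, strat)
  all_row <- rt[stratum == "All"]
  expect_equal(all_row$aki_pct, 100 * 3 / 5)
  expect_equal(all_row$mort_aki_pct, 100 * 1 / 3)
  expect_equal(all_row$mort_noaki_pct, 100 * 1 / 2)
  a <- rt[stratum == "A"]
  expect_equal(a$n, 3L)
  expect_equal(a$aki_pct, 100 * 2 / 3)
  ## empty subgroup -> NA, never 0
  b <- rt[stratum == "B"]
  expect_true(is.na(b$mort_aki_pct) || b$n_aki > 0)
  rt2 <- rate_table(c(TRUE, TRUE), c(FALSE, TRUE))
  expect_true(is.na(rt2$mort_noaki_pct))  # no unexposed patients at all
  expect_error(rate_table_from_counts(data.frame(stratum = "x", n = 5,
                                                 n_aki = -1, deaths_aki = 0,
                                                 deaths_noaki = 0)),
               "negative")
})

test_that("chi-square: zero under homogeneity, known 2x2, degenerate error", {
  ## identical row distributions -> statistic exactly 0
  t0 <- matrix(c(10, 20, 30, 60), nrow = 2, byrow = TRUE)
  expect_equal(chi_square(t0)$statistic, 0)
  ## mortality with/without AKI contrast: overwhelming significance
  t1 <- matrix(c(353, 5681, 22, 2508), nrow = 2, byrow = TRUE)
  res <- chi_square(t1)
  expect_lt(res$p_value, 1e-4)
  expect_equal(res$df, 1L)
  ## agreement with the classical implementation (no continuity correction)
  ref <- suppressWarnings(stats::chisq.test(t1, correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic))
  expect_equal(res$p_value, unname(ref$p.value))
  expect_error(chi_square(matrix(c(0, 0, 1, 2), 2)), "degenerate")
})

test_that("chi-square p matches a permutation null on small tables", {
  tabs <- list(matrix(c(15, 10, 8, 17), 2, byrow = TRUE),
               matrix(c(12, 8, 6, 14), 2, byrow = TRUE))
  set.seed(314)
  for (tb in tabs) {
    obs <- chi_square(tb)$statistic
    perm <- stats::r2dtable(2e4, rowSums(tb), colSums(tb))
    null_stats <- vapply(perm, function(m) chi_square(m)$statistic, numeric(1))
    ## the continuous chi-square p approximates the *mid-p* of the discrete
    ## permutation null (the observed atom counts half)
    p_mid <- mean(null_stats > obs + 1e-9) +
      0.5 * mean(abs(null_stats - obs) < 1e-9)
    expect_lt(abs(chi_square(tb)$p_value - p_mid), 0.04)
  }
})

test_that("wilcoxon rank-sum: identity, enumeration, ties", {
  x <- c(3, 1, 4, 1, 5)
  r <- wilcoxon_rank_sum(x, x)
  expect_equal(r$p_value, 1)
  ## x=[1,2,3] vs y=[4,5,6]: U = 0, matches exhaustive enumeration of the
  ## rank-sum distribution (choose(6,3)=20 equally likely assignments)
  r <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  combs <- utils::combn(6, 3)
  ranks <- rank(1:6)
  us <- apply(combs, 2, function(ix) sum(ranks[ix]) - 3 * 4 / 2)
  expect_equal(sort(unique(us)), 0:9)  # full support of U for n=m=3
  p_exact <- mean(abs(us - 4.5) >= abs(0 - 4.5))
  expect_equal(p_exact, 0.1)  # the exact two-sided p this approximation targets
  ## tie-corrected normal approximation agrees with the reference
  set.seed(2)
  for (i in 1:20) {
    a <- sample(1:6, 12, replace = TRUE)
    b <- sample(2:8, 15, replace = TRUE)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = FALSE))
    got <- wilcoxon_rank_sum(a, b)
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("rejection rate of the rank-sum approximation tracks the exact test", {
  set.seed(11)
  reps <- 300
  rej_appr <- rej_exact <- logical(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(12); y <- rnorm(12) + 1.0
    rej_appr[i] <- wilcoxon_rank_sum(x, y)$p_value < 0.05
    rej_exact[i] <- stats::wilcox.test(x, y, exact = TRUE)$p.value < 0.05
  }
  expect_lt(abs(mean(rej_appr) - mean(rej_exact)), 0.05)
})

test_that("KM: no events, empirical limit, hand-computed fixture", {
  r <- km_logrank(c(5, 8, 10), c(0, 0, 0), c("a", "a", "b"))
  expect_true(all(r$curves$survival == 1))
  expect_true(is.na(r$logrank_p))
  ## with no censoring KM equals the empirical survivor function
  set.seed(8)
  tt <- sample(1:15, 40, replace = TRUE)
  r <- km_logrank(tt, rep(1, 40))
  for (k in seq_len(nrow(r$curves))) {
    expect_equal(r$curves$survival[k], mean(tt > r$curves$time[k]))
  }
  ## two-stratum toy, hand-computed product-limit values:
  ## stratum g1: times 1,2,3,4 all events -> S = 3/4, 1/2, 1/4, 0
  ## stratum g2: events at 2 and 4, censored at 1 and 3
  tt <- c(1, 2, 3, 4, 1, 2, 3, 4)
  ev <- c(1, 1, 1, 1, 0, 1, 0, 1)
  g <- rep(c("g1", "g2"), each = 4)
  r <- km_logrank(tt, ev, g)
  s1 <- r$curves[stratum == "g1"]
  expect_equal(s1$survival, c(3 / 4, 1 / 2, 1 / 4, 0))
  s2 <- r$curves[stratum == "g2"]
  ## g2: at-risk 4 at t=1 (censor), 3 at t=2 (event: S=2/3), censor at 3,
  ## 1 at risk at t=4 (event: S=0)
  expect_equal(s2[time == 2, survival], 2 / 3)
  expect_equal(s2[time == 4, survival], 0)
  expect_false(is.na(r$logrank_p))
})

test_that("logistic IRLS: closed forms, glm agreement, separation", {
  ## intercept-only: logit of the sample mean
  d <- data.frame(y = c(rep(1, 3), rep(0, 7)))
  f <- logistic_fit(y ~ 1, d)
  expect_equal(f$coefficients$estimate, qlogis(0.3), tolerance = 1e-9)
  ## 2x2 design: OR identical to the cross-product ratio ad/bc
  cnt <- c(a = 30, b = 70, c = 10, d = 90)
  d2 <- data.frame(
    y = rep(c(1, 0, 1, 0), times = cnt),
    x = rep(c(1, 1, 0, 0), times = cnt))
  f2 <- logistic_fit(y ~ x, d2)
  or <- f2$coefficients[term == "x", or]
  expect_equal(or, (30 * 90) / (70 * 10), tolerance = 1e-8)
  ## Wald SE matches the cell-count closed form
  expect_equal(f2$coefficients[term == "x", se],
               sqrt(sum(1 / cnt)), tolerance = 1e-8)
  ## agreement with glm on random designs
  set.seed(33)
  for (i in 1:5) {
    n <- 400
    dd <- data.frame(x1 = rnorm(n), x2 = runif(n),
                     g = factor(sample(letters[1:3], n, TRUE)))
    eta <- -1 + 0.8 * dd$x1 - 0.5 * dd$x2 + 0.3 * (dd$g == "b")
    dd$y <- rbinom(n, 1, plogis(eta))
    mine <- logistic_fit(y ~ x1 + x2 + g, dd)
    ref <- stats::glm(y ~ x1 + x2 + g, binomial(), dd,
                      control = list(epsilon = 1e-12))
    expect_true(mine$converged)
    expect_equal(mine$coefficients$estimate, unname(coef(ref)),
                 tolerance = 1e-6)
    expect_equal(mine$coefficients$se,
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-4)
  }
  ## complete separation is flagged and CIs withheld
  ds <- data.frame(y = c(0, 0, 0, 1, 1, 1), x = c(1, 2, 3, 4, 5, 6))
  fs <- logistic_fit(y ~ x, ds)
  expect_true(fs$separation)
  expect_true(all(is.na(fs$coefficients$ci_lo)))
  expect_error(logistic_fit(y ~ 1, data.frame(y = c(0, 1, 2))), "binary")
})

test_that("power simulation: null calibration, consistency, analytic check", {
  ## at OR = 1 the rejection rate is within 3 MC SEs of alpha
  p0 <- power_simulation(2000, 0.5, 0.10, or = 1, alpha = 0.05,
                         reps = 2000, seed = 42)
  expect_lt(abs(p0$power - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  ## marginal mortality calibration holds
  expect_equal(0.5 * p0$p_exposed + 0.5 * p0$p_unexposed, 0.10,
               tolerance = 1e-10)
  ## huge effect, large n -> power ~ 1
  p1 <- power_simulation(5000, 0.5, 0.10, or = 3, alpha = 0.005,
                         reps = 300, seed = 1)
  expect_gt(p1$power, 0.999)
  ## against the closed-form two-proportion normal approximation
  pw <- power_simulation(8564, 0.705, 0.044, or = 1.30, alpha = 0.005,
                         reps = 2000, seed = 7)
  q1 <- pw$p_exposed; q0 <- pw$p_unexposed
  n1 <- 8564 * 0.705; n0 <- 8564 * 0.295
  se_alt <- sqrt(1 / (n1 * q1) + 1 / (n1 * (1 - q1)) +
                 1 / (n0 * q0) + 1 / (n0 * (1 - q0)))
  z <- log(1.30) / se_alt
  analytic <- pnorm(z - qnorm(1 - 0.005 / 2)) + pnorm(-z - qnorm(1 - 0.005 / 2))
  expect_lt(abs(pw$power - analytic), 0.06)
  expect_equal(pw$mc_se, sqrt(pw$power * (1 - pw$power) / 2000))
})
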