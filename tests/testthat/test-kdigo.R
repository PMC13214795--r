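test_that("urine rates: binning, arithmetic, gaps, weight rule", {
  ## 40 mL at hours 1 and 2 on 80 kg -> 0.5 mL/kg/h in both bins
  r <- compute_urine_rates(data.table(time_h = c(1, 2), volume_ml = c(40, 40)),
                           data.table(time_h = 0.5, weight_kg = 80))
  expect_equal(r$hour, c(1L, 2L))
  expect_equal(r$rate, c(0.5, 0.5))

  ## two volumes in one bin are summed; unobserved bins are absent (gaps)
  r <- compute_urine_rates(
    data.table(time_h = c(0.2, 0.9, 2, 4), volume_ml = c(10, 20, 40, 8)),
    data.table(time_h = 0, weight_kg = 80))
  expect_equal(r$hour, c(1L, 2L, 4L))
  expect_equal(r$volume_ml, c(30, 40, 8))
  expect_false(3L %in% r$hour)  # missing bin is a gap, not zero

  ## latest-weight-at-or-before rule with back-fill, vs brute force
  vols <- data.table(time_h = 1:6, volume_ml = c(50, 50, 50, 50, 50, 50))
  wts <- data.table(time_h = c(2, 4.5), weight_kg = c(100, 50))
  r <- compute_urine_rates(vols, wts)
  brute <- vapply(1:6, function(h) {
    w <- wts[wts$time_h <= h, ]
    wk <- if (nrow(w)) w$weight_kg[which.max(w$time_h)] else wts$weight_kg[1]
    50 / wk
  }, numeric(1))
  expect_equal(r$rate, brute)

  expect_error(compute_urine_rates(vols, data.table(time_h = 0, weight_kg = 0)),
               "weight")
  expect_error(compute_urine_rates(vols, data.table(time_h = numeric(),
                                                    weight_kg = numeric())),
               "weight")
})

test_that("urine staging: trivial and boundary cases", {
  mk <- function(rate, n = length(rate)) data.table(hour = seq_len(n), rate = rate)
  ## normal diuresis never stages
  expect_equal(nrow(stage_urine(mk(rep(1.0, 48)))), 0L)
  ## sustained anuria: stage 1 at 6 h, stage 2 and 3 (anuria >= 12 h) at 12 h
  ev <- stage_urine(mk(rep(0, 12)))
  expect_equal(events_to_first3(ev), c(6, 12, 12))
  ## exactly 0.5 mL/kg/h is NOT oliguria (strict <)
  expect_equal(nrow(stage_urine(mk(rep(0.5, 36)))), 0L)
  ## just below threshold stages; 0.3 exactly does not reach stage 3
  ev <- stage_urine(mk(rep(0.3, 36)))
  expect_equal(events_to_first3(ev), c(6, 12, NA))
  ev <- stage_urine(mk(rep(0.29, 36)))
  expect_equal(events_to_first3(ev), c(6, 12, 24))
  ## a gap breaks the window: 6 low hours split 3+3 never stage
  s <- data.table(hour = c(1:3, 5:7), rate = rep(0.2, 6))
  expect_equal(nrow(stage_urine(s)), 0L)
})

test_that("urine staging equals the exhaustive all-window oracle", {
  set.seed(421)
  for (i in 1:200) {
    s <- random_urine_series(120)
    got <- events_to_first3(stage_urine(s))
    expect_equal(got, oracle_stage_urine(s$hour, s$rate), info = paste("series", i))
  }
  ## the sawtooth from the windowed-mean edge case family
  s <- data.table(hour = 1:26, rate = c(rep(0.4, 6), rep(0.9, 2), rep(0.25, 18)))
  expect_equal(events_to_first3(stage_urine(s)),
               oracle_stage_urine(s$hour, s$rate))
})

test_that("all-hours window mode is stricter than mean mode", {
  ## mean over 6 h is < 0.5 but hour 3 itself is not: only mean mode fires
  s <- data.table(hour = 1:6, rate = c(0.2, 0.2, 0.9, 0.2, 0.2, 0.2))
  expect_equal(events_to_first3(stage_urine(s, mode = "mean"))[1], 6)
  expect_equal(nrow(stage_urine(s, mode = "all")), 0L)
  ## with uniformly low hours the two modes agree
  s2 <- data.table(hour = 1:12, rate = rep(0.4, 12))
  expect_equal(events_to_first3(stage_urine(s2, mode = "all")),
               events_to_first3(stage_urine(s2, mode = "mean")))
})

test_that("creatinine staging: bands, delta rule, lookback", {
  b <- list(value = 1.0, provenance = "preoperative")
  ## flat series never stages
  ev <- stage_creatinine(data.table(time_h = c(6, 24, 48), value = rep(1, 3)), b)
  expect_equal(nrow(ev), 0L)
  ## 4.0 mg/dL at 24 h on baseline 1.0: stage 3 (>= 3x and >= 4.0)
  ev <- stage_creatinine(data.table(time_h = 24, value = 4.0), b)
  expect_equal(events_to_first3(ev), c(24, 24, 24))
  ## rise of exactly 0.3 within 48 h DOES qualify (inclusive threshold)
  ev <- stage_creatinine(data.table(time_h = c(6, 30), value = c(1.0, 1.3)), b)
  expect_equal(events_to_first3(ev), c(30, NA, NA))
  ## the 48-h lookback is genuinely rolling: 1.45 at 49 h cannot see 1.0 at 0 h
  ev <- stage_creatinine(
    data.table(time_h = c(0, 24, 49), value = c(1.0, 1.25, 1.45)), b)
  expect_equal(nrow(ev), 0L)
  ## ratio bands within 7 days
  ev <- stage_creatinine(data.table(time_h = 72, value = 2.1), b)
  expect_equal(events_to_first3(ev), c(72, 72, NA))
  ## beyond 7 days the ratio rule is off (and the delta pool has no baseline)
  ev <- stage_creatinine(data.table(time_h = 200, value = 2.1), b)
  expect_equal(nrow(ev), 0L)
  ## no baseline anywhere: criterion skipped, not an error
  expect_equal(nrow(stage_creatinine(data.table(time_h = 1, value = 9), NULL)), 0L)
})

test_that("creatinine staging equals the all-pairs oracle", {
  set.seed(77)
  for (i in 1:200) {
    n <- sample(1:12, 1)
    tv <- sort(runif(n, 0, 220))
    vv <- round(runif(n, 0.4, 4.5), 2)
    b <- round(runif(1, 0.5, 1.8), 2)
    got <- events_to_first3(
      stage_creatinine(data.table(time_h = tv, value = vv),
                       list(value = b, provenance = "preoperative")))
    expect_equal(got, oracle_stage_creatinine(tv, vv, b), info = paste("case", i))
  }
})

test_that("dialysis staging: first session only, stage 3", {
  expect_equal(nrow(stage_dialysis(data.table(time_h = numeric()))), 0L)
  ev <- stage_dialysis(data.table(time_h = 40))
  expect_equal(ev$stage, 3L)
  expect_equal(ev$time_h, 40)
  ev <- stage_dialysis(data.table(time_h = c(52, 40)))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$time_h, 40)
})

test_that("combined assessment: ordering, tie-breaks, no-AKI case", {
  ue <- data.table(criterion = "urine", stage = 1L, time_h = 18)
  a <- combine_assessment(urine = ue)
  expect_true(a$aki)
  expect_equal(c(a$first_stage, a$max_stage), c(1L, 1L))
  expect_equal(a$trigger_criterion, "urine")

  ce <- data.table(criterion = "creatinine", stage = 2L, time_h = 30)
  a <- combine_assessment(urine = data.table(criterion = "urine", stage = 1L,
                                             time_h = 10), creatinine = ce)
  expect_equal(a$first_stage, 1L); expect_equal(a$first_time_h, 10)
  expect_equal(a$max_stage, 2L); expect_equal(a$max_time_h, 30)

  ## identical timestamps: default priority creatinine > urine > dialysis
  a <- combine_assessment(
    urine = data.table(criterion = "urine", stage = 1L, time_h = 12),
    creatinine = data.table(criterion = "creatinine", stage = 1L, time_h = 12))
  expect_equal(a$trigger_criterion, "creatinine")
  a <- combine_assessment(
    urine = data.table(criterion = "urine", stage = 1L, time_h = 12),
    creatinine = data.table(criterion = "creatinine", stage = 1L, time_h = 12),
    tie_priority = c("urine", "creatinine", "dialysis"))
  expect_equal(a$trigger_criterion, "urine")

  a <- combine_assessment()
  expect_false(a$aki)
  expect_equal(a$max_stage, 0L)
  expect_true(is.na(a$trigger_criterion))
})

test_that("combined assessment equals a merged-stream scan on random events", {
  set.seed(99)
  for (i in 1:300) {
    ev <- data.table(
      criterion = sample(c("urine", "creatinine", "dialysis"),
                         sample(0:6, 1), replace = TRUE))
    ev[, stage := sample(1:3, .N, replace = TRUE)]
    ev[, time_h := sample(1:48, .N, replace = TRUE)]
    ev[criterion == "dialysis", stage := 3L]
    a <- combine_assessment(ev[criterion == "urine"],
                            ev[criterion == "creatinine"],
                            ev[criterion == "dialysis"])
    o <- oracle_combine(ev)
    expect_equal(a$max_stage, o$max_stage)
    expect_equal(a$first_stage, o$first_stage)
    expect_equal(a$first_time_h %||% NA_real_, o$first_time,
                 ignore_attr = TRUE)
    if (a$aki) {
      expect_equal(a$max_time_h, o$max_time)
      expect_equal(a$trigger_criterion, o$trigger)
      expect_gte(a$max_stage, a$first_stage)
      expect_gte(a$max_time_h, a$first_time_h)
    }
  }
})

test_that("staging is monotone in the inputs", {
  set.seed(5)
  for (i in 1:40) {
    s <- random_urine_series(60)
    base <- events_to_first3(stage_urine(s))
    worse <- copy(s)
    k <- sample(nrow(s), max(1, nrow(s) %/% 4))
    worse$rate[k] <- worse$rate[k] * runif(length(k), 0, 0.9)
    after <- events_to_first3(stage_urine(worse))
    ## decreasing rates can only add stages or move them earlier
    for (st in 1:3) {
      if (!is.na(base[st])) {
        expect_false(is.na(after[st]))
        expect_lte(after[st], base[st])
      }
    }
  }
  set.seed(6)
  b <- list(value = 1.0, provenance = "preoperative")
  for (i in 1:40) {
    tv <- sort(runif(6, 0, 160)); vv <- runif(6, 0.6, 3.8)
    base <- events_to_first3(stage_creatinine(data.table(time_h = tv, value = vv), b))
    vv2 <- vv + runif(6, 0, 0.8)
    after <- events_to_first3(stage_creatinine(data.table(time_h = tv, value = vv2), b))
    for (st in 1:3) {
      if (!is.na(base[st])) expect_false(is.na(after[st]))
    }
  }
})

test_that("baseline resolution follows policy and records provenance", {
  ser <- data.table(time_h = c(12, 6), value = c(1.4, 1.2))
  b <- baseline_creatinine(0.9, ser)
  expect_equal(b$value, 0.9)
  expect_equal(b$provenance, "preoperative")
  b <- baseline_creatinine(NA, ser)
  expect_equal(b$value, 1.2)  # earliest post-operative value
  expect_equal(b$provenance, "first-postoperative")
  b <- baseline_creatinine(0.9, ser, policy = "first_postoperative")
  expect_equal(b$provenance, "first-postoperative")
  expect_null(baseline_creatinine(NA, data.table(time_h = numeric(),
                                                 value = numeric())))
})
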