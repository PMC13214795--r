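library(data.table)

`%||%` <- function(x, y) if (is.null(x)) y else x

## Independent brute-force oracles used to validate the detection engine.
## They re-derive every quantity from the KDIGO definitions directly,
## without sharing code paths with the package internals.

## exhaustive all-window urine staging: for every end bin, enumerate every
## contiguous gap-free window ending there and classify it. Anuria is
## "mean exactly zero over >= anuria_h" (rates are non-negative).
oracle_stage_urine <- function(hour, rate, anuria_h = 12) {
  stopifnot(length(hour) == length(rate))
  o <- order(hour)
  hour <- hour[o]; rate <- rate[o]
  first <- c(NA_real_, NA_real_, NA_real_)
  n <- length(hour)
  S <- c(0, cumsum(rate))
  for (ti in seq_len(n)) {
    ## longest gap-free window ending at ti
    ji <- ti
    while (ji > 1L && hour[ji] - hour[ji - 1L] == 1L) ji <- ji - 1L
    starts <- ji:ti
    len <- ti - starts + 1L
    mn <- (S[ti + 1L] - S[starts]) / len
    ## strict thresholds, guarded against prefix-sum accumulation error
    st <- 0L
    if (any(len >= 6L & mn < 0.5 - 1e-9)) st <- 1L
    if (any(len >= 12L & mn < 0.5 - 1e-9)) st <- 2L
    if (any((len >= 24L & mn < 0.3 - 1e-9) | (len >= anuria_h & mn == 0))) st <- 3L
    if (st > 0L) {
      for (k in seq_len(st)) if (is.na(first[k])) first[k] <- hour[ti]
    }
  }
  first
}

events_to_first3 <- function(ev) {
  out <- c(NA_real_, NA_real_, NA_real_)
  if (nrow(ev)) out[ev$stage] <- ev$time_h
  out
}

## all-pairs creatinine oracle: explicit loops, no window bookkeeping
oracle_stage_creatinine <- function(time_h, value, baseline,
                                    delta_window_h = 48,
                                    ratio_window_h = 168) {
  o <- order(time_h)
  time_h <- time_h[o]; value <- value[o]
  first <- c(NA_real_, NA_real_, NA_real_)
  for (i in seq_along(time_h)) {
    s <- 0L
    ## absolute-rise rule against every earlier measurement in the lookback
    cand <- value[i]
    for (j in seq_len(i)) {
      if (time_h[i] - time_h[j] <= delta_window_h) cand <- min(cand, value[j])
    }
    if (time_h[i] <= delta_window_h) cand <- min(cand, baseline)
    if (value[i] - cand >= 0.3 - 1e-9) s <- 1L
    if (time_h[i] <= ratio_window_h) {
      rat <- value[i] / baseline
      if (rat >= 3.0 || value[i] >= 4.0) s <- 3L
      else if (rat >= 2.0) s <- max(s, 2L)
      else if (rat >= 1.5) s <- max(s, 1L)
    }
    if (s > 0L) for (k in seq_len(s)) if (is.na(first[k])) first[k] <- time_h[i]
  }
  first
}

## merged time-sorted scan over an arbitrary event stream
oracle_combine <- function(events, priority = c("creatinine", "urine",
                                                "dialysis")) {
  if (nrow(events) == 0L) {
    return(list(first_stage = 0L, first_time = NA_real_, max_stage = 0L,
                max_time = NA_real_, trigger = NA_character_))
  }
  ft <- min(events$time_h)
  at_ft <- events[events$time_h == ft, ]
  ms <- max(events$stage)
  list(first_stage = max(at_ft$stage), first_time = ft, max_stage = ms,
       max_time = min(events$time_h[events$stage == ms]),
       trigger = priority[min(match(at_ft$criterion, priority))])
}

## random urine series generator probing gaps and threshold boundaries
random_urine_series <- function(len_max = 200) {
  n <- sample(5:len_max, 1L)
  hour <- sort(sample(seq_len(round(n * 1.3)), n))
  rate <- runif(n, 0, 1.2)
  ## sprinkle exact zeros and exact threshold values
  k <- sample(0:n, 1L)
  if (k > 0) rate[sample(n, k)] <- sample(c(0, 0.3, 0.5, 0.25, 0.45),
                                          k, replace = TRUE)
  data.table::data.table(hour = hour, rate = rate)
}

hours_between_test <- function(from, to) {
  as.numeric(difftime(to, from, units = "hours"))
}

## small fused-episode constructor for detector tests
make_episode <- function(urine_hours = numeric(), urine_vol = numeric(),
                         weight = 80, creat_t = numeric(),
                         creat_v = numeric(), dialysis_t = numeric(),
                         preop_creat = NA_real_) {
  list(urine = data.table::data.table(time_h = urine_hours,
                                      volume_ml = urine_vol),
       weights = data.table::data.table(time_h = 0.5, weight_kg = weight),
       creatinine = data.table::data.table(time_h = creat_t, value = creat_v),
       dialysis = data.table::data.table(time_h = dialysis_t),
       preop_creatinine = preop_creat)
}
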