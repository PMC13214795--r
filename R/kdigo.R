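## Full-KDIGO AKI detection on harmonized post-operative series.
##
## Staging thresholds (adult KDIGO):
##   urine output  : stage 1  mean < 0.5 mL/kg/h sustained >= 6 h
##                   stage 2  mean < 0.5 mL/kg/h sustained >= 12 h
##                   stage 3  mean < 0.3 mL/kg/h sustained >= 24 h, or
##                            anuria (0 mL/kg/h) >= 12 h
##   creatinine    : stage 1  rise >= 0.3 mg/dL within 48 h, or
##                            1.5-1.9 x baseline within 7 d
##                   stage 2  2.0-2.9 x baseline
##                   stage 3  >= 3.0 x baseline, or value >= 4.0 mg/dL
##   dialysis      : any renal replacement therapy session -> stage 3
##
## Rate comparisons are strict ("< 0.5": exactly 0.5 does not qualify);
## the creatinine delta is inclusive (">= 0.3": exactly 0.3 qualifies).

## tolerance guarding the inclusive creatinine delta against floating-point
## representation of values like 1.55 - 1.25
.CR_DELTA_TOL <- 1e-9
## tolerance keeping the *strict* urine thresholds strict under prefix-sum
## accumulation error (24 bins of exactly 0.3 must not stage)
.UO_RATE_TOL <- 1e-9

#' KDIGO detection options
#'
#' Bundles the tunable choices of the detection engine. Defaults follow the
#' package's documented reading of the KDIGO criteria; see the methods
#' vignette for rationale.
#'
#' @param uo_window_mode `"mean"` (default) stages urine output on the mean
#'   rate of every contiguous gap-free window; `"all"` requires every hourly
#'   rate in the window to be below threshold.
#' @param tie_priority order used to attribute the triggering criterion when
#'   several criteria fire at the identical timestamp.
#' @param baseline_policy `"preoperative_first"` (default): use the
#'   preoperative creatinine when available, otherwise fall back to the first
#'   post-operative measurement; `"first_postoperative"` always uses the
#'   latter.
#' @param icu_window_h surgery-to-ICU mapping window in hours (used by the
#'   fusion step).
#' @param stay_gap_h gap (hours) between consecutive PDMS observations that
#'   splits a patient's documentation into separate ICU stays.
#' @param anuria_h hours of sustained anuria that qualify as stage 3.
#' @param ratio_window_h window (hours after surgery end) within which the
#'   creatinine ratio-to-baseline bands are evaluated (7 days).
#' @param delta_window_h rolling lookback (hours) for the absolute 0.3 mg/dL
#'   creatinine rise.
#' @return a list of class `kdigo_options`.
#' @export
kdigo_options <- function(uo_window_mode = c("mean", "all"),
                          tie_priority = c("creatinine", "urine", "dialysis"),
                          baseline_policy = c("preoperative_first",
                                              "first_postoperative"),
                          icu_window_h = 48,
                          stay_gap_h = 24,
                          anuria_h = 12,
                          ratio_window_h = 168,
                          delta_window_h = 48) {
  uo_window_mode <- match.arg(uo_window_mode)
  baseline_policy <- match.arg(baseline_policy)
  stopifnot(setequal(tie_priority, c("creatinine", "urine", "dialysis")),
            icu_window_h > 0, anuria_h > 0, ratio_window_h > 0,
            delta_window_h > 0)
  structure(list(uo_window_mode = uo_window_mode,
                 tie_priority = tie_priority,
                 baseline_policy = baseline_policy,
                 icu_window_h = icu_window_h,
                 stay_gap_h = stay_gap_h,
                 anuria_h = anuria_h,
                 ratio_window_h = ratio_window_h,
                 delta_window_h = delta_window_h),
            class = "kdigo_options")
}

#' Weight-normalized hourly urine output rates
#'
#' Bins urine collection volumes onto an hourly grid (hours since surgery
#' end; bin `t` covers `(t-1, t]`, right-closed) and divides by the patient's
#' body weight. Multiple volumes falling into one bin are summed. Bins
#' without any observation are *gaps*, not zeros: a missing collection is
#' never interpreted as anuria. The weight used for a bin is the latest
#' weight measured at or before the bin end; bins before the first weight
#' measurement use the first available weight (back-fill).
#'
#' @param volumes data.frame with columns `time_h` (hours since surgery end)
#'   and `volume_ml`.
#' @param weights data.frame with columns `time_h` and `weight_kg`; at least
#'   one row, all weights positive.
#' @return a `data.table` of class `urine_rate_series` with columns `hour`
#'   (integer bin label = bin end), `volume_ml`, `weight_kg`, `rate`
#'   (mL/kg/h). Only observed bins are present.
#' @export
compute_urine_rates <- function(volumes, weights) {
  wt <- weights$time_h
  wk <- weights$weight_kg
  if (length(wk) == 0L) stop("no body weight available", call. = FALSE)
  if (any(!is.finite(wk)) || any(wk <= 0)) {
    stop("non-positive body weight", call. = FALSE)
  }
  if (nrow(volumes) == 0L) {
    out <- data.table(hour = integer(), volume_ml = numeric(),
                      weight_kg = numeric(), rate = numeric())
    setattr(out, "class", c("urine_rate_series", class(out)))
    return(out)
  }
  if (any(volumes$volume_ml < 0)) stop("negative urine volume", call. = FALSE)
  bin <- as.integer(ceiling(volumes$time_h))
  vol <- rowsum(volumes$volume_ml, bin)
  hour <- as.integer(rownames(vol))
  o <- order(hour)
  hour <- hour[o]; vol <- as.numeric(vol)[o]
  ow <- order(wt)
  wt <- wt[ow]; wk <- wk[ow]
  ## latest weight at or before bin end, back-filled before the first weight
  idx <- findInterval(hour, wt)
  idx[idx == 0L] <- 1L
  out <- data.table(hour = hour, volume_ml = vol, weight_kg = wk[idx],
                    rate = vol / wk[idx])
  setattr(out, "class", c("urine_rate_series", class(out)))
  out
}

## split an hourly series into runs of consecutive observed bins
.hour_runs <- function(hours) {
  if (length(hours) == 0L) return(list())
  brk <- c(0L, which(diff(hours) != 1L), length(hours))
  lapply(seq_len(length(brk) - 1L),
         function(i) (brk[i] + 1L):brk[i + 1L])
}

#' Stage AKI from an hourly urine-rate series
#'
#' Evaluates the KDIGO urine-output criteria over all contiguous gap-free
#' windows ending at each bin. A gap (unobserved bin) breaks every window:
#' no interpolation is performed. For each stage an event is emitted at the
#' first bin where its condition first holds; the event time is the end of
#' the qualifying window.
#'
#' @param series a [compute_urine_rates()] result (columns `hour`, `rate`).
#' @param mode `"mean"`: a window qualifies when its mean rate is below
#'   threshold; `"all"`: when every hourly rate in it is.
#' @param anuria_h hours of sustained zero output qualifying as stage 3.
#' @return data.table with columns `criterion` ("urine"), `stage`, `time_h`;
#'   zero rows when no condition is ever met.
#' @export
stage_urine <- function(series, mode = c("mean", "all"), anuria_h = 12) {
  mode <- match.arg(mode)
  hours <- as.integer(series$hour)
  rate <- as.numeric(series$rate)
  if (length(hours) > 1L && any(diff(hours) <= 0L)) {
    o <- order(hours); hours <- hours[o]; rate <- rate[o]
  }
  first_t <- c(`1` = NA_integer_, `2` = NA_integer_, `3` = NA_integer_)
  note <- function(s, t) {
    key <- as.character(s)
    if (is.na(first_t[[key]]) || t < first_t[[key]]) first_t[[key]] <<- t
  }
  for (run in .hour_runs(hours)) {
    if (!anyNA(first_t)) break
    h <- hours[run]; r <- rate[run]; m <- length(run)
    if (mode == "mean") {
      S <- c(0, cumsum(r))
      zrun <- 0L
      for (t in seq_len(m)) {
        lens <- seq_len(t)
        means <- (S[t + 1L] - S[t + 1L - lens]) / lens
        if (is.na(first_t[["1"]]) && t >= 6L &&
            any(means[lens >= 6L] < 0.5 - .UO_RATE_TOL)) note(1L, h[t])
        if (is.na(first_t[["2"]]) && t >= 12L &&
            any(means[lens >= 12L] < 0.5 - .UO_RATE_TOL)) note(2L, h[t])
        zrun <- if (r[t] == 0) zrun + 1L else 0L
        hit3 <- (t >= 24L && any(means[lens >= 24L] < 0.3 - .UO_RATE_TOL)) ||
          zrun >= anuria_h
        if (is.na(first_t[["3"]]) && hit3) note(3L, h[t])
        if (!anyNA(first_t)) break
      }
    } else {
      b5 <- cumsum_run(r < 0.5)
      b3 <- cumsum_run(r < 0.3)
      bz <- cumsum_run(r == 0)
      i1 <- which(b5 >= 6L);  if (length(i1)) note(1L, h[i1[1L]])
      i2 <- which(b5 >= 12L); if (length(i2)) note(2L, h[i2[1L]])
      i3 <- which(b3 >= 24L | bz >= anuria_h); if (length(i3)) note(3L, h[i3[1L]])
    }
  }
  ev <- data.table(criterion = "urine",
                   stage = c(1L, 2L, 3L),
                   time_h = as.numeric(first_t))
  ev[!is.na(time_h)]
}

## length of the run of TRUEs ending at each position
cumsum_run <- function(flag) {
  out <- integer(length(flag))
  acc <- 0L
  for (i in seq_along(flag)) {
    acc <- if (flag[i]) acc + 1L else 0L
    out[i] <- acc
  }
  out
}

#' Resolve the baseline creatinine for an episode
#'
#' @param preop_creatinine preoperative serum creatinine (mg/dL) or `NA`;
#'   only values measured within 30 days before surgery should be supplied.
#' @param series post-operative creatinine measurements (columns `time_h`,
#'   `value`).
#' @param policy see [kdigo_options()].
#' @return list with `value` and `provenance`
#'   (`"preoperative"`/`"first-postoperative"`), or `NULL` when no
#'   creatinine information exists anywhere.
#' @export
baseline_creatinine <- function(preop_creatinine, series,
                                policy = c("preoperative_first",
                                           "first_postoperative")) {
  policy <- match.arg(policy)
  has_preop <- length(preop_creatinine) == 1L && is.finite(preop_creatinine) &&
    preop_creatinine > 0
  if (policy == "preoperative_first" && has_preop) {
    return(list(value = as.numeric(preop_creatinine),
                provenance = "preoperative"))
  }
  if (!is.null(series) && nrow(series) > 0L) {
    first <- series[order(time_h)][1L]
    return(list(value = as.numeric(first$value),
                provenance = "first-postoperative"))
  }
  if (has_preop) {
    return(list(value = as.numeric(preop_creatinine),
                provenance = "preoperative"))
  }
  NULL
}

#' Stage AKI from serum creatinine measurements
#'
#' At each measurement time `t` two rules are evaluated: (a) the absolute
#' rise, `value - min(measured values in the rolling 48 h lookback, and the
#' baseline while t is within that lookback of surgery end) >= 0.3 mg/dL`
#' (stage 1); (b) the ratio to baseline within 7 days of surgery end:
#' 1.5-1.9x -> stage 1, 2.0-2.9x -> stage 2, >= 3.0x or an absolute value
#' >= 4.0 mg/dL -> stage 3. The stage at `t` is the highest satisfied band;
#' one event per stage is emitted at the first time that stage is reached.
#'
#' @param series data.frame with `time_h` (hours since surgery end) and
#'   `value` (mg/dL).
#' @param baseline a [baseline_creatinine()] result; `NULL` skips the
#'   criterion (empty event list), it is not an error.
#' @param delta_window_h,ratio_window_h see [kdigo_options()].
#' @return data.table `criterion`/`stage`/`time_h` as in [stage_urine()].
#' @export
stage_creatinine <- function(series, baseline,
                             delta_window_h = 48, ratio_window_h = 168) {
  if (is.null(baseline) || is.null(series) || nrow(series) == 0L) {
    return(data.table(criterion = character(), stage = integer(),
                      time_h = numeric()))
  }
  s <- as.data.table(series)[order(time_h)]
  tv <- s$time_h
  vv <- s$value
  b <- baseline$value
  n <- length(tv)
  stage_at <- integer(n)
  for (i in seq_len(n)) {
    lo <- tv[i] - delta_window_h
    pool <- vv[tv >= lo & tv <= tv[i]]
    ## baseline participates in the delta rule while the lookback still
    ## reaches back to (pre-)surgery
    if (tv[i] <= delta_window_h) pool <- c(pool, b)
    st <- 0L
    if (vv[i] - min(pool) >= 0.3 - .CR_DELTA_TOL) st <- 1L
    if (tv[i] <= ratio_window_h) {
      ratio <- vv[i] / b
      if (ratio >= 3.0 || vv[i] >= 4.0) st <- max(st, 3L)
      else if (ratio >= 2.0) st <- max(st, 2L)
      else if (ratio >= 1.5) st <- max(st, 1L)
    }
    stage_at[i] <- st
  }
  ev <- rbindlist(lapply(1:3, function(s3) {
    hit <- which(stage_at >= s3)
    if (!length(hit)) return(NULL)
    data.table(criterion = "creatinine", stage = s3, time_h = tv[hit[1L]])
  }))
  if (is.null(ev) || nrow(ev) == 0L) {
    return(data.table(criterion = character(), stage = integer(),
                      time_h = numeric()))
  }
  ev
}

#' Stage AKI from dialysis (renal replacement therapy) records
#'
#' Any dialysis session implies KDIGO stage 3; a single event is emitted at
#' the start of the first session.
#'
#' @param events data.frame with a `time_h` column (session start, hours
#'   since surgery end); zero rows allowed.
#' @return data.table `criterion`/`stage`/`time_h`.
#' @export
stage_dialysis <- function(events) {
  if (is.null(events) || nrow(events) == 0L) {
    return(data.table(criterion = character(), stage = integer(),
                      time_h = numeric()))
  }
  data.table(criterion = "dialysis", stage = 3L,
             time_h = min(events$time_h))
}

#' Combine per-criterion events into one episode assessment
#'
#' `first_time` is the earliest event time over all criteria; `first_stage`
#' the highest stage among events at exactly that time; `max_stage` the
#' highest stage overall with `max_time` the earliest time it is reached.
#' The triggering criterion is the criterion of the first event; ties at an
#' identical timestamp are broken by a fixed, configurable priority
#' (default creatinine > urine > dialysis).
#'
#' @param urine,creatinine,dialysis event tables as produced by the
#'   `stage_*` functions (possibly zero rows).
#' @param tie_priority character(3), see [kdigo_options()].
#' @return list of class `aki_assessment` with elements `aki`, `first_stage`,
#'   `first_time_h`, `max_stage`, `max_time_h`, `trigger_criterion`, `events`.
#'   No events at all yields `aki = FALSE` with stage 0 and `NA` times.
#' @export
combine_assessment <- function(urine = NULL, creatinine = NULL,
                               dialysis = NULL,
                               tie_priority = c("creatinine", "urine",
                                                "dialysis")) {
  ev <- rbindlist(list(urine, creatinine, dialysis), use.names = TRUE,
                  fill = TRUE)
  if (is.null(ev) || nrow(ev) == 0L) {
    out <- list(aki = FALSE, first_stage = 0L, first_time_h = NA_real_,
                max_stage = 0L, max_time_h = NA_real_,
                trigger_criterion = NA_character_,
                events = data.table(criterion = character(),
                                    stage = integer(), time_h = numeric()))
    class(out) <- "aki_assessment"
    return(out)
  }
  ev <- ev[order(time_h, -stage)]
  first_time <- ev$time_h[1L]
  at_first <- ev[time_h == first_time]
  first_stage <- max(at_first$stage)
  trig <- tie_priority[min(match(at_first$criterion, tie_priority))]
  max_stage <- max(ev$stage)
  max_time <- min(ev[stage == max_stage, time_h])
  stopifnot(max_stage >= first_stage, max_time >= first_time)
  out <- list(aki = TRUE, first_stage = as.integer(first_stage),
              first_time_h = first_time, max_stage = as.integer(max_stage),
              max_time_h = max_time, trigger_criterion = trig, events = ev)
  class(out) <- "aki_assessment"
  out
}

#' @export
print.aki_assessment <- function(x, ...) {
  if (!x$aki) {
    cat("AKI assessment: no AKI\n")
  } else {
    cat(sprintf(
      "AKI assessment: first stage %d at %.0f h, max stage %d at %.0f h (trigger: %s)\n",
      x$first_stage, x$first_time_h, x$max_stage, x$max_time_h,
      x$trigger_criterion))
  }
  invisible(x)
}

#' Assess a single fused episode
#'
#' Applies all three KDIGO criteria to one episode's harmonized series. The
#' urine criterion requires at least two urine observations and a usable
#' weight; the creatinine criterion requires a resolvable baseline; criteria
#' that cannot be evaluated are skipped, not errors.
#'
#' @param episode a list with elements `urine` (`time_h`, `volume_ml`),
#'   `weights` (`time_h`, `weight_kg`), `creatinine` (`time_h`, `value`),
#'   `dialysis` (`time_h`) and optionally `preop_creatinine`.
#' @param opts a [kdigo_options()] object.
#' @return an `aki_assessment`.
#' @export
assess_episode <- function(episode, opts = kdigo_options()) {
  uo_ev <- NULL
  if (!is.null(episode$urine) && nrow(episode$urine) >= 2L &&
      !is.null(episode$weights) && nrow(episode$weights) >= 1L) {
    rates <- compute_urine_rates(episode$urine, episode$weights)
    uo_ev <- stage_urine(rates, mode = opts$uo_window_mode,
                         anuria_h = opts$anuria_h)
  }
  base <- baseline_creatinine(episode$preop_creatinine %||% NA_real_,
                              episode$creatinine,
                              policy = opts$baseline_policy)
  cr_ev <- stage_creatinine(episode$creatinine, base,
                            delta_window_h = opts$delta_window_h,
                            ratio_window_h = opts$ratio_window_h)
  dx_ev <- stage_dialysis(episode$dialysis)
  combine_assessment(uo_ev, cr_ev, dx_ev, tie_priority = opts$tie_priority)
}

#' Assess a fused cohort and summarize it
#'
#' Runs [assess_episode()] over every episode of a fused cohort and returns
#' per-episode assessments together with the cohort-level summary: AKI
#' incidence, first- and maximum-stage distributions (denominator: AKI
#' episodes), onset medians with IQR, and the attribution of detection to
#' the urine, creatinine and dialysis criteria (denominator: AKI episodes).
#'
#' @param cohort a [fuse_cohort()] result or its `episodes` data.table
#'   (one row per episode, series as list columns).
#' @param opts a [kdigo_options()] object.
#' @return list with `assessments` (data.table) and `summary` (list).
#' @export
assess_cohort <- function(cohort, opts = kdigo_options()) {
  episodes <- if (is.data.frame(cohort)) as.data.table(cohort) else cohort$episodes
  stopifnot(nrow(episodes) >= 1L)
  res <- lapply(seq_len(nrow(episodes)), function(i) {
    ep <- list(urine = episodes$urine[[i]],
               weights = episodes$weights[[i]],
               creatinine = episodes$creatinine[[i]],
               dialysis = episodes$dialysis[[i]],
               preop_creatinine = episodes$preop_creatinine[i])
    assess_episode(ep, opts)
  })
  pick <- function(f, how) vapply(res, `[[`, how, f)
  ass <- data.table(patient_id = episodes$patient_id,
                    aki = pick("aki", logical(1)),
                    first_stage = pick("first_stage", integer(1)),
                    first_time_h = pick("first_time_h", numeric(1)),
                    max_stage = pick("max_stage", integer(1)),
                    max_time_h = pick("max_time_h", numeric(1)),
                    trigger_criterion = pick("trigger_criterion", character(1)))
  stopifnot(all(ass$max_stage >= ass$first_stage))
  aki <- ass[aki == TRUE]
  n_aki <- nrow(aki)
  dist <- function(x) {
    tab <- table(factor(x, levels = 1:3))
    if (n_aki == 0L) return(setNames(rep(NA_real_, 3), paste0("stage", 1:3)))
    setNames(as.numeric(tab) / n_aki, paste0("stage", 1:3))
  }
  med_iqr <- function(x) {
    if (!length(x)) return(c(median = NA_real_, q1 = NA_real_, q3 = NA_real_))
    q <- quantile(x, c(.5, .25, .75), na.rm = TRUE, names = FALSE)
    c(median = q[1], q1 = q[2], q3 = q[3])
  }
  attribution <- if (n_aki) {
    tab <- table(factor(aki$trigger_criterion,
                        levels = c("urine", "creatinine", "dialysis")))
    setNames(as.numeric(tab) / n_aki, names(tab))
  } else {
    setNames(rep(NA_real_, 3), c("urine", "creatinine", "dialysis"))
  }
  summary <- list(
    n = nrow(ass),
    n_aki = n_aki,
    incidence = n_aki / nrow(ass),
    first_stage_distribution = dist(aki$first_stage),
    max_stage_distribution = dist(aki$max_stage),
    first_time_h = med_iqr(aki$first_time_h),
    max_time_h = med_iqr(aki$max_time_h),
    criterion_attribution = attribution
  )
  list(assessments = ass, summary = summary)
}
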