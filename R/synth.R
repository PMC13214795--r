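## Synthetic two-source EHR cohort generator.
##
## The generator emits a hospital-information-system (HIS) extract
## (demographics, comorbidities, surgeries, discharge outcome), a patient
## data management system (PDMS) extract (timestamped ICU observations) and
## a ground-truth ledger. Series are built by *inverting* the KDIGO
## detector: for a target maximum stage s the emitted urine / creatinine /
## dialysis series satisfy the detection condition for exactly stage s, so
## the detector must reproduce the ledger on every computable episode.

.default_procedure_mix <- function() {
  ## procedure counts of a large contemporary cardiac-surgery cohort
  ## (n = 8564); "Other" absorbs the remainder of the published margins
  counts <- c(OPCAB = 3990, `ON-CABG` = 234, `Aortic surgery` = 244,
              `AV-Repair` = 75, `AV-Replacement` = 733, `MV-Repair` = 472,
              `MV-Replacement` = 143, `TV-Surgery` = 39, Combined = 2423,
              Other = 211)
  counts / sum(counts)
}

.default_stage_probs <- function() {
  ## maximum-stage margins of the same cohort: 2530 none, 1695 stage 1,
  ## 3256 stage 2, 1083 stage 3 of 8564
  c(none = 2530, stage1 = 1695, stage2 = 3256, stage3 = 1083) / 8564
}

.default_mortality_logit <- function() {
  ## intercept = log-odds of death without AKI (22/2530); increments give
  ## the published per-max-stage mortality (26/1695, 59/3256, 268/1083)
  p <- c(22 / 2530, 26 / 1695, 59 / 3256, 268 / 1083)
  lo <- qlogis(p)
  c(intercept = lo[1], stage1 = lo[2] - lo[1], stage2 = lo[3] - lo[1],
    stage3 = lo[4] - lo[1])
}

#' Specification of a synthetic cardiac-surgery cohort
#'
#' Collects every knob of the generator with defaults calibrated to the
#' published margins of a large CSA-AKI cohort (overall AKI incidence
#' 70.5%, per-stage mortality, procedure mix) and to the KDIGO thresholds
#' the series must invert. Probability maps are validated to sum to one.
#'
#' @param n_patients number of patients (>= 1).
#' @param procedure_mix named probabilities over procedure labels.
#' @param aki_stage_probs named probabilities of the ground-truth maximum
#'   stage, names `none`, `stage1`, `stage2`, `stage3`.
#' @param mortality_logit numeric: `intercept` (log-odds of in-hospital
#'   death without AKI) and additive increments `stage1`..`stage3`.
#' @param oliguria_params per-stage low-rate band (mL/kg/h) and duration
#'   range (h) of the oliguric block; defaults keep a safety margin to the
#'   neighbouring stage thresholds so the inversion is exact.
#' @param creatinine_params baseline lognormal (median ~0.95 mg/dL, clipped
#'   to `baseline_range`), per-stage rise multipliers, and the amplitude of
#'   benign measurement noise (kept < 0.15 so the 0.3 mg/dL delta rule can
#'   never fire accidentally).
#' @param missingness fraction of patients emitted with insufficient
#'   computable data (at most one urine value, no creatinine, no dialysis),
#'   exercising the exclusion filter.
#' @param redundancy fraction of patients whose body weight is recorded by
#'   both source processes (PDMS scale, quality rank 1, and a lower-quality
#'   HIS admission value, rank 2), exercising source prioritization.
#' @param detection_mix probabilities that an AKI episode is constructed to
#'   be detected by the urine, creatinine or dialysis criterion.
#' @param onset lognormal parameters and clamp range (h post-surgery) of the
#'   derangement onset; the default puts the median first-stage detection
#'   near 18 h post-operatively.
#' @param origin POSIXct origin of the simulated calendar.
#' @param seed integer; a fixed seed makes all outputs byte-identical.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 1000L,
                        procedure_mix = .default_procedure_mix(),
                        aki_stage_probs = .default_stage_probs(),
                        mortality_logit = .default_mortality_logit(),
                        oliguria_params = list(
                          stage1 = list(rate = c(0.35, 0.45), duration = c(6L, 9L)),
                          stage2 = list(rate = c(0.35, 0.45), duration = c(12L, 20L)),
                          stage3 = list(rate = c(0.15, 0.25), duration = c(26L, 32L))),
                        creatinine_params = list(
                          baseline_meanlog = log(0.95), baseline_sdlog = 0.2,
                          baseline_range = c(0.5, 1.9),
                          rise_multiplier = c(stage1 = 1.7, stage2 = 2.4,
                                              stage3 = 3.5),
                          noise = 0.06),
                        missingness = 0.02,
                        redundancy = 0.5,
                        detection_mix = c(urine = 0.868, creatinine = 0.121,
                                          dialysis = 0.011),
                        onset = list(meanlog = log(12), sdlog = 0.45,
                                     range = c(4L, 36L)),
                        origin = as.POSIXct("2021-01-04 08:00:00", tz = "UTC"),
                        seed = 1L) {
  check_probs <- function(p, field) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop(sprintf("invalid probability map in field '%s' (must be >= 0 and sum to 1)",
                   field), call. = FALSE)
    }
  }
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 1) {
    stop("invalid field 'n_patients' (need a positive integer)", call. = FALSE)
  }
  check_probs(procedure_mix, "procedure_mix")
  check_probs(aki_stage_probs, "aki_stage_probs")
  check_probs(detection_mix, "detection_mix")
  stopifnot(setequal(names(aki_stage_probs),
                     c("none", "stage1", "stage2", "stage3")))
  if (missingness < 0 || missingness >= 1) {
    stop("invalid field 'missingness' (need a fraction in [0, 1))", call. = FALSE)
  }
  if (redundancy < 0 || redundancy > 1) {
    stop("invalid field 'redundancy' (need a fraction in [0, 1])", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 procedure_mix = procedure_mix,
                 aki_stage_probs = aki_stage_probs[c("none", "stage1",
                                                     "stage2", "stage3")],
                 mortality_logit = mortality_logit,
                 oliguria_params = oliguria_params,
                 creatinine_params = creatinine_params,
                 missingness = missingness,
                 redundancy = redundancy,
                 detection_mix = detection_mix,
                 onset = onset,
                 origin = origin,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

## patient-level random draws shared by generate_ground_truth() and
## generate_cohort(); assumes the RNG has already been seeded
.draw_ground_truth <- function(spec) {
  n <- spec$n_patients
  stage <- sample(0:3, n, replace = TRUE, prob = spec$aki_stage_probs)
  procedure <- sample(names(spec$procedure_mix), n, replace = TRUE,
                      prob = spec$procedure_mix)
  ## dialysis detection implies stage 3, so the dialysis share of the
  ## detection mix is concentrated on stage-3 patients at a conditional
  ## probability that preserves the overall attribution margins
  aki <- stage > 0L
  trigger <- rep(NA_character_, n)
  mix <- spec$detection_mix
  p3 <- spec$aki_stage_probs[["stage3"]] / sum(spec$aki_stage_probs[-1])
  if (!is.finite(p3) || p3 <= 0) p3 <- 1
  p_dx_s3 <- min(1, mix[["dialysis"]] / p3)
  uc <- mix[c("urine", "creatinine")] / sum(mix[c("urine", "creatinine")])
  lo <- aki & stage < 3L
  trigger[lo] <- sample(c("urine", "creatinine"), sum(lo), replace = TRUE,
                        prob = uc)
  hi <- aki & stage == 3L
  trigger[hi] <- sample(c("urine", "creatinine", "dialysis"), sum(hi),
                        replace = TRUE,
                        prob = c(uc * (1 - p_dx_s3), p_dx_s3))
  eta <- spec$mortality_logit[["intercept"]] +
    c(0, spec$mortality_logit[c("stage1", "stage2", "stage3")])[stage + 1L]
  death <- runif(n) < plogis(eta)
  onset <- pmin(pmax(round(rlnorm(n, spec$onset$meanlog, spec$onset$sdlog)),
                     spec$onset$range[1]), spec$onset$range[2])
  insufficient <- runif(n) < spec$missingness
  dur_range <- t(vapply(spec$oliguria_params, `[[`, numeric(2), "duration"))
  dur <- integer(n)
  dur[aki] <- dur_range[stage[aki], 1] +
    floor(runif(sum(aki)) * (dur_range[stage[aki], 2] - dur_range[stage[aki], 1] + 1))
  first_stage <- integer(n)
  first_time <- rep(NA_real_, n)
  u <- aki & trigger == "urine"
  first_stage[u] <- 1L
  first_time[u] <- onset[u] + 6
  cr <- aki & trigger == "creatinine"
  first_stage[cr] <- stage[cr]
  first_time[cr] <- onset[cr]
  dx <- aki & trigger == "dialysis"
  first_stage[dx] <- 3L
  first_time[dx] <- onset[dx]
  data.table(patient_id = sprintf("P%05d", seq_len(n)),
             procedure = procedure,
             true_max_stage = stage,
             true_first_stage = first_stage,
             true_first_time = first_time,
             death = death,
             trigger_criterion = trigger,
             onset_h = ifelse(aki, onset, NA_real_),
             oliguria_duration_h = ifelse(u, dur, NA_real_),
             insufficient = insufficient)
}

#' Draw only the ground-truth ledger of a synthetic cohort
#'
#' Fast path used for parameter-recovery studies: the patient-level truth
#' (maximum stage, death, procedure, onset) without materializing any time
#' series. [generate_cohort()] draws the identical ledger for the same spec.
#'
#' @param spec a [cohort_spec()].
#' @return data.table, one row per patient.
#' @export
generate_ground_truth <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, .draw_ground_truth(spec))
}

#' Generate a two-source synthetic EHR cohort
#'
#' Emits the HIS extract (patients + surgeries), the PDMS observation
#' extract and the ground-truth ledger. For every computable episode the
#' series are constructed so that the KDIGO detector of [assess_episode()]
#' reports exactly the ledger's `true_max_stage` (construction by
#' inversion). A `missingness` fraction of patients is emitted with
#' insufficient computable data; a `redundancy` fraction carries the body
#' weight in both source processes with differing quality ranks.
#'
#' @param spec a [cohort_spec()].
#' @param dir optional directory; when given, writes `his_patients.csv`,
#'   `his_surgeries.csv`, `pdms_observations.csv` and `ground_truth.csv`
#'   (UTF-8, comma-separated, ISO-8601 timestamps).
#' @return (invisibly when `dir` is given) a list with `his`
#'   (list of `patients`, `surgeries`), `pdms` (observations), and
#'   `ground_truth`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  out <- with_seed(spec$seed, .generate_cohort_impl(spec))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    fwrite(out$his$patients, file.path(dir, "his_patients.csv"))
    fwrite(out$his$surgeries, file.path(dir, "his_surgeries.csv"))
    fwrite(out$pdms, file.path(dir, "pdms_observations.csv"))
    fwrite(out$ground_truth, file.path(dir, "ground_truth.csv"))
    return(invisible(out))
  }
  out
}

.generate_cohort_impl <- function(spec) {
  gt <- .draw_ground_truth(spec)
  n <- spec$n_patients
  stage <- gt$true_max_stage
  aki <- stage > 0L
  trig <- gt$trigger_criterion
  onset <- gt$onset_h
  cp <- spec$creatinine_params

  ## ----- covariates (weakly stage-associated, for realistic tables) -----
  age <- pmin(pmax(round(rnorm(n, 65 + 1.6 * stage, 10)), 30), 92)
  sex <- ifelse(runif(n) < 0.752, "M", "F")
  bmi <- round(rlnorm(n, log(26.5) + 0.012 * stage, 0.12), 1)
  weight <- round(bmi * 1.75^2 + rnorm(n, 0, 3), 1)  # nominal 1.75 m frame
  weight <- pmax(weight, 45)
  comorbidities <- rpois(n, 4 + 0.4 * stage)
  ckd <- runif(n) < (0.05 + 0.04 * (stage == 3L))
  baseline <- pmin(pmax(rlnorm(n, cp$baseline_meanlog, cp$baseline_sdlog),
                        cp$baseline_range[1]), cp$baseline_range[2])
  baseline <- round(baseline, 2)
  euroscore <- round(rlnorm(n, log(1.9 + 0.5 * stage), 0.65), 1)
  urgency <- sample(c("high", "mid", "normal"), n, replace = TRUE,
                    prob = c(0.08, 0.22, 0.70))
  cpb_used <- gt$procedure != "OPCAB"
  op_hours <- round(rlnorm(n, log(3.1 + 0.08 * stage), 0.2), 2)
  cpb_min <- ifelse(cpb_used, round(pmax(rnorm(n, 115 + 4 * stage, 35), 30)), 0)
  xclamp_min <- ifelse(cpb_used, round(pmax(cpb_min * runif(n, 0.55, 0.75), 15)), 0)

  ## ----- calendar: staggered surgeries -----
  surgery_start <- spec$origin + (seq_len(n) - 1L) * 3600 * 7 +
    round(runif(n, 0, 3000))
  surgery_end <- surgery_start + op_hours * 3600

  ## ----- stays and outcome timing -----
  adm_h <- runif(n, 0.5, 3)
  need_h <- rep(0, n)
  u <- which(aki & trig == "urine")
  need_h[u] <- onset[u] + gt$oliguria_duration_h[u] + 6
  cr <- which(aki & trig == "creatinine")
  need_h[cr] <- onset[cr] + 8
  dx <- which(aki & trig == "dialysis")
  need_h[dx] <- onset[dx] + 8
  stay_h <- pmax(rlnorm(n, log(ifelse(aki, 68, 26)), 0.35), need_h + 6)
  stay_h <- pmin(stay_h, 24 * 14)
  icu_adm <- surgery_end + adm_h * 3600
  icu_dis <- surgery_end + stay_h * 3600
  hosp_los <- pmax(round(rlnorm(n, log(6.9 + 0.8 * stage), 0.25), 1),
                   ceiling(stay_h / 24))
  death_day <- rep(NA_real_, n)
  dead <- which(gt$death)
  death_day[dead] <- pmax(pmin(round(rlnorm(length(dead), log(8), 0.5), 1),
                               40), ceiling(stay_h[dead] / 24))
  hosp_los[dead] <- death_day[dead]

  his_patients <- data.table(
    patient_id = gt$patient_id, age = age, sex = sex, bmi = bmi,
    weight_kg = round(weight + rnorm(n, 0, 1.5), 1),  # lower-quality copy
    n_comorbidities = comorbidities, ckd = ckd,
    preop_creatinine = baseline, euroscore2 = euroscore,
    in_hospital_death = gt$death, death_day = death_day,
    hospital_los_days = hosp_los)
  his_surgeries <- data.table(
    patient_id = gt$patient_id, procedure = gt$procedure, urgency = urgency,
    surgery_start = format_timestamp(surgery_start),
    surgery_end = format_timestamp(surgery_end),
    cpb_used = cpb_used, cpb_time_min = cpb_min,
    crossclamp_time_min = xclamp_min, operation_hours = op_hours)

  ## ----- PDMS observations -----
  olig <- spec$oliguria_params
  redundant <- runif(n) < spec$redundancy
  obs <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- gt$patient_id[i]
    se <- surgery_end[i]
    rows <- list()
    ts_h <- function(h) format_timestamp(se + h * 3600)
    ## weight: PDMS scale at admission (rank 1); optional redundant HIS copy
    w_t <- adm_h[i]
    rows$w <- data.table(patient_id = pid, timestamp = ts_h(w_t),
                         parameter = "weight", value = weight[i], unit = "kg",
                         source_process = "pdms_scale", quality_rank = 1L)
    if (redundant[i]) {
      rows$w2 <- data.table(patient_id = pid, timestamp = ts_h(w_t),
                            parameter = "weight",
                            value = his_patients$weight_kg[i], unit = "kg",
                            source_process = "his_admission",
                            quality_rank = 2L)
    }
    if (gt$insufficient[i]) {
      ## insufficient computable data: a single urine value, no creatinine,
      ## no dialysis -> fails the (>=2 urine | >=1 crea | >=1 dialysis) rule
      h1 <- ceiling(adm_h[i]) + 1
      rows$u <- data.table(patient_id = pid, timestamp = ts_h(h1),
                           parameter = "urine_output",
                           value = round(runif(1, 0.8, 1.5) * weight[i], 1),
                           unit = "mL", source_process = "pdms_fluid",
                           quality_rank = 1L)
      obs[[i]] <- rbindlist(rows)
      next
    }
    h0 <- as.integer(ceiling(adm_h[i]))
    H <- as.integer(floor(stay_h[i]))
    hours <- seq.int(h0, H)
    rate <- runif(length(hours), 0.8, 1.5)
    if (aki[i] && trig[i] == "urine") {
      s <- stage[i]
      band <- olig[[s]]$rate
      low <- hours > onset[i] & hours <= onset[i] + gt$oliguria_duration_h[i]
      rate[low] <- runif(sum(low), band[1], band[2])
    }
    vol <- round(rate * weight[i], 1)
    rows$uo <- data.table(patient_id = pid, timestamp = ts_h(hours),
                          parameter = "urine_output", value = vol,
                          unit = "mL", source_process = "pdms_fluid",
                          quality_rank = 1L)
    ## creatinine draws every 12 h plus benign noise
    ct <- seq(6, max(H, 7), by = 12)
    cv <- baseline[i] + runif(length(ct), -cp$noise, cp$noise)
    if (aki[i] && trig[i] == "creatinine") {
      mult <- cp$rise_multiplier[[paste0("stage", stage[i])]]
      peak <- if (stage[i] == 2L) min(mult * baseline[i], 3.9)
              else mult * baseline[i]
      ct <- sort(unique(c(ct, onset[i])))
      cv <- baseline[i] + runif(length(ct), -cp$noise, cp$noise)
      post <- ct >= onset[i]
      cv[post] <- peak + runif(sum(post), -0.02, 0.02)
    }
    rows$cr <- data.table(patient_id = pid, timestamp = ts_h(ct),
                          parameter = "creatinine", value = round(cv, 2),
                          unit = "mg/dL", source_process = "lab_interface",
                          quality_rank = 1L)
    if (aki[i] && trig[i] == "dialysis") {
      rows$dx <- data.table(patient_id = pid, timestamp = ts_h(onset[i]),
                            parameter = "dialysis", value = 1, unit = "session",
                            source_process = "pdms_rrt", quality_rank = 1L)
    }
    obs[[i]] <- rbindlist(rows)
  }
  pdms <- rbindlist(obs)
  setorder(pdms, patient_id, timestamp, parameter, source_process)

  list(his = list(patients = his_patients, surgeries = his_surgeries),
       pdms = pdms, ground_truth = gt)
}
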