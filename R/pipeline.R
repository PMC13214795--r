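#' Pipeline run configuration
#'
#' Collects everything one run needs: either a synthetic [cohort_spec()] or
#' paths to the three extracts, the detection options, the analysis
#' options, and an output directory. All defaults match the package's
#' documented design decisions, and the configuration serializes to JSON
#' losslessly (see the run manifest).
#'
#' @param spec a [cohort_spec()], or `NULL` when extracts are given.
#' @param extracts `NULL`, or a named list with `his_patients`,
#'   `his_surgeries`, `pdms` paths.
#' @param kdigo a [kdigo_options()] object.
#' @param alpha significance level for the descriptive comparisons.
#' @param power_or,power_alpha,power_reps assumptions of the post hoc power
#'   simulation (clinically relevant OR 1.30 at alpha 0.005 by default);
#'   prevalence and marginal mortality are taken from the analyzed cohort.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @param seed integer seed governing every random draw of the run.
#' @return list of class `run_config`.
#' @export
run_config <- function(spec = NULL, extracts = NULL,
                       kdigo = kdigo_options(), alpha = 0.05,
                       power_or = 1.30, power_alpha = 0.005,
                       power_reps = 2000L, out_dir = NULL, seed = 42L) {
  if (is.null(spec) && is.null(extracts)) {
    spec <- cohort_spec(seed = seed)
  }
  if (!is.null(spec)) stopifnot(inherits(spec, "cohort_spec"))
  structure(list(spec = spec, extracts = extracts, kdigo = kdigo,
                 alpha = alpha, power_or = power_or,
                 power_alpha = power_alpha,
                 power_reps = as.integer(power_reps),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

.table1 <- function(episodes, assessments) {
  d <- merge(as.data.table(episodes)[, .(patient_id, age, bmi,
                                         n_comorbidities, euroscore2,
                                         icu_los_days, hospital_los_days,
                                         in_hospital_death)],
             assessments[, .(patient_id, aki)], by = "patient_id")
  cont <- c(age = "Age (years)", bmi = "BMI (kg/m2)",
            n_comorbidities = "Comorbidities (n)",
            euroscore2 = "EuroSCORE II (%)",
            icu_los_days = "ICU stay (days)",
            hospital_los_days = "Hospital stay (days)")
  fmt_or_na <- function(x) if (length(x)) fmt_med_iqr(x) else NA_character_
  rows <- lapply(names(cont), function(v) {
    x <- d[aki == TRUE, get(v)]; y <- d[aki == FALSE, get(v)]
    data.table(variable = cont[[v]],
               total = fmt_or_na(d[[v]]),
               aki = fmt_or_na(x), no_aki = fmt_or_na(y),
               p_value = if (length(x) && length(y))
                 wilcoxon_rank_sum(x, y)$p_value else NA_real_)
  })
  da <- sum(d$aki & d$in_hospital_death); na_ <- sum(d$aki)
  dn <- sum(!d$aki & d$in_hospital_death); nn <- sum(!d$aki)
  tab <- matrix(c(da, na_ - da, dn, nn - dn), nrow = 2, byrow = TRUE)
  p_mort <- tryCatch(chi_square(tab)$p_value, error = function(e) NA_real_)
  pctf <- function(k, n) if (n > 0) sprintf("%.1f%%", 100 * k / n)
          else NA_character_
  rows <- c(rows, list(data.table(
    variable = "In-hospital mortality",
    total = pctf(sum(d$in_hospital_death), nrow(d)),
    aki = pctf(da, na_), no_aki = pctf(dn, nn),
    p_value = p_mort)))
  rbindlist(rows)
}

.model_to_table <- function(fit) {
  copy(fit$coefficients)[, .(term, or = round(or, 2),
                             ci_lo = round(ci_lo, 2),
                             ci_hi = round(ci_hi, 2),
                             p_value = signif(p_value, 3))]
}

#' Run the full pipeline
#'
#' Executes simulate (or load) -> fuse -> detect -> analyze and returns the
#' report bundle: cohort flow, per-episode assessments with the cohort
#' summary, Table-1-style covariate comparison, first- and max-stage
#' mortality models, the procedure-stratified rate table, Kaplan-Meier
#' curves with log-rank tests, the power simulation, and a run manifest
#' (configuration hash, seed, package version). Identical configurations
#' produce identical outputs. With `out_dir` set, all artifacts are also
#' written (`cohort_flow.json`, `aki_assessments.csv`, `aki_summary.json`,
#' `table1.csv`, `table2_first.csv`, `table2_max.csv`, `table3.csv`,
#' `km_curves.csv`, `power.json`, `manifest.json`, `fused_episodes.csv`).
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with all result objects.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$extracts)) {
    his <- read_his_extract(config$extracts$his_patients,
                            config$extracts$his_surgeries)
    pdms <- read_pdms_extract(config$extracts$pdms)
    gt <- NULL
  } else {
    sim <- generate_cohort(config$spec)
    his <- read_his_extract(sim$his$patients, sim$his$surgeries)
    pdms <- sim$pdms
    gt <- sim$ground_truth
  }
  fused <- fuse_cohort(his, pdms, opts = config$kdigo)
  det <- assess_cohort(fused, opts = config$kdigo)
  eps <- fused$episodes
  ass <- det$assessments

  table1 <- .table1(eps, ass)
  outcomes <- as.data.table(eps)[, .(patient_id, death = in_hospital_death,
                                     age, sex, bmi, preop_creatinine,
                                     euroscore2)]
  covs <- c("age", "sex", "bmi", "preop_creatinine", "euroscore2")
  fit_first <- aki_mortality_model(ass, outcomes, "first", covs)
  fit_max <- aki_mortality_model(ass, outcomes, "max", covs)
  d3 <- merge(as.data.table(eps)[, .(patient_id, procedure,
                                     death = in_hospital_death)],
              ass[, .(patient_id, aki)], by = "patient_id")
  table3 <- rate_table(d3$aki, d3$death, d3$procedure)
  km_dat <- merge(as.data.table(eps)[, .(patient_id,
                                         time = hospital_los_days,
                                         event = in_hospital_death)],
                  ass[, .(patient_id, aki, max_stage)], by = "patient_id")
  km_aki <- km_logrank(km_dat$time, km_dat$event,
                       ifelse(km_dat$aki, "AKI", "no AKI"))
  km_stage <- km_logrank(km_dat$time, km_dat$event,
                         paste0("stage", km_dat$max_stage))
  ## power is undefined for degenerate cohorts (no/only AKI, no deaths)
  pw <- tryCatch(
    power_simulation(n = nrow(ass),
                     exposure_prev = det$summary$incidence,
                     overall_mortality = mean(km_dat$event),
                     or = config$power_or, alpha = config$power_alpha,
                     reps = config$power_reps, seed = config$seed),
    error = function(e) list(power = NA_real_, mc_se = NA_real_,
                             note = conditionMessage(e)))
  manifest <- list(
    package = "csaki",
    version = as.character(utils::packageVersion("csaki")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = config_hash(.serializable_config(config)),
    options = .serializable_config(config))

  out <- list(flow = fused$flow, fused = fused, assessments = ass,
              summary = det$summary, ground_truth = gt, table1 = table1,
              table2_first = fit_first, table2_max = fit_max,
              table3 = table3, km_aki = km_aki, km_stage = km_stage,
              power = pw, manifest = manifest)
  if (!is.null(config$out_dir)) .write_bundle(out, config$out_dir)
  invisible(out)
}

.serializable_config <- function(config) {
  sp <- config$spec
  if (!is.null(sp)) {
    sp <- unclass(sp)
    sp$origin <- format_timestamp(sp$origin)
  }
  list(spec = sp, extracts = config$extracts,
       kdigo = unclass(config$kdigo), alpha = config$alpha,
       power_or = config$power_or, power_alpha = config$power_alpha,
       power_reps = config$power_reps, seed = config$seed)
}

.write_bundle <- function(out, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wj <- function(x, f) jsonlite::write_json(x, file.path(dir, f),
                                            auto_unbox = TRUE, digits = NA,
                                            pretty = TRUE, force = TRUE)
  wj(as.list(out$flow), "cohort_flow.json")
  fwrite(out$assessments, file.path(dir, "aki_assessments.csv"))
  wj(out$summary, "aki_summary.json")
  fwrite(out$table1, file.path(dir, "table1.csv"))
  fwrite(.model_to_table(out$table2_first), file.path(dir, "table2_first.csv"))
  fwrite(.model_to_table(out$table2_max), file.path(dir, "table2_max.csv"))
  fwrite(as.data.table(out$table3), file.path(dir, "table3.csv"))
  km <- rbind(cbind(comparison = "aki", out$km_aki$curves),
              cbind(comparison = "max_stage", out$km_stage$curves))
  fwrite(km, file.path(dir, "km_curves.csv"))
  wj(unclass(out$power), "power.json")
  wj(out$manifest, "manifest.json")
  flat <- as.data.table(out$fused$episodes)[, .(
    patient_id, procedure, surgery_start = format_timestamp(surgery_start),
    surgery_end = format_timestamp(surgery_end),
    icu_admission = format_timestamp(icu_admission),
    icu_discharge = format_timestamp(icu_discharge),
    age, sex, bmi, preop_creatinine, euroscore2, icu_los_days,
    hospital_los_days, in_hospital_death)]
  fwrite(flat, file.path(dir, "fused_episodes.csv"))
  invisible(dir)
}

#' Validate extract files
#'
#' Schema, unit, range and timestamp checks with row-level diagnostics.
#'
#' @param his_patients,his_surgeries,pdms paths or data.frames.
#' @return list of class `validation_report`: `ok` (logical) and `issues`
#'   (data.table: table, row, message).
#' @export
validate_extracts <- function(his_patients, his_surgeries, pdms) {
  issues <- list()
  flag <- function(tab, row, msg) {
    issues[[length(issues) + 1L]] <<- data.table(table = tab, row = row,
                                                 message = msg)
  }
  pat <- if (is.character(his_patients)) fread(his_patients) else as.data.table(his_patients)
  sur <- if (is.character(his_surgeries)) fread(his_surgeries) else as.data.table(his_surgeries)
  obs <- if (is.character(pdms)) fread(pdms) else as.data.table(pdms)

  dup <- which(duplicated(pat$patient_id))
  for (i in dup) flag("his_patients", i, "duplicated patient_id")
  for (col in c("surgery_start", "surgery_end")) {
    if (!col %in% names(sur)) { flag("his_surgeries", NA, paste("missing column", col)); next }
    bad <- which(is.na(safe_parse_timestamp(sur[[col]])))
    for (i in bad) flag("his_surgeries", i, paste("unparseable", col))
  }
  req <- c("patient_id", "timestamp", "parameter", "value", "unit",
           "source_process", "quality_rank")
  miss <- setdiff(req, names(obs))
  for (m in miss) flag("pdms_observations", NA, paste("missing column", m))
  if (!length(miss)) {
    bad_ts <- which(is.na(safe_parse_timestamp(obs$timestamp)))
    for (i in bad_ts) flag("pdms_observations", i, "unparseable timestamp")
    neg_u <- which(obs$parameter == "urine_output" & obs$value < 0)
    for (i in neg_u) flag("pdms_observations", i, "negative urine volume")
    bad_w <- which(obs$parameter == "weight" & obs$value <= 0)
    for (i in bad_w) flag("pdms_observations", i, "non-positive weight")
    bad_q <- which(!is.finite(obs$quality_rank) | obs$quality_rank < 1)
    for (i in bad_q) flag("pdms_observations", i, "invalid quality_rank")
    units <- obs[, .(n_units = uniqueN(unit)), by = parameter][n_units > 1L]
    for (p in units$parameter) flag("pdms_observations", NA,
                                    paste("contradictory units for", p))
    orphan <- which(!obs$patient_id %in% pat$patient_id)
    if (length(orphan) > 0L) {
      flag("pdms_observations", orphan[1L],
           sprintf("%d observation(s) with unknown patient_id", length(orphan)))
    }
  }
  issues <- if (length(issues)) rbindlist(issues) else
    data.table(table = character(), row = integer(), message = character())
  structure(list(ok = nrow(issues) == 0L, issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) cat("extracts valid: no issues\n")
  else {
    cat(nrow(x$issues), "issue(s) found:\n")
    print(x$issues)
  }
  invisible(x)
}
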