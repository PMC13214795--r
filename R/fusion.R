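## Fusion of the two EHR sources: HIS (demographics, surgeries, outcomes)
## and PDMS (timestamped ICU observations). Linkage uses the shared patient
## identifier; each surgery is mapped to the earliest ICU stay starting
## within a configurable window after surgery end; redundant observations
## are resolved by source quality; the computability exclusions produce a
## cohort-flow report. No imputation is performed anywhere.

#' Read the HIS extract
#'
#' @param patients,surgeries paths to `his_patients.csv` /
#'   `his_surgeries.csv`, or data.frames with the same columns.
#' @return list with `patients` and `surgeries` data.tables (timestamps
#'   parsed to POSIXct, UTC).
#' @export
read_his_extract <- function(patients, surgeries) {
  pat <- if (is.character(patients)) fread(patients) else as.data.table(patients)
  sur <- if (is.character(surgeries)) fread(surgeries) else as.data.table(surgeries)
  req_p <- c("patient_id", "preop_creatinine", "in_hospital_death",
             "hospital_los_days")
  req_s <- c("patient_id", "procedure", "surgery_start", "surgery_end")
  miss <- setdiff(req_p, names(pat))
  if (length(miss)) stop("HIS patients extract lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(req_s, names(sur))
  if (length(miss)) stop("HIS surgeries extract lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(pat$patient_id)) {
    stop("duplicate patient_id within the HIS patients extract", call. = FALSE)
  }
  sur[, surgery_start := parse_timestamp(surgery_start, "surgery_start")]
  sur[, surgery_end := parse_timestamp(surgery_end, "surgery_end")]
  list(patients = pat, surgeries = sur)
}

#' Read the PDMS observation extract
#'
#' @param path path to `pdms_observations.csv` or a data.frame with columns
#'   `patient_id`, `timestamp`, `parameter`, `value`, `unit`,
#'   `source_process`, `quality_rank`.
#' @return data.table with parsed timestamps.
#' @export
read_pdms_extract <- function(path) {
  obs <- if (is.character(path)) fread(path) else as.data.table(path)
  req <- c("patient_id", "timestamp", "parameter", "value", "unit",
           "source_process", "quality_rank")
  miss <- setdiff(req, names(obs))
  if (length(miss)) stop("PDMS extract lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  obs[, timestamp := parse_timestamp(timestamp, "timestamp")]
  obs
}

## cluster a patient's observation timestamps into ICU stays: a gap longer
## than `gap_h` hours starts a new stay (the extract carries no explicit
## admission table, matching real PDMS exports)
.icu_stays <- function(obs, gap_h = 24) {
  o <- obs[order(timestamp), .(timestamp)]
  gaps <- c(Inf, diff(as.numeric(o$timestamp)) / 3600)
  stay_id <- cumsum(gaps > gap_h)
  o[, stay := stay_id]
  o[, .(admission = min(timestamp), discharge = max(timestamp)), by = stay]
}

#' Link the two extracts and map surgeries to ICU stays
#'
#' Every surgery is joined to the earliest ICU stay whose admission falls in
#' `(surgery end, surgery end + icu_window_h]`; surgeries without such a
#' stay are flagged unmapped. ICU stays are reconstructed from the PDMS
#' observation timestamps (a documentation gap longer than `stay_gap_h`
#' hours separates stays). Observations outside the mapped stay are
#' discarded downstream.
#'
#' @param his a [read_his_extract()] result.
#' @param pdms a [read_pdms_extract()] result.
#' @param icu_window_h mapping window in hours after surgery end.
#' @param stay_gap_h documentation gap splitting ICU stays.
#' @return data.table with one row per surgery: identifiers, surgery and
#'   ICU interval timestamps, `linked` (patient has any PDMS data) and
#'   `mapped` flags.
#' @export
link_and_map <- function(his, pdms, icu_window_h = 48, stay_gap_h = 24) {
  if (anyDuplicated(his$patients$patient_id)) {
    stop("duplicate patient_id within the HIS patients extract", call. = FALSE)
  }
  sur <- copy(his$surgeries)
  setorder(sur, patient_id, surgery_start)
  obs <- as.data.table(pdms)
  stays <- obs[, .icu_stays(.SD, gap_h = stay_gap_h), by = patient_id]
  n <- nrow(sur)
  adm <- dis <- rep(as.POSIXct(NA_real_, origin = "1970-01-01", tz = "UTC"), n)
  linked <- logical(n)
  stay_split <- split(stays, stays$patient_id)
  for (i in seq_len(n)) {
    st <- stay_split[[sur$patient_id[i]]]
    linked[i] <- !is.null(st) && nrow(st) > 0L
    if (!linked[i]) next
    dt <- hours_between(sur$surgery_end[i], st$admission)
    ok <- which(dt > 0 & dt <= icu_window_h)
    if (length(ok)) {
      pick <- ok[which.min(st$admission[ok])]
      adm[i] <- st$admission[pick]
      dis[i] <- st$discharge[pick]
    }
  }
  out <- sur[, .(patient_id, procedure, surgery_start, surgery_end)]
  out[, `:=`(icu_admission = adm, icu_discharge = dis,
             linked = linked, mapped = !is.na(adm))]
  out
}

#' Resolve redundantly collected observations by source quality
#'
#' When the same parameter at the same timestamp is reported by several
#' source processes, the value from the process with the best (lowest)
#' `quality_rank` is kept; rank ties are broken by the lexicographically
#' smallest `source_process` name, so resolution is deterministic and
#' independent of input row order.
#'
#' @param observations PDMS observation table.
#' @return de-duplicated data.table (same columns).
#' @export
resolve_redundancy <- function(observations) {
  obs <- as.data.table(observations)
  units <- obs[, .(n_units = uniqueN(unit)), by = parameter]
  bad <- units[n_units > 1L]
  if (nrow(bad)) {
    stop("contradictory units for parameter(s): ",
         paste(bad$parameter, collapse = ", "), call. = FALSE)
  }
  setorder(obs, patient_id, parameter, timestamp, quality_rank, source_process)
  obs[!duplicated(obs, by = c("patient_id", "parameter", "timestamp"))]
}

## build the per-episode harmonized series (times in hours since surgery end)
.build_episodes <- function(mapped, his, obs_resolved) {
  pat <- his$patients
  eps <- merge(mapped, pat, by = "patient_id", all.x = TRUE, sort = FALSE)
  setorder(eps, patient_id, surgery_start)
  obs_split <- split(
    list(ts = as.numeric(obs_resolved$timestamp),
         parameter = obs_resolved$parameter,
         value = obs_resolved$value) |> as.data.frame(),
    obs_resolved$patient_id)
  empty <- list(
    urine = data.table(time_h = numeric(), volume_ml = numeric()),
    creatinine = data.table(time_h = numeric(), value = numeric()),
    weights = data.table(time_h = numeric(), weight_kg = numeric()),
    dialysis = data.table(time_h = numeric()))
  series <- function(i) {
    o <- obs_split[[eps$patient_id[i]]]
    if (is.null(o)) return(empty)
    adm <- as.numeric(eps$icu_admission[i])
    dis <- as.numeric(eps$icu_discharge[i])
    se <- as.numeric(eps$surgery_end[i])
    keep <- o$ts >= adm & o$ts <= dis
    th <- (o$ts[keep] - se) / 3600
    par <- o$parameter[keep]
    val <- o$value[keep]
    iu <- par == "urine_output"; ic <- par == "creatinine"
    iw <- par == "weight"; id <- par == "dialysis"
    list(
      urine = data.table(time_h = th[iu], volume_ml = val[iu]),
      creatinine = data.table(time_h = th[ic], value = val[ic]),
      weights = data.table(time_h = th[iw], weight_kg = val[iw]),
      dialysis = data.table(time_h = th[id])
    )
  }
  ser <- lapply(seq_len(nrow(eps)), series)
  eps[, urine := lapply(ser, `[[`, "urine")]
  eps[, creatinine := lapply(ser, `[[`, "creatinine")]
  eps[, weights := lapply(ser, `[[`, "weights")]
  eps[, dialysis := lapply(ser, `[[`, "dialysis")]
  eps[, icu_los_days := hours_between(icu_admission, icu_discharge) / 24]
  eps
}

#' Apply the computability exclusions
#'
#' An episode is computable when at least one criterion family can be
#' evaluated: two or more urine output observations, or at least one serum
#' creatinine, or at least one documented dialysis. Excluded episodes carry
#' the list of failed criteria. The filter is total (never errors) and
#' idempotent.
#'
#' @param episodes fused episode table (list columns `urine`, `creatinine`,
#'   `dialysis`).
#' @return list with `included`, `excluded` (with `failed_criteria`), and
#'   `flow` (named integer vector of cohort-flow counts).
#' @export
apply_computability_filter <- function(episodes) {
  eps <- as.data.table(episodes)
  n_u <- vapply(eps$urine, nrow, integer(1))
  n_c <- vapply(eps$creatinine, nrow, integer(1))
  n_d <- vapply(eps$dialysis, nrow, integer(1))
  computable <- (n_u >= 2L) | (n_c >= 1L) | (n_d >= 1L)
  excluded <- eps[!computable]
  if (nrow(excluded)) {
    excluded[, failed_criteria := vapply(seq_len(.N), function(i) {
      fails <- c(if (n_u[!computable][i] < 2L) "urine<2",
                 if (n_c[!computable][i] < 1L) "creatinine<1",
                 if (n_d[!computable][i] < 1L) "dialysis<1")
      paste(fails, collapse = ";")
    }, character(1))]
  } else {
    excluded[, failed_criteria := character(0)]
  }
  flow <- c(raw = nrow(eps), computable = sum(computable),
            final = sum(computable))
  list(included = eps[computable], excluded = excluded, flow = flow)
}

#' Fuse a two-source cohort end to end
#'
#' Orchestrates [link_and_map()], [resolve_redundancy()], harmonized series
#' construction and [apply_computability_filter()], and emits the
#' Fig.-1-style cohort flow (raw -> linked -> ICU-mapped -> computable).
#'
#' @param his a [read_his_extract()] result (or list of two data.frames).
#' @param pdms PDMS observation table.
#' @param opts a [kdigo_options()] object (supplies the mapping window).
#' @return list of class `fused_cohort`: `episodes` (computable),
#'   `excluded`, `unmapped`, `flow` (named counts, non-increasing).
#' @export
fuse_cohort <- function(his, pdms, opts = kdigo_options()) {
  if (!is.data.table(his$surgeries) ||
      !inherits(his$surgeries$surgery_end, "POSIXct")) {
    his <- read_his_extract(his$patients, his$surgeries)
  }
  pdms <- read_pdms_extract(pdms)
  mapped <- link_and_map(his, pdms, icu_window_h = opts$icu_window_h,
                         stay_gap_h = opts$stay_gap_h)
  n_raw <- nrow(mapped)
  n_linked <- sum(mapped$linked)
  keep <- mapped[mapped == TRUE]
  n_mapped <- nrow(keep)
  obs <- resolve_redundancy(pdms)
  eps <- .build_episodes(keep, his, obs)
  filt <- apply_computability_filter(eps)
  flow <- c(raw = n_raw, linked = n_linked, icu_mapped = n_mapped,
            computable = unname(filt$flow[["computable"]]),
            final = unname(filt$flow[["final"]]))
  stopifnot(all(diff(flow) <= 0))
  structure(list(episodes = filt$included, excluded = filt$excluded,
                 unmapped = mapped[mapped == FALSE], flow = flow),
            class = "fused_cohort")
}

#' @export
print.fused_cohort <- function(x, ...) {
  cat("Fused cohort\n")
  for (nm in names(x$flow)) cat(sprintf("  %-10s %d\n", nm, x$flow[[nm]]))
  invisible(x)
}
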