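#' Kaplan-Meier survival estimates with log-rank comparison
#'
#' Product-limit estimates per stratum (backed by the `survival` package)
#' with the log-rank chi-square across strata. Survival time is measured in
#' days from surgery end to in-hospital death, censored at discharge. With
#' no events, or a single stratum, the log-rank test is undefined and
#' reported as `NA`.
#'
#' @param time numeric follow-up times (days).
#' @param event logical/0-1 event indicator (death).
#' @param strata stratum labels; `NULL` for one overall curve.
#' @return object of class `km_estimate`: `curves` (data.table: stratum,
#'   time, survival, at_risk, events), `logrank_chisq`, `logrank_df`,
#'   `logrank_p`.
#' @export
km_logrank <- function(time, event, strata = NULL) {
  event <- as.integer(as.logical(event))
  stopifnot(length(time) == length(event), all(time >= 0, na.rm = TRUE))
  d <- data.frame(time = time, event = event,
                  stratum = if (is.null(strata)) rep("all", length(time))
                            else as.character(strata))
  fit <- survival::survfit(survival::Surv(time, event) ~ stratum, data = d)
  sm <- summary(fit, censored = TRUE)
  stratum_lab <- if (is.null(sm$strata)) rep("all", length(sm$time))
                 else sub("^stratum=", "", as.character(sm$strata))
  curves <- data.table(stratum = stratum_lab, time = sm$time,
                       survival = sm$surv, at_risk = sm$n.risk,
                       events = sm$n.event)
  lr_chisq <- NA_real_; lr_df <- NA_integer_; lr_p <- NA_real_
  if (length(unique(d$stratum)) > 1L && sum(event) > 0L) {
    lr <- survival::survdiff(survival::Surv(time, event) ~ stratum, data = d)
    lr_df <- length(lr$n) - 1L
    lr_chisq <- lr$chisq
    lr_p <- pchisq(lr$chisq, lr_df, lower.tail = FALSE)
  }
  structure(list(curves = curves, logrank_chisq = lr_chisq,
                 logrank_df = lr_df, logrank_p = lr_p),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  ns <- x$curves[, .(n_times = .N, final_surv = round(min(survival), 3)),
                 by = stratum]
  print(ns)
  if (!is.na(x$logrank_p)) {
    cat(sprintf("log-rank chi-square = %.2f (df %d), p = %.3g\n",
                x$logrank_chisq, x$logrank_df, x$logrank_p))
  } else {
    cat("log-rank: not defined (single stratum or no events)\n")
  }
  invisible(x)
}
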