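#' Stratified AKI/mortality rate table
#'
#' Builds the procedure-stratified contingency table of AKI incidence and
#' mortality. Denominator policy per column: the AKI (and no-AKI) rate is
#' taken over the stratum total; mortality with AKI over the stratum's AKI
#' subgroup; mortality without AKI over the no-AKI subgroup. Percentages of
#' empty strata are `NA`, never 0. The per-stratum p value compares the
#' mortality of the AKI vs no-AKI subgroup by Pearson chi-square (`NA` when
#' the 2x2 table is degenerate).
#'
#' @param aki logical vector (episode developed AKI).
#' @param death logical vector (in-hospital death).
#' @param stratum stratum labels (e.g. procedure); `NULL` for a single
#'   "All" row.
#' @return data.table of class `rate_table`; one row per stratum plus an
#'   "All" row, with counts and `*_pct` percentage columns (0-100 scale).
#' @export
rate_table <- function(aki, death, stratum = NULL) {
  stopifnot(length(aki) == length(death),
            is.null(stratum) || length(stratum) == length(aki))
  dt <- data.table(aki = as.logical(aki), death = as.logical(death),
                   stratum = if (is.null(stratum)) rep("All", length(aki))
                             else as.character(stratum))
  counts <- dt[, .(n = .N, n_aki = sum(aki),
                   deaths_aki = sum(aki & death),
                   deaths_noaki = sum(!aki & death)), by = stratum]
  if (!is.null(stratum)) {
    all_row <- dt[, .(stratum = "All", n = .N, n_aki = sum(aki),
                      deaths_aki = sum(aki & death),
                      deaths_noaki = sum(!aki & death))]
    counts <- rbind(all_row, counts[order(stratum)])
  }
  rate_table_from_counts(counts)
}

#' Rate table from pre-aggregated counts
#'
#' The same table as [rate_table()], computed from integer counts (one row
#' per stratum: `stratum`, `n`, `n_aki`, `deaths_aki`, `deaths_noaki`).
#' This is the "golden-counts" entry point: feeding published contingency
#' counts reproduces the published percentages.
#'
#' @param counts data.frame of counts.
#' @return data.table of class `rate_table`.
#' @export
rate_table_from_counts <- function(counts) {
  x <- as.data.table(counts)
  req <- c("stratum", "n", "n_aki", "deaths_aki", "deaths_noaki")
  miss <- setdiff(req, names(x))
  if (length(miss)) stop("counts lack column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (any(x$n < 0 | x$n_aki < 0 | x$deaths_aki < 0 | x$deaths_noaki < 0)) {
    stop("negative cell count", call. = FALSE)
  }
  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  x[, n_noaki := n - n_aki]
  x[, aki_pct := pct(n_aki, n)]
  x[, noaki_pct := pct(n_noaki, n)]
  x[, mort_aki_pct := pct(deaths_aki, n_aki)]
  x[, mort_noaki_pct := pct(deaths_noaki, n_noaki)]
  x[, p_value := vapply(seq_len(.N), function(i) {
    tab <- matrix(c(deaths_aki[i], n_aki[i] - deaths_aki[i],
                    deaths_noaki[i], n_noaki[i] - deaths_noaki[i]),
                  nrow = 2, byrow = TRUE)
    tryCatch(chi_square(tab)$p_value, error = function(e) NA_real_)
  }, numeric(1))]
  setcolorder(x, c("stratum", "n", "n_aki", "aki_pct", "deaths_aki",
                   "mort_aki_pct", "n_noaki", "noaki_pct", "deaths_noaki",
                   "mort_noaki_pct", "p_value"))
  setattr(x, "class", c("rate_table", class(x)))
  x[]
}

#' @export
print.rate_table <- function(x, digits = 1, ...) {
  y <- copy(x)
  for (col in grep("_pct$", names(y), value = TRUE)) {
    y[, (col) := round(get(col), digits)]
  }
  y[, p_value := signif(p_value, 2)]
  print(as.data.table(y))
  invisible(x)
}
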