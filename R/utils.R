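`%||%` <- function(x, y) if (is.null(x)) y else x

#' Parse ISO-8601 timestamps strictly
#'
#' Accepts `YYYY-MM-DD HH:MM:SS` or `YYYY-MM-DDTHH:MM:SS` (UTC assumed).
#' Unparseable entries raise an error that names the offending row numbers.
#'
#' @param x character vector of timestamps.
#' @param what label used in error messages (e.g. the column name).
#' @return POSIXct vector (UTC).
#' @keywords internal
parse_timestamp <- function(x, what = "timestamp") {
  if (inherits(x, "POSIXct")) return(x)
  xs <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(rep(NA_real_, length(xs)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(out))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(strptime(xs[idx], fmt, tz = "UTC"))
  }
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("unparseable %s at row(s) %s (first offending value: '%s')",
                 what, paste(head(bad, 5L), collapse = ", "), x[bad[1L]]),
         call. = FALSE)
  }
  out
}

format_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")

## non-erroring variant: unparseable entries come back NA
safe_parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  xs <- gsub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(rep(NA_real_, length(xs)), origin = "1970-01-01",
                    tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(out))
    if (!length(idx)) break
    out[idx] <- as.POSIXct(strptime(xs[idx], fmt, tz = "UTC"))
  }
  out
}

#' Hours elapsed between two timestamps
#' @keywords internal
hours_between <- function(from, to) as.numeric(difftime(to, from, units = "hours"))

## stable configuration hash without external digest dependencies:
## serialize to canonical JSON, md5 via tools::md5sum on a temp file
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), f)
  unname(tools::md5sum(f))
}

## run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

## median [IQR] formatter used in table 1 style summaries
fmt_med_iqr <- function(x, digits = 1) {
  q <- stats::quantile(x, c(.5, .25, .75), na.rm = TRUE, names = FALSE)
  sprintf("%.*f [%.*f; %.*f]", digits, q[1], digits, q[2], digits, q[3])
}
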