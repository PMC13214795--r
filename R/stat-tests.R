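#' Pearson chi-square test of independence
#'
#' Classic Pearson statistic `sum((O-E)^2/E)` on a contingency table,
#' without continuity correction, `df = (r-1)(c-1)`. Tables with a zero
#' expected count are degenerate and raise an error.
#'
#' @param table integer matrix of observed counts (r x c).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square <- function(table) {
  O <- as.matrix(table)
  if (any(O < 0)) stop("negative counts", call. = FALSE)
  rs <- rowSums(O); cs <- colSums(O); n <- sum(O)
  E <- outer(rs, cs) / n
  if (any(E == 0) || !is.finite(n) || n == 0) {
    stop("degenerate table: zero expected count", call. = FALSE)
  }
  stat <- sum((O - E)^2 / E)
  df <- (nrow(O) - 1L) * (ncol(O) - 1L)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), expected = E)
}

#' Wilcoxon rank-sum test (normal approximation, tie-corrected)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test using the normal
#' approximation with the standard tie correction of the variance and no
#' continuity correction. The reported statistic `W` is the Mann-Whitney U
#' of the first sample.
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (U), `z`, `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  nx <- length(x); ny <- length(y)
  stopifnot(nx > 0, ny > 0)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  n <- nx + ny
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) return(list(statistic = U, z = 0, p_value = 1))
  z <- (U - mu) / sqrt(sigma2)
  list(statistic = U, z = z, p_value = 2 * pnorm(-abs(z)))
}
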