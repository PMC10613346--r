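# Nonparametric two-group comparison, 2x2 association and reliability
# statistics, implemented from first principles with explicit exact /
# approximate switching so the small synthetic suites can be checked against
# enumeration while study-sized samples use the usual large-sample path.

#' Mann-Whitney U test
#'
#' U is computed from midrank sums. For combined samples of at most
#' `exact_max` observations with no ties the two-sided p-value is exact, by
#' full enumeration of the U distribution over all group labelings; otherwise
#' a normal approximation with tie correction and continuity correction is
#' used (the regime of study-sized groups).
#'
#' @param x,y numeric samples.
#' @param exact_max largest combined n for the exact path (default 16).
#' @return list with `U` (statistic of the first sample), `p` (two-sided),
#'   `method` ("exact" or "normal_approx").
#' @export
mann_whitney <- function(x, y, exact_max = 16L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) {
    stop("stats_invalid: both samples must be non-empty", call. = FALSE)
  }
  if (any(!is.finite(c(x, y)))) {
    stop("stats_invalid: samples must be finite", call. = FALSE)
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- any(duplicated(c(x, y)))
  mu <- nx * ny / 2

  if (!ties && n <= exact_max) {
    # exact: U depends only on which ranks go to x; enumerate all labelings
    combos <- utils::combn(n, nx)
    u_all <- colSums(matrix(seq_len(n)[combos], nrow = nx)) -
      nx * (nx + 1) / 2
    p <- mean(abs(u_all - mu) >= abs(U - mu) - 1e-9)
    return(list(U = U, p = p, method = "exact"))
  }

  tab <- table(c(x, y))
  tie_term <- sum(tab^3 - tab) / (n * (n - 1))
  sigma2 <- nx * ny / 12 * ((n + 1) - tie_term)
  if (sigma2 <= 0) {
    # all observations identical: no evidence against equality
    return(list(U = U, p = 1, method = "normal_approx"))
  }
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(U = U, p = p, method = "normal_approx")
}

#' Pearson chi-square with Yates continuity correction (2x2)
#'
#' chi2 = sum((|O - E| - 0.5)^2 / E) with the correction floored so
#' |O - E| - 0.5 never goes negative; p from the upper tail of chi-square
#' with 1 df. The uncorrected Pearson statistic is returned alongside,
#' because published demographic tables are sometimes computed without the
#' correction despite stating it.
#'
#' @param tab 2x2 matrix of non-negative integer counts with positive margins.
#' @return list with `stat`, `p` (Yates-corrected), `pearson_stat`,
#'   `pearson_p` (uncorrected) and `correction_matters` (TRUE when the two
#'   p-values differ at the second decimal).
#' @export
chi2_yates <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) {
    stop("stats_invalid: need a 2x2 table", call. = FALSE)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("stats_invalid: counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("stats_zero_margin: all margins must be positive", call. = FALSE)
  }
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  adj <- pmax(abs(tab - E) - 0.5, 0)
  stat <- sum(adj^2 / E)
  pearson_stat <- sum((tab - E)^2 / E)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  pearson_p <- stats::pchisq(pearson_stat, df = 1, lower.tail = FALSE)
  list(stat = stat, p = p,
       pearson_stat = pearson_stat, pearson_p = pearson_p,
       correction_matters = abs(p - pearson_p) >= 0.005)
}

#' Intraclass correlation coefficient, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC
#' (Shrout-Fleiss ICC(2,1) / McGraw-Wong ICC(A,1)) computed from the mean
#' squares of the subjects x raters two-way layout, with the 95% CI from the
#' F-distribution formulas. For `kind = "intra"` the columns are repeat
#' sessions of one rater rather than different raters; the arithmetic is
#' identical and the kind is recorded in the output.
#'
#' @param ratings numeric matrix, raters (or sessions) in rows and subjects in
#'   columns, as returned by [read_ratings()]; complete (no missing cells).
#' @param kind `"inter"` or `"intra"`.
#' @param conf confidence level for the interval.
#' @return list with `icc`, `ci` (low, high), `model`, `kind`, mean squares.
#' @export
icc <- function(ratings, kind = c("inter", "intra"), conf = 0.95) {
  kind <- match.arg(kind)
  m <- t(as.matrix(ratings))        # subjects x raters
  n <- nrow(m); k <- ncol(m)
  if (k < 2L) stop("icc_invalid: need >= 2 raters/sessions", call. = FALSE)
  if (n < 5L) stop("icc_invalid: need >= 5 subjects", call. = FALSE)
  if (any(!is.finite(m))) {
    stop("icc_invalid: ratings grid is incomplete", call. = FALSE)
  }
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- sum((m - outer(row_m, rep(1, k)) -
                 outer(rep(1, n), col_m) + grand)^2)
  msr <- ss_rows / (n - 1)          # between subjects
  msc <- ss_cols / (k - 1)          # between raters
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps * max(1, grand^2)) {
    stop("icc_degenerate: zero between-subject variance", call. = FALSE)
  }
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  value <- (msr - mse) / denom

  # McGraw & Wong (1996) CI for ICC(A,1)
  alpha <- 1 - conf
  if (mse <= 0 && msc <= 0) {
    ci <- c(1, 1)  # perfect agreement: interval degenerates
  } else {
    a <- k * value / (n * (1 - value))
    b <- 1 + k * value * (n - 1) / (n * (1 - value))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    low <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    high <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(max(-1, low), min(1, high))
  }
  list(icc = value, ci = ci, model = "ICC(2,1) absolute agreement",
       kind = kind, msr = msr, msc = msc, mse = mse, n = n, k = k)
}
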