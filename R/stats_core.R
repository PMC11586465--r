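# Elementary statistics used by every analysis stage. These are implemented
# in-package (and cross-checked against base R in the test suite) so that the
# exact conventions — uncorrected Pearson chi-square, average-rank Spearman,
# Benjamini-Hochberg step-up — are pinned down in one place.

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson chi-square on an r x c contingency table of counts,
#' with expected counts from the row/column marginals and an asymptotic
#' upper-tail p-value on (r-1)(c-1) degrees of freedom. No continuity
#' correction is applied for 2 x 2 tables: demographic tables in
#' case-control studies are conventionally reported with the plain Pearson
#' statistic.
#'
#' @param counts matrix of non-negative integer counts, at least 2 x 2.
#' @return a `test_result` list with `statistic`, `df` and `p_value`.
#' @examples
#' chi_square_test(matrix(c(17, 20, 51, 38, 38, 22), nrow = 2))
#' @export
chi_square_test <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2L || ncol(counts) < 2L) {
    stop_invalid("contingency table must be at least 2 x 2")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_invalid("counts must be finite and non-negative")
  }
  rs <- rowSums(counts)
  cs <- colSums(counts)
  n <- sum(counts)
  if (n <= 0 || any(rs == 0) || any(cs == 0)) {
    stop_invalid("every row and column must have a positive marginal total")
  }
  expected <- outer(rs, cs) / n
  statistic <- sum((counts - expected)^2 / expected)
  df <- (nrow(counts) - 1L) * (ncol(counts) - 1L)
  test_result(statistic, df, stats::pchisq(statistic, df, lower.tail = FALSE))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and an asymptotic two-sided
#' p-value from the t approximation. When a map-to-map correlation is tested
#' against a spatial null, the analytic p is superseded by the spin p-value
#' (see [spin_pvalue()]).
#'
#' @param x,y numeric vectors of equal length (>= 3), all finite.
#' @return a `test_result` list with `statistic` (rho), `df` (n - 2) and
#'   `p_value`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  if (length(x) < 3L) stop_invalid("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop_invalid("x and y must be finite")
  }
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop_invalid("correlation undefined for constant input")
  }
  rho <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tval), n - 2, lower.tail = FALSE)
  }
  test_result(rho, n - 2L, p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment: q_(i) = min over j >= i of
#' p_(j) * m / j, capped at 1. Order-preserving and elementwise >= p.
#'
#' @param p_values numeric vector of p-values in \[0, 1\]. NAs are propagated.
#' @return numeric vector of q-values in the input order.
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_invalid("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  pv <- p[ok]
  m <- length(pv)
  if (m > 0L) {
    o <- order(pv, decreasing = TRUE)
    ro <- order(o)
    # pmax guards the q >= p invariant against 1-ulp rounding in m/j * p
    q[ok] <- pmax(pmin(1, cummin(m / seq(m, 1L) * pv[o]))[ro], pv)
  }
  q
}

#' z-normalize a vector
#'
#' Centers to mean 0 and scales to sample standard deviation 1.
#'
#' @param values numeric vector of length >= 2 with non-zero spread.
#' @return the standardized vector.
#' @export
z_normalize <- function(values) {
  x <- as.numeric(values)
  if (length(x) < 2L) stop_invalid("need at least 2 values")
  if (any(!is.finite(x))) stop_invalid("values must be finite")
  s <- stats::sd(x)
  if (s == 0) stop_invalid("zero spread: z-normalization undefined")
  (x - mean(x)) / s
}

test_result <- function(statistic, df, p_value) {
  structure(
    list(statistic = unname(statistic), df = unname(df),
         p_value = unname(min(max(p_value, 0), 1))),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("statistic = %.4f, df = %s, p = %.4g\n",
              x$statistic, format(x$df), x$p_value))
  invisible(x)
}

#' @export
format.test_result <- function(x, ...) {
  sprintf("statistic=%.6g df=%s p=%.6g", x$statistic, format(x$df), x$p_value)
}
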