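#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired observations: differences of zero are
#' dropped, the absolute differences are ranked with average ranks for ties,
#' and the statistic `W` is the smaller of the positive and negative rank
#' sums. The p-value is exact (from the signed-rank null distribution) when
#' the number of non-zero differences is at most `exact_max_n` and no
#' absolute differences are tied; otherwise a normal approximation with
#' continuity correction and the standard tie correction of the variance is
#' used. When all differences are zero, `W = 0` and `p = 1` (no evidence).
#'
#' @param x numeric vector: first group values, or the paired differences if
#'   `y` is `NULL`.
#' @param y optional numeric vector paired with `x`.
#' @param exact_max_n largest number of non-zero differences for which the
#'   exact null distribution is used (in the absence of ties).
#' @return one-row tibble: `statistic` (W), `p_value`, `n_nonzero`, `method`
#'   (`"exact"`, `"normal"` or `"degenerate"`).
#' @examples
#' signed_rank_test(c(0.5, 0.3, -0.2))
#' @export
signed_rank_test <- function(x, y = NULL, exact_max_n = 12L) {
  d <- if (is.null(y)) x else x - y
  if (length(d) == 0) abort("signed-rank test needs at least one pair")
  stopifnot(is.numeric(d), !any(is.na(d)))
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(tibble(statistic = 0, p_value = 1, n_nonzero = 0L,
                  method = "degenerate"))
  }
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  w <- min(w_plus, w_minus)
  ties <- anyDuplicated(abs(d)) > 0
  if (!ties && n <= exact_max_n) {
    p <- min(1, 2 * psignrank(w, n))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (w - mu + 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(z))
    method <- "normal"
  }
  tibble(statistic = w, p_value = p, n_nonzero = n, method = method)
}
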