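#' Spearman rank correlation
#'
#' Average-rank Spearman correlation with a p-value from [stats::cor.test()]:
#' the exact permutation distribution when there are no ties and n < 1290,
#' and the t approximation otherwise.
#'
#' @param x,y Paired numeric vectors, n >= 4.
#' @param tail `"two"` (default) or `"one"`; a one-tailed p tests positive
#'   association.
#' @return A list with `rho`, `p_value` and `n`.
#' @examples
#' spearman_corr(1:10, (1:10)^3)$rho # 1: rank correlation ignores curvature
#' @export
spearman_corr <- function(x, y, tail = c("two", "one")) {
  tail <- match.arg(tail)
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("cannot rank-correlate a constant vector", call. = FALSE)
  has_ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  alternative <- if (tail == "one") "greater" else "two.sided"
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = !has_ties,
             alternative = alternative)
  )
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' Test the difference between two dependent correlations
#'
#' Compares two correlations that share a variable: r_jk (j with k) versus
#' r_jh (j with h), given r_kh and the common sample size n. The default is
#' Steiger's Z-bar statistic with the pooled estimate
#' r-bar = (r_jk + r_jh) / 2: both correlations are Fisher-z transformed and
#'
#' \deqn{Z = (z_{jk} - z_{jh}) \sqrt{(n-3) / (2 - 2 \bar{s})}}
#'
#' where s-bar is the standard covariance factor for dependent correlations,
#' \eqn{\bar{s} = [r_{kh}(1 - 2\bar{r}^2) - \bar{r}^2(1 - 2\bar{r}^2 -
#' r_{kh}^2)/2] / (1 - \bar{r}^2)^2}. The Hotelling-Williams t (df = n - 3)
#' is available as an alternative. When the inputs are Spearman rhos the same
#' machinery is applied, as is common practice for rank correlations.
#'
#' @param r_jk,r_jh The two correlations sharing variable j.
#' @param r_kh Correlation between the two non-shared variables.
#' @param n Sample size (>= 4).
#' @param tail `"one"` (tests r_jk > r_jh) or `"two"`.
#' @param method `"steiger"` (default) or `"williams"`.
#' @return A list with `statistic` (Z, or t with `df`), `p_value`, `method`
#'   and `tail`.
#' @examples
#' dependent_corr_test(0.695, 0.174, 0.2, n = 16, tail = "one")
#' @export
dependent_corr_test <- function(r_jk, r_jh, r_kh, n,
                                tail = c("one", "two"),
                                method = c("steiger", "williams")) {
  tail <- match.arg(tail)
  method <- match.arg(method)
  rs <- c(r_jk = r_jk, r_jh = r_jh, r_kh = r_kh)
  if (any(!is.finite(rs)) || any(abs(rs) > 1))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  if (abs(r_jk) == 1 || abs(r_jh) == 1)
    stop("|r| = 1: Fisher z transform undefined", call. = FALSE)
  if (n < 4) stop("need n >= 4", call. = FALSE)

  if (method == "steiger") {
    z_jk <- atanh(r_jk)
    z_jh <- atanh(r_jh)
    rbar <- (r_jk + r_jh) / 2
    psi <- r_kh * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r_kh^2)
    sbar <- psi / (1 - rbar^2)^2
    stat <- (z_jk - z_jh) * sqrt((n - 3) / (2 - 2 * sbar))
    p <- if (tail == "one") pnorm(stat, lower.tail = FALSE) else
      2 * pnorm(abs(stat), lower.tail = FALSE)
    list(statistic = stat, p_value = p, method = "steiger", tail = tail)
  } else {
    detR <- 1 - r_jk^2 - r_jh^2 - r_kh^2 + 2 * r_jk * r_jh * r_kh
    rbar <- (r_jk + r_jh) / 2
    tt <- (r_jk - r_jh) * sqrt(
      ((n - 1) * (1 + r_kh)) /
        (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r_kh)^3)
    )
    df <- n - 3
    p <- if (tail == "one") stats::pt(tt, df, lower.tail = FALSE) else
      2 * stats::pt(abs(tt), df, lower.tail = FALSE)
    list(statistic = tt, df = df, p_value = p, method = "williams", tail = tail)
  }
}
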