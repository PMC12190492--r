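#' Two-tailed Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. The U statistic uses
#' midranks for ties. The two-tailed p-value is exact — computed from the
#' null distribution of U — when the combined sample size is at most 16
#' and the pooled data are tie-free; otherwise a normal approximation
#' with tie correction and continuity correction is used. The exact
#' two-tailed p is `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param a,b Numeric vectors of measurements (non-empty, finite).
#' @param exactMaxN Combined sample size up to which the exact
#'   distribution is used (tie-free data only). Default 16.
#' @return A list with `statistic` (U of sample `a`), `p_value`, `n_a`,
#'   `n_b` and `method` (`"exact"` or `"normal-approximation"`).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, p = 0.1
#' @export
mannWhitneyU <- function(a, b, exactMaxN = 16) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("samples must be finite")
  na <- length(a); nb <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)                      # midranks for ties
  u <- sum(rk[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(pooled) > 0
  if (!ties && na + nb <= exactMaxN) {
    pLow <- stats::pwilcox(u, na, nb)
    pHigh <- 1 - stats::pwilcox(u - 1, na, nb)
    p <- min(1, 2 * min(pLow, pHigh))
    method <- "exact"
  } else {
    mu <- na * nb / 2
    n <- na + nb
    tieTab <- table(pooled)
    tieCorr <- sum(tieTab^3 - tieTab) / (n * (n - 1))
    sigma2 <- na * nb / 12 * ((n + 1) - tieCorr)
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal-approximation"
  }
  list(statistic = u, p_value = p, n_a = na, n_b = nb, method = method)
}

#' Unpaired two-sample t-test from summary statistics
#'
#' Recomputes an unpaired t-test from printed group summaries
#' (mean, SEM, n):
#' \deqn{t = \frac{\bar x_a - \bar x_b}{\sqrt{SEM_a^2 + SEM_b^2}}}
#' with `df = n_a + n_b - 2` under the classic Student convention, or the
#' Welch-Satterthwaite degrees of freedom when `welch = TRUE`.
#'
#' @param meanA,meanB Group means.
#' @param semA,semB Standard errors of the means (>= 0).
#' @param nA,nB Group sizes (>= 2).
#' @param welch Use Welch-Satterthwaite degrees of freedom. Default
#'   `FALSE`.
#' @return A list with `statistic` (t), `df`, `p_value`, `n_a`, `n_b`.
#' @examples
#' tTestFromSummary(16.70, 1.471, 6, 4.467, 1.137, 6)
#' @export
tTestFromSummary <- function(meanA, semA, nA, meanB, semB, nB,
                             welch = FALSE) {
  if (nA < 2 || nB < 2) stop("group sizes must be >= 2")
  if (semA < 0 || semB < 0) stop("SEMs must be >= 0")
  se2 <- semA^2 + semB^2
  if (se2 == 0) {
    if (meanA == meanB)
      return(list(statistic = 0, df = nA + nB - 2, p_value = 1,
                  n_a = nA, n_b = nB))
    stop("zero standard errors with unequal means: t is undefined")
  }
  t <- (meanA - meanB) / sqrt(se2)
  df <- if (welch) {
    se2^2 / (semA^4 / (nA - 1) + semB^4 / (nB - 1))
  } else {
    nA + nB - 2
  }
  p <- 2 * stats::pt(-abs(t), df)
  list(statistic = t, df = df, p_value = p, n_a = nA, n_b = nB)
}

#' Group summary: mean, SEM, n
#'
#' @param values Numeric vector of measurements (non-empty, finite).
#' @return Named vector `c(mean = , sem = , n = )`; `sem` is the sample
#'   standard deviation (n - 1 denominator) divided by `sqrt(n)`. For a
#'   single value the SEM is reported as 0 with a warning.
#' @export
groupSummary <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("'values' must be non-empty")
  if (!all(is.finite(values))) stop("'values' must be finite")
  n <- length(values)
  if (n == 1L) {
    warning("SEM undefined for a single value; reporting 0")
    return(c(mean = values, sem = 0, n = 1))
  }
  c(mean = mean(values), sem = stats::sd(values) / sqrt(n), n = n)
}

#' Fold ratio of two group means
#'
#' @param meanA Numerator group mean.
#' @param meanB Denominator group mean (> 0).
#' @return `meanA / meanB`.
#' @examples
#' round(foldRatio(16.70, 4.467), 1)  # 3.7
#' @export
foldRatio <- function(meanA, meanB) {
  if (!is.finite(meanB) || meanB <= 0)
    stop("denominator mean must be positive")
  meanA / meanB
}

#' Significance stars for a p-value
#'
#' Conventional thresholds: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `n.s.` otherwise.
#'
#' @param p A p-value in \[0, 1\].
#' @return A character string.
#' @export
significanceStars <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1) stop("'p' must be in [0, 1]")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*"
  else "n.s."
}
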