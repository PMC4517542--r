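## The inferential statistics used by the cohort comparisons, authored
## from the textbook formulas with base R's distribution functions as
## the special-function layer (normal and chi-square tails, t tail via
## the incomplete beta behind pt, beta quantiles for the exact binomial
## interval).  No continuity corrections anywhere: the uncorrected
## two-proportion z is what reproduces published panel-enrichment
## statistics, and z^2 then equals the Pearson chi-square exactly.

#' Two-proportion z test (pooled, no continuity correction)
#'
#' z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2)) with pooled
#' p = (x1+x2)/(n1+n2); two-sided p-value from the standard normal.
#' A degenerate pooled proportion (0 or 1) yields z = 0, p = 1.  The
#' confidence interval is the unpooled Wald interval on p1 - p2.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @param conf confidence level for the CI on the difference.
#' @return a [TestResult].
#' @export
twoProportionZ <- function(x1, n1, x2, n2, conf = 0.95) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  p1 <- x1 / n1; p2 <- x2 / n2
  pooled <- (x1 + x2) / (n1 + n2)
  inputs <- list(x1 = x1, n1 = n1, x2 = x2, n2 = n2)
  if (pooled <= 0 || pooled >= 1) {
    return(TestResult("two-proportion z (degenerate)", statistic = 0,
                      pValue = 1, estimate = p1 - p2, inputs = inputs))
  }
  se <- sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  z <- (p1 - p2) / se
  p <- 2 * pnorm(-abs(z))
  seU <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  q <- -stats::qnorm((1 - conf) / 2)
  TestResult("two-proportion z", statistic = z, pValue = p,
             estimate = p1 - p2, ciLow = p1 - p2 - q * seU,
             ciHigh = p1 - p2 + q * seU, inputs = inputs)
}

#' Pearson chi-square test on a 2x2 table (no Yates correction)
#'
#' Statistic n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) with df = 1; p from
#' the chi-square upper tail.  An empty margin makes the test
#' not-computable.
#'
#' @param a,b,c,d cell counts, row-wise: `matrix(c(a, b, c, d), 2, 2,
#'   byrow = TRUE)`.
#' @return a [TestResult].
#' @export
chiSquare2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  inputs <- list(a = a, b = b, c = c, d = d)
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    return(TestResult("Pearson chi-square 2x2", computable = FALSE,
                      inputs = inputs))
  stat <- n * (a * d - b * c)^2 / prod(margins)
  TestResult("Pearson chi-square 2x2", statistic = stat, df = 1,
             pValue = pchisq(stat, df = 1, lower.tail = FALSE),
             inputs = inputs)
}

#' Unpaired two-sample t test
#'
#' Pooled-variance Student t by default; Welch-Satterthwaite degrees of
#' freedom when `welch = TRUE`.  Two-sided p-value from the t
#' distribution.  Degenerate zero-variance input yields p = 1 when the
#' means are equal and p = 0 otherwise.
#'
#' @param values1,values2 numeric vectors (>= 2 values each).
#' @param welch logical; use the Welch unequal-variance form.
#' @param conf confidence level for the CI on the mean difference.
#' @return a [TestResult].
#' @export
twoSampleT <- function(values1, values2, welch = FALSE, conf = 0.95) {
  n1 <- length(values1); n2 <- length(values2)
  stopifnot(n1 >= 2, n2 >= 2)
  m1 <- mean(values1); m2 <- mean(values2)
  v1 <- stats::var(values1); v2 <- stats::var(values2)
  inputs <- list(n1 = n1, n2 = n2, mean1 = m1, mean2 = m2,
                 sd1 = sqrt(v1), sd2 = sqrt(v2), welch = welch)
  diff <- m1 - m2
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    if (se2 == 0) {
      return(TestResult("Welch two-sample t (degenerate)", statistic = 0,
                        pValue = if (diff == 0) 1 else 0, estimate = diff,
                        inputs = inputs))
    }
    se <- sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    method <- "Welch two-sample t"
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    if (sp2 == 0) {
      return(TestResult("Student two-sample t (degenerate)", statistic = 0,
                        pValue = if (diff == 0) 1 else 0, estimate = diff,
                        inputs = inputs))
    }
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    method <- "Student two-sample t"
  }
  tstat <- diff / se
  q <- stats::qt(1 - (1 - conf) / 2, df)
  TestResult(method, statistic = tstat, df = df,
             pValue = 2 * pt(-abs(tstat), df), estimate = diff,
             ciLow = diff - q * se, ciHigh = diff + q * se,
             inputs = inputs)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval by inverting the binomial tails via the beta-quantile
#' formulation: lower = qbeta(alpha/2; x, n-x+1) (0 when x = 0), upper =
#' qbeta(1-alpha/2; x+1, n-x) (1 when x = n).
#'
#' @param x successes (0 <= x <= n).
#' @param n trials (n >= 1).
#' @param conf confidence level (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
clopperPearson <- function(x, n, conf = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n)
  alpha <- 1 - conf
  lower <- if (x == 0) 0 else qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower, upper)
}

#' Percentage with half-up rounding
#'
#' `100 * x / n` rounded half-up to `digits` decimals, matching the
#' one-decimal printing convention of clinical cohort reports (e.g.
#' 165/740 -> 22.3).
#'
#' @param x numerator.
#' @param n denominator.
#' @param digits decimals (default 1).
#' @return numeric.
#' @export
pctHalfUp <- function(x, n, digits = 1) {
  p <- 100 * x / n
  f <- 10^digits
  floor(p * f + 0.5) / f
}
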