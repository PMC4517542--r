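test_that("two-proportion z reproduces the panel-enrichment contingency", {
  r <- twoProportionZ(12, 40, 41, 275)
  expect_equal(statistic(r), 2.383847, tolerance = 1e-6)
  expect_equal(pValue(r), 0.0171327, tolerance = 1e-5)
  # independent oracle: prop.test without continuity correction
  pt <- prop.test(c(12, 41), c(40, 275), correct = FALSE)
  expect_equal(statistic(r)^2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(pValue(r), pt$p.value, tolerance = 1e-10)
})

test_that("degenerate and symmetric two-proportion inputs behave", {
  r <- twoProportionZ(5, 10, 5, 10)
  expect_equal(statistic(r), 0)
  expect_equal(pValue(r), 1)
  expect_equal(pValue(twoProportionZ(0, 10, 0, 10)), 1)
  expect_equal(pValue(twoProportionZ(10, 10, 10, 10)), 1)
  # p invariant under swapping groups
  a <- twoProportionZ(3, 8, 1, 9)
  b <- twoProportionZ(1, 9, 3, 8)
  expect_equal(pValue(a), pValue(b))
  expect_equal(statistic(a), -statistic(b))
})

test_that("z approximation is close to the exact permutation null on small tables", {
  x1 <- 3; n1 <- 8; x2 <- 1; n2 <- 9
  zP <- pValue(twoProportionZ(x1, n1, x2, n2))
  # enumerate the hypergeometric null on the fixed 2x2 margins; the
  # mid-p convention (observed table at half weight) is the standard
  # yardstick for a continuous approximation to a discrete null
  k <- x1 + x2
  obs <- abs(x1 / n1 - x2 / n2)
  support <- max(0, k - n2):min(n1, k)
  probs <- dhyper(support, n1, n2, k)
  diffs <- abs(support / n1 - (k - support) / n2)
  pMid <- sum(probs[diffs > obs + 1e-12]) +
    0.5 * sum(probs[abs(diffs - obs) <= 1e-12])
  expect_lt(abs(zP - pMid), 0.02)
})

test_that("chi-square equals z squared and matches hand results", {
  r <- chiSquare2x2(12, 28, 41, 234)
  z <- twoProportionZ(12, 40, 41, 275)
  expect_equal(statistic(r), statistic(z)^2, tolerance = 1e-9)
  expect_equal(pValue(r), pValue(z), tolerance = 1e-9)
  # identical rows: no association
  same <- chiSquare2x2(5, 5, 5, 5)
  expect_equal(statistic(same), 0)
  expect_equal(pValue(same), 1)
  # perfectly separated table: statistic n (hand: 20*(100)^2/10^4 = 20)
  sep <- chiSquare2x2(10, 0, 0, 10)
  expect_equal(statistic(sep), 20)
  expect_lt(pValue(sep), 1e-4)
  # empty margin is not computable
  expect_false(isComputable(chiSquare2x2(0, 0, 3, 4)))
  # oracle: chisq.test without Yates correction
  ct <- chisq.test(matrix(c(12, 28, 41, 234), 2, byrow = TRUE),
                   correct = FALSE)
  expect_equal(statistic(r), unname(ct$statistic), tolerance = 1e-10)
})

test_that("z squared equals chi-square on random 2x2 tables", {
  set.seed(19)
  for (i in 1:200) {
    a <- rpois(1, 8); b <- rpois(1, 12) + 1
    c <- rpois(1, 20); d <- rpois(1, 50) + 1
    z <- twoProportionZ(a, a + b, c, c + d)
    x2 <- chiSquare2x2(a, b, c, d)
    expect_equal(statistic(z)^2, statistic(x2),
                 tolerance = 1e-9 * max(1, statistic(x2)))
    expect_equal(pValue(z), pValue(x2), tolerance = 1e-9)
  }
})

test_that("two-sample t matches the reference implementation and its identities", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  y <- c(2.0, 2.5, 6.1, 3.3)
  r <- twoSampleT(x, y)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(statistic(r), unname(tt$statistic), tolerance = 1e-10)
  expect_equal(pValue(r), tt$p.value, tolerance = 1e-10)
  rw <- twoSampleT(x, y, welch = TRUE)
  tw <- t.test(x, y)
  expect_equal(pValue(rw), tw$p.value, tolerance = 1e-10)
  expect_equal(rw@df, unname(tw$parameter), tolerance = 1e-10)

  # identical groups: no signal
  same <- twoSampleT(x, x)
  expect_equal(statistic(same), 0)
  expect_equal(pValue(same), 1)
  # equal n and equal variances: Welch reduces to Student
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  expect_equal(pValue(twoSampleT(a, b, welch = TRUE)),
               pValue(twoSampleT(a, b, welch = FALSE)),
               tolerance = 1e-12)
  # zero-variance degenerate cases
  expect_equal(pValue(twoSampleT(c(2, 2), c(2, 2))), 1)
  expect_equal(pValue(twoSampleT(c(2, 2), c(3, 3))), 0)
  # swap invariance
  expect_equal(pValue(twoSampleT(x, y)), pValue(twoSampleT(y, x)))
})

test_that("Clopper-Pearson matches binom.test, bisection, and its boundaries", {
  expect_equal(clopperPearson(0, 20)[1], 0)
  expect_equal(clopperPearson(20, 20)[2], 1)
  ci <- clopperPearson(41, 275)
  expect_true(ci[1] < 41 / 275 && 41 / 275 < ci[2])

  bt <- binom.test(7, 10)$conf.int
  expect_equal(clopperPearson(7, 10), as.numeric(bt), tolerance = 1e-8)

  # direct bisection on the binomial tail sums
  lowerBis <- uniroot(function(p) 1 - pbinom(6, 10, p) - 0.025,
                      c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upperBis <- uniroot(function(p) pbinom(7, 10, p) - 0.025,
                      c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  expect_equal(clopperPearson(7, 10), c(lowerBis, upperBis),
               tolerance = 1e-6)
})

test_that("Clopper-Pearson empirical coverage is at least nominal", {
  set.seed(29)
  n <- 50
  for (p in c(0.05, 0.15, 0.5)) {
    x <- rbinom(5000, n, p)
    lower <- ifelse(x == 0, 0, qbeta(0.025, x, n - x + 1))
    upper <- ifelse(x == n, 1, qbeta(0.975, x + 1, n - x))
    # the vectorized bounds above are definitionally clopperPearson();
    # spot-check then measure coverage
    i <- sample(5000, 1)
    expect_equal(c(lower[i], upper[i]), clopperPearson(x[i], n))
    expect_gte(mean(lower <= p & p <= upper), 0.95)
  }
})

test_that("percent formatting rounds half-up to one decimal", {
  expect_equal(pctHalfUp(165, 740), 22.3)
  expect_equal(pctHalfUp(1, 16), 6.3)    # 6.25 rounds up, not to even
  expect_equal(pctHalfUp(35, 38), 92.1)
})
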