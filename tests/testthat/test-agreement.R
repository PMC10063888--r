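test_that("Bland-Altman summaries match hand arithmetic", {
  s <- pairedSeries(c(3, 4, 5), c(2, 2, 2))  # differences 1, 2, 3
  ba <- blandAltman(s)
  expect_equal(ba@meanDiff, 2)
  expect_equal(ba@sdDiff, 1)
  expect_equal(ba@upperLoa, 3.96)
  expect_equal(ba@lowerLoa, 0.04)
  expect_false(ba@degenerate)
})

test_that("identical series are degenerate with zero limits", {
  x <- c(5, 6, 7, 8)
  ba <- blandAltman(pairedSeries(x, x))
  expect_equal(ba@meanDiff, 0)
  expect_equal(ba@upperLoa, 0)
  expect_equal(ba@lowerLoa, 0)
  expect_true(ba@degenerate)
  expect_true(is.na(ba@biasP))
})

test_that("swapping the methods negates the agreement summary", {
  set.seed(31)
  x <- rnorm(40, 10); y <- rnorm(40, 9)
  a <- blandAltman(pairedSeries(x, y))
  b <- blandAltman(pairedSeries(y, x))
  expect_equal(a@meanDiff, -b@meanDiff)
  expect_equal(a@upperLoa, -b@lowerLoa)
  expect_equal(a@lowerLoa, -b@upperLoa)
})

test_that("proportional bias is detected by the slope test", {
  set.seed(32)
  m <- runif(60, 50, 150)
  x <- m + 0.2 * m + rnorm(60, 0, 1)  # difference grows with the mean
  y <- m - 0.2 * m + rnorm(60, 0, 1)
  ba <- blandAltman(pairedSeries(x, y))
  expect_lt(ba@propBiasP, 0.001)
  expect_gt(ba@propBiasSlope, 0)
  # and absent when the difference is a constant shift
  ba0 <- blandAltman(pairedSeries(m + 5 + rnorm(60, 0, 1), m))
  expect_gt(ba0@propBiasP, 0.05)
})

test_that("the paired test chooses its branch by normality", {
  set.seed(33)
  x <- rnorm(50, 10, 1)
  same <- pairedCompare(pairedSeries(x, x + rnorm(50, 0, 1e-8)))
  expect_equal(same$test, "paired t")
  shifted <- pairedCompare(pairedSeries(x + 2, x))
  # constant shift with tiny noise: overwhelming evidence
  s2 <- pairedSeries(x + 2 + rnorm(50, 0, 0.3), x)
  expect_lt(pairedCompare(s2)$p, 0.001)
  skewed <- pairedSeries(x + rexp(50)^3, x)
  expect_equal(pairedCompare(skewed)$test, "wilcoxon signed rank")
  allzero <- pairedCompare(pairedSeries(x, x))
  expect_equal(allzero$p, 1)
  expect_true(allzero$degenerate)
})

test_that("the t branch agrees with the closed-form paired t-test", {
  x <- c(10.2, 11.1, 9.8, 10.6, 10.9, 11.4)
  y <- c(9.9, 10.4, 9.9, 10.1, 10.5, 10.6)
  d <- x - y
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  pManual <- 2 * pt(-abs(tstat), length(d) - 1)
  res <- pairedCompare(pairedSeries(x, y), skewnessRule = function(d) TRUE)
  expect_equal(res$p, pManual)
  expect_equal(res$statistic, tstat)
})

test_that("the Bonferroni threshold is the divided alpha", {
  expect_equal(round(bonferroniThreshold(0.05, 12), 4), 0.0042)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.06, 2), 0.03)
  expect_equal(bonferroniThreshold(0.05, 12) * 12, 0.05)
  expect_error(bonferroniThreshold(0, 12), "alpha")
  expect_error(bonferroniThreshold(0.05, 0), "m must")
})

test_that("correlation tables handle perfect, null and degenerate cells", {
  set.seed(34)
  x <- rnorm(1000)
  rv <- data.frame(lin = 2 * x + 1, anti = -x, noise = rnorm(1000))
  cl <- data.frame(x = x, const = rep(1, 1000))
  tab <- correlationTable(rv, cl)
  g <- function(c1, r1) tab[tab$clinical == c1 & tab$rvgc == r1, ]
  expect_equal(g("x", "lin")$rho, 1)
  expect_equal(g("x", "anti")$rho, -1)
  expect_lt(abs(g("x", "noise")$rho), 0.1)
  expect_true(is.na(g("const", "lin")$rho))
  expect_equal(g("x", "lin")$n, 1000)
  # missing values are handled pairwise-complete
  cl2 <- data.frame(x = replace(x, 1:100, NA))
  expect_equal(correlationTable(rv, cl2)$n[1], 900)
})
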