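# Agreement statistics between two measurement protocols: Bland-Altman
# mean difference with limits of agreement and bias tests, paired
# comparison with a normality-driven test choice, Bonferroni threshold,
# and correlation tables against clinical variables.

#' Construct a paired measurement series
#'
#' @param x,y numeric values of the same quantity measured by method 1
#'   and method 2 on the same images; differences are `x - y`.
#' @param labels image identifiers; defaults to the index.
#' @return a [PairedSeries-class].
#' @export
pairedSeries <- function(x, y, labels = as.character(seq_along(x))) {
  keep <- is.finite(x) & is.finite(y)
  new("PairedSeries", labels = as.character(labels)[keep],
      x = as.numeric(x)[keep], y = as.numeric(y)[keep])
}

#' Bland-Altman agreement analysis
#'
#' Computes the mean difference `md = mean(x - y)`, its sample SD, the
#' symmetric limits of agreement `md +/- 1.96 sd`, a one-sample t-test of
#' the differences against zero (systematic bias), and the slope of an
#' ordinary least-squares regression of the differences on the pairwise
#' means `(x + y)/2` with its t-test against zero (proportional bias).
#' Zero-variance differences make the bias tests undefined; the summary
#' is then flagged degenerate with both p-values set to NA.
#'
#' @param s a [PairedSeries-class] (or anything accepted by
#'   [pairedSeries()] when `y` is supplied).
#' @param y optional second series when `s` is given as a plain vector.
#' @return an [AgreementSummary-class].
#' @examples
#' s <- pairedSeries(c(3, 4, 5), c(2, 2, 2))
#' blandAltman(s)  # md 2, sd 1, limits 0.04 / 3.96
#' @export
blandAltman <- function(s, y = NULL) {
  if (!is(s, "PairedSeries")) s <- pairedSeries(s, y)
  d <- s@x - s@y
  m <- (s@x + s@y) / 2
  md <- mean(d)
  sdd <- sd(d)
  degenerate <- !is.finite(sdd) || sdd <= .Machine$double.eps * max(1, abs(md))
  if (degenerate) {
    biasP <- NA_real_; slope <- 0; slopeP <- NA_real_; sdd <- 0
  } else {
    biasP <- t.test(d, mu = 0)$p.value
    fit <- lm(d ~ m)
    cf <- suppressWarnings(summary(fit))$coefficients
    slope <- cf["m", "Estimate"]
    slopeP <- cf["m", "Pr(>|t|)"]
  }
  new("AgreementSummary", meanDiff = md, sdDiff = sdd,
      upperLoa = md + 1.96 * sdd, lowerLoa = md - 1.96 * sdd,
      biasP = biasP, propBiasSlope = slope, propBiasP = slopeP,
      n = length(d), degenerate = degenerate)
}

#' Paired comparison with normality-driven test choice
#'
#' A two-sided paired-samples t-test for normally distributed differences
#' and a related-samples Wilcoxon signed-rank test for skewed ones.  The
#' branch is chosen by a Shapiro-Wilk test of the differences at the
#' configured level (the conventional diagnostic; any rule mapping the
#' differences to TRUE/FALSE-normal can be supplied instead).
#'
#' @param s a [PairedSeries-class].
#' @param normalityAlpha level of the Shapiro-Wilk normality screen.
#' @param skewnessRule optional function(differences) returning TRUE when
#'   the t branch should be used; overrides the Shapiro-Wilk rule.
#' @return list with `p` (two-sided), `test` (`"paired t"` or
#'   `"wilcoxon signed rank"`), `statistic` and `degenerate`.
#' @export
pairedCompare <- function(s, normalityAlpha = 0.05, skewnessRule = NULL) {
  stopifnot(is(s, "PairedSeries"))
  d <- s@x - s@y
  if (all(d == 0))
    return(list(p = 1, test = "paired t", statistic = 0, degenerate = TRUE))
  if (sd(d) <= .Machine$double.eps * max(abs(d)))
    return(list(p = 0, test = "paired t", statistic = Inf, degenerate = TRUE))
  normal <- if (is.null(skewnessRule)) {
    n <- length(d)
    if (n >= 3 && n <= 5000) shapiro.test(d)$p.value >= normalityAlpha
    else TRUE
  } else isTRUE(skewnessRule(d))
  if (normal) {
    ht <- t.test(s@x, s@y, paired = TRUE)
    list(p = ht$p.value, test = "paired t",
         statistic = unname(ht$statistic), degenerate = FALSE)
  } else {
    ht <- suppressWarnings(wilcox.test(s@x, s@y, paired = TRUE,
                                       exact = FALSE, correct = TRUE))
    list(p = ht$p.value, test = "wilcoxon signed rank",
         statistic = unname(ht$statistic), degenerate = FALSE)
  }
}

#' Bonferroni-corrected significance threshold
#'
#' The original alpha divided by the number of comparisons on the
#' dependent variable; with alpha 0.05 over the twelve characteristics
#' this is 0.0042 at four decimals.
#'
#' @param alpha original significance level, in (0, 1).
#' @param m number of comparisons, >= 1.
#' @return the corrected threshold (full precision; round to 4 decimals
#'   for display).
#' @examples
#' round(bonferroniThreshold(0.05, 12), 4)  # 0.0042
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Pearson correlation table between characteristics and clinical data
#'
#' Pearson's correlation with a two-sided test for every (clinical
#' variable, characteristic) pair, on pairwise-complete observations.
#' Cells with fewer than 3 complete pairs or a constant column are
#' reported as undefined (NA).
#'
#' @param rvgcTable data.frame of per-image characteristics (numeric
#'   columns).
#' @param clinicalTable data.frame of per-image clinical variables, rows
#'   aligned with `rvgcTable`.
#' @return `data.frame` with columns `clinical`, `rvgc`, `rho`, `p`, `n`.
#' @export
correlationTable <- function(rvgcTable, clinicalTable) {
  if (nrow(rvgcTable) != nrow(clinicalTable))
    stop("tables must have the same number of rows (aligned images)")
  rn <- names(rvgcTable)[vapply(rvgcTable, is.numeric, TRUE)]
  cn <- names(clinicalTable)[vapply(clinicalTable, is.numeric, TRUE)]
  rows <- list()
  for (cl in cn) for (rv in rn) {
    ok <- complete.cases(clinicalTable[[cl]], rvgcTable[[rv]])
    n <- sum(ok)
    if (n < 3L || sd(clinicalTable[[cl]][ok]) == 0 ||
        sd(rvgcTable[[rv]][ok]) == 0) {
      rho <- NA_real_; p <- NA_real_
    } else {
      ct <- cor.test(clinicalTable[[cl]][ok], rvgcTable[[rv]][ok],
                     method = "pearson")
      rho <- unname(ct$estimate); p <- ct$p.value
    }
    rows[[length(rows) + 1L]] <-
      data.frame(clinical = cl, rvgc = rv, rho = rho, p = p, n = n)
  }
  do.call(rbind, rows)
}
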