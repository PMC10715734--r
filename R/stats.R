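#' Result of a two-sample statistical test
#'
#' @slot testName character(1).
#' @slot statistic numeric(1).
#' @slot pValue numeric(1) in [0, 1].
#' @slot n1,n2 integer sample sizes.
#' @slot twoSided logical(1).
#'
#' @aliases TestResult
#' @exportClass TestResult
setClass("TestResult",
  representation(testName = "character", statistic = "numeric",
                 pValue = "numeric", n1 = "integer", n2 = "integer",
                 twoSided = "logical"))

setValidity("TestResult", function(object) {
  msg <- character()
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "pValue must lie in [0, 1]")
  if (object@n1 < 1L || object@n2 < 1L)
    msg <- c(msg, "sample sizes must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (n1 = %d, n2 = %d, %s)\n",
              object@testName, object@statistic, object@pValue,
              object@n1, object@n2,
              if (object@twoSided) "two-sided" else "one-sided"))
})

#' @rdname TestResult-class
#' @param x a \code{TestResult}.
#' @export
setMethod("pValue", "TestResult", function(x) x@pValue)

#' @rdname TestResult-class
#' @export
setMethod("testStatistic", "TestResult", function(x) x@statistic)

#' Mann-Whitney U test
#'
#' Nonparametric comparison of two unpaired groups of possibly different
#' sizes. The p-value comes from the exact null distribution (full
#' enumeration of rank assignments) when the smaller sample has at most
#' \code{exactMax} observations and there are no ties; otherwise from the
#' normal approximation with tie correction and continuity correction. When
#' every pooled value is identical the test is degenerate and p = 1.
#'
#' @param x,y numeric samples.
#' @param twoSided two-sided (default) or one-sided ("greater" for x).
#' @param exactMax largest min(n1, n2) for which the exact branch is used.
#' @return a \code{\linkS4class{TestResult}} with the U statistic of
#'   \code{x}.
#' @export
mannWhitneyU <- function(x, y, twoSided = TRUE, exactMax = 8L) {
  if (length(x) == 0L || length(y) == 0L) stop("empty sample")
  alt <- if (twoSided) "two.sided" else "greater"
  hasTies <- anyDuplicated(c(x, y)) > 0L
  if (length(unique(c(x, y))) == 1L) {
    res <- list(statistic = length(x) * length(y) / 2, p.value = 1)
  } else {
    useExact <- !hasTies && min(length(x), length(y)) <= exactMax
    res <- suppressWarnings(stats::wilcox.test(
      x, y, alternative = alt, exact = useExact, correct = TRUE))
  }
  new("TestResult", testName = "Mann-Whitney U",
      statistic = unname(res$statistic), pValue = unname(res$p.value),
      n1 = length(x), n2 = length(y), twoSided = twoSided)
}

#' Paired Student's t test
#'
#' For paired groups of equal size. Degenerate pairs (zero variance of the
#' differences) are an error rather than a misleading p-value.
#'
#' @param x,y paired numeric samples of equal length >= 2.
#' @return a \code{\linkS4class{TestResult}} (two-sided).
#' @export
pairedT <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0)
    stop("zero variance of paired differences: t statistic undefined")
  res <- stats::t.test(x, y, paired = TRUE)
  new("TestResult", testName = "paired t",
      statistic = unname(res$statistic), pValue = res$p.value,
      n1 = length(x), n2 = length(y), twoSided = TRUE)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D = sup |ECDF_a - ECDF_b| with the asymptotic p-value; the convention for
#' comparing two intensity-versus-time curves is to pass the per-timepoint
#' values over the common time grid as the two samples.
#'
#' @param a,b numeric samples.
#' @return a \code{\linkS4class{TestResult}} (two-sided).
#' @export
ksTwoSample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  p <- if (res$statistic == 0) 1 else min(1, res$p.value)
  new("TestResult", testName = "Kolmogorov-Smirnov",
      statistic = unname(res$statistic), pValue = p,
      n1 = length(a), n2 = length(b), twoSided = TRUE)
}

#' False discovery rate adjustment
#'
#' Benjamini-Hochberg (independent/PRDS p-values) or Benjamini-Yekutieli
#' (arbitrary dependence; BH multiplied by the harmonic factor
#' \eqn{c(m) = \sum_{k=1}^m 1/k}) step-up adjustment. Output order matches
#' input order; adjusted values are clipped at 1.
#'
#' @param pvals numeric p-values in [0, 1].
#' @param method \code{"BH"} (default) or \code{"BY"}.
#' @return adjusted p-values.
#' @export
fdrAdjust <- function(pvals, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = method)
}
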