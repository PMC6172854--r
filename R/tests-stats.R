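## Statistical tests used by the usability and ERP analyses: paired t,
## exact Wilcoxon signed-rank (full enumeration of sign assignments,
## midranks for ties), Holm step-down correction, exact binomial test.

.SIDES <- c("two.sided", "greater", "less")

#' Paired t-test
#'
#' Classic paired t statistic with n-1 degrees of freedom (wrapper around
#' \code{stats::t.test}); errors on zero-variance differences rather than
#' returning a degenerate statistic.
#'
#' @param x,y paired numeric vectors of equal length >= 2.
#' @param sidedness "two.sided" (default), "greater" or "less".
#' @return A \linkS4class{TestResult} (statName "t").
#' @export
pairedTTest <- function(x, y, sidedness = "two.sided") {
  sidedness <- match.arg(sidedness, .SIDES)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2L) stop("need at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0)
    stop("differences have zero variance; paired t-test undefined")
  ht <- stats::t.test(x, y, paired = TRUE, alternative = sidedness)
  new("TestResult", statName = "t", statistic = unname(ht$statistic),
      pRaw = ht$p.value, pAdjusted = NA_real_, n = length(x),
      sidedness = sidedness)
}

# exact null distribution of the signed-rank sum for given |d| ranks:
# all 2^n assignments via the doubling construction
.signedRankSums <- function(ranks) {
  sums <- 0
  for (r in ranks) sums <- c(sums, sums + r)
  sums
}

#' Exact Wilcoxon signed-rank test
#'
#' Zero differences are dropped (reducing n), tied absolute differences
#' receive midranks, and the p-value is computed by full enumeration of
#' all 2^n sign assignments of the ranks — exact even under ties. The
#' reported statistic W is the smaller of the two signed-rank sums; the
#' two-sided p is twice the one-sided tail \eqn{P(W_{min} \le w)}, capped
#' at 1.
#'
#' @param x,y paired numeric vectors (y defaults to zeros: one-sample use).
#' @param sidedness "two.sided" (default), "greater" (x > y) or "less".
#' @return A \linkS4class{TestResult} (statName "W"); \code{n} is the
#'   number of non-zero differences.
#' @export
wilcoxonSignedRankExact <- function(x, y = NULL, sidedness = "two.sided") {
  sidedness <- match.arg(sidedness, .SIDES)
  if (is.null(y)) y <- numeric(length(x))
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero")
  if (n > 25L) stop("exact enumeration limited to n <= 25")
  r <- rank(abs(d))
  wPos <- sum(r[d > 0])
  wNeg <- sum(r[d < 0])
  sums <- .signedRankSums(r)
  tailLE <- function(w) mean(sums <= w + 1e-9)
  p <- switch(sidedness,
    greater = tailLE(wNeg),            # x systematically above y
    less = tailLE(wPos),
    two.sided = min(1, 2 * tailLE(min(wPos, wNeg))))
  new("TestResult", statName = "W", statistic = min(wPos, wNeg),
      pRaw = p, pAdjusted = NA_real_, n = n, sidedness = sidedness)
}

#' Holm (step-down Bonferroni) correction
#'
#' @param pValues numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values in the input order (monotone step-down
#'   adjustment, as in \code{stats::p.adjust(method = "holm")}).
#' @export
holmCorrection <- function(pValues) {
  if (any(!is.finite(pValues)) || any(pValues < 0 | pValues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pValues, method = "holm")
}

#' Exact binomial preference test
#'
#' Exact tail probability \eqn{\sum_{i \ge k} \binom{n}{i} p_0^i
#' (1-p_0)^{n-i}} for the one-sided (greater) alternative; other
#' sidednesses follow the standard exact binomial test.
#'
#' @param kSuccesses observed success count (0 <= k <= n).
#' @param n number of trials.
#' @param p0 null success probability (default 0.5).
#' @param sidedness "greater" (default), "less" or "two.sided".
#' @return A \linkS4class{TestResult} (statName "k").
#' @export
binomialPreferenceTest <- function(kSuccesses, n, p0 = 0.5,
                                   sidedness = "greater") {
  sidedness <- match.arg(sidedness, c("greater", "less", "two.sided"))
  if (kSuccesses < 0 || kSuccesses > n || n < 1)
    stop("need 0 <= kSuccesses <= n with n >= 1")
  ht <- stats::binom.test(kSuccesses, n, p = p0, alternative = sidedness)
  new("TestResult", statName = "k", statistic = as.numeric(kSuccesses),
      pRaw = ht$p.value, pAdjusted = NA_real_, n = as.integer(n),
      sidedness = sidedness)
}
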