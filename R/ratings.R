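#' Summarize usability ratings and test condition differences
#'
#' Descriptive statistics (mean, SD per item and condition) for Likert/SAM
#' usability ratings collected under both conditions, plus the
#' pre-registered inference set: paired t-tests (EC vs EO) on the four
#' rated items, an exact one-sided binomial test on the overall condition
#' preference, and Holm correction across those five tests. Subjects
#' missing a condition for an item are excluded from that item's test with
#' a warning. An item whose paired differences are all zero is reported
#' with statistic 0 and p = 1.
#'
#' @param ratings data.frame with columns \code{subject}, \code{item},
#'   \code{condition} ("EO"/"EC") and \code{rating} (Likert 1-5 or SAM
#'   1-9).
#' @param preferences optional character vector (one entry per subject) in
#'   \{"EO", "EC", "undecided"\}; the binomial test counts "EC" as success
#'   out of all subjects.
#' @param testItems items receiving a paired t-test (default: the four
#'   pre-registered rated items present in \code{ratings}).
#' @return List with \code{descriptives} (item x condition mean/SD table)
#'   and \code{tests} (data.frame: item, statistic, value, pRaw,
#'   pAdjusted, n).
#' @export
summarizeRatings <- function(ratings, preferences = NULL,
                             testItems = NULL) {
  .assertCols(ratings, c("subject", "item", "condition", "rating"),
              "ratings table")
  if (!all(ratings$condition %in% .CONDITIONS))
    stop("condition must be EO or EC")

  agg <- stats::aggregate(rating ~ item + condition, data = ratings,
                          FUN = function(v) c(mean = mean(v), sd = stats::sd(v)))
  descriptives <- data.frame(item = agg$item, condition = agg$condition,
                             mean = agg$rating[, "mean"],
                             sd = agg$rating[, "sd"])

  if (is.null(testItems)) testItems <- unique(ratings$item)
  rows <- list()
  for (it in testItems) {
    sub <- ratings[ratings$item == it, , drop = FALSE]
    wide <- stats::reshape(sub[c("subject", "condition", "rating")],
                           direction = "wide", idvar = "subject",
                           timevar = "condition", sep = ".")
    ok <- stats::complete.cases(wide)
    if (any(!ok))
      warning(sum(!ok), " subject(s) missing a condition for item '", it,
              "'; excluded")
    wide <- wide[ok, , drop = FALSE]
    ec <- wide$rating.EC
    eo <- wide$rating.EO
    if (all(ec - eo == 0)) {
      rows[[it]] <- data.frame(item = it, statistic = "t", value = 0,
                               pRaw = 1, n = nrow(wide))
    } else if (stats::sd(ec - eo) == 0) {
      # perfectly constant non-zero shift: t degenerates
      rows[[it]] <- data.frame(item = it, statistic = "t",
                               value = sign(mean(ec - eo)) * Inf,
                               pRaw = 0, n = nrow(wide))
    } else {
      tr <- pairedTTest(ec, eo, sidedness = "two.sided")
      rows[[it]] <- data.frame(item = it, statistic = "t",
                               value = tr@statistic, pRaw = tr@pRaw,
                               n = tr@n)
    }
  }
  if (!is.null(preferences)) {
    if (!all(preferences %in% c("EO", "EC", "undecided")))
      stop("preferences must be EO, EC or undecided")
    br <- binomialPreferenceTest(sum(preferences == "EC"),
                                 length(preferences))
    rows[["preference"]] <- data.frame(item = "preference", statistic = "k",
                                       value = br@statistic, pRaw = br@pRaw,
                                       n = br@n)
  }
  tests <- do.call(rbind, rows)
  rownames(tests) <- NULL
  tests$pAdjusted <- holmCorrection(tests$pRaw)
  list(descriptives = descriptives, tests = tests)
}
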