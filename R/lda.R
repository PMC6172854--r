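## Shrinkage-regularized LDA and its evaluation: analytic (Ledoit-Wolf-type)
## shrinkage of the pooled within-class covariance toward a scaled identity,
## AUC scoring via the Mann-Whitney statistic, and chronological k-fold
## cross-validation cut at trial boundaries.

# Analytic shrinkage intensity toward nu*I for pooled-centered data Z (n x d),
# following the Ledoit-Wolf/Schaefer-Strimmer estimator: the summed sampling
# variance of the covariance entries over the summed squared distance between
# the sample covariance and the target.
.analyticGamma <- function(Z) {
  n <- nrow(Z)
  S <- crossprod(Z) / (n - 1)
  nu <- mean(diag(S))
  Wbar <- crossprod(Z) / n                      # mean of z_ki z_kj over k
  W2 <- crossprod(Z^2)                          # sum_k (z_ki z_kj)^2
  varS <- (n / (n - 1)^3) * (W2 - n * Wbar^2)
  target <- diag(nu, ncol(Z))
  denom <- sum((S - target)^2)
  if (denom <= 0) return(0)
  min(1, max(0, sum(varS) / denom))
}

#' Fit a shrinkage-regularized LDA classifier
#'
#' Binary linear discriminant between target and non-target epochs. The
#' pooled within-class covariance \eqn{\hat\Sigma} is shrunk toward a
#' scaled identity, \eqn{\tilde\Sigma = (1-\gamma)\hat\Sigma + \gamma\nu I}
#' with \eqn{\nu = tr(\hat\Sigma)/d}; the shrinkage intensity \eqn{\gamma}
#' is chosen analytically (Ledoit-Wolf-type estimator) unless fixed. The
#' weight vector is \eqn{w = \tilde\Sigma^{-1}(\mu_{target} -
#' \mu_{nontarget})} and the bias places the decision boundary at the class
#' mean midpoint.
#'
#' @param x a \linkS4class{FeatureMatrix}, or a numeric matrix (epochs x d).
#' @param y class labels ("target"/"nontarget" or logical), taken from
#'   \code{epochInfo(x)} when \code{x} is a FeatureMatrix.
#' @param gamma "auto" for the analytic estimator, or a fixed value in
#'   [0, 1].
#' @return An \linkS4class{LDAModel}.
#' @export
fitShrinkageLda <- function(x, y = NULL, gamma = "auto") {
  if (is(x, "FeatureMatrix")) {
    if (is.null(y)) y <- x@info$label
    x <- x@values
  }
  stopifnot(is.matrix(x))
  if (is.logical(y)) y <- ifelse(y, "target", "nontarget")
  y <- as.character(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  pos <- y == "target"
  if (!any(pos) || !all(y %in% .CLASSES) || all(pos))
    stop("both classes (target, nontarget) must be present")
  if (sum(pos) < 2L || sum(!pos) < 2L)
    stop("need at least 2 samples per class")

  muP <- colMeans(x[pos, , drop = FALSE])
  muN <- colMeans(x[!pos, , drop = FALSE])
  Z <- x
  Z[pos, ] <- sweep(x[pos, , drop = FALSE], 2L, muP)
  Z[!pos, ] <- sweep(x[!pos, , drop = FALSE], 2L, muN)

  S <- crossprod(Z) / (nrow(Z) - 2)     # pooled within-class, 2 means fitted
  nu <- mean(diag(S))
  g <- if (identical(gamma, "auto")) .analyticGamma(Z) else {
    stopifnot(is.numeric(gamma), gamma >= 0, gamma <= 1)
    gamma
  }
  Stilde <- (1 - g) * S
  diag(Stilde) <- diag(Stilde) + g * nu
  w <- as.numeric(solve(Stilde, muP - muN))
  b <- -sum(w * (muP + muN)) / 2
  new("LDAModel", weights = w, bias = b, gamma = g,
      classMeans = cbind(target = muP, nontarget = muN),
      covShrunk = Stilde)
}

#' Decision scores of an LDA model
#'
#' @param model an \linkS4class{LDAModel}.
#' @param x a \linkS4class{FeatureMatrix} or numeric matrix (epochs x d).
#' @return Numeric vector of scores \code{w'x + bias}; higher means more
#'   target-like.
#' @export
decisionScores <- function(model, x) {
  stopifnot(is(model, "LDAModel"))
  if (is(x, "FeatureMatrix")) x <- x@values
  if (ncol(x) != length(model@weights))
    stop("feature dimension mismatch: model d = ", length(model@weights),
         ", data d = ", ncol(x))
  as.numeric(x %*% model@weights + model@bias)
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Probability that a target epoch receives a higher score than a
#' non-target epoch; ties count one half. Computed from the rank-sum
#' statistic (midranks), equivalent to pairwise enumeration.
#'
#' @param scores numeric vector of classifier scores.
#' @param labels class labels ("target"/"nontarget" or logical).
#' @return Scalar AUC in [0, 1]; chance level 0.5.
#' @export
aucScore <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "target", "nontarget")
  pos <- labels == "target"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# contiguous chronological partition of trial keys into k blocks
.chronFolds <- function(trialKeys, k) {
  n <- length(trialKeys)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  split(trialKeys, rep(seq_len(k), times = sizes))
}

# chronological trial keys of an info table ("run.trial", ordered by onset)
.trialOrder <- function(info) {
  key <- paste(info$runIndex, info$trialIndex, sep = ".")
  first <- tapply(info$onsetMs, key, min)
  names(sort(first))
}

#' Five-fold chronological cross-validation
#'
#' Partitions the trials (not epochs) into \code{k} contiguous,
#' chronologically ordered blocks of near-equal trial counts, so that no
#' trial's epochs straddle folds. Per fold, a shrinkage LDA is trained on
#' the remaining blocks and scored on the held-out block's epochs; the AUC
#' is computed per fold and averaged (unweighted).
#'
#' @param epochs an \linkS4class{EpochSet} or precomputed
#'   \linkS4class{FeatureMatrix}.
#' @param k number of folds (default 5).
#' @param intervalsMs feature intervals (used when \code{epochs} is an
#'   EpochSet).
#' @param gamma shrinkage intensity ("auto" or fixed).
#' @param labels optional replacement label vector (e.g. permuted labels
#'   for a chance-level control).
#' @param aggregate "fold" (default): unweighted mean of per-fold AUCs;
#'   "pooled": one AUC over all out-of-fold scores.
#' @return List with \code{meanAuc}, \code{aucByFold}, \code{foldTrials}.
#' @export
chronologicalCV <- function(epochs, k = 5L, intervalsMs = .DEFAULT_INTERVALS,
                            gamma = "auto", labels = NULL,
                            aggregate = c("fold", "pooled")) {
  aggregate <- match.arg(aggregate)
  fm <- if (is(epochs, "FeatureMatrix")) epochs
        else extractIntervalMeans(epochs, intervalsMs = intervalsMs)
  info <- fm@info
  y <- if (is.null(labels)) info$label else {
    stopifnot(length(labels) == nrow(info))
    as.character(labels)
  }
  trials <- .trialOrder(info)
  if (length(trials) < k)
    stop("fewer trials (", length(trials), ") than folds (", k, ")")
  folds <- .chronFolds(trials, k)
  key <- paste(info$runIndex, info$trialIndex, sep = ".")

  scoresAll <- rep(NA_real_, nrow(info))
  aucByFold <- numeric(k)
  for (f in seq_len(k)) {
    test <- key %in% folds[[f]]
    model <- fitShrinkageLda(fm@values[!test, , drop = FALSE], y[!test],
                             gamma = gamma)
    sc <- decisionScores(model, fm@values[test, , drop = FALSE])
    scoresAll[test] <- sc
    aucByFold[f] <- aucScore(sc, y[test])
  }
  meanAuc <- if (aggregate == "fold") mean(aucByFold)
             else aucScore(scoresAll, y)
  list(meanAuc = meanAuc, aucByFold = aucByFold, foldTrials = folds)
}

#' Cross-validated AUC per condition
#'
#' Runs \code{\link{chronologicalCV}} separately on the epochs of each
#' condition and returns a tidy results table.
#'
#' @param epochs an \linkS4class{EpochSet} covering one or both conditions.
#' @param k folds.
#' @param gamma shrinkage intensity.
#' @param pipeline label written into the output table.
#' @param subject subject identifier written into the table.
#' @return data.frame with columns subject, condition, pipeline, fold, auc.
#' @export
classifyByCondition <- function(epochs, k = 5L, gamma = "auto",
                                pipeline = "P1", subject = "S1") {
  stopifnot(is(epochs, "EpochSet"))
  conds <- intersect(.CONDITIONS, unique(epochs@info$condition))
  out <- lapply(conds, function(cond) {
    sub <- .subsetEpochs(epochs, epochs@info$condition == cond)
    cv <- chronologicalCV(sub, k = k, gamma = gamma)
    data.frame(subject = subject, condition = cond, pipeline = pipeline,
               fold = seq_len(k), auc = cv$aucByFold)
  })
  do.call(rbind, out)
}
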