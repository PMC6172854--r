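## Condition-switch simulation: learning curves within a condition and
## incremental retraining across a simulated transition after 18 trials,
## following the offline protocol of the paradigm (20 random repetitions,
## post-transition pool of 36 trials drawn without replacement).

# features + chronological trial bookkeeping for one condition
.condTrials <- function(fm, condition) {
  sel <- fm@info$condition == condition
  info <- fm@info[sel, , drop = FALSE]
  key <- paste(info$runIndex, info$trialIndex, sep = ".")
  list(values = fm@values[sel, , drop = FALSE],
       labels = info$label,
       key = key,
       trials = .trialOrder(info))
}

.rowsOfTrials <- function(ct, trials) which(ct$key %in% trials)

#' Within-condition learning curve
#'
#' For each training-set size m = 1 ... \code{nTrainMax} and each of
#' \code{nSeeds} random repetitions: draw m trials uniformly from the
#' condition's first \code{nTrainMax} trials, train a shrinkage LDA on
#' their epochs, and test on one randomly selected unseen trial of the
#' same condition (drawn from all of the condition's trials outside the
#' training draw). AUCs are averaged over repetitions.
#'
#' @param epochs an \linkS4class{EpochSet} or \linkS4class{FeatureMatrix}.
#' @param condition "EO" or "EC".
#' @param nTrainMax maximum training-set size in trials (default 18).
#' @param nSeeds number of random repetitions (default 20).
#' @param seed master seed; repetition r uses a derived child seed.
#' @param gamma shrinkage intensity.
#' @return Numeric vector of mean AUCs, one per training-set size.
#' @export
learningCurve <- function(epochs, condition, nTrainMax = 18L, nSeeds = 20L,
                          seed = 1L, gamma = "auto") {
  condition <- .matchCondition(condition)
  fm <- if (is(epochs, "FeatureMatrix")) epochs else extractIntervalMeans(epochs)
  ct <- .condTrials(fm, condition)
  if (length(ct$trials) < nTrainMax + 1L)
    stop("condition ", condition, " has only ", length(ct$trials),
         " trials; need at least ", nTrainMax + 1L)
  pool18 <- ct$trials[seq_len(nTrainMax)]
  acc <- matrix(NA_real_, nSeeds, nTrainMax)
  for (s in seq_len(nSeeds)) {
    withSeed(childSeed(seed, s), {
      for (m in seq_len(nTrainMax)) {
        train <- sample(pool18, m)
        testPool <- setdiff(ct$trials, train)
        test <- sample(testPool, 1L)
        tr <- .rowsOfTrials(ct, train)
        te <- .rowsOfTrials(ct, test)
        model <- fitShrinkageLda(ct$values[tr, , drop = FALSE],
                                 ct$labels[tr], gamma = gamma)
        sc <- decisionScores(model, ct$values[te, , drop = FALSE])
        acc[s, m] <- aucScore(sc, ct$labels[te])
      }
    })
  }
  colMeans(acc)
}

#' Condition-switch transfer simulation with incremental retraining
#'
#' Simulates an online transition after 18 trials. Per repetition: the
#' classifier is trained on the first \code{nTrain} trials of
#' \code{preCondition}; then, \code{nPost} times, a trial is drawn without
#' replacement from the post-transition pool (trials \code{nTrain+1} ...
#' \code{nTrain+nPost} of \code{postCondition}), the current classifier is
#' scored on that trial's epochs (AUC over its 15 target / 75 non-target
#' epochs), the trial is appended to the training set, and the classifier
#' is retrained. Step 0 is therefore the pre-transition classifier's
#' performance on unseen post-transition data.
#'
#' @param epochs an \linkS4class{EpochSet} or \linkS4class{FeatureMatrix}
#'   covering both conditions involved.
#' @param preCondition,postCondition conditions before/after the
#'   transition ("EO"/"EC"); equal values give the no-switch control.
#' @param nTrain pre-transition training trials (default 18).
#' @param nPost post-transition steps (default 36).
#' @param nSeeds random repetitions (default 20).
#' @param seed master seed.
#' @param gamma shrinkage intensity.
#' @return A \linkS4class{TransferCurve}.
#' @export
transferExperiment <- function(epochs, preCondition, postCondition,
                               nTrain = 18L, nPost = 36L, nSeeds = 20L,
                               seed = 1L, gamma = "auto") {
  preCondition <- .matchCondition(preCondition)
  postCondition <- .matchCondition(postCondition)
  fm <- if (is(epochs, "FeatureMatrix")) epochs else extractIntervalMeans(epochs)
  pre <- .condTrials(fm, preCondition)
  post <- .condTrials(fm, postCondition)
  if (length(pre$trials) < nTrain)
    stop("pre condition has fewer than ", nTrain, " trials")
  if (length(post$trials) < nTrain + nPost)
    stop("post condition needs at least ", nTrain + nPost,
         " trials (", nTrain, " reserved + ", nPost, " pool)")
  trainTrials0 <- pre$trials[seq_len(nTrain)]
  pool0 <- post$trials[(nTrain + 1L):(nTrain + nPost)]

  perSeed <- matrix(NA_real_, nSeeds, nPost)
  for (s in seq_len(nSeeds)) {
    withSeed(childSeed(seed, s), {
      Xtr <- pre$values[.rowsOfTrials(pre, trainTrials0), , drop = FALSE]
      ytr <- pre$labels[.rowsOfTrials(pre, trainTrials0)]
      pool <- pool0
      model <- fitShrinkageLda(Xtr, ytr, gamma = gamma)
      for (step in seq_len(nPost)) {
        pick <- sample(length(pool), 1L)
        trial <- pool[pick]
        pool <- pool[-pick]
        rows <- .rowsOfTrials(post, trial)
        sc <- decisionScores(model, post$values[rows, , drop = FALSE])
        perSeed[s, step] <- aucScore(sc, post$labels[rows])
        Xtr <- rbind(Xtr, post$values[rows, , drop = FALSE])
        ytr <- c(ytr, post$labels[rows])
        model <- fitShrinkageLda(Xtr, ytr, gamma = gamma)
      }
    })
  }
  new("TransferCurve", scenario = c(preCondition, postCondition),
      aucByStep = colMeans(perSeed), perSeed = perSeed,
      nSeeds = as.integer(nSeeds))
}

#' Per-step transfer loss
#'
#' Difference between the no-switch control curve and the switch curve:
#' \code{stay} mean AUC minus \code{switch} mean AUC, per step.
#'
#' @param switch,stay \linkS4class{TransferCurve}s of equal length.
#' @return Numeric vector of per-step AUC losses.
#' @export
transferLoss <- function(switch, stay) {
  stopifnot(is(switch, "TransferCurve"), is(stay, "TransferCurve"))
  if (length(switch@aucByStep) != length(stay@aucByStep))
    stop("curves have different lengths")
  stay@aucByStep - switch@aucByStep
}

#' Export a transfer curve as a tab-separated table
#'
#' @param curve a \linkS4class{TransferCurve}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeTransferCurve <- function(curve, path) {
  stopifnot(is(curve, "TransferCurve"))
  df <- data.frame(scenario = paste(curve@scenario, collapse = "->"),
                   step = seq_along(curve@aucByStep) - 1L,
                   meanAuc = curve@aucByStep,
                   sdAuc = apply(curve@perSeed, 2L, stats::sd))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
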