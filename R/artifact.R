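## Artifact handling: peak-to-peak flagging on frontal channels, bipolar EOG
## derivation, regression-based ocular cleaning, and variance criteria for
## channels and trials. Flagging marks epochs; it never deletes them.

#' Peak-to-peak artifact flagging (Minmax_60)
#'
#' Flags an epoch when the within-epoch range (max - min) strictly exceeds
#' \code{thresholdUV} on at least one of the designated frontal channels.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param thresholdUV peak-to-peak threshold in µV (default 60).
#' @param channels channels inspected (default Fp1, Fp2, F7, F8, F9, F10).
#' @return Logical vector, one flag per epoch.
#' @export
minmaxFlag <- function(epochs, thresholdUV = 60, channels = .FRONTAL6) {
  stopifnot(is(epochs, "EpochSet"))
  idx <- .channelIndex(epochs@channelLabels, channels)
  nEp <- dim(epochs@data)[1L]
  flags <- rep(FALSE, nEp)
  for (i in idx) {
    sl <- epochs@data[, i, , drop = TRUE]          # epochs x time
    if (is.null(dim(sl))) sl <- matrix(sl, nrow = nEp)
    rng <- apply(sl, 1L, function(x) max(x) - min(x))
    flags <- flags | (rng > thresholdUV)
  }
  flags
}

#' Derive bipolar EOG channels
#'
#' EOGh (horizontal) = F9 - F10; EOGv (vertical) = Fp2 - EOGvu, sample-wise.
#'
#' @param x a \linkS4class{ContinuousRecording} or \linkS4class{EpochSet}.
#' @return List with \code{eogh} and \code{eogv}: numeric vectors for a
#'   recording, epochs x time matrices for an \code{EpochSet}.
#' @export
deriveBipolarEOG <- function(x) {
  lab <- channelLabels(x)
  idx <- .channelIndex(lab, c("F9", "F10", "Fp2", "EOGvu"))
  if (is(x, "ContinuousRecording")) {
    d <- x@data
    list(eogh = d[idx[1L], ] - d[idx[2L], ],
         eogv = d[idx[3L], ] - d[idx[4L], ])
  } else if (is(x, "EpochSet")) {
    d <- x@data
    list(eogh = d[, idx[1L], ] - d[, idx[2L], ],
         eogv = d[, idx[3L], ] - d[, idx[4L], ])
  } else stop("unsupported class: ", class(x))
}

#' Regression-based ocular artifact removal
#'
#' Estimates, per scalp channel, ordinary least-squares coefficients onto
#' the bipolar EOG channels [EOGh, EOGv] from all concatenated epoch
#' samples (stationary eye-pattern assumption; an intercept is included in
#' the fit) and subtracts the fitted EOG component everywhere. The EOGvu
#' channel itself is left untouched.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param eogh,eogv optional epochs x time matrices aligned with
#'   \code{epochs}; derived from the epochs themselves when NULL.
#' @return The cleaned \linkS4class{EpochSet}.
#' @export
regressOutEOG <- function(epochs, eogh = NULL, eogv = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  if (is.null(eogh) || is.null(eogv)) {
    eog <- deriveBipolarEOG(epochs)
    eogh <- eog$eogh
    eogv <- eog$eogv
  }
  h <- as.numeric(t(eogh))
  v <- as.numeric(t(eogv))
  if (stats::sd(h) == 0 || stats::sd(v) == 0 ||
      abs(stats::cor(h, v)) > 1 - 1e-10)
    stop("EOG regressors are rank deficient (EOGh and EOGv collinear)")
  X <- cbind(1, h, v)
  XtX <- crossprod(X)
  d <- dim(epochs@data)
  target <- setdiff(seq_len(d[2L]), match("EOGvu", epochs@channelLabels))
  target <- target[!is.na(target)]
  data <- epochs@data
  for (i in target) {
    y <- as.numeric(t(data[, i, ]))        # concatenated epochs
    beta <- solve(XtX, crossprod(X, y))
    fit <- beta[2L] * h + beta[3L] * v     # subtract EOG component only
    data[, i, ] <- data[, i, ] - matrix(fit, d[1L], d[3L], byrow = TRUE)
  }
  epochs@data <- data
  epochs
}

# per-epoch, per-channel variance over time: epochs x channels matrix
.epochChannelVariance <- function(epochs, channels = NULL) {
  lab <- epochs@channelLabels
  idx <- if (is.null(channels)) seq_along(lab)
         else .channelIndex(lab, channels)
  d <- dim(epochs@data)
  v <- matrix(0, d[1L], length(idx), dimnames = list(NULL, lab[idx]))
  for (k in seq_along(idx)) {
    sl <- epochs@data[, idx[k], , drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, nrow = d[1L])
    m <- rowMeans(sl)
    v[, k] <- rowSums((sl - m)^2) / (d[3L] - 1L)
  }
  v
}

#' Variance-based channel rejection
#'
#' Two rules over the per-epoch channel variances (scalp channels only):
#' the \emph{low} rule rejects a channel whose per-epoch variance falls
#' below \code{lowUV2} (default 0.25 µV², i.e. SD < 0.5 µV) in more than
#' \code{lowFrac} of the epochs; the \emph{high} rule computes one variance
#' per channel (mean of its per-epoch variances) and rejects channels whose
#' variance exceeds \code{highMult} times the difference between the 90th
#' and 10th percentile of the channel-variance distribution.
#'
#' @param epochs an \linkS4class{EpochSet} (at least 10 epochs).
#' @param lowUV2 low-variance threshold (µV²).
#' @param lowFrac fraction of epochs above which the low rule fires.
#' @param highMult multiplier of (P90 - P10) for the high rule.
#' @return data.frame with columns \code{label} and \code{reason}
#'   ("low_variance"/"high_variance"); zero rows when nothing is rejected.
#' @export
channelVarianceReject <- function(epochs, lowUV2 = 0.25, lowFrac = 0.10,
                                  highMult = 3) {
  stopifnot(is(epochs, "EpochSet"))
  if (nEpochs(epochs) < 10L) stop("need at least 10 epochs")
  scalp <- setdiff(epochs@channelLabels, "EOGvu")
  v <- .epochChannelVariance(epochs, scalp)
  lowBad <- colMeans(v < lowUV2) > lowFrac
  chanVar <- colMeans(v)
  q <- stats::quantile(chanVar, c(0.1, 0.9), names = FALSE)
  highBad <- chanVar > highMult * (q[2L] - q[1L])
  lowLab <- names(which(lowBad))
  highLab <- names(which(highBad & !lowBad))
  out <- data.frame(label = c(lowLab, highLab),
                    reason = c(rep("low_variance", length(lowLab)),
                               rep("high_variance", length(highLab))))
  if (nrow(out) >= length(scalp))
    stop("all channels rejected: degenerate data")
  out
}

#' Variance-based trial flagging
#'
#' One variance per epoch (mean of per-channel variances over the retained
#' scalp channels); an epoch is flagged when its variance exceeds
#' \code{highMult} times the difference between the 90th and 10th
#' percentile of the per-epoch variance distribution.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param highMult multiplier of (P90 - P10).
#' @param channels channels entering the per-epoch variance (default: all
#'   scalp channels not in \code{epochs@rejectedChannels}).
#' @return Logical vector, one flag per epoch.
#' @export
trialVarianceFlag <- function(epochs, highMult = 3, channels = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  if (is.null(channels)) {
    channels <- setdiff(epochs@channelLabels, "EOGvu")
    channels <- setdiff(channels, epochs@rejectedChannels$label)
  }
  v <- rowMeans(.epochChannelVariance(epochs, channels))
  q <- stats::quantile(v, c(0.1, 0.9), names = FALSE)
  v > highMult * (q[2L] - q[1L])
}

#' Run an artifact-rejection pipeline
#'
#' \strong{P1} applies peak-to-peak flagging (\code{\link{minmaxFlag}})
#' only and never modifies the data. \strong{P2} first regresses out the
#' bipolar EOG channels, then applies the channel variance criterion, the
#' trial variance criterion, and finally peak-to-peak flagging. A custom
#' cleaning function (signature \code{function(epochs) epochs}) may be
#' supplied via \code{cleaner} to slot in an alternative artifact handler.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param pipeline "P1" or "P2".
#' @param thresholdUV peak-to-peak threshold (µV).
#' @param cleaner optional replacement for the P2 EOG regression step.
#' @param dropFlagged if TRUE the returned EpochSet excludes flagged
#'   epochs; by default flagged epochs are retained (flags only) so that
#'   classification runs on identical epoch counts across pipelines.
#' @return List with \code{epochs} (flags filled in, data cleaned for P2)
#'   and \code{report} (an \linkS4class{ArtifactReport}).
#' @export
runArtifactPipeline <- function(epochs, pipeline = c("P1", "P2"),
                                thresholdUV = 60, cleaner = NULL,
                                dropFlagged = FALSE) {
  stopifnot(is(epochs, "EpochSet"))
  pipeline <- match.arg(pipeline)
  nEp <- nEpochs(epochs)
  flags <- data.frame(row.names = seq_len(nEp))[, 0, drop = FALSE]
  rej <- data.frame(label = character(), reason = character())

  if (pipeline == "P2") {
    epochs <- if (is.null(cleaner)) regressOutEOG(epochs) else cleaner(epochs)
    rej <- channelVarianceReject(epochs)
    epochs@rejectedChannels <- rej
    flags$trialVariance <- trialVarianceFlag(epochs)
  }
  flags$minmax60 <- minmaxFlag(epochs, thresholdUV = thresholdUV)

  any_ <- Reduce(`|`, flags, accumulate = FALSE)
  pf <- vapply(.CONDITIONS, function(cond) {
    sel <- epochs@info$condition == cond
    if (!any(sel)) return(NA_real_)
    100 * mean(any_[sel])
  }, numeric(1L))
  pf <- pf[!is.na(pf)]

  epochs@flags <- flags
  report <- new("ArtifactReport", pipeline = pipeline, flags = flags,
                rejectedChannels = rej, percentFlagged = pf)
  if (dropFlagged) epochs <- .subsetEpochs(epochs, !any_)
  list(epochs = epochs, report = report)
}

#' Write an artifact report as a tab-separated table
#'
#' @param report an \linkS4class{ArtifactReport}.
#' @param path output file path.
#' @param subject subject identifier written into the table.
#' @return Invisibly, \code{path}.
#' @export
writeArtifactReport <- function(report, path, subject = "S1") {
  stopifnot(is(report, "ArtifactReport"))
  df <- data.frame(subject = subject,
                   condition = names(report@percentFlagged),
                   pipeline = report@pipeline,
                   percentFlagged = unname(report@percentFlagged),
                   nRejectedChannels = nrow(report@rejectedChannels))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
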