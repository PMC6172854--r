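#' @include AllGenerics.R
NULL

.CONDITIONS <- c("EO", "EC")
.CLASSES <- c("target", "nontarget")

.EVENT_COLS <- c("onsetMs", "stimulusId", "speakerId", "isTarget",
                 "trialIndex", "runIndex", "condition")

#' SessionSchedule: stimulus bookkeeping of one AMUSE session
#'
#' Ordered stimulus events of a session of the six-speaker auditory oddball
#' paradigm: runs alternate between eyes-open (EO) and eyes-closed (EC),
#' each run holds six trials, each trial presents each of the six word
#' stimuli 15 times (SOA 250 ms) with one cued target stimulus per trial.
#'
#' @slot events data.frame of stimulus events (one row per stimulus
#'   presentation) with columns \code{onsetMs}, \code{stimulusId},
#'   \code{speakerId}, \code{isTarget}, \code{trialIndex}, \code{runIndex},
#'   \code{condition}.
#' @slot runConditions named character vector, condition ("EO"/"EC") per run.
#' @slot soaMs stimulus onset asynchrony in ms.
#' @slot seed integer seed the schedule was generated from.
#' @slot params list of scheduling parameters (gaps, counts).
#' @export
setClass("SessionSchedule",
  representation(events = "data.frame", runConditions = "character",
                 soaMs = "numeric", seed = "integer", params = "list"))

setValidity("SessionSchedule", function(object) {
  ev <- object@events
  msg <- character()
  if (!all(.EVENT_COLS %in% names(ev)))
    msg <- c(msg, paste("events must have columns:",
                        paste(.EVENT_COLS, collapse = ", ")))
  else {
    if (nrow(ev) > 0L) {
      if (any(ev$onsetMs < 0)) msg <- c(msg, "onsetMs must be non-negative")
      if (is.unsorted(ev$onsetMs)) msg <- c(msg, "events must be time-ordered")
      if (!all(ev$stimulusId %in% 1:6)) msg <- c(msg, "stimulusId must be in 1..6")
      if (!all(ev$condition %in% .CONDITIONS))
        msg <- c(msg, "condition must be EO or EC")
      # consecutive events of a trial sit exactly one SOA apart
      key <- paste(ev$runIndex, ev$trialIndex)
      d <- diff(ev$onsetMs)
      same <- key[-1L] == key[-length(key)]
      if (any(same) && any(abs(d[same] - object@soaMs) > 1e-9))
        msg <- c(msg, "within-trial inter-onset interval must equal soaMs")
    }
  }
  rc <- object@runConditions
  if (length(rc) > 1L && any(rc[-1L] == rc[-length(rc)]))
    msg <- c(msg, "runConditions must strictly alternate")
  if (length(msg)) msg else TRUE
})

#' SubjectProfile: generative parameters of one synthetic subject
#'
#' Condition-resolved ERP component parameters (N200/P300 latency and
#' amplitude), component widths, background-noise level, occipital alpha
#' amplitude and ocular-artifact rates used by the synthetic EEG generator.
#' Per-condition slots are length-2 named numerics (\code{EO}, \code{EC}).
#'
#' @slot n200LatencyMs,n200AmpUV,p300LatencyMs,p300AmpUV per-condition
#'   component peak latency (ms) and amplitude (µV); N200 amplitude is
#'   non-positive, P300 non-negative.
#' @slot sigmaN200Ms,sigmaP300Ms Gaussian temporal widths (ms).
#' @slot noiseSdUV background noise standard deviation (µV).
#' @slot alphaAmpUV per-condition 10 Hz occipital alpha amplitude (µV).
#' @slot blinkRateHz,saccadeRateHz per-condition Poisson artifact rates (Hz).
#' @slot blinkAmpUV,saccadeAmpUV artifact peak amplitudes (µV).
#' @slot attenN200,attenP300 multiplicative attenuation of the two
#'   components on non-target epochs.
#' @slot seed integer seed the profile was drawn from.
#' @export
setClass("SubjectProfile",
  representation(n200LatencyMs = "numeric", n200AmpUV = "numeric",
                 p300LatencyMs = "numeric", p300AmpUV = "numeric",
                 sigmaN200Ms = "numeric", sigmaP300Ms = "numeric",
                 noiseSdUV = "numeric", alphaAmpUV = "numeric",
                 blinkRateHz = "numeric", saccadeRateHz = "numeric",
                 blinkAmpUV = "numeric", saccadeAmpUV = "numeric",
                 attenN200 = "numeric", attenP300 = "numeric",
                 seed = "integer"))

setValidity("SubjectProfile", function(object) {
  msg <- character()
  perCond <- c("n200LatencyMs", "n200AmpUV", "p300LatencyMs", "p300AmpUV",
               "alphaAmpUV", "blinkRateHz", "saccadeRateHz")
  for (s in perCond) {
    v <- slot(object, s)
    if (length(v) != 2L || !identical(sort(names(v)), sort(.CONDITIONS)))
      msg <- c(msg, paste0(s, " must be a length-2 numeric named EO/EC"))
  }
  if (!length(msg)) {
    lat <- c(object@n200LatencyMs, object@p300LatencyMs)
    if (any(lat < 0 | lat > 1200))
      msg <- c(msg, "latencies must lie within the epoch window [0, 1200] ms")
    if (any(object@n200AmpUV > 0)) msg <- c(msg, "n200AmpUV must be <= 0")
    if (any(object@p300AmpUV < 0)) msg <- c(msg, "p300AmpUV must be >= 0")
    if (any(c(object@blinkRateHz, object@saccadeRateHz, object@alphaAmpUV) < 0))
      msg <- c(msg, "rates and alpha amplitude must be >= 0")
    if (object@noiseSdUV < 0) msg <- c(msg, "noiseSdUV must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' ContinuousRecording: multichannel EEG trace with event markers
#'
#' Channels-by-samples matrix in µV (63 scalp channels of the 10-20 system
#' plus the EOGvu electrode below the right eye), a sampling rate and the
#' stimulus events of the session.
#'
#' @slot data numeric matrix, channels x samples (µV), rownames = labels.
#' @slot channelLabels character vector of channel labels.
#' @slot fsHz sampling rate (Hz).
#' @slot events data.frame of stimulus events (see
#'   \linkS4class{SessionSchedule}).
#' @slot meta list of provenance (seeds, generator settings).
#' @export
setClass("ContinuousRecording",
  representation(data = "matrix", channelLabels = "character",
                 fsHz = "numeric", events = "data.frame", meta = "list"))

setValidity("ContinuousRecording", function(object) {
  msg <- character()
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "data row count must equal channel label count")
  if (length(object@fsHz) != 1L || object@fsHz <= 0)
    msg <- c(msg, "fsHz must be a positive scalar")
  if (nrow(object@events) > 0L) {
    durMs <- ncol(object@data) / object@fsHz * 1000
    if (any(object@events$onsetMs >= durMs))
      msg <- c(msg, "all event onsets must fall inside the recording")
  }
  if (length(msg)) msg else TRUE
})

#' EpochSet: stimulus-locked epochs with labels and artifact flags
#'
#' Epochs x channels x time tensor (µV) cut around stimulus onsets,
#' baseline-corrected, together with per-epoch class labels, paradigm
#' bookkeeping and artifact flags. Flagging never removes epochs.
#'
#' @slot data numeric 3-D array, epochs x channels x time.
#' @slot timeMs numeric vector of sample times relative to onset (ms).
#' @slot channelLabels character channel labels (2nd dimension).
#' @slot fsHz sampling rate of the epoch grid (Hz).
#' @slot info data.frame, one row per epoch: \code{label}
#'   ("target"/"nontarget"), \code{condition}, \code{trialIndex},
#'   \code{runIndex}, \code{stimulusId}, \code{onsetMs}.
#' @slot flags data.frame of logical per-epoch flags, one column per
#'   criterion (e.g. \code{minmax60}, \code{trialVariance}).
#' @slot rejectedChannels data.frame (label, reason) of channels set aside
#'   by the variance criterion.
#' @export
setClass("EpochSet",
  representation(data = "array", timeMs = "numeric",
                 channelLabels = "character", fsHz = "numeric",
                 info = "data.frame", flags = "data.frame",
                 rejectedChannels = "data.frame"))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-D array")
  else {
    if (d[2L] != length(object@channelLabels))
      msg <- c(msg, "dim 2 must match channelLabels")
    if (d[3L] != length(object@timeMs))
      msg <- c(msg, "dim 3 must match timeMs")
    if (nrow(object@info) != d[1L])
      msg <- c(msg, "info must have one row per epoch")
    if (nrow(object@flags) > 0L && nrow(object@flags) != d[1L])
      msg <- c(msg, "flags must have one row per epoch")
    if (!all(object@info$label %in% .CLASSES))
      msg <- c(msg, "labels must be 'target' or 'nontarget'")
  }
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: interval-mean features per epoch
#'
#' @slot values numeric matrix, epochs x d (d = channels x intervals),
#'   channel-major column order.
#' @slot intervalBoundsMs list of [start, end] pairs (ms).
#' @slot channelLabels channels the features were extracted from.
#' @slot info per-epoch metadata (as in \linkS4class{EpochSet}).
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", intervalBoundsMs = "list",
                 channelLabels = "character", info = "data.frame"))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  d <- length(object@channelLabels) * length(object@intervalBoundsMs)
  if (ncol(object@values) != d)
    msg <- c(msg, "ncol(values) must equal channels x intervals")
  if (nrow(object@info) != nrow(object@values))
    msg <- c(msg, "info must have one row per epoch")
  if (length(msg)) msg else TRUE
})

#' LDAModel: shrinkage-regularized linear discriminant
#'
#' Binary linear classifier whose pooled within-class covariance is shrunk
#' toward a scaled identity, \eqn{\tilde\Sigma = (1-\gamma)\hat\Sigma +
#' \gamma\nu I} with \eqn{\nu = tr(\hat\Sigma)/d}, and whose weight vector
#' is \eqn{w = \tilde\Sigma^{-1}(\mu_+ - \mu_-)}.
#'
#' @slot weights length-d numeric weight vector.
#' @slot bias scalar offset; scores are \code{w'x + bias}.
#' @slot gamma shrinkage intensity in [0, 1].
#' @slot classMeans d x 2 matrix, columns \code{target}, \code{nontarget}.
#' @slot covShrunk d x d shrunk covariance.
#' @export
setClass("LDAModel",
  representation(weights = "numeric", bias = "numeric", gamma = "numeric",
                 classMeans = "matrix", covShrunk = "matrix"))

setValidity("LDAModel", function(object) {
  msg <- character()
  if (object@gamma < 0 || object@gamma > 1)
    msg <- c(msg, "gamma must lie in [0, 1]")
  d <- length(object@weights)
  if (!identical(dim(object@classMeans), c(d, 2L)))
    msg <- c(msg, "classMeans must be d x 2")
  if (!identical(dim(object@covShrunk), c(d, d)))
    msg <- c(msg, "covShrunk must be d x d")
  if (length(msg)) msg else TRUE
})

#' TransferCurve: AUC trace of a simulated condition switch
#'
#' @slot scenario length-2 character, pre- and post-transition condition.
#' @slot aucByStep mean AUC per number of post-transition trials added
#'   (step 0 = classifier trained on pre-transition data only).
#' @slot perSeed numeric matrix, seeds x steps, individual traces.
#' @slot nSeeds number of random repetitions.
#' @export
setClass("TransferCurve",
  representation(scenario = "character", aucByStep = "numeric",
                 perSeed = "matrix", nSeeds = "integer"))

setValidity("TransferCurve", function(object) {
  msg <- character()
  if (any(object@aucByStep < 0 | object@aucByStep > 1))
    msg <- c(msg, "AUC values must lie in [0, 1]")
  if (ncol(object@perSeed) != length(object@aucByStep))
    msg <- c(msg, "perSeed columns must match aucByStep length")
  if (nrow(object@perSeed) != object@nSeeds)
    msg <- c(msg, "perSeed rows must match nSeeds")
  if (max(abs(colMeans(object@perSeed) - object@aucByStep)) > 1e-8)
    msg <- c(msg, "aucByStep must equal the mean of per-seed traces")
  if (length(msg)) msg else TRUE
})

#' ArtifactReport: outcome of an artifact-rejection pipeline
#'
#' @slot pipeline "P1" or "P2".
#' @slot flags per-epoch logical flags by criterion.
#' @slot rejectedChannels data.frame (label, reason).
#' @slot percentFlagged named numeric, percent of epochs with any flag,
#'   per condition.
#' @export
setClass("ArtifactReport",
  representation(pipeline = "character", flags = "data.frame",
                 rejectedChannels = "data.frame",
                 percentFlagged = "numeric"))

setValidity("ArtifactReport", function(object) {
  msg <- character()
  if (any(object@percentFlagged < 0 | object@percentFlagged > 100))
    msg <- c(msg, "percentFlagged must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' TestResult: outcome of one statistical test
#'
#' @slot statName name of the statistic (e.g. "t", "W", "k").
#' @slot statistic statistic value.
#' @slot pRaw raw p-value.
#' @slot pAdjusted multiplicity-adjusted p-value (NA if not adjusted).
#' @slot n sample size the test was computed on.
#' @slot sidedness "two.sided", "greater" or "less".
#' @export
setClass("TestResult",
  representation(statName = "character", statistic = "numeric",
                 pRaw = "numeric", pAdjusted = "numeric", n = "integer",
                 sidedness = "character"))

setValidity("TestResult", function(object) {
  msg <- character()
  ps <- c(object@pRaw, object@pAdjusted)
  ps <- ps[!is.na(ps)]
  if (any(ps < 0 | ps > 1)) msg <- c(msg, "p-values must lie in [0, 1]")
  if (!is.na(object@pAdjusted) && object@pAdjusted < object@pRaw - 1e-12)
    msg <- c(msg, "pAdjusted must be >= pRaw")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @rdname events
#' @export
setMethod("events", "SessionSchedule", function(x) x@events)

#' @rdname events
#' @export
setMethod("events", "ContinuousRecording", function(x) x@events)

#' @rdname channelLabels
#' @export
setMethod("channelLabels", "ContinuousRecording", function(x) x@channelLabels)

#' @rdname channelLabels
#' @export
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)

#' @rdname channelLabels
#' @export
setMethod("channelLabels", "FeatureMatrix", function(x) x@channelLabels)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "ContinuousRecording", function(x) x@fsHz)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fsHz)

#' @rdname runConditions
#' @export
setMethod("runConditions", "SessionSchedule", function(x) x@runConditions)

#' @rdname epochInfo
#' @export
setMethod("epochInfo", "EpochSet", function(x) x@info)

#' @rdname epochInfo
#' @export
setMethod("epochInfo", "FeatureMatrix", function(x) x@info)

#' @rdname epochFlags
#' @export
setMethod("epochFlags", "EpochSet", function(x) x@flags)

#' @rdname nEpochs
#' @export
setMethod("nEpochs", "EpochSet", function(x) dim(x@data)[1L])

#' @rdname nEpochs
#' @export
setMethod("nEpochs", "FeatureMatrix", function(x) nrow(x@values))

#' @rdname epochTimes
#' @export
setMethod("epochTimes", "EpochSet", function(x) x@timeMs)

#' Raw numeric content of a container
#'
#' @param x a \linkS4class{ContinuousRecording}, \linkS4class{EpochSet},
#'   \linkS4class{FeatureMatrix} or \linkS4class{LDAModel}.
#' @return The underlying matrix/array (channels x samples for recordings,
#'   epochs x channels x time for epoch sets, epochs x d for features).
#' @export
values <- function(x) {
  if (is(x, "ContinuousRecording") || is(x, "EpochSet")) x@data
  else if (is(x, "FeatureMatrix")) x@values
  else stop("no values() accessor for class ", class(x))
}

#' LDA model components
#' @param model an \linkS4class{LDAModel}.
#' @return \code{ldaWeights}: the weight vector; \code{ldaBias}: the scalar
#'   offset; \code{ldaGamma}: the shrinkage intensity.
#' @export
ldaWeights <- function(model) model@weights

#' @rdname ldaWeights
#' @export
ldaBias <- function(model) model@bias

#' @rdname ldaWeights
#' @export
ldaGamma <- function(model) model@gamma

## ---- subsetting ----

#' @rdname subsetRuns
#' @export
setMethod("subsetRuns", "SessionSchedule", function(x, runs) {
  runs <- sort(unique(as.integer(runs)))
  ev <- x@events[x@events$runIndex %in% runs, , drop = FALSE]
  rownames(ev) <- NULL
  initialize(x, events = ev, runConditions = x@runConditions[runs])
})

#' @rdname subsetRuns
#' @export
setMethod("subsetRuns", "EpochSet", function(x, runs) {
  keep <- x@info$runIndex %in% as.integer(runs)
  .subsetEpochs(x, keep)
})

.subsetEpochs <- function(x, keep) {
  flags <- x@flags
  if (nrow(flags)) flags <- flags[keep, , drop = FALSE]
  info <- x@info[keep, , drop = FALSE]
  rownames(info) <- NULL
  initialize(x, data = x@data[keep, , , drop = FALSE], info = info,
             flags = flags)
}

#' @rdname selectChannels
#' @export
setMethod("selectChannels", "ContinuousRecording", function(x, channels) {
  idx <- .channelIndex(x@channelLabels, channels)
  initialize(x, data = x@data[idx, , drop = FALSE],
             channelLabels = x@channelLabels[idx])
})

#' @rdname selectChannels
#' @export
setMethod("selectChannels", "EpochSet", function(x, channels) {
  idx <- .channelIndex(x@channelLabels, channels)
  initialize(x, data = x@data[, idx, , drop = FALSE],
             channelLabels = x@channelLabels[idx])
})

#' Row-subset a FeatureMatrix
#'
#' @param x a \linkS4class{FeatureMatrix}.
#' @param i epoch (row) index: integer, logical or negative subscripts.
#' @param j,...,drop ignored (features are never column-subset).
#' @return A \linkS4class{FeatureMatrix} with the selected epochs.
#' @export
setMethod("[", "FeatureMatrix", function(x, i, j, ..., drop = FALSE) {
  info <- x@info[i, , drop = FALSE]
  rownames(info) <- NULL
  initialize(x, values = x@values[i, , drop = FALSE], info = info)
})

.channelIndex <- function(labels, channels) {
  idx <- match(channels, labels)
  if (anyNA(idx))
    stop("channel(s) not present: ", paste(channels[is.na(idx)], collapse = ", "))
  idx
}

## ---- show methods ----

setMethod("show", "SessionSchedule", function(object) {
  cat("SessionSchedule:", length(object@runConditions), "runs,",
      nrow(object@events), "stimulus events, SOA", object@soaMs, "ms\n")
  if (length(object@runConditions))
    cat("  conditions:", paste(object@runConditions, collapse = " "), "\n")
})

setMethod("show", "SubjectProfile", function(object) {
  cat("SubjectProfile (seed", object@seed, ")\n")
  for (cond in .CONDITIONS)
    cat(sprintf("  %s: N200 %.0f ms / %.2f uV, P300 %.0f ms / %.2f uV, alpha %.1f uV\n",
                cond, object@n200LatencyMs[cond], object@n200AmpUV[cond],
                object@p300LatencyMs[cond], object@p300AmpUV[cond],
                object@alphaAmpUV[cond]))
  cat(sprintf("  noise sd %.2f uV, blink %.2f/%.2f Hz, saccade %.2f/%.2f Hz\n",
              object@noiseSdUV, object@blinkRateHz["EO"], object@blinkRateHz["EC"],
              object@saccadeRateHz["EO"], object@saccadeRateHz["EC"]))
})

setMethod("show", "ContinuousRecording", function(object) {
  cat(sprintf("ContinuousRecording: %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(object@data), ncol(object@data), object@fsHz,
              ncol(object@data) / object@fsHz, nrow(object@events)))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d epochs x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], object@fsHz))
  cat(sprintf("  window [%g, %g] ms; %d target / %d nontarget\n",
              min(object@timeMs), max(object@timeMs),
              sum(object@info$label == "target"),
              sum(object@info$label == "nontarget")))
  if (ncol(object@flags))
    cat("  flags:", paste(sprintf("%s=%d", names(object@flags),
                                  colSums(object@flags)), collapse = ", "), "\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d epochs x %d features (%d channels x %d intervals)\n",
              nrow(object@values), ncol(object@values),
              length(object@channelLabels), length(object@intervalBoundsMs)))
})

setMethod("show", "LDAModel", function(object) {
  cat(sprintf("LDAModel: d = %d, gamma = %.4f\n",
              length(object@weights), object@gamma))
})

setMethod("show", "TransferCurve", function(object) {
  cat(sprintf("TransferCurve %s -> %s: %d steps, %d seeds; AUC %.3f (step 0) -> %.3f (last)\n",
              object@scenario[1L], object@scenario[2L],
              length(object@aucByStep), object@nSeeds,
              object@aucByStep[1L], object@aucByStep[length(object@aucByStep)]))
})

setMethod("show", "ArtifactReport", function(object) {
  cat("ArtifactReport, pipeline", object@pipeline, "\n")
  cat("  percent flagged:",
      paste(sprintf("%s=%.1f%%", names(object@percentFlagged),
                    object@percentFlagged), collapse = ", "), "\n")
  if (nrow(object@rejectedChannels))
    cat("  rejected channels:",
        paste(object@rejectedChannels$label, collapse = ", "), "\n")
})

setMethod("show", "TestResult", function(object) {
  cat(sprintf("TestResult: %s = %.4g, p = %.4g%s (n = %d, %s)\n",
              object@statName, object@statistic, object@pRaw,
              if (is.na(object@pAdjusted)) ""
              else sprintf(", p.adj = %.4g", object@pAdjusted),
              object@n, object@sidedness))
})

#' Flatten a TestResult to a one-row data.frame
#' @param result a \linkS4class{TestResult}.
#' @return A one-row \code{data.frame}.
#' @export
asDataFrame <- function(result) {
  stopifnot(is(result, "TestResult"))
  data.frame(statistic = result@statName, value = result@statistic,
             pRaw = result@pRaw, pAdjusted = result@pAdjusted,
             n = result@n, sidedness = result@sidedness)
}
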