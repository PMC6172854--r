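#' @import methods
NULL

#' Event table of a schedule or recording
#'
#' @param x a \linkS4class{SessionSchedule} or \linkS4class{ContinuousRecording}.
#' @return A \code{data.frame} of stimulus events with columns
#'   \code{onsetMs}, \code{stimulusId}, \code{speakerId}, \code{isTarget},
#'   \code{trialIndex}, \code{runIndex}, \code{condition}.
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' Channel labels
#' @param x an object holding multichannel data.
#' @return Character vector of channel labels.
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' Sampling rate in Hz
#' @param x an object with a sampling rate.
#' @return Numeric scalar (Hz).
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' Run conditions of a session schedule
#' @param x a \linkS4class{SessionSchedule}.
#' @return Character vector ("EO"/"EC"), one entry per run.
#' @export
setGeneric("runConditions", function(x) standardGeneric("runConditions"))

#' Restrict an object to a subset of runs
#' @param x a \linkS4class{SessionSchedule} or \linkS4class{EpochSet}.
#' @param runs integer vector of run indices to keep.
#' @return Object of the same class restricted to the selected runs.
#' @export
setGeneric("subsetRuns", function(x, runs) standardGeneric("subsetRuns"))

#' Restrict multichannel data to a subset of channels
#' @param x a \linkS4class{ContinuousRecording} or \linkS4class{EpochSet}.
#' @param channels character vector of channel labels to keep.
#' @return Object of the same class with only the selected channels.
#' @export
setGeneric("selectChannels", function(x, channels) standardGeneric("selectChannels"))

#' Per-epoch metadata
#' @param x an \linkS4class{EpochSet} or \linkS4class{FeatureMatrix}.
#' @return A \code{data.frame} with one row per epoch (label, condition,
#'   trial/run indices, stimulus bookkeeping).
#' @export
setGeneric("epochInfo", function(x) standardGeneric("epochInfo"))

#' Per-epoch artifact flags
#' @param x an \linkS4class{EpochSet}.
#' @return A \code{data.frame} of logical columns, one row per epoch.
#' @export
setGeneric("epochFlags", function(x) standardGeneric("epochFlags"))

#' Number of epochs
#' @param x an \linkS4class{EpochSet} or \linkS4class{FeatureMatrix}.
#' @return Integer scalar.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' Epoch time axis
#' @param x an \linkS4class{EpochSet}.
#' @return Numeric vector of sample times in ms relative to stimulus onset.
#' @export
setGeneric("epochTimes", function(x) standardGeneric("epochTimes"))
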