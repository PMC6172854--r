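# Shared fixtures, built once per test run and cached in-process. All
# synthetic sessions are generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# drop all cached fixtures (used before the memory-heavy full-session run)
clearFixtures <- function() {
  rm(list = ls(envir = .fixtures), envir = .fixtures)
  invisible(gc(FALSE))
}

# group-mean ERP parameters of the published 12-subject reference table
meanProfileOverrides <- function() {
  list(n200LatencyMs = c(EO = 201, EC = 206),
       n200AmpUV = c(EO = -1.53, EC = -1.59),
       p300LatencyMs = c(EO = 690, EC = 523),
       p300AmpUV = c(EO = 1.71, EC = 1.95))
}

quietOverrides <- function(noiseSdUV = 0.5) {
  list(noiseSdUV = noiseSdUV, blinkRateHz = 0, saccadeRateHz = 0,
       alphaAmpUV = 0)
}

# merge override lists left to right (later entries win)
mergeOv <- function(...) {
  out <- list()
  for (l in list(...)) for (nm in names(l)) out[[nm]] <- l[[nm]]
  out
}

# small clean session: 4 runs, mean profile, modest noise, no artifacts
cleanSession <- function() fixture("cleanSession", function() {
  sched <- subsetRuns(buildSessionSchedule("EO", seed = 7), 1:4)
  prof <- makeSubjectProfile(1, overrides = c(meanProfileOverrides(),
                                              quietOverrides(2)))
  syn <- synthesizeSession(sched, prof, seed = 11)
  list(schedule = sched, profile = prof, recording = syn$recording,
       artifactLog = syn$artifactLog)
})

cleanEpochs <- function() fixture("cleanEpochs", function() {
  preprocessRecording(cleanSession()$recording)
})

# latency-shift session for the transfer experiments: conditions share
# component amplitudes and differ only by the published mean latencies;
# reduced montage keeps repeated LDA retraining fast
transferFeatures <- function() fixture("transferFeatures", function() {
  sched <- subsetRuns(buildSessionSchedule("EO", seed = 41), 1:8)
  prof <- makeSubjectProfile(1, overrides = list(
    n200LatencyMs = c(EO = 201, EC = 206), n200AmpUV = -1.5,
    p300LatencyMs = c(EO = 690, EC = 523), p300AmpUV = 1.8,
    noiseSdUV = 2, alphaAmpUV = 0, blinkRateHz = 0, saccadeRateHz = 0))
  rec <- synthesizeSession(sched, prof, seed = 42)$recording
  ep <- preprocessRecording(rec)
  ep <- selectChannels(ep, c("Fz", "F3", "F4", "FCz", "FC1", "FC2", "Cz",
                             "C3", "C4", "CPz", "CP1", "CP2", "Pz", "P3",
                             "P4", "POz"))
  extractIntervalMeans(ep, channels = channelLabels(ep))
})

# blink-heavy session (no other artifact sources) for the P1-vs-P2 contrast
blinkHeavyEpochs <- function() fixture("blinkHeavyEpochs", function() {
  sched <- subsetRuns(buildSessionSchedule("EO", seed = 21), 1:2)
  prof <- makeSubjectProfile(1, overrides = c(meanProfileOverrides(),
            list(noiseSdUV = 2, alphaAmpUV = 0, saccadeRateHz = 0,
                 blinkRateHz = 0.4, blinkAmpUV = 120)))
  rec <- synthesizeSession(sched, prof, seed = 22)$recording
  preprocessRecording(rec)
})

# tiny single-channel-style recording builder for filter/epoching tests
toyRecording <- function(data, fsHz = 1000, labels = NULL, events = NULL) {
  if (is.null(dim(data))) data <- matrix(data, nrow = 1L)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  rownames(data) <- labels
  if (is.null(events))
    events <- data.frame(onsetMs = numeric(), stimulusId = integer(),
                         speakerId = integer(), isTarget = logical(),
                         trialIndex = integer(), runIndex = integer(),
                         condition = character())
  new("ContinuousRecording", data = data, channelLabels = labels,
      fsHz = fsHz, events = events, meta = list())
}

# hand-built EpochSet: epochs x channels x time array plus labels
toyEpochs <- function(data, timeMs = NULL, labels = NULL, fsHz = 100,
                      channelLabels = NULL, condition = NULL) {
  d <- dim(data)
  if (is.null(timeMs)) timeMs <- seq(-200, by = 1000 / fsHz,
                                     length.out = d[3L])
  if (is.null(channelLabels)) channelLabels <- paste0("ch", seq_len(d[2L]))
  if (is.null(labels))
    labels <- rep(c("target", "nontarget"), length.out = d[1L])
  if (is.null(condition)) condition <- rep("EO", d[1L])
  info <- data.frame(label = labels, condition = condition,
                     trialIndex = rep(1L, d[1L]),
                     runIndex = rep(1L, d[1L]),
                     stimulusId = rep(1L, d[1L]),
                     onsetMs = seq_len(d[1L]) * 250)
  new("EpochSet", data = data, timeMs = timeMs,
      channelLabels = channelLabels, fsHz = fsHz, info = info,
      flags = data.frame(row.names = seq_len(d[1L]))[, 0, drop = FALSE],
      rejectedChannels = data.frame(label = character(),
                                    reason = character()))
}
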