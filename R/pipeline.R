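#' Analysis configuration with documented defaults
#'
#' Central bundle of every tunable of the pipeline, initialized to the
#' paradigm's published values where one exists (band edges, epoch and
#' baseline windows, 60 µV peak-to-peak threshold, variance-rule
#' constants, the eight feature intervals, 5 folds, 18/36-trial transfer
#' split, 20 seeds) and to the package's documented defaults elsewhere.
#' Override any entry by name; unknown names error.
#'
#' @param ... named overrides of top-level entries (lists are merged).
#' @return Named list (class "amuseConfig").
#' @export
amuseConfig <- function(...) {
  cfg <- list(
    masterSeed = 1L,
    schedule = list(nRuns = 18L, soaMs = 250, interTrialGapMs = 6000,
                    interRunGapMs = 10000),
    filter = list(lowHz = 0.5, highHz = 8, order = 5L, stopbandDb = 40),
    fsOut = 100,
    epoch = list(windowMs = c(-200, 1200), baselineMs = c(-200, 50)),
    artifact = list(thresholdUV = 60, lowUV2 = 0.25, lowFrac = 0.10,
                    highMult = 3),
    features = list(intervalsMs = .DEFAULT_INTERVALS),
    cv = list(k = 5L),
    lda = list(gamma = "auto"),
    transfer = list(nTrain = 18L, nPost = 36L, nSeeds = 20L),
    peaks = list(windows = .DEFAULT_PEAK_WINDOWS,
                 channels = .DEFAULT_PEAK_CHANNELS))
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config entr(ies): ", paste(bad, collapse = ", "))
  for (nm in names(ov))
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(ov[[nm]]))
      utils::modifyList(cfg[[nm]], ov[[nm]]) else ov[[nm]]
  class(cfg) <- c("amuseConfig", "list")
  cfg
}

#' Write / read a configuration as YAML
#'
#' Lossless round-trip of an \code{\link{amuseConfig}} (requires the
#' suggested \pkg{yaml} package).
#'
#' @param config an "amuseConfig" list.
#' @param path file path.
#' @return \code{writeConfig} invisibly returns \code{path};
#'   \code{readConfig} returns the configuration.
#' @export
writeConfig <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for YAML config files")
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname writeConfig
#' @export
readConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required for YAML config files")
  raw <- yaml::read_yaml(path)
  do.call(amuseConfig, raw[setdiff(names(raw), character())])
}

#' Simulate one subject's full session
#'
#' Convenience wrapper chaining schedule construction, subject-profile
#' sampling and recording synthesis under a single master seed (child
#' seeds are derived deterministically, so equal master seeds give
#' bit-identical sessions).
#'
#' @param seed master seed.
#' @param firstCondition condition of run 1.
#' @param profileOverrides passed to \code{\link{makeSubjectProfile}}.
#' @param nRuns number of runs (default 18; smaller values give reduced
#'   sessions for quick experiments).
#' @param config an \code{\link{amuseConfig}} (schedule gaps, SOA).
#' @return List with \code{schedule}, \code{profile}, \code{recording},
#'   \code{artifactLog}.
#' @export
simulateSubjectSession <- function(seed = 1L, firstCondition = "EO",
                                   profileOverrides = list(),
                                   nRuns = NULL, config = amuseConfig()) {
  sc <- config$schedule
  if (is.null(nRuns)) nRuns <- sc$nRuns
  schedule <- buildSessionSchedule(firstCondition, seed = childSeed(seed, 11L),
                                   nRuns = nRuns, soaMs = sc$soaMs,
                                   interTrialGapMs = sc$interTrialGapMs,
                                   interRunGapMs = sc$interRunGapMs)
  profile <- makeSubjectProfile(seed = childSeed(seed, 12L),
                                overrides = profileOverrides)
  syn <- synthesizeSession(schedule, profile, seed = childSeed(seed, 13L))
  list(schedule = schedule, profile = profile, recording = syn$recording,
       artifactLog = syn$artifactLog)
}

#' Full offline analysis of one recording
#'
#' Runs the standard chain on a recording with event bookkeeping:
#' band-pass filter, downsample, epoch + baseline, artifact pipeline (P1
#' or P2), chronological cross-validated AUC per condition, grand
#' averages, signed r-squared map, and N200/P300 peak extraction from the
#' per-condition target averages.
#'
#' @param recording a \linkS4class{ContinuousRecording}.
#' @param pipeline "P1" or "P2".
#' @param config an \code{\link{amuseConfig}}.
#' @param subject subject identifier for the output tables.
#' @return List with \code{epochs}, \code{artifactReport},
#'   \code{aucTable} (condition x fold), \code{peaks} (one row per
#'   condition), \code{grandAverages}, \code{signedR2}.
#' @export
analyzeSession <- function(recording, pipeline = "P2",
                           config = amuseConfig(), subject = "S1") {
  ep <- preprocessRecording(recording,
                            lowHz = config$filter$lowHz,
                            highHz = config$filter$highHz,
                            fsOut = config$fsOut,
                            windowMs = config$epoch$windowMs,
                            baselineMs = config$epoch$baselineMs)
  rm(recording)                     # hour-long raw sessions are large
  invisible(gc(FALSE))
  art <- runArtifactPipeline(ep, pipeline = pipeline,
                             thresholdUV = config$artifact$thresholdUV)
  ep <- art$epochs
  aucTable <- classifyByCondition(ep, k = config$cv$k,
                                  gamma = config$lda$gamma,
                                  pipeline = pipeline, subject = subject)
  ga <- grandAverage(ep, by = c("label", "condition"))
  timeMs <- attr(ga, "timeMs")
  peaks <- do.call(rbind, lapply(intersect(.CONDITIONS,
                                           unique(ep@info$condition)),
    function(cond) {
      avg <- ga[[paste("target", cond, sep = ".")]]
      cbind(subject = subject, condition = cond,
            detectPeaks(avg, timeMs, windows = config$peaks$windows,
                        channels = config$peaks$channels))
    }))
  list(epochs = ep, artifactReport = art$report, aucTable = aucTable,
       peaks = peaks, grandAverages = ga, signedR2 = signedRSquared(ep))
}
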