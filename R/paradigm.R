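#' Build the stimulus schedule of one AMUSE session
#'
#' Constructs the full event bookkeeping of a session of the six-speaker
#' auditory oddball paradigm: \code{nRuns} runs strictly alternating between
#' eyes-open (EO) and eyes-closed (EC), six trials per run, and per trial a
#' pseudo-randomized sequence of 90 word stimuli (each of the six stimuli
#' exactly 15 times, SOA 250 ms). Within a run each stimulus is the cued
#' target of exactly one trial (target order is a seeded permutation), and
#' the stimulus-to-speaker assignment is a seeded permutation fixed for the
#' session. The default 18-run session therefore yields, per condition,
#' 54 trials, 810 target and 4050 non-target events.
#'
#' Only relative onsets matter for the downstream analysis; the cue/pause
#' structure between trials and runs is summarized by two configurable gaps.
#'
#' @param firstCondition condition of run 1 ("EO" or "EC"); subsequent runs
#'   alternate.
#' @param seed integer seed; fully determines stimulus order, target order
#'   and speaker mapping.
#' @param nRuns number of runs (default 18).
#' @param soaMs stimulus onset asynchrony in ms (default 250).
#' @param interTrialGapMs silent gap between the last stimulus of a trial
#'   and the first of the next (default 6000 ms, covering the cue).
#' @param interRunGapMs additional gap between runs (default 10000 ms).
#' @param leadInMs silence before the first stimulus (default 3000 ms),
#'   so the first epoch's pre-stimulus window exists.
#' @return A \linkS4class{SessionSchedule}.
#' @examples
#' sched <- buildSessionSchedule("EO", seed = 1)
#' countEvents(sched, "EO")   # 810 targets, 4050 non-targets, 54 trials
#' @export
buildSessionSchedule <- function(firstCondition = c("EO", "EC"), seed = 1L,
                                 nRuns = 18L, soaMs = 250,
                                 interTrialGapMs = 6000,
                                 interRunGapMs = 10000, leadInMs = 3000) {
  firstCondition <- match.arg(firstCondition)
  seed <- as.integer(seed)
  nRuns <- as.integer(nRuns)
  stopifnot(nRuns >= 1L, soaMs > 0, interTrialGapMs >= 0, interRunGapMs >= 0)

  conds <- rep(c(firstCondition, setdiff(c("EO", "EC"), firstCondition)),
               length.out = nRuns)
  names(conds) <- seq_len(nRuns)

  withSeed(seed, {
    speakerOfStimulus <- sample.int(6L)     # session-wide stimulus -> speaker
    evs <- vector("list", nRuns * 6L)
    t0 <- leadInMs
    k <- 0L
    for (r in seq_len(nRuns)) {
      targetOrder <- sample.int(6L)         # cued target of trials 1..6
      for (tr in 1:6) {
        seqIds <- sample(rep(1:6, times = 15L))   # 90 stimuli, 15 each
        onsets <- t0 + soaMs * (seq_along(seqIds) - 1L)
        k <- k + 1L
        evs[[k]] <- data.frame(
          onsetMs = onsets,
          stimulusId = seqIds,
          speakerId = speakerOfStimulus[seqIds],
          isTarget = seqIds == targetOrder[tr],
          trialIndex = tr,
          runIndex = r,
          condition = conds[[r]])
        t0 <- onsets[length(onsets)] + soaMs + interTrialGapMs
      }
      t0 <- t0 + interRunGapMs
    }
    ev <- do.call(rbind, evs)
    rownames(ev) <- NULL
    new("SessionSchedule", events = ev, runConditions = conds, soaMs = soaMs,
        seed = seed,
        params = list(firstCondition = firstCondition, nRuns = nRuns,
                      interTrialGapMs = interTrialGapMs,
                      interRunGapMs = interRunGapMs, leadInMs = leadInMs))
  })
}

#' Count events of a schedule by enumeration
#'
#' Enumerates the event table (no closed-form shortcuts) and returns the
#' number of target events, non-target events and trials recorded under a
#' condition.
#'
#' @param schedule a \linkS4class{SessionSchedule}.
#' @param condition "EO" or "EC".
#' @return Named list with \code{targets}, \code{nonTargets}, \code{trials}.
#' @export
countEvents <- function(schedule, condition) {
  stopifnot(is(schedule, "SessionSchedule"))
  if (!is.character(condition) || length(condition) != 1L ||
      !condition %in% c("EO", "EC"))
    stop("unknown condition label: ", paste(condition, collapse = ","))
  ev <- schedule@events[schedule@events$condition == condition, , drop = FALSE]
  list(targets = sum(ev$isTarget),
       nonTargets = sum(!ev$isTarget),
       trials = nrow(unique(ev[, c("runIndex", "trialIndex")])))
}

#' Export / import a schedule as a tab-separated event table
#'
#' @param schedule a \linkS4class{SessionSchedule}.
#' @param path file path of the TSV.
#' @return \code{writeScheduleTable} invisibly returns \code{path};
#'   \code{readScheduleTable} returns a \linkS4class{SessionSchedule}
#'   reconstructed from the event rows (seed recorded as NA-like 0).
#' @export
writeScheduleTable <- function(schedule, path) {
  stopifnot(is(schedule, "SessionSchedule"))
  utils::write.table(schedule@events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname writeScheduleTable
#' @export
readScheduleTable <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  .assertCols(ev, .EVENT_COLS, "schedule table")
  runs <- sort(unique(ev$runIndex))
  rc <- vapply(runs, function(r) ev$condition[ev$runIndex == r][1L], "")
  names(rc) <- runs
  soa <- if (nrow(ev) >= 2L) {
    key <- paste(ev$runIndex, ev$trialIndex)
    d <- diff(ev$onsetMs)
    d[key[-1L] == key[-length(key)]][1L]
  } else 250
  new("SessionSchedule", events = ev, runConditions = rc, soaMs = soa,
      seed = 0L, params = list(imported = TRUE))
}
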