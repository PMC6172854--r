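## Synthetic session generator: class- and condition-dependent N200/P300
## templates on Gaussian scalp maps, spatially correlated 1/f background
## noise, condition-dependent occipital alpha, and Poisson-timed ocular
## artifacts (blinks, saccades) with ground-truth logging.

# 1/f-shaped noise: white noise through a standard pink-noise IIR
# approximation, rescaled to unit standard deviation.
.pinkNoise <- function(n) {
  b <- c(0.049922035, -0.095993537, 0.050612699, -0.004408786)
  a <- c(1, -2.494956002, 2.017265875, -0.522189400)
  x <- as.numeric(signal::filter(b, a, stats::rnorm(n + 2000L)))
  x <- x[-seq_len(2000L)]                    # drop filter warm-up
  x / stats::sd(x)
}

# Gaussian bump with peak 1 at `latMs`, evaluated on `tMs`, zero before onset.
.component <- function(tMs, latMs, sigmaMs) {
  g <- exp(-(tMs - latMs)^2 / (2 * sigmaMs^2))
  g[tMs < 0] <- 0
  g
}

#' Noiseless single-epoch ERP template
#'
#' Renders the deterministic evoked response of one stimulus class under one
#' condition: a fronto-central negative component (N200, unit spatial weight
#' at FCz) plus a parietal positive component (P300, unit weight at Pz),
#' each Gaussian in time at the profile's latency/width/amplitude. On
#' non-target epochs both components are attenuated by the profile's class
#' attenuation factors (defaults 0.6 for N200, 0.15 for P300).
#'
#' @param profile a \linkS4class{SubjectProfile}.
#' @param klass "target" or "nontarget".
#' @param condition "EO" or "EC".
#' @param fsHz sampling rate of the rendered grid (default 1000).
#' @param windowMs half-open time window relative to stimulus onset.
#' @param montage montage table (see \code{\link{amuseMontage}}).
#' @return Channels x time numeric matrix (µV) with channel rownames;
#'   non-scalp channels (EOGvu) are zero.
#' @examples
#' p <- makeSubjectProfile(1)
#' tpl <- renderEpochTemplate(p, "target", "EO")
#' # Pz peaks at the profile's EO P300 latency:
#' which.max(tpl["Pz", ])
#' @export
renderEpochTemplate <- function(profile, klass = c("target", "nontarget"),
                                condition = c("EO", "EC"), fsHz = 1000,
                                windowMs = c(-200, 1200),
                                montage = amuseMontage()) {
  stopifnot(is(profile, "SubjectProfile"))
  klass <- match.arg(klass)
  condition <- match.arg(condition)
  tMs <- seq(windowMs[1L], windowMs[2L] - 1000 / fsHz, by = 1000 / fsHz)
  mapN <- gaussianScalpMap("FCz", montage = montage)
  mapP <- gaussianScalpMap("Pz", montage = montage)
  aN <- profile@n200AmpUV[condition]
  aP <- profile@p300AmpUV[condition]
  if (klass == "nontarget") {
    aN <- aN * profile@attenN200
    aP <- aP * profile@attenP300
  }
  out <- outer(mapN, aN * .component(tMs, profile@n200LatencyMs[condition],
                                     profile@sigmaN200Ms)) +
         outer(mapP, aP * .component(tMs, profile@p300LatencyMs[condition],
                                     profile@sigmaP300Ms))
  rownames(out) <- montage$label
  out
}

# Condition segments of a schedule/recording: one [startMs, endMs] per run.
.runSegments <- function(ev, padMs = 2000, maxMs = Inf) {
  runs <- sort(unique(ev$runIndex))
  do.call(rbind, lapply(runs, function(r) {
    e <- ev[ev$runIndex == r, , drop = FALSE]
    data.frame(runIndex = r, condition = e$condition[1L],
               startMs = max(0, min(e$onsetMs) - padMs),
               endMs = min(maxMs, max(e$onsetMs) + 1200 + padMs))
  }))
}

#' Synthesize a continuous recording for a session schedule
#'
#' Superimposes, on a 63-channel + EOGvu montage at \code{fsHz}:
#' \enumerate{
#'   \item per-event noiseless ERP templates (class- and condition-resolved,
#'     see \code{\link{renderEpochTemplate}});
#'   \item spatially correlated 1/f background noise (pairwise channel
#'     correlation \code{noiseCorrelation}, per-channel SD
#'     \code{profile@noiseSdUV});
#'   \item amplitude-modulated 10 Hz alpha with occipital topography,
#'     scaled by the condition's \code{alphaAmpUV} during that condition's
#'     runs;
#'   \item ocular artifacts via \code{\link{injectEyeArtifacts}}.
#' }
#' Identical (schedule, profile, seed) triples give bit-identical output.
#'
#' @param schedule a \linkS4class{SessionSchedule}.
#' @param profile a \linkS4class{SubjectProfile}.
#' @param seed integer seed for noise, alpha phases and artifact timing.
#' @param fsHz sampling rate (default 1000).
#' @param noiseCorrelation common-signal fraction of the background noise.
#' @param montage montage table.
#' @return List with \code{recording} (a
#'   \linkS4class{ContinuousRecording}) and \code{artifactLog} (data.frame:
#'   kind, onsetMs, durationMs, peakAmpUV, condition, runIndex).
#' @export
synthesizeSession <- function(schedule, profile, seed = 1L, fsHz = 1000,
                              noiseCorrelation = 0.3,
                              montage = amuseMontage()) {
  stopifnot(is(schedule, "SessionSchedule"), is(profile, "SubjectProfile"))
  seed <- as.integer(seed)
  ev <- schedule@events
  if (!nrow(ev)) stop("schedule has no events")
  nCh <- nrow(montage)
  durMs <- max(ev$onsetMs) + 2000
  nSamp <- as.integer(ceiling(durMs * fsHz / 1000))

  # Background noise: 1/f-shaped, pairwise channel correlation via a shared
  # component, with a site-dependent scale (noisier at peripheral sites) and
  # slow amplitude modulation, mimicking the nonstationary variance of
  # resting EEG. The site scale and modulation give the per-channel and
  # per-trial variance distributions a realistic spread.
  data <- matrix(0, nCh, nSamp)     # single binding: updates stay in place
  if (profile@noiseSdUV > 0) {
    withSeed(childSeed(seed, 1L), {
      siteScale <- 0.8 + 0.5 * (montage$x^2 + montage$y^2)
      tt <- (seq_len(nSamp) - 1) / fsHz
      common <- sqrt(noiseCorrelation) * .pinkNoise(nSamp)
      big <- nSamp > 5e6
      for (i in seq_len(nCh)) {
        ph <- stats::runif(2L, 0, 2 * pi)
        # stepwise to bound per-channel temporaries on hour-long sessions
        x <- sqrt(1 - noiseCorrelation) * .pinkNoise(nSamp)
        x <- x + common
        env <- 0.25 * sin(2 * pi * 0.05 * tt + ph[1L])
        env <- env + 0.15 * sin(2 * pi * 0.013 * tt + ph[2L])
        env <- env + 1
        x <- x * env
        data[i, ] <- (profile@noiseSdUV * siteScale[i]) * x
        if (big) { rm(x, env); gc(FALSE) }
      }
      rm(common, tt)
    })
  }

  # occipital alpha during each run's span (phases drawn first; the big
  # matrix is only touched from the function body, keeping updates in place)
  if (any(profile@alphaAmpUV > 0)) {
    segs <- .runSegments(ev, maxMs = durMs)
    mapA <- gaussianScalpMap("Oz", sigma = 0.4, montage = montage)
    phases <- withSeed(childSeed(seed, 2L),
                       matrix(stats::runif(2L * nrow(segs), 0, 2 * pi), 2L))
    for (k in seq_len(nrow(segs))) {
      amp <- profile@alphaAmpUV[segs$condition[k]]
      if (amp <= 0) next
      i0 <- as.integer(floor(segs$startMs[k] * fsHz / 1000)) + 1L
      i1 <- min(nSamp, as.integer(ceiling(segs$endMs[k] * fsHz / 1000)))
      tt <- (seq(i0, i1) - 1) / fsHz
      env <- 0.5 * (1 + sin(2 * pi * 0.3 * tt + phases[2L, k]))
      sig <- amp * env * sin(2 * pi * 10 * tt + phases[1L, k])
      data[, i0:i1] <- data[, i0:i1] + outer(mapA, sig)
    }
  }

  # per-event evoked templates (rendered once per class x condition)
  tplTime <- seq(0, 1200 - 1000 / fsHz, by = 1000 / fsHz)
  nTpl <- length(tplTime)
  tpl <- list()
  for (kl in .CLASSES) for (cond in .CONDITIONS)
    tpl[[paste(kl, cond)]] <- renderEpochTemplate(
      profile, kl, cond, fsHz = fsHz, windowMs = c(0, 1200),
      montage = montage)
  klass <- ifelse(ev$isTarget, "target", "nontarget")
  for (j in seq_len(nrow(ev))) {
    i0 <- as.integer(round(ev$onsetMs[j] * fsHz / 1000)) + 1L
    len <- min(nTpl, nSamp - i0 + 1L)
    if (len <= 0L) next
    cols <- i0:(i0 + len - 1L)
    data[, cols] <- data[, cols] +
      tpl[[paste(klass[j], ev$condition[j])]][, seq_len(len)]
  }

  # ocular artifacts, applied as local patches to avoid duplicating the
  # full data matrix
  art <- .eyeArtifactPatches(ev, nSamp, fsHz, montage$label, profile,
                             seed = childSeed(seed, 3L), montage = montage)
  for (p in art$patches) {
    cols <- p$i0:(p$i0 + ncol(p$add) - 1L)
    data[, cols] <- data[, cols] + p$add
  }

  rownames(data) <- montage$label
  rec <- new("ContinuousRecording", data = data,
             channelLabels = montage$label, fsHz = fsHz, events = ev,
             meta = list(seed = seed, profileSeed = profile@seed,
                         scheduleSeed = schedule@seed,
                         noiseCorrelation = noiseCorrelation,
                         synthetic = TRUE))
  list(recording = rec, artifactLog = art$log)
}

# blink: biphasic ~300 ms waveform peaking at 1
.blinkWave <- function(fsHz, durationMs = 300) {
  t <- seq(0, durationMs - 1000 / fsHz, by = 1000 / fsHz)
  w <- exp(-(t - 120)^2 / (2 * 45^2)) - 0.3 * exp(-(t - 230)^2 / (2 * 60^2))
  w / max(w)
}

# saccade: step-like ~200 ms trapezoid (30 ms ramps), peak 1
.saccadeWave <- function(fsHz, durationMs = 200) {
  t <- seq(0, durationMs - 1000 / fsHz, by = 1000 / fsHz)
  pmin(1, pmin(t, durationMs - 1000 / fsHz - t) / 30)
}

# Generate artifact waveform patches and their log without touching any
# data matrix; callers add each patch (channels x samples) in place.
.eyeArtifactPatches <- function(events, nSamp, fsHz, lab, profile, seed,
                                montage = amuseMontage()) {
  log0 <- data.frame(kind = character(), onsetMs = numeric(),
                     durationMs = numeric(), peakAmpUV = numeric(),
                     condition = character(), runIndex = integer())
  if (all(profile@blinkRateHz == 0) && all(profile@saccadeRateHz == 0))
    return(list(patches = list(), log = log0))

  durMs <- nSamp / fsHz * 1000
  segs <- .runSegments(events, maxMs = durMs)

  # projections restricted to the channels actually present
  wBlink <- gaussianScalpMap("Fp2", sigma = 0.6, montage = montage)[lab]
  wBlink["EOGvu"] <- -0.8
  wSacc <- (gaussianScalpMap("F9", sigma = 0.5, montage = montage) -
            gaussianScalpMap("F10", sigma = 0.5, montage = montage))[lab]
  wSacc <- wSacc / wSacc["F9"]
  wSacc["EOGvu"] <- 0.1

  patches <- list()
  logs <- list(log0)
  withSeed(seed, {
    for (k in seq_len(nrow(segs))) {
      cond <- segs$condition[k]
      tSec <- (segs$endMs[k] - segs$startMs[k]) / 1000
      for (kind in c("blink", "saccade")) {
        rate <- if (kind == "blink") profile@blinkRateHz[cond]
                else profile@saccadeRateHz[cond]
        if (rate <= 0) next
        n <- stats::rpois(1L, rate * tSec)
        if (n == 0L) next
        onsets <- sort(stats::runif(n, segs$startMs[k], segs$endMs[k]))
        base <- if (kind == "blink") profile@blinkAmpUV else profile@saccadeAmpUV
        wave0 <- if (kind == "blink") .blinkWave(fsHz) else .saccadeWave(fsHz)
        durationMs <- length(wave0) / fsHz * 1000
        amps <- base * stats::runif(n, 0.7, 1.3)
        signs <- if (kind == "saccade") sample(c(-1, 1), n, replace = TRUE)
                 else rep(1, n)
        w <- if (kind == "blink") wBlink else wSacc
        for (j in seq_len(n)) {
          i0 <- as.integer(round(onsets[j] * fsHz / 1000)) + 1L
          len <- min(length(wave0), nSamp - i0 + 1L)
          if (len <= 0L) next
          patches[[length(patches) + 1L]] <- list(
            i0 = i0, add = outer(unname(w * signs[j] * amps[j]),
                                 wave0[seq_len(len)]))
        }
        logs[[length(logs) + 1L]] <- data.frame(
          kind = kind, onsetMs = onsets, durationMs = durationMs,
          peakAmpUV = amps, condition = cond, runIndex = segs$runIndex[k])
      }
    }
  })
  log <- do.call(rbind, logs)
  rownames(log) <- NULL
  list(patches = patches, log = log)
}

#' Inject ocular artifacts into a recording
#'
#' Adds Poisson-timed eye blinks and saccades during each run's span, at the
#' profile's condition-dependent rates. Blinks are biphasic ~300 ms
#' deflections peaking (default 100 µV) at Fp2 with a decaying scalp
#' projection and opposite sign on the periocular channel EOGvu; saccades
#' are step-like ~200 ms deflections with opposite polarity on F9 versus
#' F10 (random direction). Every injection is logged.
#'
#' @param recording a \linkS4class{ContinuousRecording} containing channels
#'   Fp1, Fp2, F9, F10 and EOGvu.
#' @param profile a \linkS4class{SubjectProfile} (rates and amplitudes).
#' @param seed integer seed for artifact timing and amplitude jitter.
#' @param montage montage table matching the recording's channels.
#' @return List with the modified \code{recording} and the
#'   \code{artifactLog} data.frame (kind, onsetMs, durationMs, peakAmpUV,
#'   condition, runIndex); zero rates return the recording unchanged with
#'   an empty log.
#' @export
injectEyeArtifacts <- function(recording, profile, seed = 1L,
                               montage = amuseMontage()) {
  stopifnot(is(recording, "ContinuousRecording"),
            is(profile, "SubjectProfile"))
  need <- c("Fp1", "Fp2", "F9", "F10", "EOGvu")
  miss <- setdiff(need, recording@channelLabels)
  if (length(miss))
    stop("required channel(s) missing: ", paste(miss, collapse = ", "))

  art <- .eyeArtifactPatches(recording@events, ncol(recording@data),
                             recording@fsHz, recording@channelLabels,
                             profile, seed, montage = montage)
  if (length(art$patches)) {
    data <- recording@data
    for (p in art$patches) {
      cols <- p$i0:(p$i0 + ncol(p$add) - 1L)
      data[, cols] <- data[, cols] + p$add
    }
    recording@data <- data
  }
  list(recording = recording, artifactLog = art$log)
}

#' Write an artifact log as a tab-separated table
#' @param artifactLog data.frame as returned by
#'   \code{\link{injectEyeArtifacts}}.
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writeArtifactLog <- function(artifactLog, path) {
  utils::write.table(artifactLog, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
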