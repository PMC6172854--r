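## Container persistence and BrainVision triplet I/O.

.CONTAINER_MAGIC <- "amuseBCI-container"
.CONTAINER_VERSION <- 1L

#' Save / load an analysis container
#'
#' Persists a \linkS4class{ContinuousRecording} or \linkS4class{EpochSet}
#' (any package object, in fact) to a single file with a format tag,
#' version and provenance block (seeds, creation time, R version), via R
#' serialization. Loading verifies the tag and version and fails loudly on
#' truncated or foreign files rather than returning partial data.
#'
#' @param x object to persist.
#' @param path file path.
#' @param seed optional master seed recorded in the provenance block
#'   (defaults to \code{x@meta$seed} when present).
#' @return \code{saveContainer} invisibly returns \code{path};
#'   \code{loadContainer} returns the stored object.
#' @export
saveContainer <- function(x, path, seed = NULL) {
  if (is.null(seed) && isVirtualClass(class(x)) == FALSE &&
      .hasSlot(x, "meta")) seed <- x@meta$seed
  obj <- list(magic = .CONTAINER_MAGIC, version = .CONTAINER_VERSION,
              class = class(x), payload = x,
              provenance = list(seed = seed, created = format(Sys.time()),
                                rVersion = R.version.string))
  saveRDS(obj, path)
  invisible(path)
}

.hasSlot <- function(x, name) isVirtualClass(class(x)) == FALSE &&
  name %in% methods::slotNames(class(x))

#' @rdname saveContainer
#' @export
loadContainer <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read container '", path, "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$magic, .CONTAINER_MAGIC))
    stop("'", path, "' is not an amuseBCI container")
  if (!identical(obj$version, .CONTAINER_VERSION))
    stop("container version mismatch: file has ", obj$version,
         ", this package reads ", .CONTAINER_VERSION)
  obj$payload
}

#' Provenance block of a container file
#' @param path container file path.
#' @return List with \code{seed}, \code{created}, \code{rVersion}.
#' @export
containerProvenance <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read container '", path, "': ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$magic, .CONTAINER_MAGIC))
    stop("'", path, "' is not an amuseBCI container")
  obj$provenance
}

## ---- BrainVision triplet (.vhdr/.vmrk/.eeg), read + fixture writer ----

.parseIni <- function(lines) {
  out <- list()
  section <- ""
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- list()
    } else if (grepl("=", ln, fixed = TRUE) && nzchar(section)) {
      key <- sub("=.*$", "", ln)
      out[[section]][[key]] <- sub("^[^=]*=", "", ln)
    }
  }
  out
}

#' Read a BrainVision recording (.vhdr/.vmrk/.eeg triplet)
#'
#' Supports the vendor's multiplexed binary layout with IEEE_FLOAT_32 or
#' INT_16 encoding (per-channel resolutions applied, output in µV).
#' Stimulus markers are parsed into the recording's event table with
#' columns \code{onsetMs}, \code{type}, \code{description} and
#' \code{stimulusId} (from "S <n>" descriptions; NA otherwise). Paradigm
#' bookkeeping (targets, trials, runs, condition) is attached afterwards
#' with \code{\link{attachSchedule}}.
#'
#' @param headerPath path to the \code{.vhdr} header file.
#' @return A \linkS4class{ContinuousRecording}.
#' @export
readBrainVision <- function(headerPath) {
  if (!file.exists(headerPath)) stop("header file not found: ", headerPath)
  hdr <- .parseIni(readLines(headerPath, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  if (is.null(ci)) stop("no [Common Infos] section in ", headerPath)
  dir <- dirname(headerPath)
  dataPath <- file.path(dir, ci$DataFile)
  markerPath <- file.path(dir, ci$MarkerFile)
  if (!file.exists(dataPath)) stop("data file not found: ", dataPath)
  if (!file.exists(markerPath)) stop("marker file not found: ", markerPath)
  nCh <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)     # interval is in µs
  if (!identical(toupper(ci$DataOrientation %||% "MULTIPLEXED"),
                 "MULTIPLEXED"))
    stop("only MULTIPLEXED orientation is supported")
  fmt <- toupper(hdr[["Binary Infos"]]$BinaryFormat %||% "IEEE_FLOAT_32")

  chInfo <- hdr[["Channel Infos"]]
  if (length(chInfo) != nCh)
    stop("channel count mismatch: header declares ", nCh, " channels but [",
         "Channel Infos] lists ", length(chInfo))
  parts <- lapply(chInfo[paste0("Ch", seq_len(nCh))], strsplit,
                  split = ",", fixed = TRUE)
  labels <- unname(vapply(parts, function(p) p[[1L]][1L], ""))
  resol <- unname(vapply(parts, function(p) {
    r <- suppressWarnings(as.numeric(p[[1L]][3L]))
    if (is.na(r)) 1 else r
  }, numeric(1L)))

  sz <- file.size(dataPath)
  con <- file(dataPath, "rb")
  on.exit(close(con))
  raw <- switch(fmt,
    IEEE_FLOAT_32 = readBin(con, "double", n = sz / 4, size = 4L,
                            endian = "little"),
    INT_16 = readBin(con, "integer", n = sz / 2, size = 2L, signed = TRUE,
                     endian = "little"),
    stop("unknown binary encoding: ", fmt))
  nSamp <- length(raw) %/% nCh
  data <- matrix(raw[seq_len(nSamp * nCh)], nrow = nCh)   # multiplexed
  data <- data * resol
  rownames(data) <- labels

  mk <- .parseIni(readLines(markerPath, warn = FALSE))[["Marker Infos"]]
  evRows <- list()
  for (key in names(mk)) {
    f <- strsplit(mk[[key]], ",", fixed = TRUE)[[1L]]
    if (length(f) < 3L || f[1L] != "Stimulus") next
    pos <- as.numeric(f[3L])
    sid <- if (grepl("^S *[0-9]+$", f[2L]))
      as.integer(sub("^S *", "", f[2L])) else NA_integer_
    evRows[[length(evRows) + 1L]] <- data.frame(
      onsetMs = (pos - 1) / fs * 1000, type = f[1L], description = f[2L],
      stimulusId = sid)
  }
  ev <- if (length(evRows)) do.call(rbind, evRows)
        else data.frame(onsetMs = numeric(), type = character(),
                        description = character(), stimulusId = integer())
  ev <- ev[order(ev$onsetMs), , drop = FALSE]
  rownames(ev) <- NULL
  new("ContinuousRecording", data = data, channelLabels = labels,
      fsHz = fs, events = ev, meta = list(source = headerPath, format = fmt))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a BrainVision triplet (fixtures, round-trips)
#'
#' Companion writer to \code{\link{readBrainVision}} (IEEE_FLOAT_32,
#' multiplexed). Events with a \code{stimulusId} column are written as
#' Stimulus markers "S<id>".
#'
#' @param recording a \linkS4class{ContinuousRecording}.
#' @param basePath path without extension; writes
#'   \code{basePath.vhdr/.vmrk/.eeg}.
#' @return Invisibly, the header path.
#' @export
writeBrainVision <- function(recording, basePath) {
  stopifnot(is(recording, "ContinuousRecording"))
  base <- basename(basePath)
  hdrPath <- paste0(basePath, ".vhdr")
  nCh <- nrow(recording@data)
  hdr <- c("Brain Vision Data Exchange Header File Version 1.0",
           "[Common Infos]",
           paste0("DataFile=", base, ".eeg"),
           paste0("MarkerFile=", base, ".vmrk"),
           "DataFormat=BINARY", "DataOrientation=MULTIPLEXED",
           paste0("NumberOfChannels=", nCh),
           paste0("SamplingInterval=", format(1e6 / recording@fsHz,
                                              scientific = FALSE)),
           "[Binary Infos]", "BinaryFormat=IEEE_FLOAT_32",
           "[Channel Infos]",
           sprintf("Ch%d=%s,,1,µV", seq_len(nCh),
                   recording@channelLabels))
  writeLines(hdr, hdrPath, useBytes = TRUE)

  ev <- recording@events
  mk <- c("Brain Vision Data Exchange Marker File, Version 1.0",
          "[Common Infos]", paste0("DataFile=", base, ".eeg"),
          "[Marker Infos]", "Mk1=New Segment,,1,1,0,0")
  if (nrow(ev)) {
    pos <- as.integer(round(ev$onsetMs * recording@fsHz / 1000)) + 1L
    sid <- if ("stimulusId" %in% names(ev)) ev$stimulusId else rep(1L, nrow(ev))
    mk <- c(mk, sprintf("Mk%d=Stimulus,S%3d,%d,1,0",
                        seq_len(nrow(ev)) + 1L, sid, pos))
  }
  writeLines(mk, paste0(basePath, ".vmrk"), useBytes = TRUE)

  con <- file(paste0(basePath, ".eeg"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(recording@data), con, size = 4L, endian = "little")
  invisible(hdrPath)
}

#' Attach paradigm bookkeeping to an imported recording
#'
#' Replaces a recording's bare marker events with the full event table of
#' a \linkS4class{SessionSchedule} (targets, trials, runs, condition),
#' matching events by order. Event counts must agree.
#'
#' @param recording a \linkS4class{ContinuousRecording}.
#' @param schedule a \linkS4class{SessionSchedule} with the same number of
#'   stimulus events.
#' @param useRecordedOnsets if TRUE (default) the recording's marker
#'   onsets are kept; otherwise the schedule's nominal onsets replace
#'   them.
#' @return The recording with the merged event table.
#' @export
attachSchedule <- function(recording, schedule, useRecordedOnsets = TRUE) {
  stopifnot(is(recording, "ContinuousRecording"),
            is(schedule, "SessionSchedule"))
  ev <- schedule@events
  if (nrow(recording@events) != nrow(ev))
    stop("event count mismatch: recording has ", nrow(recording@events),
         ", schedule has ", nrow(ev))
  if (useRecordedOnsets) ev$onsetMs <- recording@events$onsetMs
  recording@events <- ev
  recording
}
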