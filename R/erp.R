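#' Grand-average ERP waveforms
#'
#' Sample-wise mean over epochs, grouped by class label and/or condition.
#'
#' @param epochs an \linkS4class{EpochSet}.
#' @param by character vector of grouping columns of \code{epochInfo},
#'   any of "label", "condition" (default both).
#' @return Named list of channels x time matrices (rownames = channel
#'   labels), one per group, with an \code{n} attribute (epoch count).
#' @export
grandAverage <- function(epochs, by = c("label", "condition")) {
  stopifnot(is(epochs, "EpochSet"))
  by <- match.arg(by, c("label", "condition"), several.ok = TRUE)
  if (nEpochs(epochs) == 0L) stop("empty epoch set")
  key <- do.call(paste, c(epochs@info[by], sep = "."))
  d <- dim(epochs@data)
  out <- lapply(split(seq_len(d[1L]), key), function(rows) {
    m <- colMeans(epochs@data[rows, , , drop = FALSE], dims = 1L)
    dimnames(m) <- list(epochs@channelLabels, NULL)
    attr(m, "n") <- length(rows)
    m
  })
  attr(out, "timeMs") <- epochs@timeMs
  out
}

#' Signed r-squared discriminability map
#'
#' Per channel and time point, the point-biserial correlation r between
#' the binary class label and the amplitude, returned as sign(r) * r^2.
#' The sign convention is positive where the target mean exceeds the
#' non-target mean. Points with zero amplitude variance get value 0.
#'
#' @param epochs an \linkS4class{EpochSet} containing both classes.
#' @return Channels x time numeric matrix in [-1, 1].
#' @export
signedRSquared <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  y <- epochs@info$label == "target"
  if (!any(y) || all(y)) stop("both classes must be present")
  d <- dim(epochs@data)
  n <- d[1L]
  yc <- y - mean(y)
  vy <- sum(yc^2) / (n - 1)
  out <- matrix(0, d[2L], d[3L], dimnames = list(epochs@channelLabels, NULL))
  for (ch in seq_len(d[2L])) {                 # channel-wise: bounded memory
    M <- epochs@data[, ch, , drop = TRUE]
    if (is.null(dim(M))) M <- matrix(M, nrow = n)
    sxy <- as.numeric(crossprod(yc, M)) / (n - 1)
    vx <- (colSums(M^2) - n * colMeans(M)^2) / (n - 1)
    r <- sxy / sqrt(vx * vy)
    r[!is.finite(r)] <- 0
    out[ch, ] <- sign(r) * r^2
  }
  out
}

.DEFAULT_PEAK_WINDOWS <- list(n200 = c(100, 300), p300 = c(250, 900))
.DEFAULT_PEAK_CHANNELS <- c(n200 = "FCz", p300 = "Pz")

#' N200/P300 peak extraction
#'
#' From a subject's target-class average waveform: the N200 is the minimum
#' of the FCz trace within its search window (default [100, 300] ms), the
#' P300 the maximum of the Pz trace within its window (default
#' [250, 900] ms). Reported amplitudes are the waveform values at the
#' reported latencies; a boundary extremum stays inside the window.
#'
#' @param avg channels x time matrix (e.g. one group of
#'   \code{\link{grandAverage}}) with channel rownames.
#' @param timeMs time axis of \code{avg} in ms.
#' @param windows named list of search windows (ms).
#' @param channels named character: channel per component.
#' @return One-row data.frame: n200LatencyMs, n200AmpUV, p300LatencyMs,
#'   p300AmpUV.
#' @export
detectPeaks <- function(avg, timeMs, windows = .DEFAULT_PEAK_WINDOWS,
                        channels = .DEFAULT_PEAK_CHANNELS) {
  stopifnot(is.matrix(avg), length(timeMs) == ncol(avg))
  pick <- function(comp, fun) {
    ch <- channels[[comp]]
    if (!ch %in% rownames(avg)) stop("channel ", ch, " not present")
    w <- windows[[comp]]
    idx <- which(timeMs >= w[1L] & timeMs <= w[2L])
    if (!length(idx)) stop("search window [", w[1L], ", ", w[2L],
                           "] ms outside the epoch")
    tr <- unname(avg[ch, idx])
    i <- if (identical(fun, "min")) which.min(tr) else which.max(tr)
    c(lat = timeMs[idx[i]], amp = tr[i])
  }
  n2 <- pick("n200", "min")
  p3 <- pick("p300", "max")
  data.frame(n200LatencyMs = unname(n2["lat"]), n200AmpUV = unname(n2["amp"]),
             p300LatencyMs = unname(p3["lat"]), p300AmpUV = unname(p3["amp"]))
}

#' Per-subject peak table with Mean and SD rows
#'
#' Assembles per-subject, per-condition N200/P300 latencies and amplitudes
#' into the canonical wide layout (one row per subject; EO and EC column
#' blocks) and appends recomputable Mean and SD summary rows.
#'
#' @param peaks data.frame with columns \code{subject}, \code{condition},
#'   \code{n200LatencyMs}, \code{n200AmpUV}, \code{p300LatencyMs},
#'   \code{p300AmpUV}.
#' @return Wide data.frame with one row per subject plus "Mean" and "SD"
#'   rows; columns \code{<measure>.<condition>}.
#' @seealso \code{\link{writePeakTable}} for TSV export.
#' @export
summarizePeaks <- function(peaks) {
  .assertCols(peaks, c("subject", "condition", "n200LatencyMs", "n200AmpUV",
                       "p300LatencyMs", "p300AmpUV"), "peak table")
  meas <- c("n200LatencyMs", "n200AmpUV", "p300LatencyMs", "p300AmpUV")
  wide <- stats::reshape(
    peaks[c("subject", "condition", meas)], direction = "wide",
    idvar = "subject", timevar = "condition", sep = ".")
  rownames(wide) <- NULL
  num <- wide[, -1L, drop = FALSE]
  summary <- data.frame(subject = c("Mean", "SD"),
                        rbind(colMeans(num), apply(num, 2L, stats::sd)))
  names(summary) <- names(wide)
  rbind(wide, summary)
}

#' Write a peak table as tab-separated text
#' @param peaks data.frame (long or summarized wide form).
#' @param path output file path.
#' @return Invisibly, \code{path}.
#' @export
writePeakTable <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
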