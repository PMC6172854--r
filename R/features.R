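.DEFAULT_INTERVALS <- list(c(100, 190), c(191, 300), c(301, 450),
                           c(451, 560), c(561, 700), c(701, 850),
                           c(851, 1000), c(1001, 1200))

#' Interval-mean feature extraction
#'
#' Averages each epoch's amplitude, per channel, over a fixed set of time
#' intervals (defaults: the eight handcrafted intervals [100,190],
#' [191,300], [301,450], [451,560], [561,700], [701,850], [851,1000] and
#' [1001,1200] ms). With 63 channels this yields the standard
#' 504-dimensional feature vector. A sample at time t contributes to an
#' interval [s, e] when s <= t <= e. Features are ordered channel-major
#' (all intervals of channel 1, then channel 2, ...).
#'
#' @param epochs an \linkS4class{EpochSet} whose time axis covers all
#'   intervals.
#' @param intervalsMs list of [start, end] pairs in ms.
#' @param channels channels to extract from; default: every channel except
#'   EOGvu.
#' @return A \linkS4class{FeatureMatrix}.
#' @export
extractIntervalMeans <- function(epochs, intervalsMs = .DEFAULT_INTERVALS,
                                 channels = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  if (is.null(channels)) channels <- setdiff(epochs@channelLabels, "EOGvu")
  idx <- .channelIndex(epochs@channelLabels, channels)
  tMs <- epochs@timeMs
  sampleSets <- lapply(intervalsMs, function(iv) {
    s <- which(tMs >= iv[1L] & tMs <= iv[2L])
    if (!length(s))
      stop("interval [", iv[1L], ", ", iv[2L],
           "] ms lies outside the epoch window")
    s
  })
  nEp <- dim(epochs@data)[1L]
  nIv <- length(intervalsMs)
  out <- matrix(0, nEp, length(idx) * nIv)
  col <- 0L
  for (c_ in idx) {
    sl <- epochs@data[, c_, , drop = TRUE]
    if (is.null(dim(sl))) sl <- matrix(sl, nrow = nEp)
    for (s in sampleSets) {
      col <- col + 1L
      out[, col] <- rowMeans(sl[, s, drop = FALSE])
    }
  }
  colnames(out) <- as.vector(t(outer(channels, seq_len(nIv), paste, sep = ".iv")))
  new("FeatureMatrix", values = out, intervalBoundsMs = intervalsMs,
      channelLabels = channels, info = epochs@info)
}
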