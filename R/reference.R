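#' Published reference peak table (12 subjects)
#'
#' Per-subject N200 (FCz) and P300 (Pz) peak latencies (ms) and amplitudes
#' (µV) under the eyes-open and eyes-closed conditions, as published for
#' the 12-subject group that defined this paradigm. These values seed the
#' synthetic subject generator (group means/SDs) and serve as input for
#' the deterministic statistical reproductions (recomputed column means,
#' paired t-test on the P300 latency).
#'
#' @return data.frame with one row per subject and columns
#'   \code{<measure>.<condition>} for the four measures
#'   (\code{n200LatencyMs}, \code{n200AmpUV}, \code{p300LatencyMs},
#'   \code{p300AmpUV}) under EO and EC.
#' @examples
#' ref <- referencePeakTable()
#' colMeans(ref[-1])         # group means
#' @export
referencePeakTable <- function() {
  path <- system.file("extdata", "reference_peaks.tsv", package = "amuseBCI",
                      mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
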