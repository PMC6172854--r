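## Centers and spreads of the per-condition ERP parameters. The latency and
## amplitude centers/SDs are the published 12-subject group statistics of the
## paradigm (see referencePeakTable()); everything else is a generator
## default documented in the methods vignette.
.PROFILE_CENTER <- list(
  n200LatencyMs = c(EO = 201, EC = 206),
  n200AmpUV     = c(EO = -1.53, EC = -1.59),
  p300LatencyMs = c(EO = 690, EC = 523),
  p300AmpUV     = c(EO = 1.71, EC = 1.95))
.PROFILE_SPREAD <- list(
  n200LatencyMs = c(EO = 27.6, EC = 27.4),
  n200AmpUV     = c(EO = 0.96, EC = 0.87),
  p300LatencyMs = c(EO = 158, EC = 161),
  p300AmpUV     = c(EO = 0.43, EC = 0.82))
.PROFILE_FIXED <- list(
  sigmaN200Ms = 40, sigmaP300Ms = 110,
  noiseSdUV = 4,
  alphaAmpUV = c(EO = 2, EC = 8),
  blinkRateHz = c(EO = 0.12, EC = 0.15),
  saccadeRateHz = c(EO = 0.06, EC = 0.15),
  blinkAmpUV = 100, saccadeAmpUV = 40,
  attenN200 = 0.6, attenP300 = 0.15)

#' Draw a synthetic subject profile
#'
#' Samples the per-condition N200/P300 latencies and amplitudes of a
#' synthetic subject around the published group means, with the group SDs
#' as spread (latencies truncated to the epoch window, N200 amplitudes kept
#' non-positive and P300 amplitudes non-negative by reflection at zero).
#' All remaining generator parameters (component widths, background-noise
#' level, occipital alpha amplitude, ocular-artifact rates, non-target
#' attenuation factors) take fixed documented defaults. Any field can be
#' pinned via \code{overrides}; per-condition fields accept either a single
#' number (both conditions) or a named \code{c(EO=, EC=)} pair.
#'
#' @param seed integer seed for the random draw.
#' @param overrides named list of fields to fix verbatim, e.g.
#'   \code{list(p300LatencyMs = c(EO = 690, EC = 523), noiseSdUV = 2)}.
#' @return A \linkS4class{SubjectProfile}.
#' @examples
#' p <- makeSubjectProfile(seed = 1, overrides = list(noiseSdUV = 2))
#' @export
makeSubjectProfile <- function(seed = 1L, overrides = list()) {
  seed <- as.integer(seed)
  perCond <- names(.PROFILE_CENTER)
  known <- c(perCond, names(.PROFILE_FIXED))
  bad <- setdiff(names(overrides), known)
  if (length(bad)) stop("unknown profile field(s): ", paste(bad, collapse = ", "))

  expand <- function(v, template) {
    if (length(template) == 2L) {
      if (length(v) == 1L && is.null(names(v)))
        v <- stats::setNames(rep(v, 2L), c("EO", "EC"))
      if (!all(c("EO", "EC") %in% names(v)))
        stop("per-condition override must be named EO/EC")
      v <- v[c("EO", "EC")]
    }
    v
  }

  slots <- withSeed(seed, {
    out <- list()
    for (f in perCond) {
      if (f %in% names(overrides)) {
        out[[f]] <- expand(overrides[[f]], .PROFILE_CENTER[[f]])
      } else {
        v <- stats::rnorm(2L, .PROFILE_CENTER[[f]], .PROFILE_SPREAD[[f]])
        names(v) <- c("EO", "EC")
        if (grepl("LatencyMs", f)) v <- pmin(pmax(v, 50), 1150)
        if (f == "n200AmpUV") v <- -abs(v)
        if (f == "p300AmpUV") v <- abs(v)
        out[[f]] <- v
      }
    }
    out
  })
  for (f in names(.PROFILE_FIXED)) {
    v <- if (f %in% names(overrides)) overrides[[f]] else .PROFILE_FIXED[[f]]
    slots[[f]] <- expand(v, .PROFILE_FIXED[[f]])
  }
  do.call(new, c(list("SubjectProfile", seed = seed), slots))
}

#' Default generator parameter values
#'
#' @return Named list of the fixed generator defaults (widths, noise,
#'   alpha, artifact rates/amplitudes, non-target attenuation) and the
#'   sampling centers/spreads of the per-condition ERP parameters.
#' @export
profileDefaults <- function() {
  list(center = .PROFILE_CENTER, spread = .PROFILE_SPREAD,
       fixed = .PROFILE_FIXED)
}
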