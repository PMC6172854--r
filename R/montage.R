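#' Standard 63-channel scalp montage plus EOGvu
#'
#' Idealized planar layout of the 63 scalp electrodes used throughout the
#' package (10-20/10-10 naming; nose reference, AFz ground — hence no AFz
#' channel) plus the periocular electrode EOGvu below the right eye.
#' Coordinates are schematic head-radius units used only for the generator's
#' Gaussian spatial component maps; they are not digitized positions.
#'
#' @return A \code{data.frame} with columns \code{label}, \code{x} (left
#'   negative), \code{y} (anterior positive) and \code{scalp} (logical;
#'   FALSE for EOGvu).
#' @examples
#' m <- amuseMontage()
#' nrow(m)          # 64 rows: 63 scalp channels + EOGvu
#' sum(m$scalp)     # 63
#' @export
amuseMontage <- function() {
  row <- function(labels, xs, y) data.frame(label = labels, x = xs, y = y)
  m <- rbind(
    row(c("Fp1", "Fp2"), c(-0.3, 0.3), 0.95),
    row(c("AF7", "AF3", "AF4", "AF8"), c(-0.6, -0.3, 0.3, 0.6), 0.75),
    row(c("F9", "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8", "F10"),
        c(-1.05, -0.8, -0.6, -0.4, -0.2, 0, 0.2, 0.4, 0.6, 0.8, 1.05), 0.55),
    row(c("FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8"),
        c(-0.85, -0.6, -0.4, -0.2, 0, 0.2, 0.4, 0.6, 0.85), 0.28),
    row(c("T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8"),
        c(-0.9, -0.65, -0.45, -0.2, 0, 0.2, 0.45, 0.65, 0.9), 0),
    row(c("TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8"),
        c(-0.85, -0.6, -0.4, -0.2, 0, 0.2, 0.4, 0.6, 0.85), -0.28),
    row(c("P9", "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8", "P10"),
        c(-1.05, -0.8, -0.6, -0.4, -0.2, 0, 0.2, 0.4, 0.6, 0.8, 1.05), -0.55),
    row(c("PO7", "PO3", "POz", "PO4", "PO8"),
        c(-0.6, -0.3, 0, 0.3, 0.6), -0.75),
    row(c("O1", "Oz", "O2"), c(-0.3, 0, 0.3), -0.95))
  m$scalp <- TRUE
  m <- rbind(m, data.frame(label = "EOGvu", x = 0.3, y = 1.2, scalp = FALSE))
  rownames(m) <- NULL
  m
}

#' Gaussian spatial weight map over a montage
#'
#' Unit weight at a center electrode, decaying with planar inter-electrode
#' distance — the generator's stand-in for a dipolar scalp projection
#' (fronto-central for the N200, parietal for the P300, occipital for
#' alpha, periocular for blinks).
#'
#' @param center label of the electrode carrying unit weight.
#' @param sigma Gaussian falloff scale (head-radius units).
#' @param montage montage table from \code{\link{amuseMontage}}.
#' @param scalpOnly if TRUE (default) non-scalp channels get weight 0.
#' @return Named numeric vector of weights, one per montage row.
#' @export
gaussianScalpMap <- function(center, sigma = 0.45, montage = amuseMontage(),
                             scalpOnly = TRUE) {
  i <- match(center, montage$label)
  if (is.na(i)) stop("unknown electrode: ", center)
  d2 <- (montage$x - montage$x[i])^2 + (montage$y - montage$y[i])^2
  w <- exp(-d2 / (2 * sigma^2))
  if (scalpOnly) w[!montage$scalp] <- 0
  names(w) <- montage$label
  w
}

.FRONTAL6 <- c("Fp1", "Fp2", "F7", "F8", "F9", "F10")
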