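## Pixel-value codecs for the two overflow schemes.
##
## Bruker frames store 1 byte per pixel; the sentinel value 255 means
## "take the next entry of the overflow table" (entries consumed in
## raster order), after which the baseline offset is subtracted from
## every pixel.  R-AXIS plates store unsigned 16-bit values; stored
## values >= 32768 are overflow-compressed and decode to
## (v - 32768) * R, with the scale ratio R carried in the header.

RAXIS_OVERFLOW_BASE <- 32768L
RAXIS_MAX_STORED <- 65535L
BRUKER_SENTINEL <- 255L

#' Decode stored pixel values to intensities (ADU)
#'
#' @param raw stored pixel buffer.  Bruker: integer vector of byte
#'   values in [0, 255], length \code{nFast * nSlow}.  R-AXIS: either an
#'   integer vector of stored 16-bit values in [0, 65535], or a
#'   \code{raw} vector of bytes (two per pixel, little-endian), in which
#'   case an odd byte count is an error.
#' @param md an [ImageMetadata-class] providing the overflow scheme,
#'   the baseline offset (Bruker) and the overflow scale ratio (R-AXIS).
#' @param overflowTable integer/numeric vector of wide values consumed
#'   by 255-sentinels, Bruker only.
#' @return numeric vector of decoded intensities in ADU.  Values are
#'   non-negative except where baseline subtraction legitimately yields
#'   small negatives.
#' @seealso [encodePixels()]
#' @examples
#' md <- exampleImageMetadata("bruker")
#' decodePixels(c(10L, 255L, 3L), md, overflowTable = 70000)
#' @export
decodePixels <- function(raw, md, overflowTable = numeric(0)) {
  stopifnot(is(md, "ImageMetadata"))
  nPix <- md@nFast * md@nSlow
  if (md@overflowScheme == "bruker_table") {
    raw <- as.integer(raw)
    if (length(raw) != nPix)
      stop(sprintf("buffer length %d != nFast * nSlow = %d",
                   length(raw), nPix))
    if (any(raw < 0L | raw > 255L))
      stop("bruker stored values must lie in [0, 255]")
    idx <- which(raw == BRUKER_SENTINEL)
    if (length(idx) > length(overflowTable))
      stop(sprintf(
        "buffer contains %d overflow sentinels but the table has %d entries",
        length(idx), length(overflowTable)))
    out <- as.numeric(raw)
    if (length(idx))
      out[idx] <- as.numeric(overflowTable[seq_along(idx)])
    out - md@baselineOffset
  } else {
    if (is.raw(raw)) {
      if (length(raw) %% 2L != 0L)
        stop("raxis byte buffer has an odd byte count")
      b <- as.integer(raw)
      raw <- b[c(TRUE, FALSE)] + 256L * b[c(FALSE, TRUE)]   # little-endian
    }
    raw <- as.integer(raw)
    if (length(raw) != nPix)
      stop(sprintf("buffer length %d != nFast * nSlow = %d",
                   length(raw), nPix))
    if (any(raw < 0L | raw > RAXIS_MAX_STORED))
      stop("raxis stored values must lie in [0, 65535]")
    out <- as.numeric(raw)
    ov <- raw >= RAXIS_OVERFLOW_BASE
    out[ov] <- (raw[ov] - RAXIS_OVERFLOW_BASE) * md@overflowRatio
    out
  }
}

#' Encode intensities into the stored pixel representation
#'
#' Inverse of [decodePixels()]; used for fixture generation.  Bruker
#' encoding is exact for any non-negative integer intensity (values at
#' or above 255 after baseline addition go through the overflow table).
#' R-AXIS encoding is exact for values below 32768 and for values on
#' the \code{(v - 32768) * R} grid; off-grid values are encoded to the
#' nearest grid point and flagged lossy.
#'
#' @param intensities non-negative finite numeric vector, length
#'   \code{nFast * nSlow}.
#' @param md an [ImageMetadata-class].
#' @return list with elements \code{raw} (integer buffer),
#'   \code{overflowTable} (numeric; empty for R-AXIS) and \code{lossy}
#'   (logical vector marking off-grid R-AXIS pixels).
#' @examples
#' md <- exampleImageMetadata("raxis")
#' enc <- encodePixels(c(5, 32768 * 3), md)
#' decodePixels(enc$raw, md)
#' @export
encodePixels <- function(intensities, md) {
  stopifnot(is(md, "ImageMetadata"))
  x <- as.numeric(intensities)
  if (any(!is.finite(x)) || any(x < 0))
    stop("intensities must be non-negative and finite")
  nPix <- md@nFast * md@nSlow
  if (length(x) != nPix)
    stop(sprintf("intensity length %d != nFast * nSlow = %d",
                 length(x), nPix))
  lossy <- logical(length(x))
  if (md@overflowScheme == "bruker_table") {
    y <- x + md@baselineOffset
    if (any(y != round(y)))
      stop("bruker encoding requires integer ADU values (after baseline)")
    if (any(y < 0))
      stop("value below the representable range after baseline addition")
    raw <- as.integer(pmin(y, BRUKER_SENTINEL))
    over <- which(y >= BRUKER_SENTINEL)
    raw[over] <- BRUKER_SENTINEL
    list(raw = raw, overflowTable = as.numeric(y[over]), lossy = lossy)
  } else {
    R <- md@overflowRatio
    maxVal <- (RAXIS_MAX_STORED - RAXIS_OVERFLOW_BASE) * R
    if (any(x > maxVal))
      stop(sprintf("value exceeds the representable R-AXIS range (max %g)",
                   maxVal))
    raw <- integer(length(x))
    direct <- x < RAXIS_OVERFLOW_BASE & x == round(x)
    raw[direct] <- as.integer(x[direct])
    rest <- which(!direct)
    if (length(rest)) {
      q <- round(x[rest] / R)
      lossy[rest] <- abs(q * R - x[rest]) > 1e-9
      raw[rest] <- as.integer(q + RAXIS_OVERFLOW_BASE)
    }
    list(raw = raw, overflowTable = numeric(0), lossy = lossy)
  }
}

#' Minimal ImageMetadata objects for examples and fixture generation
#'
#' @param dialect "raxis" or "bruker".
#' @param nFast,nSlow pixel counts (defaults give a small test frame).
#' @param baselineOffset Bruker baseline offset in ADU.
#' @return an [ImageMetadata-class].
#' @export
exampleImageMetadata <- function(dialect = c("raxis", "bruker"),
                                 nFast = if (dialect == "raxis") 2L else 3L,
                                 nSlow = 1L, baselineOffset = 0) {
  dialect <- match.arg(dialect)
  new("ImageMetadata",
      dialect = dialect,
      nFast = as.integer(nFast), nSlow = as.integer(nSlow),
      pixelSize = 100, beamCenter = c(fast = nFast / 2, slow = nSlow / 2),
      scanAxis = "phi",
      startAngles = c(phi = 0, omega = 0, chi = 0, theta = 0),
      rotationPerFrame = 1, gain = 1,
      overflowScheme = if (dialect == "raxis") "raxis_scaled"
                       else "bruker_table",
      baselineOffset = baselineOffset, overflowRatio = 8,
      correctionRefs = c(flood_field = NA_character_,
                         distortion = NA_character_,
                         dark = NA_character_),
      spindleSense = "unknown",
      missingFields = character(0))
}
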