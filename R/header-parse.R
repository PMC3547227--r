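## Instrument header parsing.
##
## Headers are line-oriented ASCII fixtures, one record per line:
##   R-AXIS dialect:  "key value value ..."        (e.g. "a3fPhi 0.0 0.0 1.0")
##   Bruker dialect:  "KEY : value value ..."      (e.g. "ANGLES : 0.0 358.75 0.0 0.0")
## The binary layouts of the real formats are deliberately not
## reproduced; these grammars carry the same information content.

readHeaderLines <- function(text) {
  if (length(text) == 1L && (file.exists(text) || grepl("\n", text)))
    text <- if (file.exists(text)) readLines(text, warn = FALSE)
            else strsplit(text, "\n", fixed = TRUE)[[1L]]
  text[nzchar(trimws(text))]
}

## split "key v1 v2 ..." records; returns named list of character vectors
parseKeyValueLines <- function(lines, sep = NULL) {
  out <- list()
  for (ln in lines) {
    if (!is.null(sep)) {
      parts <- strsplit(ln, sep, fixed = TRUE)[[1L]]
      key <- trimws(parts[1L])
      val <- trimws(paste(parts[-1L], collapse = sep))
    } else {
      m <- regexpr("\\S+", ln)
      key <- regmatches(ln, m)
      val <- trimws(substring(ln, m + attr(m, "match.length")))
    }
    out[[key]] <- if (nzchar(val)) strsplit(val, "\\s+")[[1L]] else character(0)
  }
  out
}

headerNumeric <- function(records, key, n = NULL, required = FALSE,
                          default = NULL) {
  if (!key %in% names(records)) {
    if (required) stop(sprintf("mandatory header key '%s' is absent", key))
    return(default)
  }
  v <- suppressWarnings(as.numeric(records[[key]]))
  if (length(v) == 0L || anyNA(v))
    stop(sprintf("malformed numeric field for header key '%s'", key))
  if (!is.null(n) && length(v) < n)
    stop(sprintf("header key '%s' carries %d value(s); %d required",
                 key, length(v), n))
  v
}

#' Parse an R-AXIS image-plate header
#'
#' Reads the key-value dialect of the R-AXIS image-plate header fixture:
#' \code{a3fPhi} (spindle start, offset, rotation range per frame),
#' \code{a3fCircle} (goniometer start angles omega, chi, swing theta),
#' \code{a2fXray1}/\code{a2fXray2} (beam centre, fast/slow pixels),
#' \code{nFast}/\code{nSlow} and \code{fPixelSize} (geometry, mandatory),
#' \code{nIP_num}, \code{ImhCompression} (overflow handling;
#' \code{RATIO R} gives the overflow scale ratio, default 8) and
#' \code{a4cSpindle} (spindle orientation, frequently left empty).
#'
#' The format carries no gain: gain defaults to 1.0 ADU/photon and
#' "gain" is recorded in the missing-fields ledger, as are the
#' fast/slow pixel-coordinate convention and the goniometer axis
#' layout, which this header type never provides.
#'
#' @param text path to a header file, or the header text itself
#'   (single string with newlines, or a character vector of lines).
#' @return an [ImageMetadata-class] with \code{dialect = "raxis"}.
#' @seealso [parseBrukerHeader()], [auditMetadata()]
#' @examples
#' hdr <- system.file("extdata", "raxis_scan001.header", package = "reflQC")
#' md <- parseRaxisHeader(hdr)
#' scanAxis(md); rotationPerFrame(md)
#' @export
parseRaxisHeader <- function(text) {
  rec <- parseKeyValueLines(readHeaderLines(text))

  nFast <- as.integer(headerNumeric(rec, "nFast", 1, required = TRUE))
  nSlow <- as.integer(headerNumeric(rec, "nSlow", 1, required = TRUE))
  pixelSize <- headerNumeric(rec, "fPixelSize", 1, required = TRUE)

  phi <- headerNumeric(rec, "a3fPhi", 3, required = TRUE)
  circ <- headerNumeric(rec, "a3fCircle", 3, default = c(0, 0, 0))
  beamFast <- headerNumeric(rec, "a2fXray1", 1, default = nFast / 2)
  beamSlow <- headerNumeric(rec, "a2fXray2", 1, default = nSlow / 2)

  missing <- c("gain", "fast/slow convention", "goniometer axis layout")
  gain <- 1.0   # the R-AXIS header has no gain field; EVAL-style default

  spindle <- "unknown"
  spindleVal <- rec[["a4cSpindle"]]
  if (is.null(spindleVal) || length(spindleVal) == 0L) {
    missing <- c(missing, "spindle orientation")
  } else if (tolower(spindleVal[1L]) %in% c("cw", "ccw")) {
    spindle <- tolower(spindleVal[1L])
  } else {
    missing <- c(missing, "spindle orientation")
  }

  ratio <- 8
  comp <- rec[["ImhCompression"]]
  if (!is.null(comp) && length(comp) >= 2L && toupper(comp[1L]) == "RATIO") {
    ratio <- suppressWarnings(as.numeric(comp[2L]))
    if (is.na(ratio) || ratio <= 0)
      stop("malformed numeric field for header key 'ImhCompression'")
  }

  if (phi[3L] <= 0)
    stop("a3fPhi: rotation range per frame must be > 0")

  new("ImageMetadata",
      dialect = "raxis", nFast = nFast, nSlow = nSlow,
      pixelSize = pixelSize, beamCenter = c(fast = beamFast, slow = beamSlow),
      scanAxis = "phi",
      startAngles = c(phi = phi[1L], omega = circ[1L], chi = circ[2L],
                      theta = circ[3L]),
      rotationPerFrame = phi[3L], gain = gain,
      overflowScheme = "raxis_scaled", baselineOffset = 0,
      overflowRatio = ratio,
      correctionRefs = c(flood_field = NA_character_,
                         distortion = NA_character_,
                         dark = NA_character_),
      spindleSense = spindle, missingFields = missing)
}

#' Parse a Bruker CCD frame header
#'
#' Reads the keyword dialect of the Bruker frame header fixture.
#' \code{ANGLES} lists the goniometer start angles in the order
#' (2theta, omega, phi, chi); \code{AXIS} selects the scan axis
#' (2 = omega, 3 = phi); \code{NPIXELB} (bytes per stored pixel) is
#' mandatory, as the pixel depth is otherwise unrecoverable;
#' \code{NEXP}'s fourth numeric field is the baseline offset;
#' \code{CCDPARM}'s first numeric field is the detector gain in
#' ADU/photon; \code{CENTER} gives the beam centre; \code{INCREME} the
#' rotation per frame; \code{CORRECT}/\code{WARFIL}/\code{DARK} name
#' the flood-field, spatial-distortion and dark-current correction
#' references.
#'
#' @inheritParams parseRaxisHeader
#' @return an [ImageMetadata-class] with \code{dialect = "bruker"}.
#' @seealso [parseRaxisHeader()], [auditMetadata()]
#' @examples
#' hdr <- system.file("extdata", "bruker_frame001.header", package = "reflQC")
#' md <- parseBrukerHeader(hdr)
#' startAngles(md); gain(md)
#' @export
parseBrukerHeader <- function(text) {
  rec <- parseKeyValueLines(readHeaderLines(text), sep = ":")

  if (!"NPIXELB" %in% names(rec))
    stop("mandatory header key 'NPIXELB' is absent (pixel depth unrecoverable)")
  headerNumeric(rec, "NPIXELB", 1)
  nSlow <- as.integer(headerNumeric(rec, "NROWS", 1, required = TRUE))
  nFast <- as.integer(headerNumeric(rec, "NCOLS", 1, required = TRUE))
  pixelSize <- headerNumeric(rec, "PIXSIZE", 1, required = TRUE)

  angles <- headerNumeric(rec, "ANGLES", 4, required = TRUE)
  names(angles) <- c("two_theta", "omega", "phi", "chi")

  axisCode <- headerNumeric(rec, "AXIS", 1, required = TRUE)
  scanAxis <- switch(as.character(as.integer(axisCode)),
                     "2" = "omega", "3" = "phi",
                     stop(sprintf(
                       "AXIS value %s outside the documented set {2 (omega), 3 (phi)}",
                       format(axisCode))))

  missing <- character(0)
  increme <- rec[["INCREME"]]
  if (is.null(increme)) {
    rotation <- 0.5
    missing <- c(missing, "rotation per frame")
  } else {
    rotation <- headerNumeric(rec, "INCREME", 1)[1L]
  }

  ccdparm <- headerNumeric(rec, "CCDPARM", 1, default = NULL)
  if (is.null(ccdparm)) {
    gain <- 1.0
    missing <- c(missing, "gain")
  } else {
    gain <- ccdparm[1L]   # fixture convention: first CCDPARM field
  }

  nexp <- headerNumeric(rec, "NEXP", 4, default = NULL)
  baseline <- if (is.null(nexp)) 0 else nexp[4L]

  centre <- headerNumeric(rec, "CENTER", 2, default = c(nFast / 2, nSlow / 2))

  refOf <- function(key) {
    v <- rec[[key]]
    if (is.null(v) || length(v) == 0L) NA_character_
    else paste(v, collapse = " ")
  }

  ## rotation senses are not encoded in this header type
  missing <- c(missing, "spindle orientation")

  new("ImageMetadata",
      dialect = "bruker", nFast = nFast, nSlow = nSlow,
      pixelSize = pixelSize,
      beamCenter = c(fast = centre[1L], slow = centre[2L]),
      scanAxis = scanAxis, startAngles = angles,
      rotationPerFrame = rotation, gain = gain,
      overflowScheme = "bruker_table", baselineOffset = baseline,
      overflowRatio = 8,
      correctionRefs = c(flood_field = refOf("CORRECT"),
                         distortion = refOf("WARFIL"),
                         dark = refOf("DARK")),
      spindleSense = "unknown", missingFields = missing)
}

## ---- accessors ----

#' ImageMetadata accessors
#'
#' @param md an [ImageMetadata-class].
#' @return the corresponding field.
#' @name ImageMetadata-accessors
NULL

#' @rdname ImageMetadata-accessors
#' @export
headerDialect <- function(md) { stopifnot(is(md, "ImageMetadata")); md@dialect }

#' @rdname ImageMetadata-accessors
#' @export
scanAxis <- function(md) { stopifnot(is(md, "ImageMetadata")); md@scanAxis }

#' @rdname ImageMetadata-accessors
#' @export
startAngles <- function(md) { stopifnot(is(md, "ImageMetadata")); md@startAngles }

#' @rdname ImageMetadata-accessors
#' @export
rotationPerFrame <- function(md) {
  stopifnot(is(md, "ImageMetadata")); md@rotationPerFrame
}

#' @rdname ImageMetadata-accessors
#' @export
gain <- function(md) { stopifnot(is(md, "ImageMetadata")); md@gain }

#' @rdname ImageMetadata-accessors
#' @export
beamCenter <- function(md) { stopifnot(is(md, "ImageMetadata")); md@beamCenter }

#' @rdname ImageMetadata-accessors
#' @export
missingFields <- function(md) {
  stopifnot(is(md, "ImageMetadata")); md@missingFields
}

#' @rdname ImageMetadata-accessors
#' @export
correctionRefs <- function(md) {
  stopifnot(is(md, "ImageMetadata")); md@correctionRefs
}

#' @rdname ImageMetadata-accessors
#' @export
spindleSense <- function(md) { stopifnot(is(md, "ImageMetadata")); md@spindleSense }

setMethod("show", "ImageMetadata", function(object) {
  cat(sprintf("ImageMetadata [%s]\n", object@dialect))
  cat(sprintf("  detector : %d x %d px, %.2f um/px, beam (%.1f, %.1f)\n",
              object@nFast, object@nSlow, object@pixelSize,
              object@beamCenter[1L], object@beamCenter[2L]))
  cat(sprintf("  scan     : %s, %.3f deg/frame, start [%s]\n",
              object@scanAxis, object@rotationPerFrame,
              paste(sprintf("%s=%.2f", names(object@startAngles),
                            object@startAngles), collapse = ", ")))
  cat(sprintf("  gain     : %.2f ADU/photon;  overflow: %s;  baseline %g ADU\n",
              object@gain, object@overflowScheme, object@baselineOffset))
  cat(sprintf("  spindle  : %s\n", object@spindleSense))
  if (length(object@missingFields))
    cat("  missing  :", paste(object@missingFields, collapse = "; "), "\n")
})
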