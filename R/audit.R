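#' Audit image-header metadata for completeness
#'
#' Checks a parsed header against the list of things data-processing
#' software needs but vendor headers frequently omit: the spindle
#' rotation sense, the fast/slow pixel-coordinate convention, the
#' detector gain, the goniometer axis layout, and (for detectors whose
#' images are vendor-corrected) the provenance of the flood-field,
#' distortion and dark-current corrections.  Each absent item yields
#' one finding; a fully specified header yields an empty table.  The
#' audit is monotone: removing information from a header can only add
#' findings.
#'
#' @param md an [ImageMetadata-class].
#' @return data.frame with columns \code{field}, \code{severity}
#'   ("warning" for items that block unambiguous reprocessing,
#'   "info" where a documented default is in force), \code{note}.
#' @seealso [parseRaxisHeader()], [parseBrukerHeader()]
#' @examples
#' md <- parseRaxisHeader(system.file("extdata", "raxis_scan001.header",
#'                                    package = "reflQC"))
#' auditMetadata(md)
#' @export
auditMetadata <- function(md) {
  stopifnot(is(md, "ImageMetadata"))
  findings <- list()
  add <- function(field, severity, note)
    findings[[length(findings) + 1L]] <<-
      data.frame(field = field, severity = severity, note = note)

  if (md@spindleSense == "unknown")
    add("spindle orientation", "warning",
        "rotation sense of the scan axis not recorded; must be known a priori or inferred from consecutive frames")
  if ("fast/slow convention" %in% md@missingFields)
    add("fast/slow convention", "warning",
        "fastest and slowest running pixel coordinates not given; eight interpretations of the image axes are possible")
  if ("gain" %in% md@missingFields)
    add("gain", "info",
        "no detector gain in header; default 1.0 ADU/photon assumed, affecting sigma(I) estimates")
  if ("goniometer axis layout" %in% md@missingFields)
    add("goniometer axis layout", "warning",
        "layout of the goniometer axes not described in the header")
  if ("rotation per frame" %in% md@missingFields)
    add("rotation per frame", "info",
        "rotation increment per frame absent; dialect default applied")
  if (md@dialect == "bruker") {
    ## vendor-corrected detector: correction provenance must travel with
    ## the image for faithful reprocessing
    corrNote <- c(
      flood_field = "flood-field (non-uniformity) correction reference absent; detector sensitivity provenance unknown",
      distortion = "spatial-distortion (unwarp) reference absent",
      dark = "dark-current correction reference absent")
    for (nm in names(corrNote))
      if (is.na(md@correctionRefs[[nm]]))
        add(paste0(nm, " provenance"), "info", corrNote[[nm]])
  }

  if (!length(findings))
    return(data.frame(field = character(0), severity = character(0),
                      note = character(0)))
  out <- do.call(rbind, findings)
  rownames(out) <- NULL
  out
}
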