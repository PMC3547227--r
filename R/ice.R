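#' Detect ice-ring contamination in resolution windows
#'
#' For each candidate ice-ring d-spacing, compares the median merged
#' group intensity inside the window \code{[center - halfWidth, center
#' + halfWidth]} against a local baseline, the median over the two
#' flanking windows of equal width on either side.  The raw detection
#' statistic is a robust z-score of the median shift,
#' \deqn{z = \frac{\mathrm{med}_{in} - \mathrm{med}_{flank}}
#'   {1.4826\,\mathrm{MAD}_{flank}\sqrt{\pi/(2 n_{in})}},}
#' i.e. the shift divided by the approximate standard error of the
#' window median under the flanking intensity distribution (Wilson
#' intensities have unit coefficient of variation, so the raw spread
#' itself would mask any plausible ring).  Because that standard error
#' is only asymptotic and the Wilson falloff tilts the local baseline,
#' the raw z is standardised against its own empirical null: the same
#' statistic is evaluated at decoy centers spanning the data's
#' resolution range away from every candidate, and the calibrated
#' score is \eqn{(z - \mathrm{med}_{decoy}) /
#' (1.4826\,\mathrm{MAD}_{decoy})}.  Windows whose calibrated score
#' exceeds \code{zThreshold} are returned.  With fewer than 8 usable
#' decoys the raw z is compared against the threshold directly.
#'
#' @param merged a [MergedReflections-class].
#' @param candidateCenters candidate ring d-spacings in Angstrom
#'   (default: the three strongest hexagonal-ice rings).
#' @param halfWidth window half width in Angstrom (default 0.05).
#' @param zThreshold detection threshold (default 4).
#' @param minGroups minimum groups required inside the window and in
#'   the flanks to attempt detection (default 10 each).
#' @return data.frame with one row per \emph{flagged} window: columns
#'   dCenter, halfWidth, zscore, nIn.
#' @seealso [applyExclusions()]
#' @export
detectIceRings <- function(merged,
                           candidateCenters = c(3.90, 3.67, 3.44),
                           halfWidth = 0.05, zThreshold = 4,
                           minGroups = 10L) {
  stopifnot(is(merged, "MergedReflections"))
  empty <- data.frame(dCenter = numeric(0), halfWidth = numeric(0),
                      zscore = numeric(0), nIn = integer(0))
  if (length(candidateCenters) == 0L) return(empty)
  g <- merged@groups

  rawZ <- function(ctr) {
    inWin <- abs(g$d - ctr) <= halfWidth
    flank <- !inWin & abs(g$d - ctr) <= 3 * halfWidth
    if (sum(inWin) < minGroups || sum(flank) < minGroups)
      return(c(z = NA_real_, nIn = sum(inWin)))
    madFl <- mad(g$Imean[flank])   # 1.4826 * MAD, already scaled
    if (madFl <= 0) return(c(z = NA_real_, nIn = sum(inWin)))
    z <- (median(g$Imean[inWin]) - median(g$Imean[flank])) /
      (madFl * sqrt(pi / (2 * sum(inWin))))
    c(z = z, nIn = sum(inWin))
  }

  ## empirical null from decoy windows away from every candidate
  decoys <- seq(min(g$d) + 3 * halfWidth, max(g$d) - 3 * halfWidth,
                by = 2 * halfWidth)
  decoys <- decoys[vapply(decoys, function(x)
    all(abs(x - candidateCenters) > 3 * halfWidth), logical(1))]
  zDecoy <- vapply(decoys, function(x) rawZ(x)[["z"]], numeric(1))
  zDecoy <- zDecoy[is.finite(zDecoy)]
  calibrate <- function(z) {
    if (length(zDecoy) < 8L) return(z)
    scale <- mad(zDecoy, center = median(zDecoy))
    if (scale <= 0) return(z)
    (z - median(zDecoy)) / scale
  }

  rows <- list()
  for (ctr in candidateCenters) {
    rz <- rawZ(ctr)
    z <- calibrate(rz[["z"]])
    if (is.finite(z) && z > zThreshold)
      rows[[length(rows) + 1L]] <-
        data.frame(dCenter = ctr, halfWidth = halfWidth,
                   zscore = z, nIn = as.integer(rz[["nIn"]]))
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exclude resolution windows and a low-resolution cutoff
#'
#' Flags \code{flagIce} on every observation whose d-spacing lies
#' inside any of the given (non-overlapping) windows, and
#' \code{flagLowres} on observations with \code{d > lowResCutoff}
#' (reflections at very low scattering angle, e.g. partly shadowed by
#' the beam stop).  Whole-window exclusion is deliberately independent
#' of the per-observation sigma-based rejection so the interplay of the
#' two paths can be studied.
#'
#' @param observations observation data.frame (see
#'   [mergeObservations()] for the required columns).
#' @param windows data.frame with columns dCenter, halfWidth (e.g. from
#'   [detectIceRings()]); must be non-overlapping.
#' @param lowResCutoff d-spacing in Angstrom above which observations
#'   are excluded, or NULL for none.
#' @param uniqueRef unique reference set from [generateUnique()], used
#'   with \code{lc} to report the completeness cost.
#' @param lc the [LaueClass-class] for the completeness bookkeeping.
#' @return list with \code{observations} (flags updated),
#'   \code{completenessBefore}, \code{completenessAfter} and
#'   \code{windows} (input windows with an \code{nExcluded} column).
#' @export
applyExclusions <- function(observations, windows = NULL,
                            lowResCutoff = NULL,
                            uniqueRef = NULL, lc = NULL) {
  obs <- normalizeObservations(observations)
  if (!is.null(windows) && nrow(windows) > 1L) {
    o <- order(windows$dCenter)
    lo <- windows$dCenter[o] - windows$halfWidth[o]
    hi <- windows$dCenter[o] + windows$halfWidth[o]
    if (any(lo[-1L] < hi[-length(hi)]))
      stop("exclusion windows overlap")
  }
  comp <- function(o) {
    if (is.null(uniqueRef) || is.null(lc)) return(NA_real_)
    keep <- !(o$flagOutlier | o$flagIce | o$flagLowres)
    if (!any(keep)) return(0)
    asu <- mapToASU(cbind(o$h[keep], o$k[keep], o$l[keep]), lc)
    length(unique(paste(asu[, 1L], asu[, 2L], asu[, 3L]))) /
      nrow(uniqueRef)
  }
  before <- comp(obs)
  nExcluded <- integer(0)
  if (!is.null(windows) && nrow(windows)) {
    nExcluded <- integer(nrow(windows))
    for (i in seq_len(nrow(windows))) {
      hit <- abs(obs$d - windows$dCenter[i]) <= windows$halfWidth[i]
      nExcluded[i] <- sum(hit & !obs$flagIce)
      obs[hit, flagIce := TRUE]
    }
    windows <- cbind(as.data.frame(windows), nExcluded = nExcluded)
  } else {
    windows <- data.frame(dCenter = numeric(0), halfWidth = numeric(0),
                          nExcluded = integer(0))
  }
  if (!is.null(lowResCutoff))
    obs[d > lowResCutoff, flagLowres := TRUE]
  list(observations = as.data.frame(obs),
       completenessBefore = before,
       completenessAfter = comp(obs),
       windows = windows)
}
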