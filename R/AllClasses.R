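## S4 class definitions and validity methods.

#' UnitCell: crystallographic unit-cell constants
#'
#' Cell edge lengths in Angstrom and angles in degrees.  Only orthogonal
#' cells (all angles 90 degrees) are supported by the resolution
#' machinery; the tetragonal constraint (a = b) is checkable via
#' [isTetragonal()] but never enforced, because detecting its violation
#' is part of the analysis.
#'
#' @slot a,b,c cell edges (Angstrom), all > 0.
#' @slot alpha,beta,gamma cell angles (degrees), each in (0, 180).
#' @seealso [unitCell()], [dSpacing()], [isOrthogonal()]
#' @exportClass UnitCell
setClass("UnitCell",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 alpha = "numeric", beta = "numeric", gamma = "numeric"))

setValidity("UnitCell", function(object) {
  len <- c(a = object@a, b = object@b, c = object@c)
  ang <- c(alpha = object@alpha, beta = object@beta, gamma = object@gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    return("cell edges must be finite and > 0")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    return("cell angles must lie in (0, 180) degrees")
  TRUE
})

#' LaueClass: point-group operators of a Laue class
#'
#' Holds the name and the full set of 3x3 integer matrices acting on
#' Miller indices (h, k, l) by right multiplication.  Only the two
#' classes relevant to tetragonal lysozyme-style problems are provided:
#' \describe{
#'   \item{"4/mmm"}{16 operators (holohedral tetragonal).}
#'   \item{"mmm"}{8 operators (orthorhombic; all sign combinations).}
#' }
#' The operator set always forms a group and contains the inversion.
#'
#' @slot name "4/mmm" or "mmm".
#' @slot operators list of 3x3 integer matrices.
#' @seealso [laueClass()], [mapToASU()], [generateUnique()]
#' @exportClass LaueClass
setClass("LaueClass",
  representation(name = "character", operators = "list"))

setValidity("LaueClass", function(object) {
  if (length(object@name) != 1L || !object@name %in% c("4/mmm", "mmm"))
    return("name must be one of '4/mmm', 'mmm'")
  ops <- object@operators
  expected <- if (object@name == "4/mmm") 16L else 8L
  if (length(ops) != expected)
    return(sprintf("class %s must carry %d operators", object@name, expected))
  keys <- vapply(ops, function(m) paste(m, collapse = ","), character(1))
  if (anyDuplicated(keys))
    return("duplicate operators")
  if (!paste(-diag(3), collapse = ",") %in% keys)
    return("operator set must contain the inversion -I")
  ## closure under multiplication
  for (m1 in ops) for (m2 in ops) {
    if (!paste(m1 %*% m2, collapse = ",") %in% keys)
      return("operator set is not closed under multiplication")
  }
  TRUE
})

#' ImageMetadata: unified instrument/scan/detector description
#'
#' The dialect-independent result of parsing one diffraction image
#' header, together with a ledger of fields the header did not provide
#' (for which documented defaults are in force).
#'
#' @slot dialect "raxis" or "bruker".
#' @slot nFast,nSlow detector pixel counts along the fast and slow
#'   directions.
#' @slot pixelSize pixel size in micrometres.
#' @slot beamCenter direct-beam position, (fast, slow) in pixels.
#' @slot scanAxis "phi" or "omega".
#' @slot startAngles named numeric vector of goniometer start angles in
#'   degrees (R-AXIS: phi, omega, chi, theta; Bruker: two_theta, omega,
#'   phi, chi).
#' @slot rotationPerFrame rotation range per frame, degrees.
#' @slot gain detector gain in ADU per X-ray photon; defaults to 1.0
#'   when the header carries no gain (and "gain" is listed in
#'   \code{missingFields}).
#' @slot overflowScheme "raxis_scaled" or "bruker_table"; tied to the
#'   dialect.
#' @slot baselineOffset ADU offset added on storage so that small
#'   negative values fit the stored integer range (Bruker).
#' @slot overflowRatio scale ratio R of the R-AXIS overflow rule
#'   (stored v >= 32768 decodes to (v - 32768) * R).
#' @slot correctionRefs named character vector with entries
#'   flood_field, distortion, dark; \code{NA} when the header carries no
#'   reference.
#' @slot spindleSense "cw", "ccw" or "unknown".
#' @slot missingFields character vector naming fields absent from the
#'   header whose documented defaults apply.
#' @seealso [parseRaxisHeader()], [parseBrukerHeader()],
#'   [auditMetadata()], [decodePixels()]
#' @exportClass ImageMetadata
setClass("ImageMetadata",
  representation(
    dialect = "character",
    nFast = "integer", nSlow = "integer",
    pixelSize = "numeric",
    beamCenter = "numeric",
    scanAxis = "character",
    startAngles = "numeric",
    rotationPerFrame = "numeric",
    gain = "numeric",
    overflowScheme = "character",
    baselineOffset = "numeric",
    overflowRatio = "numeric",
    correctionRefs = "character",
    spindleSense = "character",
    missingFields = "character"))

setValidity("ImageMetadata", function(object) {
  if (!object@dialect %in% c("raxis", "bruker"))
    return("dialect must be 'raxis' or 'bruker'")
  if (object@nFast <= 0L || object@nSlow <= 0L)
    return("pixel counts must be > 0")
  if (!is.finite(object@pixelSize) || object@pixelSize <= 0)
    return("pixelSize must be > 0")
  if (!is.finite(object@rotationPerFrame) || object@rotationPerFrame <= 0)
    return("rotationPerFrame must be > 0")
  if (!is.finite(object@gain) || object@gain <= 0)
    return("gain must be > 0")
  if (!object@scanAxis %in% c("phi", "omega"))
    return("scanAxis must be 'phi' or 'omega'")
  if (!object@spindleSense %in% c("cw", "ccw", "unknown"))
    return("spindleSense must be 'cw', 'ccw' or 'unknown'")
  want <- switch(object@dialect, raxis = "raxis_scaled", bruker = "bruker_table")
  if (object@overflowScheme != want)
    return(sprintf("dialect '%s' requires overflowScheme '%s'",
                   object@dialect, want))
  if (!all(c("flood_field", "distortion", "dark") %in%
           names(object@correctionRefs)))
    return("correctionRefs must have entries flood_field, distortion, dark")
  if (object@overflowRatio <= 0)
    return("overflowRatio must be > 0")
  TRUE
})

#' NoiseModel: physical detector noise constants
#'
#' Variance decomposition used by the generator and by
#' [varianceModel()]:
#' \deqn{\sigma^2(I) = (\sigma^2_{dark} + \sigma^2_{read}) +
#'   (\sigma^2_{bg} + I) + (g I)^2,}
#' i.e. a second-order polynomial \eqn{k_0 + k_1 I + k_2 I^2} with
#' \eqn{k_0 = \sigma^2_{dark}+\sigma^2_{read}+\sigma^2_{bg}},
#' \eqn{k_1 = 1}, \eqn{k_2 = g^2}.  \code{KTrue} is a multiplicative
#' misestimation factor applied by the generator to the polynomial part
#' (what error-model refinement should recover as K).
#'
#' @slot sigmaDark,sigmaRead,sigmaBg noise standard deviations, ADU.
#' @slot gain detector gain, ADU per photon (metadata; the Poisson term
#'   is expressed directly in ADU with \eqn{k_1 = 1}).
#' @slot gTrue fractional-intensity (instability) error, dimensionless,
#'   in [0, 1).
#' @slot KTrue variance misestimation factor, >= 0 (0 disables the
#'   polynomial noise entirely, giving noise-free observations for
#'   exactness checks).
#' @seealso [noiseModel()], [varianceModel()], [simulateDataset()]
#' @exportClass NoiseModel
setClass("NoiseModel",
  representation(sigmaDark = "numeric", sigmaRead = "numeric",
                 sigmaBg = "numeric", gain = "numeric",
                 gTrue = "numeric", KTrue = "numeric"))

setValidity("NoiseModel", function(object) {
  if (any(c(object@sigmaDark, object@sigmaRead, object@sigmaBg) < 0))
    return("sigma terms must be >= 0")
  if (object@gain <= 0) return("gain must be > 0")
  if (object@gTrue < 0 || object@gTrue >= 1)
    return("gTrue must lie in [0, 1)")
  if (object@KTrue < 0) return("KTrue must be >= 0")
  TRUE
})

#' SimulationConfig: study conditions for the reflection generator
#'
#' @slot cell a [UnitCell-class].
#' @slot trueLaue declared symmetry label ("4/mmm" or "mmm"); the
#'   effective symmetry is controlled continuously by \code{tau}.
#' @slot dMin,dMax resolution range, Angstrom (dMin < dMax).
#' @slot BTrue overall Wilson B factor, Angstrom^2.
#' @slot scaleC mean-intensity scale at zero scattering angle, ADU.
#' @slot targetRedundancy mean observations per unique reflection.
#' @slot noise a [NoiseModel-class].
#' @slot tau symmetry correlation between 4/mmm-equivalent mmm pairs in
#'   [0, 1]; 1 restores exact tetragonal equality.
#' @slot iceWindows data.frame with columns dCenter, halfWidth,
#'   excessFactor, contaminationFraction (possibly 0 rows); windows must
#'   not overlap.
#' @slot pObserve per-drawn-observation inclusion probability.
#' @slot seed integer RNG seed.
#' @seealso [simulationConfig()], [simulateDataset()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(cell = "UnitCell", trueLaue = "character",
                 dMin = "numeric", dMax = "numeric",
                 BTrue = "numeric", scaleC = "numeric",
                 targetRedundancy = "numeric",
                 noise = "NoiseModel", tau = "numeric",
                 iceWindows = "data.frame",
                 pObserve = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  if (!object@trueLaue %in% c("4/mmm", "mmm"))
    return("trueLaue must be '4/mmm' or 'mmm'")
  if (object@dMin <= 0 || object@dMin >= object@dMax)
    return("need 0 < dMin < dMax")
  if (object@targetRedundancy <= 0)
    return("targetRedundancy must be > 0")
  if (object@tau < 0 || object@tau > 1)
    return("tau must lie in [0, 1]")
  if (object@pObserve <= 0 || object@pObserve > 1)
    return("pObserve must lie in (0, 1]")
  iw <- object@iceWindows
  need <- c("dCenter", "halfWidth", "excessFactor", "contaminationFraction")
  if (!all(need %in% names(iw)))
    return("iceWindows must have columns dCenter, halfWidth, excessFactor, contaminationFraction")
  if (nrow(iw) > 1L) {
    o <- order(iw$dCenter)
    lo <- iw$dCenter[o] - iw$halfWidth[o]
    hi <- iw$dCenter[o] + iw$halfWidth[o]
    if (any(lo[-1L] < hi[-length(hi)]))
      return("ice windows overlap")
  }
  if (nrow(iw) > 0L &&
      (any(iw$halfWidth <= 0) || any(iw$contaminationFraction < 0) ||
       any(iw$contaminationFraction > 1)))
    return("iceWindows: halfWidth > 0 and contaminationFraction in [0, 1] required")
  TRUE
})

#' MergedReflections: observations grouped by symmetry-unique reflection
#'
#' Result of [mergeObservations()].  Observations flagged by any of the
#' rejection paths (outlier, ice, low resolution) do not participate in
#' groups.  Group means are inverse-variance weighted:
#' \eqn{\langle I\rangle = \sum w I / \sum w} with \eqn{w = 1/\sigma^2},
#' and \eqn{\sigma_{\langle I\rangle} = (\sum w)^{-1/2}}.
#'
#' @slot observations data.frame of participating and flagged
#'   observations with their asymmetric-unit key (asuH, asuK, asuL) and
#'   integer groupId (NA for flagged rows).
#' @slot groups data.frame, one row per symmetry-unique reflection:
#'   asuH, asuK, asuL, d, n, Imean, sigmaMean.
#' @slot laue the [LaueClass-class] used for grouping.
#' @seealso [groupTable()], [observationTable()], [computeStats()]
#' @exportClass MergedReflections
setClass("MergedReflections",
  representation(observations = "data.frame", groups = "data.frame",
                 laue = "LaueClass"))

#' ErrorModel: refined (K, g) sigma-correction parameters
#'
#' SADABS-style corrected variance
#' \eqn{\sigma^2_{new} = K[\sigma^2 + (g\langle I\rangle)^2]}, with K and
#' g chosen so that the merging \eqn{\chi^2} is close to 1 in every
#' intensity bin.
#'
#' @slot K multiplicative variance factor (> 0).
#' @slot g fractional-intensity error term (>= 0).
#' @slot chi2Before,chi2After overall \eqn{\chi^2} with delivered and
#'   corrected sigmas.
#' @slot converged FALSE when refinement hit the degenerate-input
#'   fallback (K = 1, g = 0).
#' @slot nBins number of equal-count intensity bins used.
#' @seealso [refineErrorModel()], [applyErrorModel()], [chiSquare()]
#' @exportClass ErrorModel
setClass("ErrorModel",
  representation(K = "numeric", g = "numeric",
                 chi2Before = "numeric", chi2After = "numeric",
                 converged = "logical", nBins = "integer"))

setValidity("ErrorModel", function(object) {
  if (object@K <= 0) return("K must be > 0")
  if (object@g < 0) return("g must be >= 0")
  TRUE
})

#' MergeStats: merging statistics overall and per resolution shell
#'
#' Standard internal-agreement residuals over groups with n >= 2:
#' \deqn{R_{merge} = \sum_h\sum_i |I_i - \langle I\rangle_h| /
#'   \sum_h\sum_i I_i}
#' with the group numerator terms multiplied by
#' \eqn{\sqrt{n_h/(n_h-1)}} for \eqn{R_{meas}} and
#' \eqn{\sqrt{1/(n_h-1)}} for \eqn{R_{pim}}.  Completeness is the
#' fraction of the unique reference set observed; redundancy is mean
#' observations per observed unique; mean I/sigma is the per-group mean
#' of \eqn{I_{mean}/\sigma_{mean}}.
#'
#' @slot rMerge,rMeas,rPim dimensionless residuals (NA when no group
#'   has n >= 2).
#' @slot meanIOverSigma per-group mean merged I/sigma.
#' @slot redundancy mean observations per observed unique reflection.
#' @slot completeness fraction of the unique reference observed.
#' @slot nObs,nUnique observation and unique counts.
#' @slot perShell data.frame of the same fields per resolution shell
#'   (equal group count, ordered by d; the last row is the outer,
#'   highest-resolution shell), with dMin/dMax columns.
#' @seealso [computeStats()], [outerShell()]
#' @exportClass MergeStats
setClass("MergeStats",
  representation(rMerge = "numeric", rMeas = "numeric", rPim = "numeric",
                 meanIOverSigma = "numeric", redundancy = "numeric",
                 completeness = "numeric",
                 nObs = "integer", nUnique = "integer",
                 perShell = "data.frame"))

#' WilsonFit: straight-line Wilson plot fit
#'
#' Ordinary least squares of \eqn{\ln\langle I\rangle} on shell-mean
#' \eqn{s^2 = (\sin\theta/\lambda)^2}; \eqn{B = -slope/2}.
#'
#' @slot B Wilson B factor, Angstrom^2.
#' @slot lnC intercept.
#' @slot stderrB standard error of B.
#' @slot s2Range range of shell-mean s^2 used.
#' @slot nShellsUsed shells entering the fit (>= 3).
#' @slot shells data.frame with s2, meanI, n per shell.
#' @seealso [wilsonFit()]
#' @exportClass WilsonFit
setClass("WilsonFit",
  representation(B = "numeric", lnC = "numeric", stderrB = "numeric",
                 s2Range = "numeric", nShellsUsed = "integer",
                 shells = "data.frame"))

#' LaueDecision: symmetry choice from internal agreement
#'
#' @slot statsByClass named list of [MergeStats-class], one per
#'   candidate Laue class.
#' @slot chosen name of the selected class.
#' @slot deltaRMeas \eqn{R_{meas}(4/mmm) - R_{meas}(mmm)}.
#' @slot deltaThreshold decision threshold applied.
#' @seealso [laueCompare()]
#' @exportClass LaueDecision
setClass("LaueDecision",
  representation(statsByClass = "list", chosen = "character",
                 deltaRMeas = "numeric", deltaThreshold = "numeric"))

#' QCReport: one-dataset quality summary
#'
#' Collects the outputs of the full pipeline into the row format of a
#' data-processing statistics table (outer-resolution-shell values shown
#' in brackets by the show method).
#'
#' @slot label dataset label.
#' @slot cell the [UnitCell-class].
#' @slot resolutionRange c(dMax, dMin), Angstrom.
#' @slot stats final [MergeStats-class] under the chosen Laue class.
#' @slot errorModel the refined [ErrorModel-class].
#' @slot wilson the [WilsonFit-class].
#' @slot laue the [LaueDecision-class].
#' @slot nRejectedOutliers observations flagged by 4-sigma rejection.
#' @slot iceWindows data.frame of detected/excluded ice windows.
#' @slot completenessBeforeExclusion,completenessAfterExclusion
#'   completeness on either side of the resolution-window exclusions.
#' @slot files named character vector of intermediate files written.
#' @seealso [runPipeline()]
#' @exportClass QCReport
setClass("QCReport",
  representation(label = "character", cell = "UnitCell",
                 resolutionRange = "numeric",
                 stats = "MergeStats", errorModel = "ErrorModel",
                 wilson = "WilsonFit", laue = "LaueDecision",
                 nRejectedOutliers = "integer",
                 iceWindows = "data.frame",
                 completenessBeforeExclusion = "numeric",
                 completenessAfterExclusion = "numeric",
                 files = "character"))
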