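#' Construct a detector noise model
#'
#' @param sigmaDark,sigmaRead,sigmaBg noise standard deviations in ADU
#'   (defaults 2, 3, 5: a quiet CCD/image-plate-scale dark and read
#'   noise with a moderate diffuse background).
#' @param gain detector gain, ADU per photon (default 1).
#' @param gTrue fractional-intensity instability factor (default 0.03,
#'   the middle of the range such refinements typically report).
#' @param KTrue variance misestimation factor the generator applies to
#'   the polynomial part of the variance (default 1: sigmas delivered
#'   on the correct scale).
#' @return a [NoiseModel-class].
#' @seealso [varianceModel()], [simulationConfig()]
#' @export
noiseModel <- function(sigmaDark = 2, sigmaRead = 3, sigmaBg = 5,
                       gain = 1, gTrue = 0.03, KTrue = 1) {
  new("NoiseModel", sigmaDark = as.numeric(sigmaDark),
      sigmaRead = as.numeric(sigmaRead), sigmaBg = as.numeric(sigmaBg),
      gain = as.numeric(gain), gTrue = as.numeric(gTrue),
      KTrue = as.numeric(KTrue))
}

#' @rdname noiseModel
#' @param nm a [NoiseModel-class].
#' @return \code{noiseFloor}: \eqn{k_0 = \sigma^2_{dark} +
#'   \sigma^2_{read} + \sigma^2_{bg}} in ADU^2.
#' @export
noiseFloor <- function(nm) {
  stopifnot(is(nm, "NoiseModel"))
  nm@sigmaDark^2 + nm@sigmaRead^2 + nm@sigmaBg^2
}

#' Standard hexagonal-ice contamination windows
#'
#' The three strongest hexagonal-ice powder rings (3.90, 3.67,
#' 3.44 Angstrom).  Excess factor and contamination fraction are
#' package conventions, not measured values.
#'
#' @param excessFactor multiplicative intensity inflation of a
#'   contaminated observation.
#' @param contaminationFraction probability that an observation inside
#'   a window is contaminated.
#' @param halfWidth window half width in Angstrom.
#' @return data.frame suitable for the \code{iceWindows} slot of a
#'   [SimulationConfig-class].
#' @export
defaultIceWindows <- function(excessFactor = 10,
                              contaminationFraction = 0.3,
                              halfWidth = 0.05) {
  data.frame(dCenter = c(3.90, 3.67, 3.44),
             halfWidth = halfWidth,
             excessFactor = excessFactor,
             contaminationFraction = contaminationFraction)
}

emptyIceWindows <- function() defaultIceWindows()[0L, , drop = FALSE]

#' Configure a synthetic reflection dataset
#'
#' Defaults describe the study conditions the package emulates: a
#' tetragonal lysozyme-style cell (a = b = 78.53, c = 37.36 Angstrom),
#' Wilson B of 15 Angstrom^2, mean redundancy 20 (the home-source data
#' sets this models had redundancies between roughly 12 and 31), near
#' complete observation (pObserve = 0.98), exact tetragonal symmetry
#' (tau = 1) and no ice contamination.
#'
#' @param cell a [UnitCell-class].
#' @param trueLaue declared symmetry label.
#' @param dMin,dMax resolution range in Angstrom.
#' @param BTrue Wilson B factor, Angstrom^2.
#' @param scaleC mean intensity at s = 0, ADU.
#' @param targetRedundancy mean observations per unique reflection.
#' @param noise a [NoiseModel-class].
#' @param tau symmetry correlation in [0, 1] between 4/mmm-equivalent
#'   mmm pairs; 1 = exact tetragonal intensities.
#' @param iceWindows data.frame as from [defaultIceWindows()]; empty
#'   for clean data.
#' @param pObserve inclusion probability per drawn observation.
#' @param seed integer RNG seed.
#' @return a [SimulationConfig-class].
#' @seealso [simulateDataset()]
#' @export
simulationConfig <- function(cell = unitCell(78.53, 78.53, 37.36),
                             trueLaue = "4/mmm",
                             dMin = 2.5, dMax = 20,
                             BTrue = 15, scaleC = 1000,
                             targetRedundancy = 20,
                             noise = noiseModel(),
                             tau = 1,
                             iceWindows = emptyIceWindows(),
                             pObserve = 0.98,
                             seed = 1L) {
  new("SimulationConfig", cell = cell, trueLaue = trueLaue,
      dMin = as.numeric(dMin), dMax = as.numeric(dMax),
      BTrue = as.numeric(BTrue), scaleC = as.numeric(scaleC),
      targetRedundancy = as.numeric(targetRedundancy),
      noise = noise, tau = as.numeric(tau),
      iceWindows = as.data.frame(iceWindows),
      pObserve = as.numeric(pObserve), seed = as.integer(seed))
}

#' Read a simulation config from a YAML file
#'
#' Keys mirror the arguments of [simulationConfig()]; \code{cell} is a
#' list/vector (a, b, c) or (a, b, c, alpha, beta, gamma), \code{noise}
#' a mapping of [noiseModel()] arguments, \code{iceWindows} a list of
#' mappings with dCenter/halfWidth/excessFactor/contaminationFraction.
#'
#' @param path YAML file path.
#' @return a [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$cell)) {
    v <- as.numeric(unlist(y$cell))
    args$cell <- if (length(v) >= 6) unitCell(v[1], v[2], v[3], v[4], v[5], v[6])
                 else unitCell(v[1], v[2], v[3])
  }
  if (!is.null(y$noise)) args$noise <- do.call(noiseModel, y$noise)
  if (!is.null(y$iceWindows))
    args$iceWindows <- do.call(rbind, lapply(y$iceWindows, as.data.frame))
  for (nm in c("trueLaue", "dMin", "dMax", "BTrue", "scaleC",
               "targetRedundancy", "tau", "pObserve", "seed"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  do.call(simulationConfig, args)
}

#' Simulate an unmerged reflection dataset with ground truth
#'
#' Generates the statistical structure the downstream analysis assumes:
#' \enumerate{
#'   \item Unique reflections are enumerated under mmm in
#'     \code{[dMin, dMax]}.  True intensities are acentric-Wilson
#'     (exponential) with mean \eqn{C\exp(-2 B s^2)}, \eqn{s = 1/(2d)}.
#'   \item For 4/mmm-equivalent mmm pairs (h,k,l)/(k,h,l), the second
#'     member's intensity is \eqn{\tau I_1 + (1-\tau) I_{indep}};
#'     \eqn{\tau = 1} restores exact tetragonal equality.
#'   \item Multiplicity per unique is Poisson(targetRedundancy), each
#'     drawn observation kept with probability \code{pObserve}.
#'   \item Each observation gets Gaussian noise with variance
#'     \eqn{K_{true}(k_0 + I_{true}) + (g_{true} I_{true})^2}, while the
#'     \emph{delivered} sigma is \eqn{\sqrt{k_0 + \max(I, 0)}} (the
#'     first two terms only), so error-model refinement has parameters
#'     to recover: analytically \eqn{K \approx K_{true}} and
#'     \eqn{g \approx g_{true}/\sqrt{K_{true}}}.
#'   \item Observations inside an ice window are inflated by
#'     \code{excessFactor} with probability
#'     \code{contaminationFraction}, without any sigma inflation; the
#'     ground-truth \code{contaminated} column records them.
#' }
#' Observation Miller indices are scattered over the mmm orbit by
#' random sign changes, so merging has to perform the asymmetric-unit
#' mapping.  Output is deterministic given \code{cfg@seed}.
#'
#' @param cfg a [SimulationConfig-class].
#' @return list with elements \code{observations} (data.frame: h, k, l,
#'   batch, I, sigma, d, flagOutlier, flagIce, flagLowres,
#'   contaminated), \code{truth} (data.frame: h, k, l, d, Itrue, one
#'   row per mmm-unique reflection) and \code{config}.
#' @examples
#' sim <- simulateDataset(simulationConfig(cell = unitCell(30, 30, 20),
#'                                         dMin = 3, seed = 7L))
#' head(sim$observations)
#' @export
simulateDataset <- function(cfg) {
  stopifnot(is(cfg, "SimulationConfig"))
  validObject(cfg)
  set.seed(cfg@seed)
  nm <- cfg@noise
  k0 <- noiseFloor(nm)

  uniq <- generateUnique(cfg@cell, laueClass("mmm"), cfg@dMin, cfg@dMax)
  nU <- nrow(uniq)
  s2 <- (1 / (2 * uniq$d))^2
  meanI <- cfg@scaleC * exp(-2 * cfg@BTrue * s2)
  Itrue <- rexp(nU) * meanI

  ## couple 4/mmm-equivalent pairs: the partner of (h,k,l) under the
  ## 4-fold is the mmm representative (k,h,l); rows with h > k are the
  ## "first" member, h < k the "second" (h == k is its own partner)
  if (cfg@tau < 1) {
    second <- which(uniq$h < uniq$k)
    if (length(second)) {
      firstKey <- paste(uniq$k[second], uniq$h[second], uniq$l[second])
      firstIdx <- match(firstKey, paste(uniq$h, uniq$k, uniq$l))
      Iindep <- rexp(length(second)) * meanI[second]
      Itrue[second] <- cfg@tau * Itrue[firstIdx] +
        (1 - cfg@tau) * Iindep
    }
  } else {
    second <- which(uniq$h < uniq$k)
    if (length(second)) {
      firstKey <- paste(uniq$k[second], uniq$h[second], uniq$l[second])
      firstIdx <- match(firstKey, paste(uniq$h, uniq$k, uniq$l))
      Itrue[second] <- Itrue[firstIdx]
    }
  }

  mult <- rpois(nU, cfg@targetRedundancy)
  if (cfg@pObserve < 1) mult <- rbinom(nU, mult, cfg@pObserve)
  obsIdx <- rep.int(seq_len(nU), mult)
  nObs <- length(obsIdx)

  ItrueObs <- Itrue[obsIdx]
  varObs <- nm@KTrue * (k0 + ItrueObs) + (nm@gTrue * ItrueObs)^2
  I <- ItrueObs + rnorm(nObs, 0, sqrt(varObs))
  sigma <- sqrt(k0 + pmax(I, 0))

  ## scatter indices over the mmm orbit (random sign changes)
  sgn <- matrix(sample(c(1L, -1L), 3L * nObs, replace = TRUE), ncol = 3L)
  h <- uniq$h[obsIdx] * sgn[, 1L]
  k <- uniq$k[obsIdx] * sgn[, 2L]
  l <- uniq$l[obsIdx] * sgn[, 3L]

  dObs <- uniq$d[obsIdx]
  contaminated <- logical(nObs)
  iw <- cfg@iceWindows
  if (nrow(iw)) {
    for (i in seq_len(nrow(iw))) {
      inWin <- abs(dObs - iw$dCenter[i]) <= iw$halfWidth[i]
      hit <- inWin & runif(nObs) < iw$contaminationFraction[i]
      I[hit] <- I[hit] * iw$excessFactor[i]
      contaminated <- contaminated | hit
    }
  }

  observations <- data.frame(
    h = h, k = k, l = l,
    batch = sample.int(360L, nObs, replace = TRUE),
    I = I, sigma = sigma, d = dObs,
    flagOutlier = FALSE, flagIce = FALSE, flagLowres = FALSE,
    contaminated = contaminated)

  list(observations = observations,
       truth = data.frame(h = uniq$h, k = uniq$k, l = uniq$l,
                          d = uniq$d, Itrue = Itrue),
       config = cfg)
}
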