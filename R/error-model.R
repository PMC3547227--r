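#' Physical variance model for integrated intensities
#'
#' Evaluates \eqn{(\sigma^2_{dark} + \sigma^2_{read}) + (\sigma^2_{bg} +
#' \max(I, 0)) + (g I)^2}, the physical rewriting of the second-order
#' polynomial \eqn{k_0 + k_1 I + k_2 I^2} with
#' \eqn{k_0 = \sigma^2_{dark}+\sigma^2_{read}+\sigma^2_{bg}},
#' \eqn{k_1 = 1} and \eqn{k_2 = g^2}.
#'
#' @param I intensity (ADU), vectorised.
#' @param nm a [NoiseModel-class].
#' @return variance in ADU^2.
#' @seealso [polynomialCoefficients()] for the k-form.
#' @export
varianceModel <- function(I, nm) {
  stopifnot(is(nm, "NoiseModel"))
  (nm@sigmaDark^2 + nm@sigmaRead^2) + (nm@sigmaBg^2 + pmax(I, 0)) +
    (nm@gTrue * I)^2
}

#' @rdname varianceModel
#' @return \code{polynomialCoefficients}: named vector (k0, k1, k2).
#' @export
polynomialCoefficients <- function(nm) {
  stopifnot(is(nm, "NoiseModel"))
  c(k0 = noiseFloor(nm), k1 = 1, k2 = nm@gTrue^2)
}

## observation-level working table for chi2/refinement: active
## observations of multiply-observed groups with group n and weighted
## mean attached
chi2Worktable <- function(merged) {
  stopifnot(is(merged, "MergedReflections"))
  groups <- as.data.table(merged@groups)[n >= 2L]
  if (nrow(groups) == 0L) return(NULL)
  obs <- as.data.table(merged@observations)[!is.na(groupId)]
  obs[groups[, .(groupId, n, Imean)], on = "groupId", nomatch = NULL]
}

#' Merging chi-square of the error model
#'
#' Goodness of the delivered (or corrected) sigmas judged from the
#' scatter of symmetry equivalents: per multiply-observed group,
#' \deqn{T_h = \frac{N_h}{N_h - 1}\sum_i \frac{(I_i - \langle
#'   I\rangle_h)^2}{\sigma_i^2},}
#' and \eqn{\chi^2 = \sum_h T_h / \sum_h N_h}, whose expectation is 1
#' when the sigmas describe the scatter correctly (the \eqn{N/(N-1)}
#' factor undoes the variance absorbed by the group mean).
#'
#' @param merged a [MergedReflections-class] with at least one group of
#'   n >= 2.
#' @return the chi-square value (dimensionless).
#' @seealso [refineErrorModel()], [applyErrorModel()]
#' @export
chiSquare <- function(merged) {
  obs <- chi2Worktable(merged)
  if (is.null(obs))
    stop("chi-square undefined: no group has two or more observations")
  ## sum over groups of N/(N-1) * sum_i dev_i^2/sigma_i^2, divided by
  ## the total observation count sum_h N_h
  sum(obs$n / (obs$n - 1) * (obs$I - obs$Imean)^2 / obs$sigma^2) / nrow(obs)
}

#' Apply a refined error model to the delivered sigmas
#'
#' Replaces each participating observation's sigma by
#' \eqn{\sqrt{K[\sigma^2 + (g\langle I\rangle)^2]}} with
#' \eqn{\langle I\rangle} the current group mean, then re-merges so the
#' group means and sigmas reflect the corrected weights.
#'
#' @param merged a [MergedReflections-class].
#' @param model an [ErrorModel-class].
#' @return a new [MergedReflections-class] with corrected sigmas.
#' @export
applyErrorModel <- function(merged, model) {
  stopifnot(is(merged, "MergedReflections"), is(model, "ErrorModel"))
  obs <- as.data.table(merged@observations)
  groups <- as.data.table(merged@groups)
  Imean <- groups$Imean[match(obs$groupId, groups$groupId)]
  Imean[is.na(Imean)] <- 0
  obs[, sigma := sqrt(model@K * (sigma^2 + (model@g * Imean)^2))]
  mergeObservations(as.data.frame(obs), merged@laue)
}

#' Refine the (K, g) error model
#'
#' Finds the SADABS-style correction \eqn{\sigma^2_{new} = K[\sigma^2 +
#' (g\langle I\rangle)^2]} that normalises the merging chi-square:
#' groups are binned by \eqn{\langle I\rangle} into \code{nBins}
#' equal-count bins and \eqn{\sum_b (\chi^2_b(K, g) - 1)^2} is
#' minimised over \eqn{K \in [0.1, 10]}, \eqn{g \in [0, 0.2]} by a
#' coarse grid search refined with bounded quasi-Newton iterations;
#' the procedure is deterministic.  Group means are computed once from
#' the delivered sigmas and held fixed during the search (K rescales
#' all weights uniformly and g perturbs them only mildly).
#'
#' Each bin's \eqn{\chi^2} is estimated robustly: the median of the
#' per-observation normalised squared deviations
#' \eqn{t_i = \frac{N}{N-1}(I_i - \langle I\rangle)^2/\sigma^2_{new}},
#' rescaled by the median of the \eqn{\chi^2_1} distribution so its
#' null expectation is 1.  Refinement must run \emph{before} outlier
#' rejection, and a mean-based estimate would let gross outliers (ice,
#' zingers) inflate the refined model until the subsequent
#' sigma-based rejection is blind to them; the median ignores them.
#' Set \code{robust = FALSE} for the plain mean-based estimate.
#'
#' @param merged a [MergedReflections-class].
#' @param nBins number of equal-count intensity bins (default 10).
#' @param minGroups minimum number of multiply-observed groups required
#'   (default 50).
#' @param robust use the outlier-resistant per-bin chi-square estimate
#'   (default TRUE).
#' @return an [ErrorModel-class]; on degenerate input (no intensity
#'   spread) a fallback with K = 1, g = 0 and \code{converged = FALSE}
#'   is returned with a warning.
#' @seealso [chiSquare()], [applyErrorModel()]
#' @export
refineErrorModel <- function(merged, nBins = 10L, minGroups = 50L,
                             robust = TRUE) {
  obs <- chi2Worktable(merged)
  if (is.null(obs) || length(unique(obs$groupId)) < minGroups)
    stop(sprintf(
      "error-model refinement needs at least %d multiply-observed groups",
      minGroups))
  fallback <- function() {
    warning("degenerate input: error-model refinement failed; returning K = 1, g = 0")
    new("ErrorModel", K = 1, g = 0,
        chi2Before = chiSquare(merged), chi2After = chiSquare(merged),
        converged = FALSE, nBins = as.integer(nBins))
  }
  if (sd(obs$I) == 0) return(fallback())

  ## equal-count bins over group mean intensity
  groups <- unique(obs[, .(groupId, Imean)])
  setorder(groups, Imean, groupId)
  nBins <- max(1L, min(as.integer(nBins), nrow(groups)))
  groups[, bin := ceiling(.I / (nrow(groups) / nBins))]
  groups[bin > nBins, bin := nBins]
  binOf <- groups$bin[match(obs$groupId, groups$groupId)]

  dev2 <- obs$n / (obs$n - 1) * (obs$I - obs$Imean)^2
  sigma2 <- obs$sigma^2
  Imean2 <- obs$Imean^2
  nPerBin <- tabulate(binOf, nbins = nBins)
  binSplit <- split(seq_len(nrow(obs)), binOf)
  chi1Median <- qchisq(0.5, df = 1)   # null median of t_i

  binChi2 <- function(K, g) {
    contrib <- dev2 / (K * (sigma2 + g^2 * Imean2))
    if (robust)
      vapply(binSplit, function(ix) median(contrib[ix]), numeric(1)) /
        chi1Median
    else
      rowsum(contrib, binOf)[, 1L] / nPerBin
  }
  objective <- function(par) {
    ch <- binChi2(exp(par[1L]), par[2L])
    sum((ch - 1)^2)
  }

  Kgrid <- exp(seq(log(0.1), log(10), length.out = 17L))
  ggrid <- seq(0, 0.2, length.out = 21L)
  grid <- expand.grid(K = Kgrid, g = ggrid)
  vals <- vapply(seq_len(nrow(grid)),
                 function(i) objective(c(log(grid$K[i]), grid$g[i])),
                 numeric(1))
  start <- grid[which.min(vals), ]
  fit <- optim(c(log(start$K), start$g), objective,
               method = "L-BFGS-B",
               lower = c(log(0.1), 0), upper = c(log(10), 0.2))
  K <- exp(fit$par[1L])
  g <- fit$par[2L]

  chi2Before <- sum(dev2 / sigma2) / nrow(obs)
  chi2After <- sum(dev2 / (K * (sigma2 + g^2 * Imean2))) / nrow(obs)
  new("ErrorModel", K = K, g = g,
      chi2Before = chi2Before, chi2After = chi2After,
      converged = TRUE, nBins = as.integer(nBins))
}

#' ErrorModel accessors
#'
#' @param x an [ErrorModel-class].
#' @name ErrorModel-accessors
NULL

#' @rdname ErrorModel-accessors
#' @export
errorK <- function(x) { stopifnot(is(x, "ErrorModel")); x@K }

#' @rdname ErrorModel-accessors
#' @export
errorG <- function(x) { stopifnot(is(x, "ErrorModel")); x@g }

#' @rdname ErrorModel-accessors
#' @export
chiSquareBefore <- function(x) { stopifnot(is(x, "ErrorModel")); x@chi2Before }

#' @rdname ErrorModel-accessors
#' @export
chiSquareAfter <- function(x) { stopifnot(is(x, "ErrorModel")); x@chi2After }

setMethod("show", "ErrorModel", function(object) {
  cat(sprintf(
    "ErrorModel: K = %.3f, g = %.4f (chi2 %.3f -> %.3f over %d bins)%s\n",
    object@K, object@g, object@chi2Before, object@chi2After, object@nBins,
    if (object@converged) "" else "  [NOT CONVERGED: fallback]"))
})

#' Iterative sigma-based outlier rejection
#'
#' Flags observations deviating from their group's consensus by more
#' than \code{threshold} sigma (two-sided), the SADABS-style 4-sigma
#' rejection.  Each iteration recomputes the consensus excluding
#' already-flagged members and flags every observation with
#' \eqn{|I - \langle I\rangle|/\sigma >} threshold; iteration stops at
#' a fixed point or after \code{maxIter} rounds.  The consensus is the
#' unweighted median of unflagged members when three or more remain
#' (robust against the heavy one-sided contamination ice produces) and
#' the weighted mean for pairs; groups reduced below two unflagged
#' members stop participating, and no rejection is attempted in groups
#' with fewer than three members (a discordant pair cannot be
#' arbitrated).
#'
#' @param merged a [MergedReflections-class], normally with corrected
#'   sigmas (see [applyErrorModel()]).
#' @param threshold rejection threshold in sigma units (> 0, default 4).
#' @param maxIter maximum sweeps (default 5).
#' @return list with \code{merged} (re-merged [MergedReflections-class]
#'   whose observation table has \code{flagOutlier} set) and
#'   \code{nRejected}.
#' @export
rejectOutliers <- function(merged, threshold = 4, maxIter = 5L) {
  stopifnot(is(merged, "MergedReflections"))
  if (threshold <= 0) stop("threshold must be > 0")
  obs <- as.data.table(merged@observations)
  if (!"asuH" %in% names(obs)) {
    asu <- mapToASU(cbind(obs$h, obs$k, obs$l), merged@laue)
    obs[, `:=`(asuH = asu[, 1L], asuK = asu[, 2L], asuL = asu[, 3L])]
  }
  ## group key under the merge's Laue class is the ASU triple
  obs[, groupId := .GRP, by = .(asuH, asuK, asuL)]
  obs[, rowId := .I]
  active <- !(obs$flagIce | obs$flagLowres)
  flagged <- obs$flagOutlier
  for (iter in seq_len(maxIter)) {
    work <- obs[active & !flagged]
    centers <- work[, {
      ctr <- if (.N >= 3L) median(I)
             else sum(I / sigma^2) / sum(1 / sigma^2)
      .(center = ctr, nUnflagged = .N)
    }, by = groupId]
    work <- work[centers, on = "groupId"]
    ## only groups with >= 3 unflagged members can arbitrate an outlier
    bad <- work[nUnflagged >= 3L & abs(I - center) / sigma > threshold]
    if (nrow(bad) == 0L) break
    flagged[bad$rowId] <- TRUE
  }
  obs[, flagOutlier := flagged]
  obs[, c("asuH", "asuK", "asuL", "groupId", "rowId") := NULL]
  remerged <- mergeObservations(as.data.frame(obs), merged@laue)
  list(merged = remerged,
       nRejected = sum(flagged) - sum(merged@observations$flagOutlier))
}
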