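## Grouping of observations by symmetry-unique reflection and the
## merging statistics computed from the groups.

## ensure the observation table carries the flag columns and valid sigmas
normalizeObservations <- function(observations) {
  obs <- as.data.table(observations)
  need <- c("h", "k", "l", "I", "sigma", "d")
  if (!all(need %in% names(obs)))
    stop("observations need columns ", paste(need, collapse = ", "))
  if (!"batch" %in% names(obs)) obs[, batch := 1L]
  for (fl in c("flagOutlier", "flagIce", "flagLowres"))
    if (!fl %in% names(obs)) obs[, (fl) := FALSE]
  obs
}

#' Merge observations under a Laue class
#'
#' Groups unflagged observations by their asymmetric-unit
#' representative and computes inverse-variance weighted group means
#' (\eqn{w = 1/\sigma^2}): \eqn{\langle I\rangle = \sum wI/\sum w},
#' \eqn{\sigma_{\langle I\rangle} = (\sum w)^{-1/2}}.  Observations with
#' any rejection flag set do not participate.
#'
#' @param observations data.frame with columns h, k, l, batch, I,
#'   sigma, d (and optionally the three flag columns); sigmas must be
#'   positive.
#' @param lc a [LaueClass-class].
#' @return a [MergedReflections-class].
#' @examples
#' obs <- data.frame(h = c(1, 2), k = c(2, 1), l = 3, batch = 1,
#'                   I = c(90, 110), sigma = 10, d = 5)
#' nGroups(mergeObservations(obs, laueClass("4/mmm")))  # 1
#' nGroups(mergeObservations(obs, laueClass("mmm")))    # 2
#' @export
mergeObservations <- function(observations, lc) {
  stopifnot(is(lc, "LaueClass"))
  obs <- normalizeObservations(observations)
  if (nrow(obs) == 0L)
    return(new("MergedReflections",
               observations = as.data.frame(obs),
               groups = data.frame(asuH = integer(0), asuK = integer(0),
                                   asuL = integer(0), d = numeric(0),
                                   n = integer(0), Imean = numeric(0),
                                   sigmaMean = numeric(0)),
               laue = lc))
  asu <- mapToASU(cbind(obs$h, obs$k, obs$l), lc)
  obs[, `:=`(asuH = asu[, 1L], asuK = asu[, 2L], asuL = asu[, 3L])]
  active <- !(obs$flagOutlier | obs$flagIce | obs$flagLowres)
  if (any(obs$sigma[active] <= 0))
    stop("all participating observations must carry positive sigmas")
  act <- obs[active]
  groups <- act[, {
    w <- 1 / sigma^2
    .(d = d[1L], n = .N, Imean = sum(w * I) / sum(w),
      sigmaMean = 1 / sqrt(sum(w)))
  }, by = .(asuH, asuK, asuL)]
  setorder(groups, -d, asuH, asuK, asuL)
  groups[, groupId := .I]
  obs[, groupId := NA_integer_]
  obs[active, groupId := groups[obs[active],
                                on = c("asuH", "asuK", "asuL"),
                                groupId]]
  new("MergedReflections", observations = as.data.frame(obs),
      groups = as.data.frame(groups), laue = lc)
}

#' MergedReflections accessors
#'
#' @param x a [MergedReflections-class].
#' @return \code{groupTable}: data.frame of per-unique-reflection
#'   statistics; \code{observationTable}: the annotated observation
#'   table; \code{nGroups}: number of groups.
#' @name MergedReflections-accessors
NULL

#' @rdname MergedReflections-accessors
#' @export
groupTable <- function(x) {
  stopifnot(is(x, "MergedReflections")); x@groups
}

#' @rdname MergedReflections-accessors
#' @export
observationTable <- function(x) {
  stopifnot(is(x, "MergedReflections")); x@observations
}

#' @rdname MergedReflections-accessors
#' @export
nGroups <- function(x) {
  stopifnot(is(x, "MergedReflections")); nrow(x@groups)
}

setMethod("show", "MergedReflections", function(object) {
  g <- object@groups
  cat(sprintf(
    "MergedReflections under %s: %d observations in %d groups",
    object@laue@name,
    sum(!is.na(object@observations$groupId)), nrow(g)))
  if (nrow(g))
    cat(sprintf(", d %.2f-%.2f A, mean redundancy %.1f",
                max(g$d), min(g$d), mean(g$n)))
  cat("\n")
})

## r-factor workhorse shared by overall and per-shell statistics.
## obsAct: active observations joined with their group n and Imean.
rFactorSums <- function(obsAct) {
  multi <- obsAct[n >= 2L]
  if (nrow(multi) == 0L)
    return(list(rMerge = NA_real_, rMeas = NA_real_, rPim = NA_real_))
  dev <- abs(multi$I - multi$Imean)
  den <- sum(multi$I)
  list(rMerge = sum(dev) / den,
       rMeas = sum(sqrt(multi$n / (multi$n - 1)) * dev) / den,
       rPim = sum(sqrt(1 / (multi$n - 1)) * dev) / den)
}

#' Merging statistics overall and in resolution shells
#'
#' Computes \eqn{R_{merge}}, \eqn{R_{meas}}, \eqn{R_{pim}} over groups
#' with at least two observations, completeness against a
#' symmetry-unique reference set, mean redundancy, and the per-group
#' mean merged \eqn{I/\sigma}; then repeats all of it in
#' \code{nShells} equal-group-count resolution shells ordered from low
#' to high resolution (the last shell is the outer shell).  Groups with
#' a single observation contribute to completeness and redundancy but
#' not to the R factors; when no group is multiply observed the R
#' factors are \code{NA}.
#'
#' @param merged a [MergedReflections-class].
#' @param uniqueRef data.frame from [generateUnique()] on the same cell,
#'   class and resolution range (the completeness denominator).
#' @param nShells number of resolution shells (default 10).
#' @return a [MergeStats-class].
#' @examples
#' obs <- data.frame(h = 1, k = 2, l = 3, batch = 1:2,
#'                   I = c(90, 110), sigma = 10, d = 5)
#' m <- mergeObservations(obs, laueClass("mmm"))
#' ref <- data.frame(h = 1, k = 2, l = 3, d = 5)
#' rMerge(computeStats(m, ref, nShells = 1))  # 0.1
#' @export
computeStats <- function(merged, uniqueRef, nShells = 10L) {
  stopifnot(is(merged, "MergedReflections"))
  uniqueRef <- as.data.frame(uniqueRef)
  if (nrow(uniqueRef) == 0L) stop("unique_reference set is empty")
  if (!"d" %in% names(uniqueRef))
    stop("uniqueRef needs a d column")
  groups <- as.data.table(merged@groups)
  obs <- as.data.table(merged@observations)[!is.na(groupId)]
  obs <- obs[groups[, .(groupId, n, Imean)], on = "groupId"]

  nShells <- max(1L, min(as.integer(nShells), nrow(groups)))
  setorder(groups, -d)
  groups[, shell := ceiling(.I / (nrow(groups) / nShells))]
  groups[shell > nShells, shell := nShells]
  obs[, shell := groups[match(obs$groupId, groups$groupId), shell]]

  ## shell edges at midpoints of adjacent shell d-ranges; outermost
  ## edges open so every reference reflection lands in a shell
  bounds <- groups[, .(dHi = max(d), dLo = min(d)), by = shell][order(shell)]
  edges <- c(Inf, (bounds$dLo[-nrow(bounds)] + bounds$dHi[-1L]) / 2, -Inf)
  refShell <- findInterval(-uniqueRef$d, -edges, rightmost.closed = TRUE)
  refShell[refShell < 1L] <- 1L
  refShell[refShell > nShells] <- nShells
  refCount <- tabulate(refShell, nbins = nShells)

  shellRow <- function(s) {
    g <- groups[shell == s]
    o <- obs[shell == s]
    rf <- rFactorSums(o)
    data.frame(shell = s, dMax = max(g$d), dMin = min(g$d),
               nObs = nrow(o), nUnique = nrow(g),
               completeness = nrow(g) / max(refCount[s], 1L),
               redundancy = sum(g$n) / nrow(g),
               rMerge = rf$rMerge, rMeas = rf$rMeas, rPim = rf$rPim,
               meanIOverSigma = mean(g$Imean / g$sigmaMean))
  }
  perShell <- do.call(rbind, lapply(seq_len(nShells), shellRow))

  rf <- rFactorSums(obs)
  new("MergeStats",
      rMerge = rf$rMerge, rMeas = rf$rMeas, rPim = rf$rPim,
      meanIOverSigma = mean(groups$Imean / groups$sigmaMean),
      redundancy = sum(groups$n) / nrow(groups),
      completeness = nrow(groups) / nrow(uniqueRef),
      nObs = nrow(obs), nUnique = nrow(groups),
      perShell = perShell)
}

#' MergeStats accessors
#'
#' @param x a [MergeStats-class].
#' @name MergeStats-accessors
NULL

#' @rdname MergeStats-accessors
#' @export
rMerge <- function(x) { stopifnot(is(x, "MergeStats")); x@rMerge }

#' @rdname MergeStats-accessors
#' @export
rMeas <- function(x) { stopifnot(is(x, "MergeStats")); x@rMeas }

#' @rdname MergeStats-accessors
#' @export
rPim <- function(x) { stopifnot(is(x, "MergeStats")); x@rPim }

#' @rdname MergeStats-accessors
#' @export
completeness <- function(x) { stopifnot(is(x, "MergeStats")); x@completeness }

#' @rdname MergeStats-accessors
#' @export
redundancy <- function(x) { stopifnot(is(x, "MergeStats")); x@redundancy }

#' @rdname MergeStats-accessors
#' @export
meanIOverSigma <- function(x) {
  stopifnot(is(x, "MergeStats")); x@meanIOverSigma
}

#' @rdname MergeStats-accessors
#' @return \code{outerShell}: one-row data.frame with the
#'   highest-resolution shell's statistics.
#' @export
outerShell <- function(x) {
  stopifnot(is(x, "MergeStats"))
  x@perShell[nrow(x@perShell), , drop = FALSE]
}

#' @rdname MergeStats-accessors
#' @export
shellTable <- function(x) { stopifnot(is(x, "MergeStats")); x@perShell }

setMethod("show", "MergeStats", function(object) {
  os <- outerShell(object)
  fmt <- function(v, vo, digits = 3)
    sprintf("%.*f (%.*f)", digits, v, digits, vo)
  cat("MergeStats\n")
  cat(sprintf("  Observed reflections  %d\n", object@nObs))
  cat(sprintf("  Unique reflections    %d\n", object@nUnique))
  cat(sprintf("  Resolution (A)        %.2f-%.2f (%.2f-%.2f)\n",
              object@perShell$dMax[1L], os$dMin, os$dMax, os$dMin))
  cat(sprintf("  Completeness (%%)      %s\n",
              fmt(100 * object@completeness, 100 * os$completeness, 1)))
  cat(sprintf("  R_merge               %s\n", fmt(object@rMerge, os$rMerge)))
  cat(sprintf("  R_meas                %s\n", fmt(object@rMeas, os$rMeas)))
  cat(sprintf("  R_pim                 %s\n", fmt(object@rPim, os$rPim)))
  cat(sprintf("  Merged mean I/sigma   %s\n",
              fmt(object@meanIOverSigma, os$meanIOverSigma, 1)))
  cat(sprintf("  Redundancy            %s\n",
              fmt(object@redundancy, os$redundancy, 1)))
  cat("  (outer resolution shell values in brackets)\n")
})
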