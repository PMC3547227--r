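#' Wilson B-factor estimation from merged intensities
#'
#' Bins merged groups with \code{d <= dFitMax} into equal-count shells
#' over \eqn{s^2 = (1/(2d))^2 = (\sin\theta/\lambda)^2}, and fits
#' \eqn{\ln\langle I\rangle_{shell}} on the shell-mean \eqn{s^2} by
#' ordinary least squares.  The Wilson B factor is \eqn{-slope/2}.
#' Shells whose mean intensity is not positive are dropped; at least
#' three usable shells are required.  The low-resolution limit excludes
#' the non-Wilson regime dominated by solvent and large-scale contrast.
#'
#' @param merged a [MergedReflections-class].
#' @param dFitMax low-resolution limit of the fit window in Angstrom
#'   (default 4.5).
#' @param nShells target number of shells (default 20; reduced when
#'   there are fewer than 20 groups per shell, floor 3).
#' @return a [WilsonFit-class].
#' @examples
#' sim <- simulateDataset(simulationConfig(seed = 3L))
#' fit <- wilsonFit(mergeObservations(sim$observations, laueClass("mmm")))
#' wilsonB(fit)
#' @export
wilsonFit <- function(merged, dFitMax = 4.5, nShells = 20L) {
  stopifnot(is(merged, "MergedReflections"))
  g <- as.data.table(merged@groups)[d <= dFitMax]
  if (nrow(g) < 9L)
    stop("wilson fit failed: fewer than 3 usable shells below dFitMax")
  nShells <- max(3L, min(as.integer(nShells), nrow(g) %/% 20L, nrow(g) %/% 3L))
  g[, s2 := (1 / (2 * d))^2]
  setorder(g, s2)
  g[, shell := pmin(ceiling(.I / (nrow(g) / nShells)), nShells)]
  shells <- g[, .(s2 = mean(s2), meanI = mean(Imean), n = .N), by = shell]
  shells <- shells[meanI > 0]
  if (nrow(shells) < 3L)
    stop("wilson fit failed: fewer than 3 shells with positive mean intensity")
  fit <- lm(log(meanI) ~ s2, data = shells)
  slope <- coef(fit)[["s2"]]
  ## slope standard error computed directly (vcov warns on an exact fit)
  res <- residuals(fit)
  sxx <- sum((shells$s2 - mean(shells$s2))^2)
  se <- sqrt(sum(res^2) / (nrow(shells) - 2) / sxx)
  new("WilsonFit",
      B = -slope / 2, lnC = coef(fit)[["(Intercept)"]],
      stderrB = se / 2,
      s2Range = range(shells$s2), nShellsUsed = nrow(shells),
      shells = as.data.frame(shells[, .(s2, meanI, n)]))
}

#' WilsonFit accessors
#'
#' @param x a [WilsonFit-class].
#' @name WilsonFit-accessors
NULL

#' @rdname WilsonFit-accessors
#' @export
wilsonB <- function(x) { stopifnot(is(x, "WilsonFit")); x@B }

#' @rdname WilsonFit-accessors
#' @export
wilsonIntercept <- function(x) { stopifnot(is(x, "WilsonFit")); x@lnC }

setMethod("show", "WilsonFit", function(object) {
  cat(sprintf(
    "WilsonFit: B = %.2f +/- %.2f A^2, lnC = %.2f (%d shells, s2 %.4f-%.4f)\n",
    object@B, object@stderrB, object@lnC, object@nShellsUsed,
    object@s2Range[1L], object@s2Range[2L]))
})
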