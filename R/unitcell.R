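#' Construct a unit cell
#'
#' @param a,b,c cell edges in Angstrom.  \code{b} defaults to \code{a}
#'   (tetragonal habit).
#' @param alpha,beta,gamma cell angles in degrees (default 90).
#' @return a [UnitCell-class] object.
#' @examples
#' unitCell(78.53, 78.53, 37.36)
#' @export
unitCell <- function(a, b = a, c, alpha = 90, beta = 90, gamma = 90) {
  new("UnitCell", a = as.numeric(a), b = as.numeric(b), c = as.numeric(c),
      alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma))
}

#' Cell parameter accessor
#'
#' @param cell a [UnitCell-class].
#' @return named numeric vector (a, b, c, alpha, beta, gamma).
#' @export
cellParameters <- function(cell) {
  stopifnot(is(cell, "UnitCell"))
  c(a = cell@a, b = cell@b, c = cell@c,
    alpha = cell@alpha, beta = cell@beta, gamma = cell@gamma)
}

#' Is the cell orthogonal / metrically tetragonal?
#'
#' @param cell a [UnitCell-class].
#' @param tol relative tolerance for the a = b comparison and absolute
#'   tolerance (degrees) for angles.
#' @return logical.
#' @export
isOrthogonal <- function(cell, tol = 1e-8) {
  stopifnot(is(cell, "UnitCell"))
  all(abs(c(cell@alpha, cell@beta, cell@gamma) - 90) <= tol)
}

#' @rdname isOrthogonal
#' @export
isTetragonal <- function(cell, tol = 1e-6) {
  isOrthogonal(cell, tol) && abs(cell@a - cell@b) <= tol * cell@a
}

#' Resolution (d-spacing) of reflections in an orthogonal cell
#'
#' Computes \eqn{1/d^2 = h^2/a^2 + k^2/b^2 + l^2/c^2}.  The quantity
#' \eqn{s = 1/(2d)} equals \eqn{\sin\theta/\lambda}, the abscissa of the
#' Wilson plot.
#'
#' @param cell an orthogonal [UnitCell-class]; non-orthogonal cells are
#'   rejected.
#' @param hkl integer matrix with 3 columns (h, k, l) or a length-3
#'   vector.  (0, 0, 0) is not a reflection.
#' @return numeric vector of d-spacings in Angstrom.
#' @examples
#' cell <- unitCell(78.53, 78.53, 37.36)
#' dSpacing(cell, c(0, 0, 1))   # = c
#' dSpacing(cell, c(1, 1, 0))   # = a / sqrt(2)
#' @export
dSpacing <- function(cell, hkl) {
  stopifnot(is(cell, "UnitCell"))
  if (!isOrthogonal(cell))
    stop("unsupported cell: only orthogonal cells (all angles 90 deg) are handled")
  hkl <- asHklMatrix(hkl)
  if (any(rowSums(hkl != 0L) == 0L))
    stop("(0,0,0) is not a valid reflection")
  invd2 <- (hkl[, 1L] / cell@a)^2 + (hkl[, 2L] / cell@b)^2 +
    (hkl[, 3L] / cell@c)^2
  1 / sqrt(invd2)
}

## coerce vector/matrix/data.frame input to an n x 3 integer matrix
asHklMatrix <- function(hkl) {
  if (is.data.frame(hkl)) {
    stopifnot(all(c("h", "k", "l") %in% names(hkl)))
    hkl <- cbind(hkl$h, hkl$k, hkl$l)
  }
  if (is.null(dim(hkl))) {
    if (length(hkl) != 3L) stop("hkl vector must have length 3")
    hkl <- matrix(hkl, ncol = 3L)
  }
  if (ncol(hkl) != 3L) stop("hkl matrix must have 3 columns")
  storage.mode(hkl) <- "integer"
  hkl
}

setMethod("show", "UnitCell", function(object) {
  cat(sprintf(
    "UnitCell: a = %.2f  b = %.2f  c = %.2f A;  %.1f/%.1f/%.1f deg%s\n",
    object@a, object@b, object@c, object@alpha, object@beta, object@gamma,
    if (isTetragonal(object)) "  [tetragonal metric]" else ""))
})
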