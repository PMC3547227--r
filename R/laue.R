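#' Laue-class operator sets
#'
#' Builds the operator set of a Laue class as 3x3 integer matrices
#' acting on (h, k, l).  "mmm" comprises the 8 sign combinations
#' (+-h, +-k, +-l); "4/mmm" adds the h/k exchange for 16 operators.
#' Both sets contain the inversion and are closed under multiplication
#' (enforced by the class validity method).
#'
#' @param name "4/mmm" or "mmm".
#' @return a [LaueClass-class].
#' @examples
#' laueClass("mmm")
#' length(laueOperators(laueClass("4/mmm")))  # 16
#' @export
laueClass <- function(name = c("4/mmm", "mmm")) {
  name <- match.arg(name)
  signs <- expand.grid(s1 = c(1L, -1L), s2 = c(1L, -1L), s3 = c(1L, -1L))
  ops <- lapply(seq_len(nrow(signs)), function(i)
    diag(c(signs$s1[i], signs$s2[i], signs$s3[i])))
  if (name == "4/mmm") {
    swap <- matrix(c(0L, 1L, 0L, 1L, 0L, 0L, 0L, 0L, 1L), nrow = 3L)
    ops <- c(ops, lapply(ops, function(m) swap %*% m))
  }
  ops <- lapply(ops, function(m) { storage.mode(m) <- "integer"; m })
  new("LaueClass", name = name, operators = ops)
}

#' @rdname laueClass
#' @param lc a [LaueClass-class].
#' @export
laueOperators <- function(lc) {
  stopifnot(is(lc, "LaueClass"))
  lc@operators
}

#' @rdname laueClass
#' @export
laueName <- function(lc) {
  stopifnot(is(lc, "LaueClass"))
  lc@name
}

setMethod("show", "LaueClass", function(object) {
  cat(sprintf("LaueClass %s with %d operators\n",
              object@name, length(object@operators)))
})

#' Map Miller indices to their asymmetric-unit representative
#'
#' The representative of the orbit \{M hkl : M in operators\} is its
#' lexicographically greatest member (h compared first, then k, then l).
#' The map is idempotent and constant on orbits.
#'
#' @param hkl integer matrix with columns (h, k, l) or length-3 vector;
#'   (0, 0, 0) excluded.
#' @param lc a [LaueClass-class].
#' @return integer matrix of the same shape with representative indices.
#' @examples
#' lc <- laueClass("4/mmm")
#' mapToASU(c(1, 2, 3), lc)  # same representative as (2, 1, 3)
#' @export
mapToASU <- function(hkl, lc) {
  stopifnot(is(lc, "LaueClass"))
  hkl <- asHklMatrix(hkl)
  if (any(rowSums(hkl != 0L) == 0L))
    stop("(0,0,0) is not a valid reflection")
  best <- hkl
  for (M in lc@operators) {
    cand <- hkl %*% t(M)
    better <- cand[, 1L] > best[, 1L] |
      (cand[, 1L] == best[, 1L] &
         (cand[, 2L] > best[, 2L] |
            (cand[, 2L] == best[, 2L] & cand[, 3L] > best[, 3L])))
    if (any(better)) best[better, ] <- cand[better, , drop = FALSE]
  }
  storage.mode(best) <- "integer"
  colnames(best) <- c("h", "k", "l")
  best
}

#' Enumerate symmetry-unique reflections in a resolution range
#'
#' All asymmetric-unit representatives with \eqn{d_{min} \le d \le
#' d_{max}}.  Equivalence is at the Laue level; space-group systematic
#' absences are not removed, so this set is the completeness
#' denominator in the Laue sense.
#'
#' @param cell an orthogonal [UnitCell-class].
#' @param lc a [LaueClass-class].
#' @param dMin,dMax resolution limits in Angstrom, 0 < dMin < dMax.
#' @return data.frame with columns h, k, l, d, one row per unique
#'   reflection, sorted by decreasing d.
#' @examples
#' nrow(generateUnique(unitCell(10, 10, 10), laueClass("mmm"), 5, 100))
#' @export
generateUnique <- function(cell, lc, dMin, dMax) {
  stopifnot(is(cell, "UnitCell"), is(lc, "LaueClass"))
  if (!(dMin > 0 && dMin < dMax)) stop("need 0 < dMin < dMax")
  ## ASU representatives have h, k, l >= 0 (lexicographic max over all
  ## sign combinations), so enumerating the non-negative octant suffices.
  hMax <- floor(cell@a / dMin)
  kMax <- floor(cell@b / dMin)
  lMax <- floor(cell@c / dMin)
  grid <- as.matrix(expand.grid(h = 0:hMax, k = 0:kMax, l = 0:lMax))
  grid <- grid[rowSums(grid != 0L) > 0L, , drop = FALSE]
  d <- dSpacing(cell, grid)
  keep <- d >= dMin & d <= dMax
  grid <- grid[keep, , drop = FALSE]
  d <- d[keep]
  rep <- mapToASU(grid, lc)
  key <- paste(rep[, 1L], rep[, 2L], rep[, 3L])
  first <- !duplicated(key)
  rep <- rep[first, , drop = FALSE]
  ## d evaluated on the representative itself (equal to any orbit
  ## member's d whenever the cell metric respects the class)
  out <- data.frame(h = rep[, 1L], k = rep[, 2L], l = rep[, 3L],
                    d = dSpacing(cell, rep))
  out[order(-out$d, out$h, out$k, out$l), , drop = FALSE] |>
    `rownames<-`(NULL)
}
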