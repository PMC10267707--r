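#' Construct a square-symmetry group
#'
#' @param name `"p4"` (four 90-degree rotations) or `"p4m"` (rotations plus
#'   horizontal mirror, the dihedral group of the square).
#' @return a [GroupSpec-class].
#' @examples
#' groupSpec("p4m")
#' @export
groupSpec <- function(name = c("p4", "p4m")) {
  name <- match.arg(name)
  new("GroupSpec", name = name, order = if (name == "p4") 4L else 8L)
}

#' Construct a group element
#'
#' The element (r, m) acts on a grid as: flip horizontally `m` times, then
#' rotate counter-clockwise by `r` quarter turns.
#'
#' @param r rotation count, integer in 0..3.
#' @param m mirror flag, 0 or 1.
#' @return a [GroupElement-class].
#' @export
groupElement <- function(r, m = 0L) {
  new("GroupElement", r = as.integer(r) %% 4L, m = as.integer(m))
}

.checkElement <- function(group, g) {
  if (group@name == "p4" && g@m != 0L)
    stop("mirror element supplied to a p4 group", call. = FALSE)
  invisible(g)
}

#' Identity element
#'
#' @param group a [GroupSpec-class].
#' @return the identity element (r = 0, m = 0).
#' @export
groupIdentity <- function(group) {
  stopifnot(is(group, "GroupSpec"))
  groupElement(0L, 0L)
}

#' Group product
#'
#' `groupCompose(group, a, b)` is the element "apply `b`, then `a`":
#' acting with `b` on a grid and then with `a` equals acting with the
#' composite. In (r, m) coordinates the dihedral product is
#' `(m_a + m_b mod 2, r_a + (-1)^m_a r_b mod 4)`.
#'
#' @param group a [GroupSpec-class].
#' @param a,b [GroupElement-class] objects valid for `group`.
#' @return a [GroupElement-class].
#' @export
groupCompose <- function(group, a, b) {
  .checkElement(group, a); .checkElement(group, b)
  m <- (a@m + b@m) %% 2L
  r <- (a@r + (if (a@m == 1L) -b@r else b@r)) %% 4L
  groupElement(r, m)
}

#' Group inverse
#'
#' @param group a [GroupSpec-class].
#' @param g a [GroupElement-class].
#' @return the element `h` with `groupCompose(group, g, h)` the identity.
#' @export
groupInverse <- function(group, g) {
  .checkElement(group, g)
  if (g@m == 0L) groupElement((-g@r) %% 4L, 0L) else g  # mirrors self-invert
}

#' Canonical enumeration of group elements
#'
#' Rotations ascending within mirror = 0, then (for p4m) within mirror = 1.
#' This order indexes the orientation channels of every group feature map.
#'
#' @param group a [GroupSpec-class].
#' @return list of [GroupElement-class] objects, length `group@order`.
#' @export
groupElements <- function(group) {
  stopifnot(is(group, "GroupSpec"))
  ms <- if (group@name == "p4") 0L else c(0L, 1L)
  out <- list()
  for (m in ms) for (r in 0:3) out[[length(out) + 1L]] <- groupElement(r, m)
  out
}

#' Index of an element in the canonical enumeration
#'
#' @param group a [GroupSpec-class].
#' @param g a [GroupElement-class].
#' @return integer position of `g` in [groupElements()].
#' @export
elementIndex <- function(group, g) {
  .checkElement(group, g)
  g@m * 4L + g@r + 1L
}

# 90-degree counter-clockwise rotation of a matrix (top row -> left column).
.rotCCW <- function(k) t(k)[rev(seq_len(ncol(k))), , drop = FALSE]

# horizontal flip (mirror across the vertical axis).
.flipH <- function(k) k[, rev(seq_len(ncol(k))), drop = FALSE]

# spatial transform without the squareness requirement (internal; feature
# maps may be rectangular, in which case odd rotations change their shape).
.spatialTransform <- function(g, k) {
  if (g@m == 1L) k <- .flipH(k)
  if (g@r > 0L) for (i in seq_len(g@r)) k <- .rotCCW(k)
  k
}

#' Act with a group element on a square kernel grid
#'
#' Permutes the entries of `k`: horizontal flip if `m = 1`, then `r`
#' counter-clockwise quarter turns. This is a left action:
#' `actOnGrid(a, actOnGrid(b, k)) == actOnGrid(groupCompose(group, a, b), k)`.
#'
#' @param g a [GroupElement-class].
#' @param k a square numeric matrix (typically 3 x 3).
#' @return the transformed matrix (same multiset of entries).
#' @export
actOnGrid <- function(g, k) {
  if (!is.matrix(k) || nrow(k) != ncol(k))
    stop("actOnGrid requires a square matrix", call. = FALSE)
  .spatialTransform(g, k)
}

# entry-permutation table: actOnGrid(g, M)[i] == M[.gridPermutation(g, n)[i]]
.gridPermutation <- function(g, n) {
  idx <- matrix(seq_len(n * n), n, n)
  as.integer(.spatialTransform(g, idx))
}
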