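#' Valid 2-D cross-correlation
#'
#' The spatial primitive of every convolution layer in the package:
#' `out[i, j] = sum_{a,b} x[i + a - 1, j + b - 1] * k[a, b]` (no padding,
#' no kernel flip).
#'
#' @param x numeric matrix (input plane).
#' @param k numeric matrix (kernel), no larger than `x` in either dimension.
#' @return matrix of size `(nrow(x) - nrow(k) + 1) x (ncol(x) - ncol(k) + 1)`.
#' @export
corr2d <- function(x, k) {
  kh <- nrow(k); kw <- ncol(k)
  oh <- nrow(x) - kh + 1L; ow <- ncol(x) - kw + 1L
  if (oh < 1L || ow < 1L) stop("kernel larger than input", call. = FALSE)
  out <- matrix(0, oh, ow)
  for (a in seq_len(kh)) for (b in seq_len(kw))
    out <- out + k[a, b] * x[a:(a + oh - 1L), b:(b + ow - 1L), drop = FALSE]
  out
}

.asZ2 <- function(f) {
  if (is.matrix(f)) f <- array(f, c(1L, dim(f)))
  stopifnot(length(dim(f)) == 3L)
  f
}

#' Lifting convolution: planar signal to group feature map
#'
#' Correlates a planar multi-channel input with every group-transformed copy
#' of each base kernel. Orientation slot `g` of output filter `o` is the sum
#' over input channels `c` of `corr2d(f[c, , ], actOnGrid(g, psi[o, c, , ]))`,
#' with slots in the canonical [groupElements()] order.
#'
#' @param f input: numeric matrix `[h x w]` or array `[channels x h x w]`.
#' @param psi kernel array `[out x in x k x k]`, `k` odd.
#' @param group a [GroupSpec-class].
#' @return array `[out x group order x oh x ow]`.
#' @export
liftingConv <- function(f, psi, group) {
  f <- .asZ2(f)
  stopifnot(length(dim(psi)) == 4L)
  if (dim(f)[1] != dim(psi)[2])
    stop("channel mismatch between input and kernel", call. = FALSE)
  els <- groupElements(group)
  nOut <- dim(psi)[1]; nIn <- dim(psi)[2]
  oh <- dim(f)[2] - dim(psi)[3] + 1L
  ow <- dim(f)[3] - dim(psi)[4] + 1L
  out <- array(0, c(nOut, length(els), oh, ow))
  for (o in seq_len(nOut)) for (gi in seq_along(els)) {
    acc <- matrix(0, oh, ow)
    for (c in seq_len(nIn))
      acc <- acc + corr2d(f[c, , ], actOnGrid(els[[gi]], psi[o, c, , ]))
    out[o, gi, , ] <- acc
  }
  out
}

#' Group convolution: group feature map to group feature map
#'
#' Output slot `g` sums, over input channels `c` and group elements `s`, the
#' correlation of input slice `f[c, s, , ]` with the kernel slice indexed by
#' `inverse(g) * s`, spatially transformed by `g` -- the spatial transform
#' and the orientation-channel permutation are both applied.
#'
#' @param f input array `[channels x group order x h x w]`.
#' @param psi kernel array `[out x in x group order x k x k]`.
#' @param group a [GroupSpec-class].
#' @return array `[out x group order x oh x ow]`.
#' @export
groupConv <- function(f, psi, group) {
  stopifnot(length(dim(f)) == 4L, length(dim(psi)) == 5L)
  els <- groupElements(group)
  if (dim(f)[2] != length(els) || dim(psi)[3] != length(els))
    stop("group mismatch between input, kernel and group", call. = FALSE)
  if (dim(f)[1] != dim(psi)[2])
    stop("channel mismatch between input and kernel", call. = FALSE)
  nOut <- dim(psi)[1]; nIn <- dim(psi)[2]
  oh <- dim(f)[3] - dim(psi)[4] + 1L
  ow <- dim(f)[4] - dim(psi)[5] + 1L
  out <- array(0, c(nOut, length(els), oh, ow))
  for (o in seq_len(nOut)) for (gi in seq_along(els)) {
    g <- els[[gi]]; gInv <- groupInverse(group, g)
    acc <- matrix(0, oh, ow)
    for (c in seq_len(nIn)) for (si in seq_along(els)) {
      ki <- elementIndex(group, groupCompose(group, gInv, els[[si]]))
      acc <- acc + corr2d(f[c, si, , ], actOnGrid(g, psi[o, c, ki, , ]))
    }
    out[o, gi, , ] <- acc
  }
  out
}

#' Transform a group feature map by a group element
#'
#' Spatially transforms every slice by `g` and permutes the orientation
#' slots by left multiplication: output slot `s` is the spatially
#' transformed input slot `inverse(g) * s`. The equivariance property of
#' [liftingConv()]/[groupConv()] is stated with respect to this operator.
#'
#' @param g a [GroupElement-class].
#' @param f array `[channels x group order x h x w]`.
#' @param group a [GroupSpec-class].
#' @return the transformed feature map (odd rotations swap h and w).
#' @export
transformFeature <- function(g, f, group) {
  stopifnot(length(dim(f)) == 4L)
  els <- groupElements(group)
  gInv <- groupInverse(group, g)
  d <- dim(f)
  if (g@r %% 2L == 1L) d[3:4] <- d[4:3]
  out <- array(0, d)
  for (c in seq_len(d[1])) for (si in seq_along(els)) {
    src <- elementIndex(group, groupCompose(group, gInv, els[[si]]))
    out[c, si, , ] <- .spatialTransform(g, f[c, src, , ])
  }
  out
}

#' Transform a planar feature map by a group element
#'
#' Spatial-only counterpart of [transformFeature()] for signals on the
#' plane (the input of a lifting layer).
#'
#' @inheritParams transformFeature
#' @param f matrix or array `[channels x h x w]`.
#' @export
transformPlane <- function(g, f) {
  if (is.matrix(f)) return(.spatialTransform(g, f))
  f <- .asZ2(f)
  d <- dim(f)
  if (g@r %% 2L == 1L) d[2:3] <- d[3:2]
  out <- array(0, d)
  for (c in seq_len(d[1])) out[c, , ] <- .spatialTransform(g, f[c, , ])
  out
}

#' Pool a group feature map over the orientation axis
#'
#' Reduces the group axis with max or mean, producing a planar feature map
#' that is invariant to [transformFeature()] up to the spatial transform of
#' its argument.
#'
#' @param f array `[channels x group order x h x w]`.
#' @param mode `"max"` or `"mean"`.
#' @return array `[channels x h x w]`.
#' @export
groupPool <- function(f, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  stopifnot(length(dim(f)) == 4L)
  apply(f, c(1, 3, 4), if (mode == "max") max else mean)
}
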