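# 90-degree counter-clockwise rotation written independently of the
# package's implementation: coordinate map (i, j) -> (n + 1 - j, i)
rotCCWOracle <- function(k) {
  n <- nrow(k)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    out[n + 1L - j, i] <- k[i, j]
  out
}

flipHOracle <- function(k) k[, rev(seq_len(ncol(k))), drop = FALSE]

applyElementOracle <- function(r, m, k) {
  if (m == 1) k <- flipHOracle(k)
  if (r > 0) for (i in seq_len(r)) k <- rotCCWOracle(k)
  k
}

# naive O(n^4) valid cross-correlation
corrOracle <- function(x, k) {
  oh <- nrow(x) - nrow(k) + 1L; ow <- ncol(x) - ncol(k) + 1L
  out <- matrix(0, oh, ow)
  for (i in seq_len(oh)) for (j in seq_len(ow))
    out[i, j] <- sum(x[i:(i + nrow(k) - 1L), j:(j + ncol(k) - 1L)] * k)
  out
}

# 2x2 orthogonal-matrix representation of a square-symmetry element
elementMatrix <- function(r, m) {
  R <- matrix(c(0, 1, -1, 0), 2, 2)   # 90-degree CCW rotation
  Fm <- diag(c(-1, 1))                # horizontal flip (x -> -x)
  M <- diag(2)
  if (m == 1) M <- Fm %*% M
  if (r > 0) for (i in seq_len(r)) M <- R %*% M
  M
}

# small easy synthetic image set for trainer tests: class 0 bright at the
# top rows, class 1 bright at the bottom rows, plus noise
twoBlobImages <- function(n, h = 23L, w = 17L, seed = 1L) {
  set.seed(seed)
  X <- array(rnorm(h * w * n, sd = 0.3), c(h, w, n))
  labels <- rep(0:1, length.out = n)
  for (i in seq_len(n)) {
    rows <- if (labels[i] == 0L) 1:6 else (h - 5L):h
    X[rows, , i] <- X[rows, , i] + 1.5
  }
  list(X = X, labels = labels)
}
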