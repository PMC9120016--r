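# Shared numerical helpers.

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Kabsch least-squares rigid superposition of `mobile` onto `fixed`
# (n x 3 matrices, same row order). Returns rotation R, translation t and
# rmsd such that mobile %*% R + t best matches fixed.
kabsch <- function(mobile, fixed) {
  stopifnot(nrow(mobile) == nrow(fixed), ncol(mobile) == 3L)
  cm <- colMeans(mobile)
  cf <- colMeans(fixed)
  m0 <- sweep(mobile, 2, cm)
  f0 <- sweep(fixed, 2, cf)
  h <- crossprod(m0, f0)
  s <- svd(h)
  d <- sign(det(tcrossprod(s$v, s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted <- m0 %*% rot
  rmsd <- sqrt(mean(rowSums((fitted - f0)^2)))
  list(rotation = rot,
       translation = cf - cm %*% rot,
       rmsd = rmsd,
       fitted = sweep(fitted, 2, cf, `+`))
}

# Apply a fitted rigid transform to an n x 3 matrix.
apply_transform <- function(x, rotation, translation) {
  sweep(x %*% rotation, 2, as.numeric(translation), `+`)
}

# Unit-normalize a vector; zero vectors returned unchanged.
unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) v else v / n
}

# Principal (long) axis of a point set: leading eigenvector of the
# coordinate covariance. Sign fixed so the largest-magnitude component
# is positive unless a reference direction is supplied.
principal_axis <- function(xyz, align_to = NULL) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  ev <- eigen(crossprod(c0) / nrow(xyz), symmetric = TRUE)
  ax <- ev$vectors[, 1]
  if (!is.null(align_to)) {
    if (sum(ax * align_to) < 0) ax <- -ax
  } else if (ax[which.max(abs(ax))] < 0) {
    ax <- -ax
  }
  ax
}

# Clamp numeric vector into [lo, hi].
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
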