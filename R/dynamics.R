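# Essential dynamics: PCA of Cα ensembles, subspace-overlap convergence
# diagnostics, and interface hinge-angle descriptors.

#' Principal component analysis of a conformational ensemble
#'
#' Diagonalises the covariance matrix of Cα positions over conformers
#' (each conformer best-fit superposed onto the reference structure first).
#' Eigenvalue fractions measure how much of the total motion each
#' collective mode carries; the first few modes are the slow, large
#' amplitude motions.
#'
#' @param e a `fold_ensemble`.
#' @param superpose fit each conformer to the reference before PCA
#'   (default TRUE).
#' @return A `fold_pca` object: `eigenvalues` (descending), `vectors`
#'   (3N x K orthonormal modes, sign fixed so each mode's
#'   largest-magnitude component is positive), `fractions`, `mean`,
#'   `projections` (m x K conformer scores), `n_conformers`.
#' @export
ens_pca <- function(e, superpose = TRUE) {
  if (n_conformers(e) < 2) stop("need at least 2 conformers")
  if (superpose) e <- superpose_ensemble(e)
  x <- ensemble_matrix(e)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  cv <- crossprod(xc) / (nrow(xc) - 1)
  ev <- eigen(cv, symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  vecs <- ev$vectors
  for (k in seq_len(ncol(vecs))) {
    if (vecs[which.max(abs(vecs[, k])), k] < 0) vecs[, k] <- -vecs[, k]
  }
  tot <- sum(vals)
  structure(list(eigenvalues = vals,
                 vectors = vecs,
                 fractions = if (tot > 0) vals / tot else vals * 0,
                 mean = mu,
                 projections = xc %*% vecs,
                 n_conformers = nrow(x),
                 topology = e$topology),
            class = "fold_pca")
}

#' @export
print.fold_pca <- function(x, ...) {
  f <- round(x$fractions[1:min(3, length(x$fractions))], 3)
  cat(sprintf("<fold_pca> %d conformers, leading fractions: %s\n",
              x$n_conformers, paste(f, collapse = ", ")))
  invisible(x)
}

#' Subspace overlap (RMSIP) between two PCA results
#'
#' Root-mean-square inner product over the top `k` modes of each result;
#' 1 for identical subspaces, 0 for orthogonal ones. The standard
#' essential-dynamics convergence measure: disjoint subsets of a converged
#' ensemble should show RMSIP near 1.
#'
#' @param a,b `fold_pca` objects over the same topology.
#' @param k number of leading modes to compare (default 10).
#' @return RMSIP in `[0, 1]`.
#' @export
subspace_overlap <- function(a, b, k = 10L) {
  stopifnot(k > 0)
  if (nrow(a$vectors) != nrow(b$vectors))
    stop("mode dimensionality differs")
  k <- min(k, ncol(a$vectors), ncol(b$vectors))
  ip <- crossprod(a$vectors[, seq_len(k), drop = FALSE],
                  b$vectors[, seq_len(k), drop = FALSE])
  sqrt(sum(ip^2) / k)
}

#' Hinge-angle descriptors of an interface over an ensemble
#'
#' For two residue sets (e.g. the long axes of the β-sheets flanking an
#' interface) the inertial long axis of each set is computed per
#' conformer. Relative to the reference conformer frame the angles are:
#' `tilt` — change in the inter-axis angle; `twist` — in-plane rotation of
#' the second axis about the interface normal; `bend` — out-of-plane
#' deflection of the second axis towards the normal. All angles are in
#' degrees and zero at the reference.
#'
#' @param e a `fold_ensemble`.
#' @param set1,set2 integer vectors of residue indices (>= 2 each)
#'   defining the two axes.
#' @param name interface name carried into the output.
#' @return tibble of class `fold_hinges`: `conformer`, `tilt`, `bend`,
#'   `twist`, `degenerate` (axis collinearity flag).
#' @export
hinge_descriptors <- function(e, set1, set2, name = "interface") {
  stopifnot(length(set1) >= 2, length(set2) >= 2)
  e <- superpose_ensemble(e)
  ref <- e$topology$xyz
  a1r <- principal_axis(ref[set1, , drop = FALSE])
  a2r <- principal_axis(ref[set2, , drop = FALSE])
  nrm <- crossprod_vec(a1r, a2r)
  degenerate_frame <- sqrt(sum(nrm^2)) < 1e-6
  nrm <- unit(nrm)
  bvec <- unit(crossprod_vec(nrm, a2r))  # in-plane, perpendicular to a2r
  ang_ref <- angle_deg(a1r, a2r)
  m <- n_conformers(e)
  tilt <- bend <- twist <- numeric(m)
  degen <- logical(m)
  for (mi in seq_len(m)) {
    xyz <- e$coords[mi, , ]
    a1 <- principal_axis(xyz[set1, , drop = FALSE], align_to = a1r)
    a2 <- principal_axis(xyz[set2, , drop = FALSE], align_to = a2r)
    tilt[mi] <- angle_deg(a1, a2) - ang_ref
    if (degenerate_frame) {
      degen[mi] <- TRUE
      bend[mi] <- twist[mi] <- NA_real_
    } else {
      # transport the reference frame with the first axis (minimal
      # rotation a1r -> a1), so bend/twist report the deformation of
      # axis 2 relative to axis 1, not residual global motion
      rot <- rotation_between(a1r, a1)
      e2t <- as.numeric(rot %*% a2r)
      bt <- as.numeric(rot %*% bvec)
      nt <- as.numeric(rot %*% nrm)
      twist[mi] <- atan2(sum(a2 * bt), sum(a2 * e2t)) * 180 / pi
      bend[mi] <- asin(clip(sum(a2 * nt), -1, 1)) * 180 / pi
    }
  }
  out <- tibble::tibble(conformer = seq_len(m), tilt = tilt,
                        bend = bend, twist = twist, degenerate = degen)
  class(out) <- c("fold_hinges", class(out))
  attr(out, "interface") <- name
  out
}

# minimal rotation matrix taking unit vector u onto unit vector v
rotation_between <- function(u, v) {
  ax <- crossprod_vec(u, v)
  s <- sqrt(sum(ax^2))
  cth <- clip(sum(u * v), -1, 1)
  if (s < 1e-12) return(diag(3) * sign(cth))
  k <- ax / s
  kmat <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
                 3, 3, byrow = TRUE)
  diag(3) + sin(acos(cth)) * kmat + (1 - cth) * kmat %*% kmat
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

angle_deg <- function(a, b) {
  acos(clip(sum(a * b) / sqrt(sum(a^2) * sum(b^2)), -1, 1)) * 180 / pi
}

#' Correlate PCA mode projections with hinge-angle series
#'
#' Pearson correlation of each conformer's projection on the leading
#' principal components against each hinge-angle series, mapping which
#' collective mode drives which interface motion.
#'
#' @param pc a `fold_pca`.
#' @param hinges a `fold_hinges` tibble (same conformer count).
#' @param n_pc number of leading components to correlate (default 3).
#' @return tibble with `pc`, `angle`, `r` (NA where a series has zero
#'   variance).
#' @export
project_hinges <- function(pc, hinges, n_pc = 3L) {
  if (nrow(hinges) != pc$n_conformers)
    stop("conformer counts differ")
  n_pc <- min(n_pc, ncol(pc$projections))
  angles <- c("tilt", "bend", "twist")
  out <- tidyr::expand_grid(pc = seq_len(n_pc), angle = angles)
  out$r <- purrr::map2_dbl(out$pc, out$angle, function(k, a) {
    x <- pc$projections[, k]
    y <- hinges[[a]]
    if (anyNA(y) || stats::sd(y) == 0 || stats::sd(x) == 0)
      return(NA_real_)
    stats::cor(x, y)
  })
  out
}
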