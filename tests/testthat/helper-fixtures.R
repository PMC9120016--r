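# Shared fixtures, all generated in code.

# a minimal three-residue PDB text block (coordinates in Angstrom)
toy_pdb_text <- function() {
  paste(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2       4.800   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  VAL A   3       8.600   0.000   0.000  1.00  0.00           C",
    "END", sep = "\n")
}

write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(toy_pdb_text(), path)
  path
}

# collinear chain of n residues spaced `gap` nm along x
collinear_structure <- function(n = 5, gap = 0.38) {
  new_structure(
    tibble::tibble(chain = "A", resno = seq_len(n), ins = "",
                   aa = rep_len(c("A", "G", "V"), n)),
    cbind((seq_len(n) - 1) * gap, 0, 0),
    id = "collinear")
}

# rigid transform of a structure: rotate about z by `deg` and translate
transform_structure <- function(s, deg = 30, shift = c(1, -2, 0.5)) {
  th <- deg * pi / 180
  rot <- matrix(c(cos(th), -sin(th), 0,
                  sin(th), cos(th), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
  s$xyz <- sweep(s$xyz %*% t(rot), 2, shift, `+`)
  s
}

# brute-force nMI oracle: exhaustive joint counts, plug-in entropies,
# Miller-Madow bias, written independently of the package internals
oracle_nmi <- function(ci, cj) {
  m <- length(ci)
  li <- sort(unique(ci)); lj <- sort(unique(cj))
  joint <- matrix(0, length(li), length(lj))
  for (k in seq_len(m)) {
    a <- match(ci[k], li); b <- match(cj[k], lj)
    joint[a, b] <- joint[a, b] + 1
  }
  pj <- joint / m
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hj <- h(as.numeric(pj))
  mi <- h(rowSums(pj)) + h(colSums(pj)) - hj
  eps <- (length(li) - 1) * (length(lj) - 1) / (2 * m)
  nmi <- if (hj <= 0) 0 else min(max((mi - eps) / hj, 0), 1)
  list(nmi = nmi, mi = mi, h_joint = hj, epsilon = eps)
}

# wrap an integer letter matrix as a fold_strings-compatible object
strings_from_matrix <- function(mat, chain = "A") {
  structure(list(letters = mat,
                 window_map = tibble::tibble(
                   fragment = seq_len(ncol(mat)), chain = chain,
                   start = seq_len(ncol(mat)),
                   resno_start = seq_len(ncol(mat))),
                 alphabet = list(K = max(mat))),
            class = "fold_strings")
}

# random additive (tree-generated) distance matrix plus its tree
random_additive_matrix <- function(n_taxa, seed) {
  tr <- with_seed(seed, ape::rtree(n_taxa))
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                     globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# max bound violation of one conformation, reimplemented for tests
bound_violation_for_test <- function(xyz, cs) {
  d <- sqrt(rowSums((xyz[cs$i, , drop = FALSE] -
                     xyz[cs$j, , drop = FALSE])^2))
  pmax(cs$d_min - d, d - cs$d_max, 0)
}

# small vector helpers reimplemented for tests
crossv <- function(a, b) c(a[2]*b[3] - a[3]*b[2],
                           a[3]*b[1] - a[1]*b[3],
                           a[1]*b[2] - a[2]*b[1])
unitv <- function(v) v / sqrt(sum(v^2))

principal_axis_for_test <- function(xyz) {
  c0 <- sweep(xyz, 2, colMeans(xyz))
  eigen(crossprod(c0) / nrow(c0), symmetric = TRUE)$vectors[, 1]
}

# rotate the residues in `idx` about axis (through their centroid) by deg
rotate_set <- function(xyz, idx, axis, deg) {
  th <- deg * pi / 180
  k <- unitv(axis)
  ctr <- colMeans(xyz[idx, , drop = FALSE])
  kmat <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
                 3, 3, byrow = TRUE)
  rot <- diag(3) + sin(th) * kmat + (1 - cos(th)) * kmat %*% kmat
  xyz[idx, ] <- sweep(sweep(xyz[idx, , drop = FALSE], 2, ctr) %*% t(rot),
                      2, ctr, `+`)
  xyz
}

# per-coordinate variance summed per residue, for the trace identity
apply_var_for_test <- function(e) {
  v <- 0
  for (k in 1:3) v <- v + apply(e$coords[, , k], 2, stats::var)
  v
}

# 10-mode decaying spectrum whose top three fractions are 0.46/0.14/0.10;
# a well-determined top-10 subspace for convergence studies
decaying_spectrum <- function() {
  c(0.46, 0.14, 0.10, 0.07, 0.06, 0.05, 0.04, 0.03, 0.025, 0.02)
}

# dimer-like structure whose two chain axes are tilted 40 degrees apart,
# so the interface frame is well defined
tilted_dimer <- function(n = 12) {
  s <- synth_structure(n, "dimer")
  s$xyz <- rotate_set(s$xyz, (n + 1):(2 * n), c(1, 0, 0), 40)
  s
}

# build a minimal fold_network-compatible object from an edge tibble
fake_network <- function(n_nodes, edges) {
  structure(list(
    edges = edges, all_pairs = edges,
    window_map = tibble::tibble(fragment = seq_len(n_nodes), chain = "A",
                                start = seq_len(n_nodes),
                                resno_start = seq_len(n_nodes)),
    n_nodes = n_nodes, significance_cut = -Inf,
    nmi_threshold = 0, min_sep = 4L), class = "fold_network")
}
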