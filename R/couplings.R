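# Structural-alphabet encoding of ensembles and normalized
# mutual-information coupling networks.
#
# Each conformer is discretised into overlapping 4-residue fragments; a
# fragment's geometry is summarised by a scale-free descriptor (three
# planar angles plus the pseudo-torsion, the latter embedded as
# cos/sin to respect its periodicity) and assigned the nearest prototype
# letter of a finite structural alphabet. Column-pair couplings in the
# resulting string alignment are scored with bias-corrected normalized
# mutual information.

# descriptor of one 4-point fragment: theta(1,2,3), theta(2,3,4),
# theta(1,2,4) in radians, plus cos/sin of torsion(1,2,3,4)
fragment_descriptor <- function(p) {
  ang <- function(a, b, c) {
    u <- p[a, ] - p[b, ]; v <- p[c, ] - p[b, ]
    acos(clip(sum(u * v) / sqrt(sum(u^2) * sum(v^2)), -1, 1))
  }
  b1 <- p[2, ] - p[1, ]; b2 <- p[3, ] - p[2, ]; b3 <- p[4, ] - p[3, ]
  n1 <- crossprod_vec(b1, b2); n2 <- crossprod_vec(b2, b3)
  m1 <- crossprod_vec(n1, unit(b2))
  tau <- atan2(sum(m1 * n2), sum(n1 * n2))
  c(ang(1, 2, 3), ang(2, 3, 4), ang(1, 2, 4), cos(tau), sin(tau))
}

#' Structural alphabet of fragment prototypes
#'
#' @param prototypes K x 5 matrix of fragment descriptors (rows are
#'   letters).
#' @param name provenance label.
#' @return A `fold_alphabet` object.
#' @export
new_alphabet <- function(prototypes, name = "custom") {
  prototypes <- as.matrix(prototypes)
  stopifnot(ncol(prototypes) == 5, all(is.finite(prototypes)))
  if (anyDuplicated(round(prototypes, 10)))
    stop("prototypes must be pairwise distinct")
  structure(list(prototypes = unname(prototypes),
                 K = nrow(prototypes), name = name),
            class = "fold_alphabet")
}

#' @export
print.fold_alphabet <- function(x, ...) {
  cat(sprintf("<fold_alphabet> %d letters (%s)\n", x$K, x$name))
  invisible(x)
}

#' Default 25-letter structural alphabet
#'
#' A synthetic prototype set constructed on a deterministic grid of
#' backbone geometries: five pseudo-bond angles spanning helix-like to
#' extended fragments crossed with five pseudo-torsions spanning the
#' torsional circle. It is a self-contained stand-in covering the
#' commonly populated fragment conformations, not a fit to any structure
#' database; [fit_alphabet()] derives a data-driven alphabet instead.
#'
#' @return A `fold_alphabet` with 25 letters.
#' @export
default_alphabet <- function() {
  thetas <- c(85, 100, 115, 130, 145) * pi / 180
  taus <- c(-160, -80, 0, 80, 160) * pi / 180
  g <- expand.grid(theta = thetas, tau = taus)
  proto <- cbind(g$theta, g$theta, g$theta, cos(g$tau), sin(g$tau))
  new_alphabet(proto, name = "synthetic-grid-25")
}

# all fragment descriptors of an ensemble: (m * F) x 5 matrix plus the
# fragment->residue window map
ensemble_descriptors <- function(e) {
  res <- e$topology$residues
  n <- nrow(res)
  ch <- res$chain
  starts <- which(seq_len(n) <= n - 3 &
                  ch == c(ch[-(1:3)], rep(NA, 3)))
  # keep only windows fully inside one chain
  starts <- starts[ch[starts] == ch[starts + 3]]
  if (length(starts) == 0) stop("no chain has >= 4 residues")
  m <- n_conformers(e)
  desc <- matrix(0, m * length(starts), 5)
  rowix <- 0L
  for (mi in seq_len(m)) {
    xyz <- e$coords[mi, , ]
    for (f in seq_along(starts)) {
      rowix <- rowix + 1L
      desc[rowix, ] <- fragment_descriptor(
        xyz[starts[f] + 0:3, , drop = FALSE])
    }
  }
  wmap <- tibble::tibble(fragment = seq_along(starts),
                         chain = ch[starts],
                         start = starts,
                         resno_start = res$resno[starts])
  list(desc = desc, window_map = wmap, m = m)
}

#' Fit a structural alphabet de novo by k-means on fragment descriptors
#'
#' Seeded k-means over all (conformer, window) fragment descriptors of an
#' ensemble; prototypes are the cluster centres.
#'
#' @param e a `fold_ensemble`.
#' @param K number of letters (default 25).
#' @param seed integer seed.
#' @return A `fold_alphabet`.
#' @export
fit_alphabet <- function(e, K = 25L, seed = 1L) {
  d <- ensemble_descriptors(e)
  K <- min(K, nrow(unique(round(d$desc, 8))))
  km <- with_local_seed(seed,
                        stats::kmeans(d$desc, centers = K, nstart = 5,
                                      iter.max = 50))
  new_alphabet(km$centers, name = sprintf("kmeans-%d", K))
}

#' Encode an ensemble as a structural-string alignment
#'
#' Every 4-residue window of every conformer is assigned the nearest
#' prototype letter (Euclidean distance on fragment descriptors; ties go
#' to the lowest letter index). Windows never span chain breaks, so a
#' chain of N residues contributes N - 3 fragment columns.
#'
#' @param e a `fold_ensemble`.
#' @param alphabet a `fold_alphabet` (default [default_alphabet()]).
#' @return A `fold_strings` object: `letters` (m x F integer matrix),
#'   `window_map` (fragment -> chain/start residue), `alphabet`.
#' @export
encode_ensemble <- function(e, alphabet = default_alphabet()) {
  d <- ensemble_descriptors(e)
  proto <- alphabet$prototypes
  # squared distances to each prototype; nearest (first on tie)
  d2 <- outer(rowSums(d$desc^2), rowSums(proto^2), `+`) -
    2 * d$desc %*% t(proto)
  letters <- max.col(-d2, ties.method = "first")
  mat <- matrix(letters, nrow = d$m, ncol = nrow(d$window_map),
                byrow = TRUE)
  structure(list(letters = mat, window_map = d$window_map,
                 alphabet = alphabet),
            class = "fold_strings")
}

#' @export
print.fold_strings <- function(x, ...) {
  cat(sprintf("<fold_strings> %d conformers x %d fragments (%d letters)\n",
              nrow(x$letters), ncol(x$letters), x$alphabet$K))
  invisible(x)
}

#' Normalized mutual information between two string columns
#'
#' Plug-in mutual information and joint entropy from empirical joint
#' counts (natural log), corrected for finite-sample bias with the
#' Miller–Madow term `(r_i - 1)(r_j - 1)/(2M)` nats (r = observed letter
#' counts), then normalized by the joint entropy and clipped to `[0, 1]`:
#' `nMI = (I - eps)/H_joint`. A constant joint column (zero joint
#' entropy) is defined as nMI = 0.
#'
#' @param s a `fold_strings` object, or an integer matrix of letters.
#' @param i,j column indices (i != j).
#' @return tibble row with `nmi`, `mi`, `h_joint`, `epsilon`.
#' @export
string_nmi <- function(s, i, j) {
  mat <- if (inherits(s, "fold_strings")) s$letters else s
  stopifnot(i != j, nrow(mat) >= 2)
  ci <- mat[, i]; cj <- mat[, j]
  m <- length(ci)
  jt <- table(ci, cj) / m
  p <- as.numeric(jt)
  p <- p[p > 0]
  h_joint <- -sum(p * log(p))
  pi_ <- rowSums(jt); pj_ <- colSums(jt)
  hi <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hj <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  mi <- hi + hj - h_joint
  eps <- (sum(pi_ > 0) - 1) * (sum(pj_ > 0) - 1) / (2 * m)
  nmi <- if (h_joint <= 0) 0 else clip((mi - eps) / h_joint, 0, 1)
  tibble::tibble(nmi = nmi, mi = mi, h_joint = h_joint, epsilon = eps)
}

#' Build a dynamic-coupling network from a string alignment
#'
#' Corrected nMI is computed for every eligible fragment pair (different
#' chains, or same-chain window separation greater than `min_sep`
#' residues). Edges are retained when nMI exceeds `nmi_threshold` and,
#' optionally, the 2s significance level (mean + 2 sd of the all-pairs
#' corrected-nMI distribution).
#'
#' @param s a `fold_strings`.
#' @param nmi_threshold retention threshold on nMI (default 0.15).
#' @param min_sep minimum same-chain window separation in residues
#'   (default 4; cross-chain pairs always eligible).
#' @param significance apply the 2s filter (default TRUE).
#' @return A `fold_network`: `edges` tibble (fragment pair, nmi, mi,
#'   h_joint, epsilon, inter_chain, significant), `all_pairs` (the full
#'   eligible-pair score table), `window_map`, `n_nodes`,
#'   `significance_cut`.
#' @export
coupling_network <- function(s, nmi_threshold = 0.15, min_sep = 4L,
                             significance = TRUE) {
  stopifnot(is.finite(nmi_threshold), is.finite(min_sep))
  wm <- s$window_map
  f <- nrow(wm)
  pr <- which(upper.tri(matrix(0, f, f)), arr.ind = TRUE)
  same <- wm$chain[pr[, 1]] == wm$chain[pr[, 2]]
  sep <- abs(wm$start[pr[, 1]] - wm$start[pr[, 2]])
  elig <- !same | sep > min_sep
  pr <- pr[elig, , drop = FALSE]
  scores <- purrr::map2_dfr(pr[, 1], pr[, 2],
                            function(i, j) string_nmi(s, i, j))
  all_pairs <- dplyr::bind_cols(
    tibble::tibble(i = as.integer(pr[, 1]), j = as.integer(pr[, 2]),
                   inter_chain = wm$chain[pr[, 1]] != wm$chain[pr[, 2]]),
    scores)
  cut2s <- if (nrow(all_pairs) > 1)
    mean(all_pairs$nmi) + 2 * stats::sd(all_pairs$nmi) else -Inf
  keep <- all_pairs$nmi > nmi_threshold
  if (significance) keep <- keep & all_pairs$nmi > cut2s
  edges <- all_pairs[keep, , drop = FALSE]
  edges$significant <- edges$nmi > cut2s
  structure(list(edges = edges, all_pairs = all_pairs,
                 window_map = wm, n_nodes = f,
                 significance_cut = cut2s,
                 nmi_threshold = nmi_threshold, min_sep = min_sep),
            class = "fold_network")
}

#' @export
print.fold_network <- function(x, ...) {
  cat(sprintf(
    "<fold_network> %d fragments, %d edges (nMI > %.3g, 2s cut %.3g)\n",
    x$n_nodes, nrow(x$edges), x$nmi_threshold, x$significance_cut))
  invisible(x)
}

#' Eigenvector centrality of a coupling network
#'
#' Leading eigenvector of the symmetric fragment coupling matrix (nMI
#' edge weights, zero diagonal), unit-normalized and nonnegative. On a
#' disconnected network the centrality is computed on the full matrix
#' (mass concentrates on the dominant component) and the component index
#' of every node is reported.
#'
#' @param net a `fold_network`.
#' @return tibble: `fragment`, `centrality`, `component`, plus attributes
#'   `lambda` (leading eigenvalue) and `n_components`.
#' @export
network_centrality <- function(net) {
  if (nrow(net$edges) == 0) stop("network has no edges")
  f <- net$n_nodes
  a <- matrix(0, f, f)
  a[cbind(net$edges$i, net$edges$j)] <- net$edges$nmi
  a <- a + t(a)
  ev <- eigen(a, symmetric = TRUE)
  v <- ev$vectors[, which.max(ev$values)]
  v <- abs(v) / sqrt(sum(v^2))
  g <- igraph::graph_from_adjacency_matrix(a > 0, mode = "undirected")
  comp <- igraph::components(g)$membership
  out <- tibble::tibble(fragment = seq_len(f), centrality = v,
                        component = as.integer(comp))
  attr(out, "lambda") <- max(ev$values)
  attr(out, "n_components") <- max(comp)
  out
}

#' Per-residue centrality profile
#'
#' Projects fragment centralities back onto residues: each residue's
#' score is the mean centrality of the 4-residue windows covering it.
#'
#' @param net a `fold_network`.
#' @param centrality optional precomputed [network_centrality()] table.
#' @return tibble: `residue` (internal index), `chain`, `centrality`.
#' @export
residue_centrality <- function(net, centrality = NULL) {
  cen <- centrality %||% network_centrality(net)
  wm <- net$window_map
  cover <- tidyr::expand_grid(fragment = wm$fragment, offset = 0:3)
  cover$residue <- wm$start[cover$fragment] + cover$offset
  cover$chain <- wm$chain[cover$fragment]
  cover$centrality <- cen$centrality[cover$fragment]
  dplyr::summarise(dplyr::group_by(cover, .data$residue, .data$chain),
                   centrality = mean(.data$centrality), .groups = "drop")
}

#' Export a coupling network as GraphML
#'
#' @param net a `fold_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$edges$i, to = net$edges$j,
               weight = net$edges$nmi),
    directed = FALSE,
    vertices = data.frame(name = seq_len(net$n_nodes),
                          chain = net$window_map$chain,
                          start = net$window_map$start))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a coupling network as a weighted edge-list TSV
#'
#' @param net a `fold_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  utils::write.table(as.data.frame(net$edges), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
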