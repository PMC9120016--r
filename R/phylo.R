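# Distance-based trees, tree-topology similarity, tip diversity,
# greedy sequence clustering and clade composition statistics.

#' Pairwise sequence distance matrix from an alignment
#'
#' `identity`: fraction of differing residues over positions where both
#' sequences are ungapped. `kimura`: the distance-corrected form
#' `-ln(1 - d - d^2/5)` of the identity distance.
#'
#' @param m a `fold_msa`.
#' @param model `"identity"` or `"kimura"`.
#' @return symmetric distance matrix with MSA ids as dimnames.
#' @export
seq_distance_matrix <- function(m, model = c("identity", "kimura")) {
  model <- match.arg(model)
  if (m$n < 3) stop("need at least 3 sequences")
  idm <- pairwise_identity_checked(m$mat)
  d <- 1 - idm
  if (model == "kimura") {
    arg <- 1 - d - d^2 / 5
    if (any(arg <= 0.01)) {
      warning("saturated distances capped in kimura correction")
      arg <- pmax(arg, 0.01)
    }
    d <- -log(arg)
    diag(d) <- 0
  }
  dimnames(d) <- list(m$ids, m$ids)
  d
}

pairwise_identity_checked <- function(mat) {
  n <- nrow(mat)
  gap <- !(mat %in% AA1)
  dim(gap) <- dim(mat)
  out <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      both <- !gap[i, ] & !gap[j, ]
      if (!any(both)) stop("zero aligned overlap between rows ", i,
                           " and ", j)
      out[i, j] <- out[j, i] <- mean(mat[i, both] == mat[j, both])
    }
  }
  out
}

#' Neighbor-joining tree from a distance matrix
#'
#' Wraps [ape::nj()]; negative branch lengths are clamped to zero with
#' the original values recorded in the `original_lengths` attribute.
#'
#' @param d symmetric distance matrix with taxon dimnames.
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d)))) stop("distance matrix not symmetric")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(stats::as.dist(d))
  orig <- tr$edge.length
  tr$edge.length <- pmax(orig, 0)
  attr(tr, "original_lengths") <- orig
  tr
}

#' Tree-topology similarity (r score)
#'
#' Pearson correlation between the vectors of all pairwise tip
#' path-length distances of two trees over their shared tip set, ordered
#' identically. Used to compare domain trees of the same proteins (e.g.
#' association-domain versus kinase-domain trees); r is invariant to
#' uniform rescaling of either tree's branch lengths.
#'
#' @param a,b `phylo` trees.
#' @param pairing optional named character vector mapping tip names of
#'   `a` to tip names of `b`; by default tips pair by shared name, with
#'   unmatched tips dropped (count reported in the result).
#' @return A `fold_treecomp`: `r`, `n_tips`, `n_pairs`, `n_dropped`,
#'   `distances` tibble (`tip1`, `tip2`, `x`, `y`).
#' @export
tree_similarity <- function(a, b, pairing = NULL) {
  if (is.null(pairing)) {
    shared <- intersect(a$tip.label, b$tip.label)
    pairing <- setNames(shared, shared)
  }
  pairing <- pairing[names(pairing) %in% a$tip.label &
                     pairing %in% b$tip.label]
  if (length(pairing) < 3) stop("fewer than 3 shared tips")
  n_dropped <- length(a$tip.label) - length(pairing)
  da <- ape::cophenetic.phylo(a)[names(pairing), names(pairing)]
  db <- ape::cophenetic.phylo(b)[pairing, pairing]
  ut <- upper.tri(da)
  ij <- which(ut, arr.ind = TRUE)
  x <- da[ut]; y <- db[ut]
  structure(list(r = stats::cor(x, y),
                 n_tips = length(pairing),
                 n_pairs = length(x),
                 n_dropped = n_dropped,
                 distances = tibble::tibble(
                   tip1 = rownames(da)[ij[, 1]],
                   tip2 = rownames(da)[ij[, 2]],
                   x = x, y = y)),
            class = "fold_treecomp")
}

#' @export
print.fold_treecomp <- function(x, ...) {
  cat(sprintf("<fold_treecomp> r = %.3f over %d shared tips (%d pairs)\n",
              x$r, x$n_tips, x$n_pairs))
  invisible(x)
}

#' Mean tip distance (diversity) of a tip subset
#'
#' Average pairwise path-length distance among the selected tips — the
#' diversity measure used to compare isoform clades.
#'
#' @param tree a `phylo`.
#' @param tips character vector of tip labels (>= 2).
#' @return mean pairwise tip distance.
#' @export
tip_diversity <- function(tree, tips = tree$tip.label) {
  missing_t <- setdiff(tips, tree$tip.label)
  if (length(missing_t) > 0)
    stop("tips absent from tree: ", paste(missing_t, collapse = ","))
  if (length(tips) < 2) stop("need at least 2 tips")
  d <- ape::cophenetic.phylo(tree)[tips, tips]
  mean(d[upper.tri(d)])
}

#' Greedy identity clustering of sequences
#'
#' CD-Hit-style greedy clustering: sequences are visited longest first
#' (ties keep input order); each joins the first existing cluster whose
#' representative has identity at or above the cutoff, else founds a new
#' cluster. An optional second pass re-clusters the representatives at a
#' lower cutoff. Deterministic given the input order.
#'
#' @param seqs named character vector of (aligned or equal-length)
#'   sequences.
#' @param cutoff identity cutoff in (0, 1).
#' @param then optional second-pass cutoff applied to representatives.
#' @return tibble: `id`, `cluster`, `representative` (logical),
#'   `rep_id`.
#' @export
cluster_sequences <- function(seqs, cutoff = 0.8, then = NULL) {
  stopifnot(cutoff > 0, cutoff < 1)
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  ungapped <- gsub("-", "", seqs)
  ord <- order(-nchar(ungapped), seq_along(seqs))
  reps <- integer(0)  # indices of representatives
  memb <- integer(length(seqs))
  for (k in ord) {
    placed <- FALSE
    for (r in seq_along(reps)) {
      if (seq_identity(seqs[[k]], seqs[[reps[r]]]) >= cutoff) {
        memb[k] <- r; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, k)
      memb[k] <- length(reps)
    }
  }
  out <- tibble::tibble(id = ids, cluster = memb,
                        representative = seq_along(seqs) %in% reps,
                        rep_id = ids[reps[memb]])
  if (!is.null(then)) {
    second <- cluster_sequences(setNames(seqs[reps], ids[reps]),
                                cutoff = then)
    remap <- second$cluster[match(out$rep_id, second$id)]
    out$cluster <- remap
    out$rep_id <- second$rep_id[match(out$rep_id, second$id)]
    out$representative <- out$id %in% second$id[second$representative]
  }
  out
}

# identity between two sequences: aligned (equal length) -> column
# identity over mutually ungapped positions; otherwise identity over the
# shorter ungapped sequence via exact matching is not defined -> error.
seq_identity <- function(s1, s2) {
  a <- strsplit(s1, "")[[1]]
  b <- strsplit(s2, "")[[1]]
  if (length(a) != length(b))
    stop("sequences must be aligned (equal length) for identity")
  both <- a != "-" & b != "-"
  if (!any(both)) return(0)
  mean(a[both] == b[both])
}

#' Clade composition and homeotherm:poikilotherm outlier flags
#'
#' For each requested internal node: member count, label histograms and
#' the H:P tip-count ratio. A clade is flagged when its ratio falls
#' outside mean +/- 2s of the *other* clades' finite ratios (population
#' s). All-H clades have infinite ratio and are excluded from the
#' reference mean.
#'
#' @param tree a `phylo`.
#' @param labels tibble with columns `tip`, `thermo` (`"H"`, `"P"` or
#'   `"unknown"`), and optionally `isoform`, `phylum`.
#' @param clades internal node numbers (default: all internal nodes with
#'   at least `min_tips` tips, root excluded).
#' @param min_tips minimum clade size for the default clade set.
#' @return tibble of class `fold_nodecomp`: `node`, `n_tips`, `n_h`,
#'   `n_p`, `hp_ratio`, `flagged`, `ref_mean`, `ref_sd`, plus
#'   `isoform_counts`/`phylum_counts` list-columns when those labels are
#'   present.
#' @export
node_composition <- function(tree, labels, clades = NULL, min_tips = 3L) {
  nt <- ape::Ntip(tree)
  if (is.null(clades)) {
    clades <- setdiff((nt + 1L):(nt + tree$Nnode), nt + 1L)
    sizes <- vapply(clades, function(nd)
      length(clade_tip_labels(tree, nd)), 0L)
    clades <- clades[sizes >= min_tips]
  }
  if (length(clades) == 0) stop("no clades to score")
  rows <- lapply(clades, function(nd) {
    tl <- clade_tip_labels(tree, nd)
    lab <- labels[match(tl, labels$tip), , drop = FALSE]
    if (all(is.na(lab$thermo)) || nrow(lab) == 0)
      stop("clade ", nd, " has zero labeled tips")
    nh <- sum(lab$thermo == "H", na.rm = TRUE)
    np <- sum(lab$thermo == "P", na.rm = TRUE)
    tibble::tibble(
      node = nd, n_tips = length(tl), n_h = nh, n_p = np,
      hp_ratio = if (np == 0) Inf else nh / np,
      isoform_counts = if ("isoform" %in% names(lab))
        list(table(lab$isoform)) else list(NULL),
      phylum_counts = if ("phylum" %in% names(lab))
        list(table(lab$phylum)) else list(NULL))
  })
  out <- dplyr::bind_rows(rows)
  out$flagged <- vapply(seq_len(nrow(out)), function(k) {
    others <- out$hp_ratio[-k]
    others <- others[is.finite(others)]
    if (length(others) < 2 || !is.finite(out$hp_ratio[k])) return(FALSE)
    mu <- mean(others)
    s <- sqrt(mean((others - mu)^2))
    out$hp_ratio[k] < mu - 2 * s || out$hp_ratio[k] > mu + 2 * s
  }, logical(1))
  ref <- out$hp_ratio[is.finite(out$hp_ratio)]
  out$ref_mean <- mean(ref)
  out$ref_sd <- sqrt(mean((ref - mean(ref))^2))
  class(out) <- c("fold_nodecomp", class(out))
  out
}

clade_tip_labels <- function(tree, node) {
  nt <- ape::Ntip(tree)
  if (node <= nt) return(tree$tip.label[node])
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, function(k) clade_tip_labels(tree, k)))
}
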