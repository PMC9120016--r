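# MSA statistics: conservation entropy, redundancy weighting, scaled
# coevolution scores, and real-valued Evolutionary Trace.

#' Multiple sequence alignment container
#'
#' @param seqs character vector of aligned sequences (20 amino acids plus
#'   `-` gaps; `.` is normalised to `-`), or a character matrix
#'   (sequences x positions).
#' @param ids sequence identifiers (defaults to names of `seqs`).
#' @return A `fold_msa`: `ids`, `mat` (Nseq x L character matrix), `L`,
#'   `n`.
#' @export
new_msa <- function(seqs, ids = NULL) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
    ids <- ids %||% rownames(seqs) %||% paste0("seq", seq_len(nrow(seqs)))
  } else {
    ids <- ids %||% names(seqs) %||% paste0("seq", seq_along(seqs))
    seqs <- toupper(gsub("\\.", "-", seqs))
    if (length(unique(nchar(seqs))) != 1)
      stop("sequences are not aligned (unequal lengths)")
    mat <- do.call(rbind, strsplit(seqs, ""))
  }
  mat[mat == "."] <- "-"
  bad <- !(mat %in% c(AA1, "-", "X"))
  if (any(bad)) stop("invalid alignment characters: ",
                     paste(unique(mat[bad]), collapse = ","))
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  structure(list(ids = as.character(ids), mat = unname(mat),
                 L = ncol(mat), n = nrow(mat)),
            class = "fold_msa")
}

#' @export
print.fold_msa <- function(x, ...) {
  cat(sprintf("<fold_msa> %d sequences x %d positions\n", x$n, x$L))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' @param path FASTA path.
#' @return A `fold_msa`.
#' @export
read_msa <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  new_msa(as.character(aa), ids = names(aa))
}

#' Write an MSA as aligned FASTA
#'
#' @param m a `fold_msa`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(m, path) {
  seqs <- apply(m$mat, 1, paste, collapse = "")
  aa <- Biostrings::AAStringSet(setNames(seqs, m$ids))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# weighted aa frequency vector of one column (gaps excluded)
column_freqs <- function(col, weights) {
  keep <- col %in% AA1
  if (!any(keep)) return(setNames(numeric(20), AA1))
  w <- weights[keep]
  f <- vapply(AA1, function(a) sum(w[col[keep] == a]), 0)
  f / sum(f)
}

shannon <- function(f) {
  f <- f[f > 0]
  if (length(f) == 0) return(0)
  -sum(f * log(f))
}

#' Per-column conservation entropy
#'
#' Natural-log Shannon entropy of the (optionally weighted) amino-acid
#' frequencies at each position; gaps are excluded from the frequencies.
#' An all-gap column has entropy 0 and is flagged.
#'
#' @param m a `fold_msa`.
#' @param positions positions to score (default all).
#' @param weights optional per-sequence weights.
#' @return tibble: `position`, `entropy`, `gap_fraction`, `all_gap`.
#' @export
column_entropy <- function(m, positions = NULL, weights = NULL) {
  positions <- positions %||% seq_len(m$L)
  weights <- weights %||% rep(1, m$n)
  ent <- vapply(positions, function(i)
    shannon(column_freqs(m$mat[, i], weights)), 0)
  gapf <- vapply(positions, function(i) mean(!(m$mat[, i] %in% AA1)), 0)
  tibble::tibble(position = positions, entropy = ent,
                 gap_fraction = gapf, all_gap = gapf == 1)
}

#' Redundancy-correcting sequence weights
#'
#' Weight of a sequence = 1 / (number of alignment rows, itself included,
#' with pairwise identity at or above the cutoff). Identity is the match
#' fraction over positions where both sequences are ungapped.
#'
#' @param m a `fold_msa`.
#' @param identity_cutoff fraction in (0, 1), default 0.8.
#' @return numeric weight vector of length `m$n`.
#' @export
sequence_weights <- function(m, identity_cutoff = 0.8) {
  stopifnot(identity_cutoff > 0, identity_cutoff < 1)
  idm <- pairwise_identity(m$mat)
  1 / rowSums(idm >= identity_cutoff)
}

# n x n pairwise identity over mutually ungapped positions
pairwise_identity <- function(mat) {
  n <- nrow(mat)
  out <- diag(1, n)
  gap <- !(mat %in% AA1)
  dim(gap) <- dim(mat)
  for (i in seq_len(n - 1)) {
    ri <- mat[i, ]
    for (j in (i + 1):n) {
      both <- !gap[i, ] & !gap[j, ]
      out[i, j] <- out[j, i] <-
        if (any(both)) mean(ri[both] == mat[j, both]) else 0
    }
  }
  out
}

#' Coevolution scores with product (APC) correction and scaled-score tiers
#'
#' The default scorer is average-product-corrected mutual information on
#' redundancy-weighted frequencies; any plug-in scorer returning a raw
#' score per eligible pair can be substituted. Only pairs with sequence
#' separation strictly greater than `min_sep` are scored, and columns with
#' more than `max_gap` gaps are excluded. The scaled score is
#' `S_s = S_r / mean(S_r)` (so mean S_s is exactly 1); the significance
#' threshold `Nseq/L` is reported alongside.
#'
#' @param m a `fold_msa`.
#' @param scorer optional function(msa, weights, pairs-tibble) returning a
#'   numeric raw score per row of the pairs tibble.
#' @param min_sep minimum |i - j| exclusive bound (default 3: pairs with
#'   separation <= 3 are absent).
#' @param max_gap maximum per-column gap fraction (default 0.5).
#' @param identity_cutoff redundancy-weighting cutoff (default 0.8).
#' @param top_tier,mapped_tier scaled-score tier thresholds
#'   (defaults 1.4 and 0.5).
#' @return A `fold_coevolution`: `pairs` tibble (`i`, `j`, `s_r`, `s_s`,
#'   `tier`), `threshold` (Nseq/L), `excluded_columns`, tier cutoffs.
#' @export
coevolve <- function(m, scorer = NULL, min_sep = 3L, max_gap = 0.5,
                     identity_cutoff = 0.8, top_tier = 1.4,
                     mapped_tier = 0.5) {
  if (m$n < 2) stop("need at least 2 sequences")
  if (m$L < 5) stop("alignment too short")
  w <- sequence_weights(m, identity_cutoff)
  gap <- !(m$mat %in% AA1)
  dim(gap) <- dim(m$mat)
  gapf <- colMeans(gap)
  ok_cols <- which(gapf <= max_gap)
  pairs <- tidyr::expand_grid(i = ok_cols, j = ok_cols)
  pairs <- pairs[pairs$j - pairs$i > min_sep, , drop = FALSE]
  if (nrow(pairs) == 0) stop("no eligible column pairs")
  scorer <- scorer %||% apc_mi_scorer
  pairs$s_r <- scorer(m, w, pairs)
  pairs$s_s <- pairs$s_r / mean(pairs$s_r)
  pairs$tier <- dplyr::case_when(pairs$s_s > top_tier ~ "top",
                                 pairs$s_s > mapped_tier ~ "mapped",
                                 TRUE ~ "background")
  pairs <- pairs[order(-pairs$s_s), ]
  structure(list(pairs = tibble::as_tibble(pairs),
                 threshold = m$n / m$L,
                 excluded_columns = setdiff(seq_len(m$L), ok_cols),
                 top_tier = top_tier, mapped_tier = mapped_tier,
                 n_seq = m$n, L = m$L),
            class = "fold_coevolution")
}

# APC-corrected weighted mutual information raw scorer
apc_mi_scorer <- function(m, w, pairs) {
  cols <- sort(unique(c(pairs$i, pairs$j)))
  # weighted MI between every needed pair
  mi_pair <- function(i, j) {
    ci <- m$mat[, i]; cj <- m$mat[, j]
    keep <- ci %in% AA1 & cj %in% AA1
    if (!any(keep)) return(0)
    wk <- w[keep] / sum(w[keep])
    jf <- tapply(wk, list(factor(ci[keep], AA1), factor(cj[keep], AA1)),
                 sum, default = 0)
    fi <- rowSums(jf); fj <- colSums(jf)
    shannon(fi) + shannon(fj) - shannon(as.numeric(jf))
  }
  all_ij <- tidyr::expand_grid(i = cols, j = cols)
  all_ij <- all_ij[all_ij$i < all_ij$j, ]
  mi_all <- purrr::map2_dbl(all_ij$i, all_ij$j, mi_pair)
  mi_mat <- matrix(0, m$L, m$L)
  mi_mat[cbind(all_ij$i, all_ij$j)] <- mi_all
  mi_mat <- mi_mat + t(mi_mat)
  colmean <- rowSums(mi_mat[cols, cols]) / (length(cols) - 1)
  names(colmean) <- cols
  allmean <- mean(mi_mat[cols, cols][upper.tri(diag(length(cols)))])
  apc <- outer(colmean, colmean) / allmean
  raw <- mi_mat[cbind(pairs$i, pairs$j)] -
    apc[cbind(match(pairs$i, cols), match(pairs$j, cols))]
  # negative product-corrected values carry no coupling evidence; the
  # raw score stays nonnegative so the scaled score S_r/mean(S_r)
  # preserves ranking (as with pseudo-likelihood couplings)
  pmax(raw, 0)
}

#' @export
print.fold_coevolution <- function(x, ...) {
  cat(sprintf(
    "<fold_coevolution> %d pairs (%d seq x %d pos), Nseq/L = %.1f; top tier (S_s > %.2g): %d\n",
    nrow(x$pairs), x$n_seq, x$L, x$threshold, x$top_tier,
    sum(x$pairs$tier == "top")))
  invisible(x)
}

#' Select a coevolution tier
#'
#' @param coev a `fold_coevolution`.
#' @param tier `"top"` (S_s above the top threshold) or `"mapped"` (above
#'   the mapped threshold).
#' @return tibble of the selected pairs, strongest first.
#' @export
coevolution_tier <- function(coev, tier = c("top", "mapped")) {
  tier <- match.arg(tier)
  cut <- if (tier == "top") coev$top_tier else coev$mapped_tier
  coev$pairs[coev$pairs$s_s > cut, , drop = FALSE]
}

#' Real-valued Evolutionary Trace
#'
#' Integrates per-column entropy with the phylogenetic grouping hierarchy:
#' for every split level n (1 to Ntips - 1 groups, formed by cutting the
#' rooted tree at its shallowest internal nodes first), the entropy of
#' each column within each group is averaged with node weights
#' `w_node(n) = 1/n` and group weights proportional to `1/group size`
#' (normalised per level). Scores are `1 + ` the weighted sum, so a fully
#' conserved column scores exactly 1 and lower means more
#' conserved/ancient.
#'
#' @param m a `fold_msa`.
#' @param tree a rooted `phylo` whose tip labels are a subset of the MSA
#'   ids (an unrooted tree is midpoint-rooted).
#' @return tibble of class `fold_et`: `position`, `entropy`, `rvet`,
#'   `rank`.
#' @export
rvet <- function(m, tree) {
  if (!all(tree$tip.label %in% m$ids))
    stop("tree tips missing from MSA: ",
         paste(setdiff(tree$tip.label, m$ids), collapse = ","))
  if (!ape::is.rooted(tree)) tree <- midpoint_root(tree)
  rows <- match(tree$tip.label, m$ids)
  groups_by_level <- tree_partition_levels(tree)
  ent_total <- column_entropy(m)$entropy
  rv <- rep(1, m$L)
  for (lev in seq_along(groups_by_level)) {
    gl <- groups_by_level[[lev]]
    n <- length(gl)  # group count defines the node weight 1/n
    sizes <- vapply(gl, length, 0L)
    wg <- (1 / sizes) / sum(1 / sizes)
    for (g in seq_along(gl)) {
      sub <- m$mat[rows[gl[[g]]], , drop = FALSE]
      s_g <- vapply(seq_len(m$L), function(i)
        shannon(column_freqs(sub[, i], rep(1, nrow(sub)))), 0)
      rv <- rv + (1 / n) * wg[g] * s_g
    }
  }
  out <- tibble::tibble(position = seq_len(m$L), entropy = ent_total,
                        rvet = rv, rank = rank(rv, ties.method = "min"))
  class(out) <- c("fold_et", class(out))
  out
}

# Partition levels of a rooted tree: element n is a list of tip-index
# groups obtained after splitting the n-1 shallowest internal nodes
# (root first). Level 1 is the whole tip set.
tree_partition_levels <- function(tree) {
  nt <- ape::Ntip(tree)
  root <- nt + 1L
  depth <- ape::node.depth.edgelength(tree)
  clade_tips <- function(node) {
    if (node <= nt) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, clade_tips))
  }
  internal <- (nt + 1L):(nt + tree$Nnode)
  internal <- internal[order(depth[internal])]
  active <- root  # active clade roots
  levels <- list(list(sort(clade_tips(root))))
  for (nd in internal) {
    pos <- which(active == nd)
    if (length(pos) == 0) next
    kids <- tree$edge[tree$edge[, 1] == nd, 2]
    active <- c(active[-pos], kids)
    if (length(active) > nt - 1) break
    levels[[length(levels) + 1]] <-
      lapply(active, function(x) sort(clade_tips(x)))
  }
  levels
}

# midpoint rooting without extra dependencies: root on the edge at the
# centre of the longest tip-to-tip path
midpoint_root <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  ij <- which(d == max(d), arr.ind = TRUE)[1, ]
  ape::root(tree, outgroup = rownames(d)[ij[1]], resolve.root = TRUE)
}
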