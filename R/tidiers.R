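# broom-style tidiers for fitted objects.

#' Tidy a PCA result into an eigen-table
#'
#' @param x a `fold_pca`.
#' @param n_modes number of leading modes to report (default all with
#'   positive eigenvalue).
#' @param ... unused.
#' @return tibble: `mode`, `eigenvalue`, `fraction`, `cumulative`.
#' @method tidy fold_pca
#' @export
tidy.fold_pca <- function(x, n_modes = NULL, ...) {
  n_modes <- n_modes %||% max(sum(x$eigenvalues > 0), 1)
  k <- seq_len(min(n_modes, length(x$eigenvalues)))
  tibble::tibble(mode = k, eigenvalue = x$eigenvalues[k],
                 fraction = x$fractions[k],
                 cumulative = cumsum(x$fractions)[k])
}

#' @method glance fold_pca
#' @export
glance.fold_pca <- function(x, ...) {
  tibble::tibble(n_conformers = x$n_conformers,
                 total_variance = sum(x$eigenvalues),
                 pc1_fraction = x$fractions[1],
                 top3_fraction = sum(x$fractions[1:min(3,
                   length(x$fractions))]))
}

#' @method tidy fold_network
#' @export
tidy.fold_network <- function(x, ...) x$edges

#' @method glance fold_network
#' @export
glance.fold_network <- function(x, ...) {
  tibble::tibble(n_nodes = x$n_nodes, n_edges = nrow(x$edges),
                 nmi_threshold = x$nmi_threshold,
                 significance_cut = x$significance_cut,
                 max_nmi = if (nrow(x$all_pairs)) max(x$all_pairs$nmi)
                           else NA_real_)
}

#' @method tidy fold_coevolution
#' @export
tidy.fold_coevolution <- function(x, ...) x$pairs

#' @method glance fold_coevolution
#' @export
glance.fold_coevolution <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x$pairs), n_seq = x$n_seq, L = x$L,
                 threshold = x$threshold,
                 n_top = sum(x$pairs$tier == "top"),
                 n_mapped = sum(x$pairs$tier %in% c("top", "mapped")))
}

#' @method tidy fold_treecomp
#' @export
tidy.fold_treecomp <- function(x, ...) x$distances

#' @method glance fold_treecomp
#' @export
glance.fold_treecomp <- function(x, ...) {
  tibble::tibble(r = x$r, n_tips = x$n_tips, n_pairs = x$n_pairs,
                 n_dropped = x$n_dropped)
}

#' @method tidy fold_sectors
#' @export
tidy.fold_sectors <- function(x, ...) x$membership

#' @method glance fold_sectors
#' @export
glance.fold_sectors <- function(x, ...) {
  tibble::tibble(n_sectors = nrow(x$sectors),
                 n_residues = nrow(x$membership))
}

#' @method tidy fold_overlay
#' @export
tidy.fold_overlay <- function(x, ...) x$edges

#' @method glance fold_frustration
#' @export
glance.fold_frustration <- function(x, ...) {
  tibble::tibble(n_contacts = nrow(x),
                 n_relaxed = sum(x$class == "relaxed"),
                 n_neutral = sum(x$class == "neutral"),
                 n_stressed = sum(x$class == "stressed"),
                 h = attr(x, "h"))
}
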