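# Overlay of dynamic couplings, coevolved contacts and frustration
# classes, and partition of the fold into interface-associated sectors.

#' Overlay dynamic, coevolutionary and energetic layers at residue level
#'
#' Builds a residue-level graph whose edges are the union of (a) dynamic
#' fragment couplings projected onto residues (a fragment edge contributes
#' to all 4 x 4 residue pairs of its two windows, weight split evenly) and
#' (b) coevolved column pairs above the `coev_top` scaled-score tier.
#' Edges present in both layers are tagged `both`; where a native contact
#' exists the frustration class and interface class are attached.
#'
#' @param net a `fold_network` of dynamic couplings.
#' @param coev a `fold_coevolution`.
#' @param frus a `fold_frustration` profile (optional).
#' @param cmap a `fold_contacts` map (optional; supplies interface and
#'   contact annotation).
#' @param coev_top scaled-score threshold for coevolved edges (default
#'   the coevolution object's top tier).
#' @param n_residues total residue count of the shared numbering; checked
#'   against all inputs.
#' @param position_map optional integer vector mapping MSA columns to
#'   residue indices (default identity).
#' @return A `fold_overlay`: `edges` tibble (`i`, `j`, `source`,
#'   `weight_dynamic`, `s_s`, `frustration_class`, `interface_class`,
#'   `contact`), `n_residues`.
#' @export
overlay_layers <- function(net, coev, frus = NULL, cmap = NULL,
                           coev_top = NULL, n_residues = NULL,
                           position_map = NULL) {
  wm <- net$window_map
  n_res <- n_residues %||% max(wm$start + 3)
  # dynamic fragment edges -> residue pairs
  dyn <- if (nrow(net$edges) > 0) {
    purrr::pmap_dfr(net$edges[, c("i", "j", "nmi")], function(i, j, nmi) {
      ri <- wm$start[i] + 0:3
      rj <- wm$start[j] + 0:3
      g <- tidyr::expand_grid(a = ri, b = rj)
      g <- g[g$a != g$b, ]
      tibble::tibble(i = pmin(g$a, g$b), j = pmax(g$a, g$b),
                     weight_dynamic = nmi / nrow(g))
    })
  } else tibble::tibble(i = integer(), j = integer(),
                        weight_dynamic = numeric())
  dyn <- dplyr::summarise(dplyr::group_by(dyn, .data$i, .data$j),
                          weight_dynamic = sum(.data$weight_dynamic),
                          .groups = "drop")
  # coevolved column pairs -> residue pairs
  coev_top <- coev_top %||% coev$top_tier
  cp <- coev$pairs[coev$pairs$s_s > coev_top, , drop = FALSE]
  pm <- position_map %||% seq_len(coev$L)
  bad <- unique(c(cp$i, cp$j))
  bad <- bad[bad > length(pm) | is.na(pm[bad])]
  if (length(bad) > 0)
    stop("coevolution positions with no residue mapping: ",
         paste(sort(bad), collapse = ","))
  ce <- tibble::tibble(i = pmin(pm[cp$i], pm[cp$j]),
                       j = pmax(pm[cp$i], pm[cp$j]), s_s = cp$s_s)
  off <- unique(c(ce$i, ce$j, dyn$i, dyn$j))
  off <- off[off < 1 | off > n_res]
  if (length(off) > 0)
    stop("residue indices outside 1..", n_res, ": ",
         paste(sort(off), collapse = ","))
  edges <- dplyr::full_join(dyn, ce, by = c("i", "j"))
  edges$source <- dplyr::case_when(
    !is.na(edges$weight_dynamic) & !is.na(edges$s_s) ~ "both",
    !is.na(edges$s_s) ~ "coevolved",
    TRUE ~ "dynamic")
  if (!is.null(cmap)) {
    ckey <- paste(pmin(cmap$i, cmap$j), pmax(cmap$i, cmap$j))
    hit <- match(paste(edges$i, edges$j), ckey)
    edges$contact <- !is.na(hit)
    edges$interface_class <- cmap$interface_class[hit]
  } else {
    edges$contact <- FALSE
    edges$interface_class <- NA_character_
  }
  if (!is.null(frus)) {
    fkey <- paste(pmin(frus$i, frus$j), pmax(frus$i, frus$j))
    fh <- match(paste(edges$i, edges$j), fkey)
    edges$frustration_class <- frus$class[fh]
  } else {
    edges$frustration_class <- NA_character_
  }
  edges <- edges[order(edges$i, edges$j), ]
  structure(list(edges = tibble::as_tibble(edges), n_residues = n_res),
            class = "fold_overlay")
}

#' @export
print.fold_overlay <- function(x, ...) {
  cat(sprintf("<fold_overlay> %d residue edges (%s)\n", nrow(x$edges),
              paste(names(table(x$edges$source)),
                    table(x$edges$source), sep = ":", collapse = ", ")))
  invisible(x)
}

#' Partition an overlay graph into interface-associated sectors
#'
#' Sectors are communities of the coevolved-edge subgraph (edges tagged
#' `coevolved` or `both`), found by deterministic random-walk (walktrap)
#' community detection so that a small fraction of cross-sector edges
#' does not fuse two sectors; on a graph of disjoint dense components
#' this reduces to connected components. Each community is assigned the
#' interface class holding the majority among native interface contacts
#' within `merge_radius` contact steps of its residues; exact ties give
#' `"mixed"`, components touching no interface are `"unassigned"`. The
#' per-sector frustration composition of sector contacts is reported.
#'
#' @param ov a `fold_overlay`.
#' @param cmap a `fold_contacts` map carrying interface classes.
#' @param merge_radius contact steps used to associate a component with
#'   interface contacts (default 1).
#' @return A `fold_sectors`: `membership` tibble (`residue`, `sector`),
#'   `sectors` tibble (`sector`, `interface`, `n_residues`,
#'   `n_coevolved_edges`, `n_relaxed`, `n_stressed`), deterministic and
#'   independent of edge input order.
#' @export
partition_sectors <- function(ov, cmap, merge_radius = 1L) {
  ce <- ov$edges[ov$edges$source %in% c("coevolved", "both"), ,
                 drop = FALSE]
  if (nrow(ce) == 0) {
    return(structure(list(
      membership = tibble::tibble(residue = integer(), sector = integer()),
      sectors = tibble::tibble(sector = integer(), interface = character(),
                               n_residues = integer(),
                               n_coevolved_edges = integer(),
                               n_relaxed = integer(),
                               n_stressed = integer())),
      class = "fold_sectors"))
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ce$i, to = ce$j), directed = FALSE,
    vertices = data.frame(name = sort(unique(c(ce$i, ce$j)))))
  g <- igraph::simplify(g)
  comp <- igraph::membership(igraph::cluster_walktrap(g, steps = 6))
  resid <- as.integer(names(comp))
  # deterministic sector ids: order components by smallest residue
  first_res <- tapply(resid, comp, min)
  sec_of_comp <- rank(first_res, ties.method = "first")
  membership <- tibble::tibble(residue = resid,
                               sector = as.integer(sec_of_comp[comp]))
  membership <- membership[order(membership$residue), ]
  # contact adjacency for the merge radius
  adj <- split(c(cmap$j, cmap$i), c(cmap$i, cmap$j))
  iface <- cmap[cmap$interface_class %in%
                c("vert_dim", "lat_dim", "kd_ad"), , drop = FALSE]
  sectors <- lapply(sort(unique(membership$sector)), function(sid) {
    res <- membership$residue[membership$sector == sid]
    grown <- res
    for (step in seq_len(merge_radius)) {
      grown <- unique(c(grown,
                        unlist(adj[as.character(grown)], use.names = FALSE)))
    }
    touch <- iface$interface_class[iface$i %in% grown |
                                   iface$j %in% grown]
    label <- if (length(touch) == 0) "unassigned" else {
      tc <- sort(table(touch), decreasing = TRUE)
      if (length(tc) > 1 && tc[1] == tc[2]) "mixed" else names(tc)[1]
    }
    in_sec <- ce$i %in% res & ce$j %in% res
    fr <- ov$edges$frustration_class[ov$edges$i %in% res &
                                     ov$edges$j %in% res]
    tibble::tibble(sector = sid, interface = label,
                   n_residues = length(res),
                   n_coevolved_edges = sum(in_sec),
                   n_relaxed = sum(fr == "relaxed", na.rm = TRUE),
                   n_stressed = sum(fr == "stressed", na.rm = TRUE))
  })
  structure(list(membership = membership,
                 sectors = dplyr::bind_rows(sectors)),
            class = "fold_sectors")
}

#' @export
print.fold_sectors <- function(x, ...) {
  cat(sprintf("<fold_sectors> %d sector(s), %d residues assigned\n",
              nrow(x$sectors), nrow(x$membership)))
  if (nrow(x$sectors) > 0) print(x$sectors)
  invisible(x)
}
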