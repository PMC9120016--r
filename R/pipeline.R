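# Validated configuration and an end-to-end pipeline driver over the
# synthetic study system.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    # structure / contacts
    contact_cutoff = 0.8, min_seq_sep = 3L,
    # ensemble generation
    m_conformers = 200L, displacement_limit = 0.2, max_iter = 500L,
    retain_fraction = 1.0,
    # coupling network
    nmi_threshold = 0.15, fragment_min_sep = 4L,
    # frustration
    decoys = 400L, relaxed_cut = 0.78, stressed_cut = -1,
    # coevolution
    coev_min_sep = 3L, ss_top = 1.4, ss_mapped = 0.5,
    # clustering
    cluster_cutoff = 0.8, cluster_second = 0.6,
    # synthetic study system
    n_res = 12L, layout = "tetramer", spectrum = c(0.46, 0.14, 0.10),
    msa_L = 40L, msa_rate = 1, coev_strength = 0.9, tree_tips = 16L)
}

#' Build and validate a pipeline configuration
#'
#' Starts from the package defaults (the analysis thresholds are the
#' published operating points: nMI 0.15 with fragment separation 4,
#' scaled-coevolution tiers 1.4/0.5, frustration cuts 0.78/-1, cluster
#' cutoffs 0.8/0.6, up to 500 correction sweeps) and overrides the named
#' values given. Unknown keys and non-numeric thresholds are rejected
#' before any stage runs.
#'
#' @param ... named overrides of the default parameters.
#' @return A validated `fold_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ","))
  cfg[names(over)] <- over
  num <- c("contact_cutoff", "displacement_limit", "nmi_threshold",
           "relaxed_cut", "stressed_cut", "ss_top", "ss_mapped",
           "cluster_cutoff", "cluster_second", "retain_fraction",
           "msa_rate", "coev_strength")
  for (k in num) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 ||
        !is.finite(cfg[[k]]))
      stop("config key '", k, "' must be a finite number")
  }
  if (!is.numeric(cfg$spectrum) || sum(cfg$spectrum) > 1)
    stop("config key 'spectrum' must be fractions summing to <= 1")
  structure(cfg, class = "fold_config")
}

#' Run the integrated pipeline on the synthetic study system
#'
#' Chains the stages end to end on generated inputs with planted ground
#' truth: synthetic structure -> constraint ensemble -> PCA/rmsf ->
#' structural-alphabet coupling network + centrality -> contact
#' frustration -> synthetic tree/MSA -> coevolution + rvET ->
#' phylogenetic statistics -> sector overlay and partition. Every stage
#' records its parameters and seed in the returned manifest; the run is
#' deterministic given the configuration.
#'
#' @param config a `fold_config` from [pipeline_config()].
#' @param out_dir optional directory; when given, stage tables and a
#'   `manifest.json` are written there.
#' @return list of stage results plus `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "fold_config"))
  sd0 <- as.integer(config$seed)
  s <- synth_structure(config$n_res, config$layout)
  roles <- attr(s, "groundtruth")$interface_roles
  cmap <- contacts(s, config$contact_cutoff, config$min_seq_sep,
                   interface_roles = roles)
  cs <- build_constraints(s, config$contact_cutoff,
                          config$retain_fraction, seed = sd0)
  ens <- generate_ensemble(s, cs, m = config$m_conformers,
                           displacement_limit = config$displacement_limit,
                           max_iter = config$max_iter, seed = sd0 + 1L)
  flex <- ens_rmsf(ens)
  pca <- ens_pca(ens)
  strings <- encode_ensemble(ens)
  net <- coupling_network(strings, config$nmi_threshold,
                          config$fragment_min_sep)
  cen <- if (nrow(net$edges) > 0) network_centrality(net) else NULL
  frus <- frustration(cmap, h = config$decoys, seed = sd0 + 2L,
                      relaxed_cut = config$relaxed_cut,
                      stressed_cut = config$stressed_cut)
  st <- synth_tree(config$tree_tips, seed = sd0 + 3L)
  msa <- synth_msa(st$tree, L = config$msa_L, rate = config$msa_rate,
                   coupled_cols = list(c(5L, 15L), c(8L, 25L)),
                   strength = config$coev_strength, seed = sd0 + 4L)
  coev <- coevolve(msa, min_sep = config$coev_min_sep,
                   top_tier = config$ss_top,
                   mapped_tier = config$ss_mapped)
  et <- rvet(msa, st$tree)
  dmat <- seq_distance_matrix(msa, "identity")
  tr2 <- nj_tree(dmat)
  comp <- tree_similarity(st$tree, tr2)
  ov <- overlay_layers(net, coev, frus, cmap,
                       n_residues = n_residues(s))
  sectors <- partition_sectors(ov, cmap)
  manifest <- list(config = unclass(config),
                   seed = sd0,
                   stages = list(
                     ensemble = list(accepted = ens$accepted,
                                     rejected = ens$rejected,
                                     seed = sd0 + 1L),
                     network = list(edges = nrow(net$edges),
                                    cut_2s = net$significance_cut),
                     frustration = list(seed = sd0 + 2L,
                                        h = attr(frus, "h")),
                     coevolution = list(threshold = coev$threshold),
                     tree = list(r = comp$r),
                     sectors = list(n = nrow(sectors$sectors))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(as.data.frame(flex),
                       file.path(out_dir, "rmsf.tsv"),
                       sep = "\t", row.names = FALSE)
    write_network_tsv(net, file.path(out_dir, "network.tsv"))
    write_frustration_tsv(frus, file.path(out_dir, "frustration.tsv"))
    utils::write.table(as.data.frame(coev$pairs),
                       file.path(out_dir, "coevolution.tsv"),
                       sep = "\t", row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(structure = s, contacts = cmap, ensemble = ens, rmsf = flex,
       pca = pca, network = net, centrality = cen, frustration = frus,
       tree = st, msa = msa, coevolution = coev, et = et,
       nj = tr2, tree_comparison = comp, overlay = ov,
       sectors = sectors, manifest = manifest)
}
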