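# Contact frustration: z-score of each native contact's energy against a
# distribution of randomized-identity decoys.

#' Pairwise contact energy model
#'
#' A symmetric 20 x 20 dimensionless contact potential indexed by
#' one-letter amino acid codes. Any such table can be injected; the
#' frustration index is invariant to shifting or positively scaling the
#' table.
#'
#' @param table 20 x 20 symmetric numeric matrix with dimnames over the
#'   standard amino acids.
#' @param name provenance label.
#' @return A `fold_energy_model`.
#' @export
new_energy_model <- function(table, name = "custom") {
  table <- as.matrix(table)
  stopifnot(nrow(table) == 20, ncol(table) == 20, all(is.finite(table)),
            isTRUE(all.equal(table, t(table))))
  if (is.null(dimnames(table))) dimnames(table) <- list(AA1, AA1)
  structure(list(table = table, name = name), class = "fold_energy_model")
}

#' Default contact energy model
#'
#' A deterministic, synthetic knowledge-based-style potential built from
#' the Kyte–Doolittle hydropathy scale: hydrophobic–hydrophobic contacts
#' are favourable (negative energy), mixed polar/hydrophobic contacts
#' unfavourable. It stands in for server-side statistical potentials and
#' is fully replaceable via [new_energy_model()].
#'
#' @return A `fold_energy_model`.
#' @export
default_energy_model <- function() {
  kd <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
          E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
          M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
          Y = -1.3, V = 4.2)
  kd <- kd[AA1]
  tab <- -outer(kd, kd) / 20
  new_energy_model(tab, name = "kd-hydropathy")
}

#' Contact frustration profile
#'
#' For every contact the native pair energy is compared against `h` decoy
#' energies obtained by randomizing both residue identities uniformly over
#' the 20 amino acids (geometry fixed). The frustration index is the
#' z-score `(decoy_mean - native)/decoy_sd` (population sd), so
#' stabilizing contacts — native energies at the lower end of the decoy
#' distribution — score positive. Contacts with index above
#' `relaxed_cut` are minimally frustrated ("relaxed"), below
#' `stressed_cut` highly frustrated ("stressed"), otherwise neutral.
#'
#' @param cmap a `fold_contacts` tibble (its `aa_a`/`aa_b` columns supply
#'   the native identities).
#' @param model a `fold_energy_model`.
#' @param h decoy count per contact (>= 2); `h = 400` with
#'   `exhaustive = TRUE` enumerates every amino-acid combination.
#' @param seed integer seed for decoy draws.
#' @param exhaustive use all 400 ordered identity combinations instead of
#'   sampling.
#' @param relaxed_cut,stressed_cut classification thresholds
#'   (defaults 0.78 and -1).
#' @return tibble of class `fold_frustration`: contact identifiers,
#'   `native_energy`, `decoy_mean`, `decoy_sd`, `index`, `class`,
#'   `flagged` (TRUE where decoy sd was zero and the index is undefined).
#' @export
frustration <- function(cmap, model = default_energy_model(), h = 400L,
                        seed = 1L, exhaustive = FALSE,
                        relaxed_cut = 0.78, stressed_cut = -1) {
  stopifnot(h >= 2)
  tab <- model$table
  bad <- !(cmap$aa_a %in% AA1) | !(cmap$aa_b %in% AA1)
  if (any(bad)) stop("non-standard amino acid in contacts: rows ",
                     paste(which(bad), collapse = ","))
  nc <- nrow(cmap)
  native <- tab[cbind(cmap$aa_a, cmap$aa_b)]
  if (exhaustive) {
    dvals <- as.numeric(tab)  # all 400 ordered combinations
    dmean <- rep(mean(dvals), nc)
    dsd <- rep(sqrt(mean((dvals - mean(dvals))^2)), nc)
  } else {
    dm <- with_local_seed(seed, {
      matrix(tab[cbind(sample(AA1, nc * h, replace = TRUE),
                       sample(AA1, nc * h, replace = TRUE))], nc, h)
    })
    dmean <- rowMeans(dm)
    dsd <- sqrt(rowMeans((dm - dmean)^2))
  }
  flagged <- dsd == 0
  index <- ifelse(flagged, NA_real_, (dmean - native) / dsd)
  cls <- dplyr::case_when(
    is.na(index) ~ "neutral",
    index > relaxed_cut ~ "relaxed",
    index < stressed_cut ~ "stressed",
    TRUE ~ "neutral")
  out <- dplyr::bind_cols(
    cmap[, c("chain_a", "resno_a", "aa_a", "chain_b", "resno_b", "aa_b",
             "i", "j", "interface_class")],
    tibble::tibble(native_energy = native, decoy_mean = dmean,
                   decoy_sd = dsd, index = index, class = cls,
                   flagged = flagged))
  class(out) <- c("fold_frustration", class(out))
  attr(out, "h") <- if (exhaustive) 400L else as.integer(h)
  attr(out, "seed") <- seed
  attr(out, "model") <- model$name
  out
}

#' Frustration class counts by interface class
#'
#' Contingency table of contact frustration classes across interface
#' classes; zero cells are retained so empty interfaces stay visible.
#'
#' @param fr a `fold_frustration` profile.
#' @return tibble: `interface_class`, `relaxed`, `neutral`, `stressed`,
#'   `n`, `stressed_fraction`.
#' @export
frustration_summary <- function(fr) {
  counts <- dplyr::count(
    tibble::as_tibble(fr),
    interface_class = factor(.data$interface_class),
    class = factor(.data$class,
                   levels = c("relaxed", "neutral", "stressed")),
    .drop = FALSE)
  wide <- tidyr::pivot_wider(counts, names_from = "class",
                             values_from = "n", values_fill = 0L)
  wide$interface_class <- as.character(wide$interface_class)
  wide$n <- wide$relaxed + wide$neutral + wide$stressed
  wide$stressed_fraction <- ifelse(wide$n > 0, wide$stressed / wide$n, NA)
  wide
}

#' Export a frustration profile as TSV
#'
#' @param fr a `fold_frustration`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_frustration_tsv <- function(fr, path) {
  utils::write.table(as.data.frame(fr), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
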