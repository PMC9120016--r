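#' Cα-reduced protein structure
#'
#' `fold_structure` objects hold a Cα-only reduced model of one or more
#' protein chains: per-residue identity (chain, author residue number,
#' insertion code, one-letter amino acid) and an N x 3 coordinate matrix in
#' nanometres. All downstream analysis in the package (ensembles, PCA,
#' structural-alphabet encoding, frustration) operates on this reduced
#' representation.
#'
#' @param residues tibble with columns `chain`, `resno`, `ins`, `aa`.
#' @param xyz numeric N x 3 matrix of Cα coordinates in nm.
#' @param id identifier string.
#' @return A `fold_structure` object.
#' @export
new_structure <- function(residues, xyz, id = "structure") {
  residues <- tibble::as_tibble(residues)
  xyz <- as.matrix(xyz)
  stopifnot(nrow(residues) == nrow(xyz), ncol(xyz) == 3L)
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  key <- paste(residues$chain, residues$resno, residues$ins)
  if (anyDuplicated(key)) stop("duplicate residue identities")
  structure(list(id = id, residues = residues, xyz = unname(xyz)),
            class = "fold_structure")
}

#' @export
print.fold_structure <- function(x, ...) {
  ch <- unique(x$residues$chain)
  cat(sprintf("<fold_structure> %s: %d residues, %d chain(s) [%s]\n",
              x$id, nrow(x$residues), length(ch),
              paste(ch, collapse = ",")))
  invisible(x)
}

n_residues <- function(s) nrow(s$residues)

residue_key <- function(residues) {
  paste(residues$chain, residues$resno, residues$ins, sep = "|")
}

#' Read a PDB file into a Cα-reduced structure
#'
#' Parses ATOM records with [bio3d::read.pdb()], keeps the first-listed Cα
#' of each residue (first occupancy for altlocs) and converts coordinates
#' from Angstrom to nm. Residues lacking a Cα atom are skipped and their
#' count reported via a message.
#'
#' @param path PDB file path.
#' @param model model number to read (default 1).
#' @param chain_filter optional character vector of chain identifiers to
#'   retain, e.g. `c("A","C","G","I")` to extract a tetramer sub-assembly.
#' @return A [new_structure()] object.
#' @export
read_pdb <- function(path, model = 1L, chain_filter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = model > 1L, verbose = FALSE)
  atoms <- pdb$atom
  atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (!is.null(chain_filter)) {
    missing_ch <- setdiff(chain_filter, unique(atoms$chain))
    if (length(missing_ch) > 0)
      stop("requested chain(s) not in file: ",
           paste(missing_ch, collapse = ","))
    atoms <- atoms[atoms$chain %in% chain_filter, , drop = FALSE]
  }
  ins <- ifelse(is.na(atoms$insert), "", atoms$insert)
  rkey <- paste(atoms$chain, atoms$resno, ins, sep = "|")
  is_ca <- atoms$elety == "CA"
  n_skipped <- length(setdiff(unique(rkey), unique(rkey[is_ca])))
  ca <- atoms[is_ca, , drop = FALSE]
  ca_ins <- ins[is_ca]
  keep <- !duplicated(paste(ca$chain, ca$resno, ca_ins, sep = "|"))
  ca <- ca[keep, , drop = FALSE]
  ca_ins <- ca_ins[keep]
  if (nrow(ca) == 0) stop("zero C-alpha atoms")
  if (n_skipped > 0)
    message(n_skipped, " residue(s) lacking a C-alpha skipped")
  xyz <- if (model > 1L) {
    if (is.null(dim(pdb$xyz)) || nrow(pdb$xyz) < model)
      stop("model ", model, " not present")
    mx <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    mx[which(is_ca)[keep], , drop = FALSE]
  } else {
    cbind(ca$x, ca$y, ca$z)
  }
  res <- tibble::tibble(chain = ca$chain, resno = ca$resno, ins = ca_ins,
                        aa = bio3d::aa321(ca$resid))
  new_structure(res, xyz / 10, id = basename(path))
}

#' Write a structure with per-residue scores in the B-factor column
#'
#' Exports the Cα model as a PDB file, placing `scores` in the
#' temperature-factor column (two decimals) so couplings, frustration or
#' sector assignments can be visualised in any molecular viewer. Coordinates
#' are written in Angstrom.
#'
#' @param s a `fold_structure`.
#' @param scores numeric vector with one value per residue, or a named
#'   partial vector resolved against `chain|resno|ins` keys when `fill`
#'   is given.
#' @param path output file path.
#' @param fill default score for residues not covered by `scores`.
#' @return `path`, invisibly.
#' @export
write_scored_pdb <- function(s, scores, path, fill = NULL) {
  n <- n_residues(s)
  if (length(scores) != n) {
    if (is.null(fill)) stop("score count mismatch and no fill value")
    full <- rep(fill, n)
    if (!is.null(names(scores))) {
      idx <- match(names(scores), residue_key(s$residues))
      full[idx[!is.na(idx)]] <- scores[!is.na(idx)]
    }
    scores <- full
  }
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(s$xyz * 10)),
                   resno = s$residues$resno,
                   resid = bio3d::aa123(s$residues$aa),
                   chain = s$residues$chain,
                   insert = ifelse(s$residues$ins == "", NA,
                                   s$residues$ins),
                   elety = rep("CA", n),
                   b = round(scores, 2))
  invisible(path)
}

#' Cα contact map
#'
#' All Cα pairs within `cutoff` (nm), subject to a minimum sequence
#' separation within a chain; cross-chain pairs are kept at any separation.
#' Each pair is stored once with `(i < j)` in internal residue order; the
#' map is symmetric by construction.
#'
#' Cross-chain pairs are classified through `interface_roles`, a named
#' character vector keyed by the sorted chain pair (e.g.
#' `c("A:C" = "vert_dim", "A:I" = "lat_dim")`); interface roles are supplied
#' by the user, never inferred from geometry. Same-chain pairs are `intra`;
#' cross-chain pairs without a role are `unclassified`.
#'
#' @param s a `fold_structure`.
#' @param cutoff contact distance cutoff in nm (default 0.8 Cα–Cα).
#' @param min_seq_sep minimum |i - j| within a chain (default 3).
#' @param interface_roles optional named character vector of chain-pair
#'   interface classes.
#' @return tibble of class `fold_contacts` with one row per contact:
#'   chain/resno/aa for both partners, internal indices `i`, `j`,
#'   `dist_nm` and `interface_class`.
#' @export
contacts <- function(s, cutoff = 0.8, min_seq_sep = 3L,
                     interface_roles = NULL) {
  stopifnot(cutoff > 0)
  d <- as.matrix(stats::dist(s$xyz))
  n <- n_residues(s)
  idx <- which(upper.tri(d) & d <= cutoff, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    out <- tibble::tibble(chain_a = character(), resno_a = integer(),
                          aa_a = character(), chain_b = character(),
                          resno_b = integer(), aa_b = character(),
                          i = integer(), j = integer(),
                          dist_nm = numeric(), interface_class = character())
    class(out) <- c("fold_contacts", class(out))
    attr(out, "cutoff") <- cutoff
    return(out)
  }
  res <- s$residues
  ch_a <- res$chain[idx[, 1]]
  ch_b <- res$chain[idx[, 2]]
  # positional index within chain for sequence separation
  pos <- stats::ave(seq_len(n), res$chain, FUN = seq_along)
  same <- ch_a == ch_b
  keep <- !same | abs(pos[idx[, 1]] - pos[idx[, 2]]) >= min_seq_sep
  idx <- idx[keep, , drop = FALSE]
  ch_a <- ch_a[keep]; ch_b <- ch_b[keep]
  cls <- ifelse(ch_a == ch_b, "intra", "unclassified")
  if (!is.null(interface_roles)) {
    key <- ifelse(ch_a < ch_b, paste(ch_a, ch_b, sep = ":"),
                  paste(ch_b, ch_a, sep = ":"))
    hit <- !is.na(interface_roles[key]) & ch_a != ch_b
    cls[hit] <- interface_roles[key][hit]
  }
  out <- tibble::tibble(
    chain_a = ch_a, resno_a = res$resno[idx[, 1]], aa_a = res$aa[idx[, 1]],
    chain_b = ch_b, resno_b = res$resno[idx[, 2]], aa_b = res$aa[idx[, 2]],
    i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
    dist_nm = d[idx],
    interface_class = cls)
  out <- out[order(out$i, out$j), ]
  class(out) <- c("fold_contacts", class(out))
  attr(out, "cutoff") <- cutoff
  out
}

#' Export a contact map as TSV
#'
#' @param cmap a `fold_contacts` tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contacts_tsv <- function(cmap, path) {
  utils::write.table(
    as.data.frame(cmap)[, c("chain_a", "resno_a", "chain_b", "resno_b",
                            "dist_nm", "interface_class")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Least-squares rigid superposition of two structures
#'
#' Optimal (Kabsch) rotation/translation of `a` onto `b` over a set of
#' mapped residue pairs, reporting the Cα RMSD in nm. Used e.g. to compare
#' a bacterial dimer against the vertical dimer of a metazoan hub over a
#' common structural core.
#'
#' @param a,b `fold_structure` objects (a is mobile, b fixed).
#' @param mapping a two-column integer matrix/data frame of residue indices
#'   (rows of `a` and `b`), or a data frame with columns
#'   `chain_a,resno_a,chain_b,resno_b`. Defaults to the identity mapping
#'   when the two structures have equal length.
#' @return list of class `fold_superposition` with `rotation` (3 x 3),
#'   `translation` (length 3, nm), `rmsd_nm`, `n_mapped` and the `mapping`
#'   used (recorded so the core choice is part of the output metadata).
#' @export
superpose <- function(a, b, mapping = NULL) {
  if (is.null(mapping)) {
    if (n_residues(a) != n_residues(b))
      stop("no mapping given and structures differ in length")
    mapping <- cbind(seq_len(n_residues(a)), seq_len(n_residues(b)))
  }
  if (is.data.frame(mapping) && all(c("chain_a", "resno_a") %in%
                                    names(mapping))) {
    ia <- match(paste(mapping$chain_a, mapping$resno_a, sep = "|"),
                paste(a$residues$chain, a$residues$resno, sep = "|"))
    ib <- match(paste(mapping$chain_b, mapping$resno_b, sep = "|"),
                paste(b$residues$chain, b$residues$resno, sep = "|"))
    if (anyNA(ia) || anyNA(ib)) stop("mapping names unmatched residues")
    mapping <- cbind(ia, ib)
  }
  mapping <- as.matrix(mapping)
  if (nrow(mapping) < 3) stop("underdetermined: need >= 3 mapped residues")
  fit <- kabsch(a$xyz[mapping[, 1], , drop = FALSE],
                b$xyz[mapping[, 2], , drop = FALSE])
  structure(list(rotation = fit$rotation,
                 translation = as.numeric(fit$translation),
                 rmsd_nm = fit$rmsd, n_mapped = nrow(mapping),
                 mapping = mapping),
            class = "fold_superposition")
}

#' @export
print.fold_superposition <- function(x, ...) {
  cat(sprintf("<fold_superposition> %d mapped residues, RMSD %.4f nm\n",
              x$n_mapped, x$rmsd_nm))
  invisible(x)
}

#' @rdname tidy.fold_structure
#' @method tidy fold_structure
#' @export
tidy.fold_structure <- function(x, ...) {
  dplyr::bind_cols(x$residues,
                   tibble::tibble(x_nm = x$xyz[, 1], y_nm = x$xyz[, 2],
                                  z_nm = x$xyz[, 3]))
}

#' Tidy a structure into a residue-level tibble
#'
#' @param x a `fold_structure`.
#' @param ... unused.
#' @return tibble with one row per residue (chain, resno, ins, aa,
#'   coordinates in nm).
#' @name tidy.fold_structure
NULL
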