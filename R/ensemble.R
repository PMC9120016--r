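# Constraint-based conformational ensemble generation.
#
# A reduced-representation analogue of constraint-satisfaction conformer
# engines: distance bounds are derived from the native structure (tight
# bonded bounds for chain neighbours, looser bounds for native contacts,
# with stochastic removal of a fraction of non-local bounds emulating
# predicted-unstable-bond pruning), and conformers are produced by random
# displacement followed by iterative projection onto violated bounds.

# Evaluate expr with a temporary, seeded RNG state; the caller's RNG
# stream is untouched.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a distance-bound constraint set from a native structure
#'
#' Bonded bounds (native distance +/- 5%) are created for every
#' consecutive-residue pair within a chain. Contact bounds (+/- 15%) are
#' created for native Cα contacts within `contact_cutoff`; a seeded random
#' `retain_fraction` of these non-local bounds is kept and the rest
#' dropped, emulating the removal of contacts predicted to be unstable in
#' solvent.
#'
#' @param s a `fold_structure`.
#' @param contact_cutoff native contact cutoff in nm.
#' @param retain_fraction fraction of non-local contact bounds to keep.
#' @param seed integer seed for the retention draw.
#' @return tibble of class `fold_constraints` with columns `i`, `j`,
#'   `d_min`, `d_max` (nm) and `rule` (`bonded` or `contact`).
#' @export
build_constraints <- function(s, contact_cutoff = 0.8,
                              retain_fraction = 1, seed = 1L) {
  stopifnot(retain_fraction >= 0, retain_fraction <= 1)
  n <- n_residues(s)
  if (n == 0) stop("empty structure")
  ch <- s$residues$chain
  # bonded: consecutive residues of the same chain
  bi <- which(ch[-n] == ch[-1])
  bd <- sqrt(rowSums((s$xyz[bi, , drop = FALSE] -
                      s$xyz[bi + 1, , drop = FALSE])^2))
  bonded <- tibble::tibble(i = bi, j = bi + 1L,
                           d_min = bd * 0.95, d_max = bd * 1.05,
                           rule = "bonded")
  cmap <- contacts(s, cutoff = contact_cutoff, min_seq_sep = 2L)
  nonbonded <- !(paste(cmap$i, cmap$j) %in% paste(bonded$i, bonded$j))
  cmap <- cmap[nonbonded, , drop = FALSE]
  keep <- with_local_seed(seed, {
    nk <- round(retain_fraction * nrow(cmap))
    sort(sample.int(nrow(cmap), nk))
  })
  ct <- tibble::tibble(i = cmap$i[keep], j = cmap$j[keep],
                       d_min = cmap$dist_nm[keep] * 0.85,
                       d_max = cmap$dist_nm[keep] * 1.15,
                       rule = "contact")
  out <- dplyr::bind_rows(bonded, ct)
  class(out) <- c("fold_constraints", class(out))
  out
}

# max violation of a bound set for one conformation (nm)
bound_violation <- function(xyz, cs) {
  d <- sqrt(rowSums((xyz[cs$i, , drop = FALSE] -
                     xyz[cs$j, , drop = FALSE])^2))
  pmax(cs$d_min - d, d - cs$d_max, 0)
}

# one pass of pairwise projection over bounds, in the given order
project_bounds <- function(xyz, cs, order, tol) {
  for (b in order) {
    i <- cs$i[b]; j <- cs$j[b]
    v <- xyz[j, ] - xyz[i, ]
    d <- sqrt(sum(v^2))
    if (d < 1e-12) {
      v <- c(1, 0, 0); d <- 1e-12
    }
    tgt <- if (d < cs$d_min[b]) cs$d_min[b]
           else if (d > cs$d_max[b]) cs$d_max[b] else next
    shift <- (d - tgt) / 2
    u <- v / d
    xyz[i, ] <- xyz[i, ] + shift * u
    xyz[j, ] <- xyz[j, ] - shift * u
  }
  xyz
}

#' Generate a constraint-satisfying conformational ensemble
#'
#' Each trial conformer starts from the reference structure with every Cα
#' displaced uniformly at random within a cube of side `displacement_limit`,
#' then is corrected by iterative pairwise projection onto violated bounds
#' (processed in seeded random order each sweep) until all bounds are
#' satisfied within `tol` or `max_iter` sweeps are exhausted. Unconverged
#' trials are rejected; the process repeats until `m` conformers are
#' accepted. Accepted conformers are superposed back onto the reference.
#'
#' @param s reference `fold_structure`.
#' @param cs a `fold_constraints` set from [build_constraints()].
#' @param m number of conformers to accept.
#' @param displacement_limit side of the per-move displacement cube (nm).
#' @param max_iter maximum correction sweeps per trial.
#' @param seed integer seed.
#' @param tol bound-satisfaction tolerance in nm.
#' @return A `fold_ensemble`: list with `topology`, `coords`
#'   (m x N x 3 array, nm), `seed`, `accepted`, `rejected`.
#' @export
generate_ensemble <- function(s, cs, m, displacement_limit = 0.2,
                              max_iter = 500L, seed = 1L, tol = 1e-4) {
  stopifnot(m >= 1, max_iter >= 1)
  n <- n_residues(s)
  coords <- array(NA_real_, c(m, n, 3))
  acc <- 0L; rej <- 0L
  with_local_seed(seed, {
    while (acc < m) {
      xyz <- s$xyz + matrix(runif(3 * n, -displacement_limit / 2,
                                  displacement_limit / 2), n, 3)
      ok <- FALSE
      for (it in seq_len(max_iter)) {
        viol <- which(bound_violation(xyz, cs) > tol)
        if (length(viol) == 0) { ok <- TRUE; break }
        xyz <- project_bounds(xyz, cs, sample(viol), tol)
      }
      if (ok) {
        acc <- acc + 1L
        coords[acc, , ] <- kabsch(xyz, s$xyz)$fitted
      } else {
        rej <- rej + 1L
      }
      if (acc + rej >= 200L && acc / (acc + rej) < 0.01)
        stop("infeasible constraints: acceptance rate < 1%")
    }
  })
  new_ensemble(s, coords, seed = seed, rejected = rej,
               params = list(displacement_limit = displacement_limit,
                             max_iter = max_iter, tol = tol))
}

#' Construct an ensemble object from a coordinate array
#'
#' @param topology reference `fold_structure`.
#' @param coords m x N x 3 array of Cα coordinates (nm).
#' @param seed seed recorded as provenance.
#' @param rejected rejected-trial count.
#' @param params generation parameter list.
#' @return A `fold_ensemble` object.
#' @export
new_ensemble <- function(topology, coords, seed = NA_integer_,
                         rejected = 0L, params = list()) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[2] == n_residues(topology),
            dim(coords)[3] == 3)
  structure(list(topology = topology, coords = coords,
                 seed = seed, accepted = dim(coords)[1],
                 rejected = rejected, params = params),
            class = "fold_ensemble")
}

#' @export
print.fold_ensemble <- function(x, ...) {
  cat(sprintf("<fold_ensemble> %d conformers x %d residues (seed %s, %d rejected)\n",
              x$accepted, dim(x$coords)[2], format(x$seed), x$rejected))
  invisible(x)
}

n_conformers <- function(e) dim(e$coords)[1]

# m x 3N matrix with per-residue coordinate triples contiguous
ensemble_matrix <- function(e) {
  m <- dim(e$coords)[1]
  n <- dim(e$coords)[2]
  out <- matrix(0, m, 3 * n)
  for (k in 1:3) out[, seq(k, 3 * n, by = 3)] <- e$coords[, , k]
  out
}

matrix_to_coords <- function(x, n) {
  m <- nrow(x)
  co <- array(0, c(m, n, 3))
  for (k in 1:3) co[, , k] <- x[, seq(k, 3 * n, by = 3), drop = FALSE]
  co
}

# superpose every conformer onto reference coordinates; returns ensemble
superpose_ensemble <- function(e, ref_xyz = e$topology$xyz) {
  for (mi in seq_len(dim(e$coords)[1]))
    e$coords[mi, , ] <- kabsch(e$coords[mi, , ], ref_xyz)$fitted
  e
}

#' Per-residue flexibility (rmsf) profile of an ensemble
#'
#' Root-mean-square fluctuation of each Cα over conformers after best-fit
#' rigid superposition of every conformer onto the reference — either the
#' reference ("crystal") structure of the ensemble topology or the
#' ensemble mean.
#'
#' @param e a `fold_ensemble`.
#' @param reference `"crystal"` (deviations from the topology structure) or
#'   `"mean"` (deviations from the post-fit ensemble mean).
#' @return tibble of class `fold_flexprofile`: `chain`, `resno`, `aa`,
#'   `rmsf_nm`.
#' @export
ens_rmsf <- function(e, reference = c("crystal", "mean")) {
  reference <- match.arg(reference)
  if (n_conformers(e) < 2) stop("need at least 2 conformers")
  e <- superpose_ensemble(e)
  ref <- if (reference == "crystal") e$topology$xyz
         else apply(e$coords, c(2, 3), mean)
  dev2 <- sweep(e$coords, c(2, 3), ref)^2
  r <- sqrt(apply(dev2, 2, mean) * 3)  # mean over (conformer, axis) * 3
  out <- tibble::tibble(chain = e$topology$residues$chain,
                        resno = e$topology$residues$resno,
                        aa = e$topology$residues$aa,
                        rmsf_nm = r)
  class(out) <- c("fold_flexprofile", class(out))
  attr(out, "reference") <- reference
  out
}

#' Write an ensemble as a plain-text coordinate matrix with a JSON sidecar
#'
#' The matrix has one conformer per row (x,y,z triples per residue, nm);
#' the sidecar records seed, accepted/rejected counts, parameters and the
#' residue table.
#'
#' @param e a `fold_ensemble`.
#' @param basename output path prefix; writes `<basename>.tsv` and
#'   `<basename>.json`.
#' @return basename, invisibly.
#' @export
write_ensemble <- function(e, basename) {
  utils::write.table(ensemble_matrix(e), paste0(basename, ".tsv"),
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  meta <- list(seed = e$seed, accepted = e$accepted, rejected = e$rejected,
               params = e$params, id = e$topology$id,
               residues = as.data.frame(e$topology$residues))
  jsonlite::write_json(meta, paste0(basename, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(basename)
}

#' Read an ensemble written by [write_ensemble()]
#'
#' @param basename path prefix used at write time.
#' @return A `fold_ensemble`.
#' @export
read_ensemble <- function(basename) {
  meta <- jsonlite::read_json(paste0(basename, ".json"),
                              simplifyVector = TRUE)
  x <- as.matrix(utils::read.table(paste0(basename, ".tsv"), sep = "\t"))
  n <- nrow(meta$residues)
  res <- tibble::as_tibble(meta$residues)
  res$ins <- as.character(res$ins %||% rep("", n))
  res$ins[is.na(res$ins)] <- ""
  co <- matrix_to_coords(unname(x), n)
  topo <- new_structure(res, co[1, , ], id = meta$id)
  new_ensemble(topo, co, seed = meta$seed,
               rejected = meta$rejected %||% 0L,
               params = meta$params %||% list())
}
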