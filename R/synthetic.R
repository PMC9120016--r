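# Seeded synthetic-data generators with planted ground truth for every
# input class: idealized multi-chain Cα structures, ensembles with a
# planted mode spectrum and planted fragment couplings, MSAs evolved
# along a known tree with planted covarying columns, and annotated
# coalescent trees with planted clade label compositions.

# ideal helix Cα trace: radius 0.23 nm, 100 deg/residue, 0.15 nm rise
helix_coords <- function(n, origin = c(0, 0, 0)) {
  i <- seq_len(n) - 1
  cbind(0.23 * cos(i * 100 * pi / 180) + origin[1],
        0.23 * sin(i * 100 * pi / 180) + origin[2],
        0.15 * i + origin[3])
}

#' Synthetic idealized multi-chain structure
#'
#' Ideal helical Cα chains arranged as a monomer, a dimer or a 2 x 2
#' "tetramer" with designated vertical and lateral interfaces. The
#' ground-truth attribute records the interface chain-role map and the
#' interface contact pairs present by construction.
#'
#' @param n_res residues per chain (>= 8).
#' @param layout `"monomer"`, `"dimer"` or `"tetramer"`.
#' @param spacing inter-chain axis spacing in nm (default 0.95).
#' @return A `fold_structure` with a `groundtruth` attribute
#'   (`interface_roles`, `interface_pairs`).
#' @export
synth_structure <- function(n_res = 12L, layout = c("monomer", "dimer",
                                                    "tetramer"),
                            spacing = 0.95) {
  layout <- match.arg(layout)
  stopifnot(n_res >= 8)
  offsets <- switch(layout,
    monomer = list(A = c(0, 0, 0)),
    dimer = list(A = c(0, 0, 0), C = c(spacing, 0, 0)),
    tetramer = list(A = c(0, 0, 0), C = c(spacing, 0, 0),
                    I = c(0, spacing, 0), G = c(spacing, spacing, 0)))
  roles <- switch(layout,
    monomer = character(0),
    dimer = c("A:C" = "vert_dim"),
    tetramer = c("A:C" = "vert_dim", "G:I" = "vert_dim",
                 "A:I" = "lat_dim", "C:G" = "lat_dim"))
  xyz <- do.call(rbind, lapply(offsets, function(o) helix_coords(n_res, o)))
  chains <- rep(names(offsets), each = n_res)
  res <- tibble::tibble(chain = chains,
                        resno = rep(seq_len(n_res), length(offsets)),
                        ins = "",
                        aa = rep_len(c("A", "L", "V", "I", "F", "S", "K",
                                       "E", "G", "T"), n_res *
                                       length(offsets)))
  s <- new_structure(res, xyz, id = paste0("synth-", layout))
  if (length(offsets) > 1) {
    d <- as.matrix(stats::dist(xyz))
    inter <- outer(chains, chains, `!=`)
    mind <- min(d[inter])
    if (mind < 0.35)
      stop(sprintf("infeasible layout: inter-chain clash (%.2f nm)", mind))
  }
  cm <- contacts(s, cutoff = 0.8, min_seq_sep = 3L,
                 interface_roles = roles)
  attr(s, "groundtruth") <- list(
    interface_roles = roles,
    interface_pairs = cm[cm$interface_class %in%
                         c("vert_dim", "lat_dim"), , drop = FALSE])
  s
}

# orthonormal basis of the 6 rigid-body modes (translations + rotations)
rigid_modes <- function(xyz) {
  n <- nrow(xyz)
  ctr <- sweep(xyz, 2, colMeans(xyz))
  modes <- matrix(0, 3 * n, 6)
  for (k in 1:3) modes[seq(k, 3 * n, by = 3), k] <- 1
  axes <- diag(3)
  for (k in 1:3) {
    rot <- t(apply(ctr, 1, function(p) crossprod_vec(axes[k, ], p)))
    modes[, 3 + k] <- as.numeric(t(rot))
  }
  qr.Q(qr(modes))
}

#' Synthetic ensemble with a planted mode spectrum and planted couplings
#'
#' Conformers are the reference plus Gaussian amplitudes along planted
#' orthonormal internal modes (random directions with rigid-body motion
#' projected out) carrying the requested variance fractions, plus an
#' isotropic residual spread over the orthogonal complement. Optionally,
#' designated 4-residue windows deform between two discrete states in
#' lockstep, with a copy-noise probability of the second window
#' disobeying the first — planting a fragment coupling recoverable as the
#' top nMI edge.
#'
#' @param s reference `fold_structure`.
#' @param spectrum variance fractions of the planted modes (sum <= 1).
#' @param m number of conformers (>= 2).
#' @param seed integer seed.
#' @param coupled_windows optional list of length-2 integer vectors: the
#'   start residues of window pairs to couple.
#' @param noise copy-noise probability for coupled windows (default 0).
#' @param scale per-coordinate baseline sd in nm (default 0.05).
#' @param jump deformation amplitude of coupled windows in nm
#'   (default 0.2).
#' @return A `fold_ensemble` with a `groundtruth` element
#'   (spectrum, modes, coupled windows, latent states, seed).
#' @export
synth_ensemble <- function(s, spectrum = c(0.46, 0.14, 0.10), m = 1000L,
                           seed = 1L, coupled_windows = NULL, noise = 0,
                           scale = 0.05, jump = 0.2) {
  stopifnot(sum(spectrum) <= 1 + 1e-12, m >= 2)
  n <- n_residues(s)
  d3 <- 3 * n
  k <- length(spectrum)
  vtot <- d3 * scale^2
  out <- with_local_seed(seed, {
    rb <- rigid_modes(s$xyz)
    raw <- matrix(rnorm(d3 * k), d3, k)
    raw <- raw - rb %*% crossprod(rb, raw)
    q <- qr.Q(qr(raw))
    amps <- matrix(rnorm(m * k), m, k) %*%
      diag(sqrt(spectrum * vtot), k, k)
    resid_var <- (1 - sum(spectrum)) * vtot / max(d3 - k - 6, 1)
    g <- matrix(rnorm(m * d3, sd = sqrt(resid_var)), m, d3)
    g <- g - (g %*% q) %*% t(q)
    g <- g - (g %*% rb) %*% t(rb)
    ref_flat <- as.numeric(t(s$xyz))  # x1 y1 z1 x2 ... order
    x <- sweep(amps %*% t(q) + g, 2, ref_flat, `+`)
    z1 <- z2 <- NULL
    if (!is.null(coupled_windows)) {
      z1 <- stats::rbinom(m, 1, 0.5)
      z2 <- lapply(coupled_windows, function(w)
        as.integer(xor(z1, stats::rbinom(m, 1, noise))))
      for (wi in seq_along(coupled_windows)) {
        w <- coupled_windows[[wi]]
        # coherent zig-zag kink: alternating displacement of the 4
        # residues along a random direction, strong enough to move the
        # window between two distinct fragment letters
        defs <- lapply(1:2, function(q2) {
          v <- unit(rnorm(3))
          outer(c(1, -1, 1, -1), v) * jump
        })
        st <- list(z1, z2[[wi]])
        for (side in 1:2) {
          cols <- as.numeric(t(cbind((w[side] + 0:3 - 1) * 3 + 1,
                                     (w[side] + 0:3 - 1) * 3 + 2,
                                     (w[side] + 0:3 - 1) * 3 + 3)))
          add <- as.numeric(t(defs[[side]]))
          # states sit at +def and -def so they are 2*jump apart
          x[, cols] <- x[, cols] + outer(2 * st[[side]] - 1, add)
        }
      }
    }
    list(x = x, z1 = z1, z2 = z2)
  })
  e <- new_ensemble(s, matrix_to_coords(out$x, n), seed = seed,
                    params = list(spectrum = spectrum, scale = scale,
                                  noise = noise))
  e$groundtruth <- list(spectrum = spectrum, scale = scale,
                        coupled_windows = coupled_windows, noise = noise,
                        latent = out$z1, latent_copies = out$z2,
                        seed = seed)
  e
}

#' Synthetic annotated random tree with planted clade composition
#'
#' Without a clade plan, a random tree with `n_tips` tips: a Kingman
#' coalescent (`model = "coalescent"`, default — deep clade structure,
#' suited to clade-composition studies) or a Yule pure-birth tree
#' (`model = "yule"`, balanced diversified sampling emulating clustered
#' homolog sets, root-to-tip depth scaled to `depth`). With a plan, one
#' coalescent subtree per clade is generated and the clades are joined
#' on a pectinate backbone, so each planted clade is a genuine internal
#' node; tips carry thermoregulation (`H`/`P`) and isoform labels per
#' plan.
#'
#' @param n_tips tip count when no plan is given (>= 4).
#' @param clades optional list of plans: each a list with `n_h`, `n_p`,
#'   optionally `n_u` (unknown) and `isoform`.
#' @param seed integer seed.
#' @param model tree model when no plan is given.
#' @param depth root-to-tip depth the Yule tree is scaled to (expected
#'   substitutions per site at unit rate).
#' @return list: `tree` (`phylo`), `labels` tibble (`tip`, `isoform`,
#'   `thermo`, `clade`), `clade_nodes` (named internal node numbers, plan
#'   case only).
#' @export
synth_tree <- function(n_tips = 16L, clades = NULL, seed = 1L,
                       model = c("coalescent", "yule"), depth = 1.5) {
  model <- match.arg(model)
  with_local_seed(seed, {
    if (is.null(clades)) {
      stopifnot(n_tips >= 4)
      tr <- if (model == "coalescent") {
        ape::rcoal(n_tips, tip.label = paste0("t", seq_len(n_tips)))
      } else {
        ty <- ape::rphylo(n_tips, birth = 1, death = 0)
        ty$tip.label <- paste0("t", seq_len(n_tips))
        ty$edge.length <- ty$edge.length /
          max(ape::node.depth.edgelength(ty)) * depth
        ty
      }
      labels <- tibble::tibble(tip = tr$tip.label, isoform = "none",
                               thermo = "unknown", clade = NA_integer_)
      return(list(tree = tr, labels = labels, clade_nodes = NULL))
    }
    subs <- character(length(clades))
    labels <- list()
    for (k in seq_along(clades)) {
      pl <- clades[[k]]
      nh <- pl$n_h %||% 0L; np <- pl$n_p %||% 0L; nu <- pl$n_u %||% 0L
      sz <- nh + np + nu
      if (sz < 2) stop("infeasible plan: clade ", k, " needs >= 2 tips")
      tips <- sprintf("c%d_t%d", k, seq_len(sz))
      sub <- ape::rcoal(sz, tip.label = tips)
      sub$edge.length <- sub$edge.length / max(
        ape::node.depth.edgelength(sub)) * 0.1
      subs[k] <- sub("(;$)", "", ape::write.tree(sub))
      labels[[k]] <- tibble::tibble(
        tip = tips,
        isoform = pl$isoform %||% "none",
        thermo = sample(c(rep("H", nh), rep("P", np), rep("unknown", nu))),
        clade = k)
    }
    nw <- subs[1]
    if (length(subs) > 1) {
      for (k in 2:length(subs))
        nw <- sprintf("(%s:0.2,%s:0.2)", nw, subs[k])
    }
    tr <- ape::read.tree(text = paste0(nw, ";"))
    labels <- dplyr::bind_rows(labels)
    clade_nodes <- vapply(seq_along(clades), function(k) {
      tl <- labels$tip[labels$clade == k]
      if (length(tl) == 1) match(tl, tr$tip.label)
      else ape::getMRCA(tr, tl)
    }, 0L)
    names(clade_nodes) <- paste0("clade", seq_along(clades))
    list(tree = tr, labels = labels, clade_nodes = clade_nodes)
  })
}

#' Synthetic MSA evolved along a tree with planted covarying columns
#'
#' Sequences evolve tip-ward from a uniform-random root by per-site
#' Markov substitution (uniform exchange among the 20 amino acids;
#' substitution probability `1 - exp(-rate * branch length)` per site per
#' edge). Planted column pairs are then made compensatory: with
#' probability `strength` per sequence, the second column is replaced by
#' a fixed seeded permutation mapping of the first.
#'
#' @param tree a `phylo` whose tips name the sequences.
#' @param L alignment length (>= 20).
#' @param rate substitutions per site per unit branch length (default 1).
#' @param coupled_cols optional list of length-2 integer column pairs.
#' @param strength compensatory coupling probability (default 0.9).
#' @param seed integer seed.
#' @return A `fold_msa` with a `groundtruth` attribute (`coupled_cols`,
#'   `strength`, `rate`, `map`, `seed`).
#' @export
synth_msa <- function(tree, L = 60L, rate = 1, coupled_cols = NULL,
                      strength = 0.9, seed = 1L) {
  stopifnot(L >= 20)
  if (rate == 0 && !is.null(coupled_cols))
    stop("zero substitution rate cannot produce covariation")
  nt <- ape::Ntip(tree)
  with_local_seed(seed, {
    tr <- ape::reorder.phylo(tree, "cladewise")
    states <- matrix(NA_integer_, nt + tr$Nnode, L)
    states[nt + 1L, ] <- sample.int(20, L, replace = TRUE)
    for (ed in seq_len(nrow(tr$edge))) {
      par <- tr$edge[ed, 1]; chd <- tr$edge[ed, 2]
      p <- 1 - exp(-rate * tr$edge.length[ed])
      mut <- runif(L) < p
      row <- states[par, ]
      row[mut] <- sample.int(20, sum(mut), replace = TRUE)
      states[chd, ] <- row
    }
    sigma <- sample.int(20)
    if (!is.null(coupled_cols)) {
      for (cp in coupled_cols) {
        copy <- runif(nt) < strength
        states[seq_len(nt), cp[2]][copy] <-
          sigma[states[seq_len(nt), cp[1]][copy]]
      }
    }
    mat <- matrix(AA1[states[seq_len(nt), ]], nt, L)
    msa <- new_msa(mat, ids = tr$tip.label)
    attr(msa, "groundtruth") <- list(coupled_cols = coupled_cols,
                                     strength = strength, rate = rate,
                                     map = sigma, seed = seed)
    msa
  })
}
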