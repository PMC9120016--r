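# Build a small overlay fixture: residues 1..n, chosen dynamic and
# coevolved residue edges, and a contact map wiring two interfaces.
fixture_contacts <- function(pairs, classes) {
  cm <- tibble::tibble(
    chain_a = "A", resno_a = pairs[, 1], aa_a = "A",
    chain_b = "A", resno_b = pairs[, 2], aa_b = "A",
    i = as.integer(pairs[, 1]), j = as.integer(pairs[, 2]),
    dist_nm = 0.5, interface_class = classes)
  class(cm) <- c("fold_contacts", class(cm))
  cm
}

fixture_coevolution <- function(pairs, L = 40) {
  s_s <- rep(2, nrow(pairs))
  structure(list(pairs = tibble::tibble(i = as.integer(pairs[, 1]),
                                        j = as.integer(pairs[, 2]),
                                        s_r = s_s, s_s = s_s,
                                        tier = "top"),
                 threshold = 10, excluded_columns = integer(),
                 top_tier = 1.4, mapped_tier = 0.5, n_seq = 100, L = L),
            class = "fold_coevolution")
}

test_that("overlay tags edge sources and attaches contact annotations", {
  net <- fake_network(5, tibble::tibble(i = 1L, j = 5L, nmi = 0.3))
  # dynamic windows 1 (res 1-4) and 5 (res 5-8); coevolved pair (2, 6)
  # overlaps the dynamic projection; pair (20, 30) is coevolved-only
  coev <- fixture_coevolution(rbind(c(2, 6), c(20, 30)))
  cmap <- fixture_contacts(rbind(c(2, 6), c(20, 30)),
                           c("vert_dim", "lat_dim"))
  fr <- frustration(cmap, default_energy_model(), exhaustive = TRUE)
  ov <- overlay_layers(net, coev, fr, cmap, n_residues = 40)
  e26 <- ov$edges[ov$edges$i == 2 & ov$edges$j == 6, ]
  expect_equal(e26$source, "both")
  expect_equal(e26$interface_class, "vert_dim")
  expect_false(is.na(e26$frustration_class))
  e2030 <- ov$edges[ov$edges$i == 20 & ov$edges$j == 30, ]
  expect_equal(e2030$source, "coevolved")
  # disjoint layers produce no "both" tags
  coev2 <- fixture_coevolution(rbind(c(20, 30)))
  ov2 <- overlay_layers(net, coev2, NULL, NULL, n_residues = 40)
  expect_false(any(ov2$edges$source == "both"))
  # identical layers are all "both"
  netless <- fake_network(5, tibble::tibble(i = integer(), j = integer(),
                                            nmi = numeric()))
  ov3 <- overlay_layers(netless, coev2, NULL, NULL, n_residues = 40)
  expect_true(all(ov3$edges$source == "coevolved"))
})

test_that("overlay rejects out-of-range residue numbering with offenders listed", {
  net <- fake_network(3, tibble::tibble(i = 1L, j = 3L, nmi = 0.3))
  coev <- fixture_coevolution(rbind(c(2, 35)))
  expect_error(overlay_layers(net, coev, n_residues = 10), "35")
})

test_that("two planted interface-wired communities give sectors V and L", {
  # community 1: residues 1-6 coevolving, wired to a vert_dim contact;
  # community 2: residues 21-26, wired to lat_dim contacts
  com1 <- t(utils::combn(1:6, 2))
  com2 <- t(utils::combn(21:26, 2))
  coev <- fixture_coevolution(rbind(com1, com2))
  cmap <- fixture_contacts(rbind(c(1, 30), c(21, 35), c(22, 36)),
                           c("vert_dim", "lat_dim", "lat_dim"))
  net <- fake_network(2, tibble::tibble(i = integer(), j = integer(),
                                        nmi = numeric()))
  ov <- overlay_layers(net, coev, NULL, cmap, n_residues = 40)
  ps <- partition_sectors(ov, cmap)
  expect_equal(nrow(ps$sectors), 2)
  expect_setequal(ps$sectors$interface, c("vert_dim", "lat_dim"))
  expect_setequal(ps$membership$residue[ps$membership$sector ==
    ps$sectors$sector[ps$sectors$interface == "vert_dim"]], 1:6)
  expect_setequal(ps$membership$residue[ps$membership$sector ==
    ps$sectors$sector[ps$sectors$interface == "lat_dim"]], 21:26)
})

test_that("interface ties break to mixed and empty coevolution gives no sectors", {
  com <- t(utils::combn(1:4, 2))
  coev <- fixture_coevolution(com)
  cmap <- fixture_contacts(rbind(c(1, 30), c(2, 35)),
                           c("vert_dim", "lat_dim"))
  net <- fake_network(2, tibble::tibble(i = integer(), j = integer(),
                                        nmi = numeric()))
  ov <- overlay_layers(net, coev, NULL, cmap, n_residues = 40)
  ps <- partition_sectors(ov, cmap)
  expect_equal(ps$sectors$interface, "mixed")
  # a community touching no interface is unassigned
  cmap2 <- fixture_contacts(rbind(c(30, 35)), "intra")
  ov2 <- overlay_layers(net, coev, NULL, cmap2, n_residues = 40)
  ps2 <- partition_sectors(ov2, cmap2)
  expect_equal(ps2$sectors$interface, "unassigned")
  # empty coevolved set: empty partition
  coev0 <- fixture_coevolution(matrix(numeric(0), 0, 2))
  ov0 <- overlay_layers(net, coev0, NULL, cmap, n_residues = 40)
  ps0 <- partition_sectors(ov0, cmap)
  expect_equal(nrow(ps0$sectors), 0)
})

test_that("partition is deterministic and edge-order invariant", {
  com1 <- t(utils::combn(1:5, 2))
  com2 <- t(utils::combn(11:15, 2))
  cmap <- fixture_contacts(rbind(c(1, 30), c(11, 35)),
                           c("vert_dim", "lat_dim"))
  net <- fake_network(2, tibble::tibble(i = integer(), j = integer(),
                                        nmi = numeric()))
  all_pairs <- rbind(com1, com2)
  ov_a <- overlay_layers(net, fixture_coevolution(all_pairs), NULL, cmap,
                         n_residues = 40)
  perm <- with_seed(2, sample(nrow(all_pairs)))
  ov_b <- overlay_layers(net, fixture_coevolution(all_pairs[perm, ]),
                         NULL, cmap, n_residues = 40)
  expect_equal(partition_sectors(ov_a, cmap)$membership,
               partition_sectors(ov_b, cmap)$membership)
})

test_that("planted two-community graphs are recovered with Rand index >= 0.9", {
  rand_index <- function(a, b) {
    n <- length(a)
    same_a <- outer(a, a, `==`)[upper.tri(diag(n))]
    same_b <- outer(b, b, `==`)[upper.tri(diag(n))]
    mean(same_a == same_b)
  }
  scores <- vapply(1:20, function(sd) {
    set.seed(sd)
    n1 <- sample(8:20, 1); n2 <- sample(8:20, 1)
    res1 <- 1:n1; res2 <- (n1 + 1):(n1 + n2)
    within1 <- t(utils::combn(res1, 2))
    within2 <- t(utils::combn(res2, 2))
    # a spanning path keeps each planted community connected; random
    # extra edges densify it
    path1 <- cbind(res1[-n1], res1[-1])
    path2 <- cbind(res2[-n2], res2[-1])
    keep1 <- rbind(path1, within1[runif(nrow(within1)) < 0.4, ,
                                  drop = FALSE])
    keep2 <- rbind(path2, within2[runif(nrow(within2)) < 0.4, ,
                                  drop = FALSE])
    # up to 10% cross-community edges
    cross <- cbind(sample(res1, 2, TRUE), sample(res2, 2, TRUE))
    pairs <- rbind(keep1, keep2)
    n_cross <- min(nrow(cross), floor(0.1 * nrow(pairs)))
    pairs <- rbind(pairs, cross[seq_len(n_cross), , drop = FALSE])
    cmap <- fixture_contacts(rbind(c(res1[1], 60), c(res2[1], 65)),
                             c("vert_dim", "lat_dim"))
    net <- fake_network(2, tibble::tibble(i = integer(), j = integer(),
                                          nmi = numeric()))
    ov <- overlay_layers(net, fixture_coevolution(pairs), NULL, cmap,
                         n_residues = 70)
    ps <- partition_sectors(ov, cmap)
    memb <- ps$membership
    truth <- ifelse(memb$residue <= n1, 1L, 2L)
    rand_index(memb$sector, truth)
  }, 0)
  expect_gte(min(scores), 0.9)
})

test_that("sector frustration composition is consistent with the energetics module", {
  com1 <- t(utils::combn(1:6, 2))
  coev <- fixture_coevolution(com1)
  cmap <- fixture_contacts(rbind(c(1, 30), c(2, 4), c(3, 5)),
                           c("vert_dim", "intra", "intra"))
  fr <- frustration(cmap, default_energy_model(), exhaustive = TRUE)
  net <- fake_network(2, tibble::tibble(i = integer(), j = integer(),
                                        nmi = numeric()))
  ov <- overlay_layers(net, coev, fr, cmap, n_residues = 40)
  ps <- partition_sectors(ov, cmap)
  res <- ps$membership$residue
  in_sector <- fr$i %in% res & fr$j %in% res
  expect_equal(ps$sectors$n_relaxed, sum(fr$class[in_sector] == "relaxed"))
  expect_equal(ps$sectors$n_stressed,
               sum(fr$class[in_sector] == "stressed"))
})
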