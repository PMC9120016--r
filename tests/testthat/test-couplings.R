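test_that("encoding is deterministic, nearest-prototype and chain-aware", {
  s <- synth_structure(10, "dimer")
  coords <- array(rep(s$xyz, each = 5), c(5, 20, 3))
  e <- new_ensemble(s, coords)
  st <- encode_ensemble(e)
  # identical conformers encode to identical rows
  expect_true(all(apply(st$letters, 2, function(x) length(unique(x))) == 1))
  # F = N - 3 per chain, no cross-chain windows
  expect_equal(ncol(st$letters), 2 * (10 - 3))
  expect_true(all(st$window_map$chain[1:7] == "A"))

  # a fragment placed exactly at a prototype geometry encodes to it
  ab <- default_alphabet()
  expect_equal(ab$K, 25)
  expect_error(new_alphabet(ab$prototypes[c(1, 1, 2), ]), "distinct")
})

test_that("nmi matches the brute-force joint-count oracle exactly", {
  set.seed(42)
  for (rep in 1:20) {
    m <- sample(20:200, 1)
    k <- sample(2:5, 1)
    mat <- cbind(sample.int(k, m, replace = TRUE),
                 sample.int(k, m, replace = TRUE),
                 sample.int(k, m, replace = TRUE))
    s <- strings_from_matrix(mat)
    got <- string_nmi(s, 1, 2)
    want <- oracle_nmi(mat[, 1], mat[, 2])
    expect_equal(got$nmi, want$nmi, tolerance = 1e-12)
    expect_equal(got$mi, want$mi, tolerance = 1e-12)
    expect_equal(got$h_joint, want$h_joint, tolerance = 1e-12)
    expect_equal(got$epsilon, want$epsilon, tolerance = 1e-12)
  }
})

test_that("nmi closed forms: perfect copy, independence, constants", {
  # two equi-probable letters, identical columns: I = H = ln 2
  ci <- rep(c(1L, 2L), 500)
  s <- strings_from_matrix(cbind(ci, ci))
  got <- string_nmi(s, 1, 2)
  eps <- (2 - 1) * (2 - 1) / (2 * 1000)
  expect_equal(got$mi, log(2), tolerance = 1e-12)
  expect_equal(got$h_joint, log(2), tolerance = 1e-12)
  expect_equal(got$nmi, (log(2) - eps) / log(2), tolerance = 1e-12)

  # independent uniform 4-letter columns: nMI near zero
  set.seed(7)
  a <- sample.int(4, 10000, replace = TRUE)
  b <- sample.int(4, 10000, replace = TRUE)
  expect_lt(string_nmi(strings_from_matrix(cbind(a, b)), 1, 2)$nmi, 0.02)

  # both columns constant: defined as zero
  expect_equal(string_nmi(strings_from_matrix(cbind(rep(1L, 50),
                                                    rep(1L, 50))),
                          1, 2)$nmi, 0)
})

test_that("nmi is invariant under letter relabeling within a column", {
  set.seed(3)
  a <- sample.int(5, 300, replace = TRUE)
  b <- as.integer((a + sample.int(2, 300, replace = TRUE)) %% 5 + 1)
  base <- string_nmi(strings_from_matrix(cbind(a, b)), 1, 2)$nmi
  perm <- sample.int(5)
  expect_equal(string_nmi(strings_from_matrix(cbind(perm[a], b)), 1, 2)$nmi,
               base, tolerance = 1e-12)
})

test_that("planted copy coupling ranks top and nMI decreases with copy noise", {
  set.seed(11)
  m <- 600
  base <- sapply(1:10, function(k) sample.int(4, m, replace = TRUE))
  noise_grid <- c(0, 0.1, 0.25, 0.4)
  vals <- sapply(noise_grid, function(p) {
    mat <- base
    flip <- runif(m) < p
    mat[, 8] <- ifelse(flip, sample.int(4, m, replace = TRUE), mat[, 2])
    string_nmi(strings_from_matrix(mat), 2, 8)$nmi
  })
  expect_true(all(diff(vals) < 0))
  # at 10% noise the planted pair is the unique top edge
  mat <- base
  flip <- runif(m) < 0.1
  mat[, 8] <- ifelse(flip, sample.int(4, m, replace = TRUE), mat[, 2])
  net <- coupling_network(strings_from_matrix(mat), nmi_threshold = 0.15,
                          min_sep = 4)
  top <- net$edges[which.max(net$edges$nmi), ]
  expect_equal(c(top$i, top$j), c(2L, 8L))
})

test_that("network construction applies nMI, separation and 2s filters", {
  # all-constant alignment: no edges
  mat <- matrix(1L, 100, 8)
  net0 <- coupling_network(strings_from_matrix(mat))
  expect_equal(nrow(net0$edges), 0)
  # same-chain separation: pairs with start separation <= min_sep absent
  set.seed(5)
  mat <- sapply(1:12, function(k) sample.int(3, 200, replace = TRUE))
  net <- coupling_network(strings_from_matrix(mat), nmi_threshold = -1,
                          min_sep = 4, significance = FALSE)
  expect_true(all(abs(net$edges$j - net$edges$i) > 4))
  # the 2s filter removes weak edges that pass a permissive threshold
  net2s <- coupling_network(strings_from_matrix(mat), nmi_threshold = -1,
                            min_sep = 4, significance = TRUE)
  expect_true(all(net2s$edges$nmi > net2s$significance_cut))
  expect_lte(nrow(net2s$edges), nrow(net$edges))
})

test_that("geometric round trip: planted window coupling is recovered", {
  s <- synth_structure(16, "dimer")
  e <- synth_ensemble(s, spectrum = c(0.3), m = 400, seed = 4,
                      coupled_windows = list(c(2L, 9L)), noise = 0.05)
  st <- encode_ensemble(e)
  net <- coupling_network(st)
  expect_gt(nrow(net$edges), 0)
  # the top edge involves windows overlapping the planted pair
  top <- net$edges[which.max(net$edges$nmi), ]
  overlaps <- function(f, w) abs(st$window_map$start[f] - w) <= 3
  expect_true(overlaps(top$i, 2) || overlaps(top$i, 9))
  expect_true(overlaps(top$j, 2) || overlaps(top$j, 9))
  # the planted pair itself carries strong coupling
  expect_gt(string_nmi(st, 2, 9)$nmi, net$significance_cut)
})

test_that("centrality matches small closed forms and power iteration", {
  # two nodes, one edge: equal centrality 1/sqrt(2)
  net2 <- fake_network(2, tibble::tibble(i = 1L, j = 2L, nmi = 0.5))
  cen2 <- network_centrality(net2)
  expect_equal(cen2$centrality, rep(1 / sqrt(2), 2), tolerance = 1e-10)

  # 3-node path with equal weights: E(mid)/E(end) = sqrt(2)
  net3 <- fake_network(3, tibble::tibble(i = c(1L, 2L), j = c(2L, 3L),
                                         nmi = 0.4))
  cen3 <- network_centrality(net3)
  expect_equal(cen3$centrality[2] / cen3$centrality[1], sqrt(2),
               tolerance = 1e-10)

  # star graph: hub strictly maximal; power iteration agreement
  edges <- tibble::tibble(i = 1L, j = 2:6, nmi = 0.3)
  net6 <- fake_network(6, edges)
  cen6 <- network_centrality(net6)
  expect_equal(which.max(cen6$centrality), 1)
  a <- matrix(0, 6, 6); a[cbind(edges$i, edges$j)] <- edges$nmi
  a <- a + t(a)
  for (start in 1:3) {
    v <- with_seed(start, abs(rnorm(6)))
    # shifted iteration: the star graph is bipartite, so iterate a + cI
    for (it in 1:500) v <- unitv(as.numeric(a %*% v + 0.5 * v))
    expect_equal(v, cen6$centrality, tolerance = 1e-8)
  }
})

test_that("residue centrality profile averages covering windows", {
  # single window: all four residues share its centrality
  net1 <- fake_network(2, tibble::tibble(i = 1L, j = 2L, nmi = 0.5))
  net1$window_map <- tibble::tibble(fragment = 1:2, chain = "A",
                                    start = c(1L, 8L),
                                    resno_start = c(1L, 8L))
  rp <- residue_centrality(net1)
  expect_equal(rp$centrality[rp$residue %in% 1:4],
               rep(1 / sqrt(2), 4), tolerance = 1e-10)
  # a hub fragment produces a local peak spanning its residues; place
  # the hub at the chain start so its leading residues are covered by
  # the hub window alone
  edges <- tibble::tibble(i = 1L, j = c(6L, 9L), nmi = 0.4)
  neth <- fake_network(10, edges)
  rph <- residue_centrality(neth)
  peak <- rph$residue[which.max(rph$centrality)]
  expect_true(peak %in% 1:4)
})
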