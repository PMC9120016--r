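test_that("sequence distances match closed forms", {
  m <- new_msa(c(a = "AAAAAAAAAA", b = "AAAAAAAAVV", c = "VVVVVAAAAA"))
  d <- seq_distance_matrix(m, "identity")
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], 0.2)
  expect_equal(d["a", "c"], 0.5)
  dk <- seq_distance_matrix(m, "kimura")
  expect_equal(dk["a", "b"], -log(1 - 0.2 - 0.04 / 5), tolerance = 1e-12)
  expect_equal(dk["a", "b"], 0.2333, tolerance = 1e-3)
  # zero-overlap pair errors
  m2 <- new_msa(c(a = "AA--", b = "--VV", c = "AAVV"))
  expect_error(seq_distance_matrix(m2), "zero aligned overlap")
})

test_that("NJ recovers additive trees exactly", {
  # the classic 4-taxon additive case with known branch lengths
  tr0 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  d <- ape::cophenetic.phylo(tr0)
  tr <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  # split AB|CD present
  expect_true(ape::is.monophyletic(ape::root(tr, "C"), c("A", "B")))

  # 50 random additive matrices, 4..12 taxa: path distances reproduced
  for (k in 1:50) {
    ra <- random_additive_matrix(sample(4:12, 1), seed = k)
    tr <- nj_tree(ra$d)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(ra$d), colnames(ra$d)],
                 ra$d, tolerance = 1e-8)
  }
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("tree similarity: self is 1, rescaling invariant, random pairs near 0", {
  st <- synth_tree(n_tips = 15, seed = 4)
  tr <- st$tree
  expect_equal(tree_similarity(tr, tr)$r, 1, tolerance = 1e-12)
  tr2 <- tr
  tr2$edge.length <- tr2$edge.length * 3.7
  expect_equal(tree_similarity(tr, tr2)$r, 1, tolerance = 1e-12)

  # 100 random 20-tip tree pairs: mean r near zero
  rs <- vapply(1:100, function(k) {
    a <- with_seed(1000 + k, ape::rtree(20))
    b <- with_seed(2000 + k, ape::rtree(20))
    tree_similarity(a, b)$r
  }, 0)
  expect_lt(abs(mean(rs)), 0.15)

  # tip order invariance
  rot <- ape::rotateConstr(tr, rev(tr$tip.label))
  st2 <- synth_tree(n_tips = 15, seed = 5)
  expect_equal(tree_similarity(rot, st2$tree)$r,
               tree_similarity(tr, st2$tree)$r, tolerance = 1e-12)
  disjoint <- with_seed(1, ape::rtree(4, tip.label = paste0("x", 1:4)))
  expect_error(tree_similarity(tr, disjoint),
               "fewer than 3 shared tips")
})

test_that("tip diversity matches closed forms and planted orderings", {
  # two tips joined with branches 0.05 each
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
  expect_equal(tip_diversity(tr), 0.1)
  # star tree with equal branches b: every pair at 2b
  star <- ape::read.tree(text = "(a:0.2,b:0.2,c:0.2,d:0.2);")
  expect_equal(tip_diversity(star), 0.4)
  expect_error(tip_diversity(star, c("a", "zz")), "absent")
  # planted divergent clade is more diverse than the background clades
  ts <- synth_tree(clades = list(list(n_h = 4, n_p = 4),
                                 list(n_h = 4, n_p = 4),
                                 list(n_h = 4, n_p = 4)), seed = 6)
  tips1 <- ts$labels$tip[ts$labels$clade == 1]
  tips23 <- ts$labels$tip[ts$labels$clade != 1]
  # cross-clade diversity exceeds within-clade diversity by construction
  expect_gt(tip_diversity(ts$tree, c(tips1, tips23[1:4])),
            tip_diversity(ts$tree, tips1))
})

test_that("greedy clustering follows the identity cutoffs deterministically", {
  expect_equal(max(cluster_sequences(c(a = "AAAA", b = "AAAA"),
                                     0.8)$cluster), 1)
  expect_equal(max(cluster_sequences(c(a = "AAAA", b = "AAVV"),
                                     0.8)$cluster), 2)
  # 5-sequence fixture: greedy longest-first, by hand.
  # order: all length 10. s1 founds c1; s2 (0.9 to s1) joins c1;
  # s3 (0.5 to s1) founds c2; s4 (0.9 to s3) joins c2; s5 distinct.
  seqs <- c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAV", s3 = "AAAAAVVVVV",
            s4 = "AAAAAVVVVL", s5 = "KKKKKKKKKK")
  cl <- cluster_sequences(seqs, 0.8)
  expect_equal(cl$cluster, c(1, 1, 2, 2, 3))
  expect_equal(cl$rep_id, c("s1", "s1", "s3", "s3", "s5"))
  # second pass at 0.5 merges the first two clusters (s1~s3 identity 0.5)
  cl2 <- cluster_sequences(seqs, 0.8, then = 0.5)
  expect_equal(cl2$cluster[1], cl2$cluster[3])
  expect_false(cl2$cluster[1] == cl2$cluster[5])
  # determinism given input order
  expect_identical(cl, cluster_sequences(seqs, 0.8))
})

test_that("node composition computes H:P ratios and the 2s outlier flag", {
  ts <- synth_tree(clades = list(list(n_h = 6, n_p = 3, isoform = "beta"),
                                 list(n_h = 17, n_p = 3,
                                      isoform = "alpha"),
                                 list(n_h = 5, n_p = 5,
                                      isoform = "gamma"),
                                 list(n_h = 4, n_p = 4,
                                      isoform = "delta")),
                   seed = 3)
  nc <- node_composition(ts$tree, ts$labels, clades = ts$clade_nodes)
  expect_equal(nc$hp_ratio[1], 2.0)
  expect_equal(nc$hp_ratio[2], 17 / 3, tolerance = 1e-12)
  # the planted extreme clade (H:P = 5.67 vs background ~1-2) is flagged
  expect_true(nc$flagged[2])
  expect_false(any(nc$flagged[c(1, 3, 4)]))
  # counts sum to clade sizes
  expect_equal(nc$n_h + nc$n_p, nc$n_tips)

  # an all-H clade is infinite and excluded from the reference mean
  ts2 <- synth_tree(clades = list(list(n_h = 4, n_p = 0),
                                  list(n_h = 3, n_p = 3),
                                  list(n_h = 2, n_p = 2),
                                  list(n_h = 3, n_p = 2)), seed = 9)
  nc2 <- node_composition(ts2$tree, ts2$labels, clades = ts2$clade_nodes)
  expect_true(is.infinite(nc2$hp_ratio[1]))
  expect_false(nc2$flagged[1])
  expect_equal(unique(nc2$ref_mean), mean(c(1, 1, 1.5)),
               tolerance = 1e-12)
})
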