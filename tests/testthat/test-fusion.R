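test_that("link overlap matches the defining ratio", {
  net <- as_multiplex(data.frame(layer = c(1, 1, 2, 2),
                                 from = c(1, 2, 1, 1),
                                 to = c(2, 3, 2, 3)))
  # E1 = {(1,2),(2,3)}, E2 = {(1,2),(1,3)} -> 2*1/(2+2)
  expect_equal(link_overlap(net, 1, 2), 0.5)
  expect_equal(link_overlap(net, 1, 2), link_overlap(net, 2, 1))
  expect_equal(link_overlap(net, 1, 1), 1)

  disjoint <- as_multiplex(data.frame(layer = c(1, 2),
                                      from = c(1, 2), to = c(2, 3)))
  expect_equal(link_overlap(disjoint, 1, 2), 0)

  empty <- as_multiplex(data.frame(layer = 1, from = 1, to = 2),
                        layer_names = c("1", "2", "3"))
  expect_error(link_overlap(empty, 2, 3), "empty")
})

test_that("link overlap agrees with the counting oracle on random nets", {
  for (s in 1:20) {
    net <- random_multiplex(10, 2, 0.3, seed = 500 + s)
    expect_equal(link_overlap(net, 1, 2), oracle_link_overlap(net, 1, 2))
  }
})

test_that("adjacency-indicator correlations behave as correlations", {
  ident <- as_multiplex(data.frame(layer = c(1, 1, 2, 2),
                                   from = c(1, 2, 1, 2), to = c(2, 3, 2, 3)))
  expect_equal(layer_correlation(ident, 1, 2, "pearson"), 1)
  expect_equal(layer_correlation(ident, 1, 2, "spearman"), 1)
  # complementary layers on K4's pair set anti-correlate perfectly
  ap <- t(combn(4, 2))
  half <- c(1, 3, 5)
  comp <- as_multiplex(rbind(
    data.frame(layer = 1, from = ap[half, 1], to = ap[half, 2]),
    data.frame(layer = 2, from = ap[-half, 1], to = ap[-half, 2])))
  expect_equal(layer_correlation(comp, 1, 2, "pearson"), -1)
  # matches a direct computation on the 0/1 pair vectors
  net <- random_multiplex(9, 2, 0.4, seed = 9)
  A1 <- layer_adjacency(net, 1); A2 <- layer_adjacency(net, 2)
  expect_equal(layer_correlation(net, 1, 2, "pearson"),
               cor(A1[upper.tri(A1)], A2[upper.tri(A2)]))
})

test_that("relevance matrix is symmetric with unit diagonal", {
  net <- random_multiplex(12, 3, 0.3, seed = 31)
  for (m in c("lo", "pearson", "spearman")) {
    R <- layer_relevance(net, m)
    expect_equal(R, t(R))
    if (m == "lo") expect_equal(diag(R), rep(1, 3), ignore_attr = TRUE)
  }
})

test_that("fusion is the stated linear combination", {
  pairs <- tibble::tibble(i = c(1, 1, 2), j = c(2, 3, 3))
  tgt <- new_score_table(pairs, c(1, 2, 3), "cn")
  o1 <- new_score_table(pairs, c(10, 0, 5), "cn")
  o2 <- new_score_table(pairs, c(4, 4, 4), "cn")

  # eta = 0 reduces to the target table
  f0 <- fuse_scores(tgt, list(o1, o2), c(0.5, 0.25), eta = 0)
  expect_equal(f0$score, tgt$score)

  # mu = 1, eta = 1, identical tables double the score, same ranking
  f1 <- fuse_scores(tgt, list(tgt), 1, eta = 1)
  expect_equal(f1$score, 2 * tgt$score)

  # hand-set three-layer case: S = s1 + 0.5*s2 + 0.25*s3
  f2 <- fuse_scores(tgt, list(o1, o2), c(0.5, 0.25), eta = 1)
  expect_equal(f2$score, c(1, 2, 3) + 0.5 * c(10, 0, 5) + 0.25 * c(4, 4, 4))

  # linearity in each input
  f3 <- fuse_scores(tgt, list(o1, o2), c(0.5, 0.25), eta = 2)
  expect_equal(f3$score - f0$score, 2 * (f2$score - f0$score))
})

test_that("distance tables are negated into similarity orientation", {
  pairs <- tibble::tibble(i = 1, j = 2:3)
  hp_t <- new_score_table(pairs, c(2, 5), "hp", "lower_is_link")
  hp_o <- new_score_table(pairs, c(4, 1), "hp", "lower_is_link")
  f <- fuse_scores(hp_t, list(hp_o), 0.5, eta = 1)
  expect_equal(score_orientation(f), "higher_is_link")
  expect_equal(f$score, -c(2, 5) - 0.5 * c(4, 1))
  # mixing orientations is an error
  cn <- new_score_table(pairs, c(1, 2), "cn")
  expect_error(fuse_scores(cn, list(hp_o), 0.5), "orientation mismatch")
})

test_that("adding a constant to a non-target layer shifts but not reranks", {
  pairs <- all_pairs(5)
  set.seed(8)
  tgt <- new_score_table(pairs, runif(nrow(pairs)), "cn")
  oth <- new_score_table(pairs, runif(nrow(pairs)), "cn")
  oth_shift <- new_score_table(pairs, oth$score + 7, "cn")
  f <- fuse_scores(tgt, list(oth), 0.6)
  fs <- fuse_scores(tgt, list(oth_shift), 0.6)
  expect_equal(order(-fs$score), order(-f$score))
  expect_equal(fs$score - f$score, rep(0.6 * 7, nrow(pairs)))
})
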