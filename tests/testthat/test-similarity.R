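test_that("degree-product and common-neighbor scores match hand cases", {
  star <- as_multiplex(data.frame(layer = 1, from = 1, to = 2:4))
  expect_equal(score_of(score_pa(star), 1, 2), 3)   # center deg 3 x leaf 1
  expect_equal(score_of(score_pa(star), 2, 3), 1)
  path <- as_multiplex(data.frame(layer = 1, from = c(1, 2), to = c(2, 3)))
  expect_equal(score_of(score_cn(path), 1, 3), 1)
  expect_equal(score_of(score_cn(path), 1, 2), 0)   # disjoint neighborhoods
})

test_that("CAR and CJC match hand enumeration on K4", {
  k4 <- as_multiplex(data.frame(layer = 1, from = t(combn(4, 2))[, 1],
                                to = t(combn(4, 2))[, 2]))
  # pair (1,2): CN = {3,4}, one link among them -> CAR = 2
  expect_equal(score_of(score_car(k4), 1, 2), 2)
  # |union of neighborhoods| = |{2,3,4} u {1,3,4}| = 4 -> CJC = 0.5
  expect_equal(score_of(score_cjc(k4), 1, 2), 0.5)
  # a pair with fewer than 2 common neighbors scores CAR = 0
  path <- as_multiplex(data.frame(layer = 1, from = c(1, 2), to = c(2, 3)))
  expect_equal(score_of(score_car(path), 1, 3), 0)
  # two isolated nodes: empty union scores 0, not an error
  iso <- as_multiplex(data.frame(layer = 1, from = 1, to = 2), nodes = 1:4)
  expect_equal(score_of(score_cjc(iso), 3, 4), 0)
})

test_that("every topological measure equals its brute-force oracle", {
  oracles <- list(pa = oracle_pa, cn = oracle_cn, car = oracle_car,
                  cjc = oracle_cjc)
  for (s in 1:15) {
    net <- random_layer(n = sample(6:15, 1), p = runif(1, 0.15, 0.5),
                        seed = 200 + s)
    pairs <- all_pairs(n_nodes(net))
    for (ms in names(oracles)) {
      tab <- .score_measure_public(ms, net, pairs)
      want <- mapply(oracles[[ms]], i = pairs$i, j = pairs$j,
                     MoreArgs = list(net = net, layer = 1))
      expect_equal(tab$score, unname(want), info = paste(ms, "seed", s))
    }
  }
})

test_that("WCN matches a line-by-line run of its pseudocode", {
  # path 1-2-3 with nearly collinear coordinates
  path <- as_multiplex(data.frame(layer = 1, from = c(1, 2), to = c(2, 3)))
  co <- tibble::tibble(node = 1:3, r = c(1, 1, 1), theta = c(0, 0.1, 0.2))
  got <- score_of(score_wcn(path, co), 1, 3)
  expect_equal(got, oracle_wcn(path, 1, co, 1, 3))
  # both ties have the same distance H(1,2) = H(2,3) < h is impossible when
  # h is their mean and they are equal -> both weak -> WCN = 2 CN
  expect_equal(got, 2)

  # no common neighbors -> 0
  expect_equal(score_of(score_wcn(path, co), 1, 2), 0)

  # random graphs with random coordinates
  for (s in 1:20) {
    net <- random_layer(n = 10, p = 0.35, seed = 300 + s)
    set.seed(s)
    co <- tibble::tibble(node = 1:10, r = runif(10, 0.5, 4),
                         theta = runif(10, 0, 2 * pi))
    tab <- score_wcn(net, co)
    pairs <- all_pairs(10)
    want <- mapply(oracle_wcn, i = pairs$i, j = pairs$j,
                   MoreArgs = list(net = net, layer = 1, coords = co))
    expect_equal(tab$score, unname(want), info = paste("seed", s))
    # invariant: WCN >= 2 CN, equality iff all ties weak
    cn <- score_cn(net, pairs = pairs)
    expect_true(all(tab$score >= 2 * cn$score - 1e-12))
  }
})

test_that("Borda credit counts strictly-worse elements, ties share", {
  # reversed preferences cancel into a full tie
  t1 <- new_score_table(tibble::tibble(i = 1, j = 2:4), c(3, 2, 1), "m1")
  t2 <- new_score_table(tibble::tibble(i = 1, j = 2:4), c(1, 2, 3), "m1")
  agg <- borda_aggregate(list(t1, t2))
  expect_equal(agg$score, c(2, 2, 2))

  # identical lists preserve the consensus order
  agg2 <- borda_aggregate(list(t1, t1, t1))
  expect_equal(order(-agg2$score), order(-t1$score))

  # random score lists vs the counting oracle
  for (s in 1:10) {
    set.seed(s)
    pairs <- all_pairs(5)[1:8, ]
    lists <- lapply(1:6, function(q) {
      new_score_table(pairs, sample(1:4, 8, replace = TRUE), "x")
    })
    agg <- borda_aggregate(lists)
    expect_equal(agg$score,
                 oracle_borda(lapply(lists, function(t) t$score)))
  }

  # mismatched pair sets are an error
  t3 <- new_score_table(tibble::tibble(i = 1, j = 2:3), c(1, 2), "m1")
  expect_error(borda_aggregate(list(t1, t3)), "pair sets differ")
})

test_that("orientation is respected in Borda aggregation", {
  pairs <- tibble::tibble(i = 1, j = 2:3)
  cn <- new_score_table(pairs, c(5, 1), "cn")                # A > B
  hp <- new_score_table(pairs, c(2, 8), "hp", "lower_is_link")  # A > B too
  agg <- borda_aggregate(list(cn, hp))
  expect_equal(agg$score, c(2, 0))
  # conflicting orderings tie
  hp2 <- new_score_table(pairs, c(8, 2), "hp", "lower_is_link")  # B > A
  expect_equal(borda_aggregate(list(cn, hp2))$score, c(1, 1))
})

test_that("Rank-CN-HP equals the composition of its two components", {
  g <- grow_pso(60, 3, 3, 0.3, seed = 12)
  pairs <- candidate_pairs(g$net, 1, "non_edges")[1:20, ]
  got <- score_rank_cn_hp(g$net, g$coords, pairs = pairs)
  want <- borda_aggregate(list(score_cn(g$net, pairs = pairs),
                               score_hp(g$coords, pairs = pairs)))
  expect_equal(got$score, want$score)
  # agreement case: when CN and HP order pairs identically the aggregate
  # preserves that order
  ord_cn <- order(-score_cn(g$net, pairs = pairs)$score)
  ord_hp <- order(score_hp(g$coords, pairs = pairs)$score)
  if (identical(ord_cn, ord_hp)) {
    expect_equal(order(-got$score), ord_cn)
  }
})

test_that("all similarity scores are symmetric and nonnegative", {
  net <- random_layer(12, 0.3, seed = 77)
  set.seed(77)
  co <- tibble::tibble(node = 1:12, r = runif(12, 0.5, 4),
                       theta = runif(12, 0, 2 * pi))
  rev_pairs <- tibble::tibble(i = c(7, 3), j = c(2, 9))  # unsorted input
  for (ms in c("pa", "cn", "car", "cjc", "wcn")) {
    tab <- .score_measure_public(ms, net, all_pairs(12), co)
    expect_true(all(tab$score >= 0), info = ms)
    tab2 <- .score_measure_public(ms, net, rev_pairs, co)
    expect_equal(tab2$score,
                 c(score_of(tab, 2, 7), score_of(tab, 3, 9)), info = ms)
  }
})
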