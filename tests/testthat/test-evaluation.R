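test_that("precision is the top-L positive fraction", {
  ranked <- tibble::tibble(i = rep(1, 6), j = 2:7)
  pos <- tibble::tibble(i = 1, j = c(2, 3, 5, 9))
  expect_equal(precision_at(ranked, pos, 4), 0.75)
  expect_equal(precision_at(ranked, pos[1:2, ], 2), 1)
  expect_error(precision_at(ranked, pos, 0), "L")
  expect_error(precision_at(ranked, pos, 7), "exceeds")
})

test_that("random rankings hit the null precision L/#candidates", {
  set.seed(42)
  hits <- replicate(1000, {
    perm <- sample.int(100)
    ranked <- tibble::tibble(i = rep(0, 100), j = perm)
    precision_at(ranked, tibble::tibble(i = rep(0, 10), j = 1:10), 10)
  })
  expect_lt(abs(mean(hits) - 0.1), 0.02)
})

test_that("missing-link folds are disjoint and cover the edge set", {
  set.seed(1)
  stream <- hyplink:::.fold_stream(40, 5)
  folds <- lapply(1:5, function(i) stream())
  expect_equal(sort(unlist(folds)), 1:40)
  expect_equal(sum(lengths(folds)), 40)
  # next cycle reshuffles but still covers
  folds2 <- lapply(1:5, function(i) stream())
  expect_equal(sort(unlist(folds2)), 1:40)
})

test_that("a constructed fixture is predicted perfectly", {
  # two disjoint K5 cliques: a hidden within-clique edge keeps >= 2 common
  # neighbors while every cross-clique non-edge has 0, so CN ranks every
  # hidden edge above all other candidates in every repetition
  cl <- t(combn(5, 2))
  net <- as_multiplex(data.frame(layer = 1,
                                 from = c(cl[, 1], cl[, 1] + 5),
                                 to = c(cl[, 2], cl[, 2] + 5)))
  r <- run_missing(net, measures = "cn", holdout_fraction = 0.15,
                   repetitions = 6, seed = 7)
  expect_equal(tidy(r)$precision, rep(1, 6))
})

test_that("reports are reproducible from the master seed", {
  g <- grow_pso(120, 3, 3, 0.3, seed = 33)
  r1 <- run_missing(g$net, measures = c("cn", "pa"), repetitions = 3,
                    gamma = 3, temperature = 0.3, seed = 9)
  r2 <- run_missing(g$net, measures = c("cn", "pa"), repetitions = 3,
                    gamma = 3, temperature = 0.3, seed = 9)
  expect_equal(tidy(r1), tidy(r2))
  s1 <- run_spurious(g$net, measures = "cn", repetitions = 3,
                     gamma = 3, temperature = 0.3, seed = 9)
  s2 <- run_spurious(g$net, measures = "cn", repetitions = 3,
                     gamma = 3, temperature = 0.3, seed = 9)
  expect_equal(tidy(s1), tidy(s2))
})

test_that("single-layer mode equals multiplex mode on a 1-layer network", {
  g <- grow_pso(120, 3, 3, 0.3, seed = 44)
  r0 <- run_missing(g$net, measures = "cn", repetitions = 3, eta = 0,
                    gamma = 3, temperature = 0.3, seed = 5)
  r1 <- run_missing(g$net, measures = "cn", repetitions = 3, eta = 1,
                    gamma = 3, temperature = 0.3, seed = 5)
  expect_equal(tidy(r0), tidy(r1))
})

test_that("spurious fixture with telltale additions is fully identified", {
  # dense clique plus two outside nodes: any added link touching them has
  # few common neighbors while clique links have CN = 5
  cl <- t(combn(7, 2))
  net <- as_multiplex(data.frame(layer = 1, from = cl[, 1], to = cl[, 2]),
                      nodes = 1:9)
  r <- run_spurious(net, measures = "cn", added_fraction = 0.2,
                    repetitions = 5, seed = 3)
  expect_equal(mean(tidy(r)$precision), 1)
})

test_that("spurious guard rejects empty perturbations", {
  cl <- t(combn(8, 2))
  net <- as_multiplex(data.frame(layer = 1, from = cl[, 1], to = cl[, 2]))
  expect_error(run_spurious(net, added_fraction = 0.001), "L = 0")
})

test_that("bin curve conserves density and handles extremes", {
  # complete graph: every bin has probability 1
  k8 <- as_multiplex(data.frame(layer = 1, from = t(combn(8, 2))[, 1],
                                to = t(combn(8, 2))[, 2]))
  set.seed(2)
  co <- tibble::tibble(node = 1:8, r = runif(8, 0, 3),
                       theta = runif(8, 0, 2 * pi))
  bc <- distance_bin_curve(k8, co, n_bins = 4)
  expect_equal(bc$p_link, rep(1, 4))

  # empty layer: all zero
  empty <- as_multiplex(data.frame(layer = 1, from = 1, to = 2),
                        nodes = 1:8, layer_names = c("1", "2"))
  bc0 <- distance_bin_curve(empty, co, layer = 2, n_bins = 4)
  expect_equal(bc0$p_link, rep(0, 4))

  # conservation on a generated network, uneven bin sizes included
  g <- grow_pso(90, 3, 3, 0.4, seed = 6)
  bc2 <- distance_bin_curve(g$net, g$coords, n_bins = 7)
  expect_equal(sum(bc2$n_pairs), choose(90, 2))
  expect_equal(sum(bc2$n_pairs * bc2$p_link) / sum(bc2$n_pairs),
               layer_stats(g$net)$density)
  expect_error(distance_bin_curve(k8, co, n_bins = 100), "more bins")
})

test_that("tidiers and plots expose the report contents", {
  g <- grow_pso(100, 3, 3, 0.3, seed = 2)
  r <- run_missing(g$net, measures = c("cn", "pa"), repetitions = 2,
                   gamma = 3, temperature = 0.3, seed = 1)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 4)
  gl <- glance(r)
  expect_equal(sort(gl$measure), c("cn", "pa"))
  expect_equal(gl$mean_precision[gl$measure == "cn"],
               mean(td$precision[td$measure == "cn"]))
  expect_s3_class(autoplot(r), "ggplot")
  bc <- distance_bin_curve(g$net, g$coords, n_bins = 5)
  expect_s3_class(autoplot(bc), "ggplot")
})
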