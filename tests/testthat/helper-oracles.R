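# Brute-force oracles and small fixture builders. Everything here is kept
# deliberately naive (set operations, explicit enumeration) so it stays
# independent of the package's vectorized implementations.

# Erdos-Renyi G(n, p) as a one-layer multiplex
random_layer <- function(n, p, seed) {
  set.seed(seed)
  ap <- t(combn(n, 2))
  keep <- runif(nrow(ap)) < p
  edges <- ap[keep, , drop = FALSE]
  if (nrow(edges) == 0) edges <- ap[1, , drop = FALSE]
  as_multiplex(data.frame(layer = 1, from = edges[, 1], to = edges[, 2]),
               nodes = 1:n)
}

# random multiplex with independently drawn layers
random_multiplex <- function(n, m_layers, p, seed) {
  set.seed(seed)
  ap <- t(combn(n, 2))
  edges <- do.call(rbind, lapply(1:m_layers, function(l) {
    keep <- runif(nrow(ap)) < p
    if (!any(keep)) keep[sample.int(nrow(ap), 1)] <- TRUE
    data.frame(layer = l, from = ap[keep, 1], to = ap[keep, 2])
  }))
  as_multiplex(edges, nodes = 1:n)
}

neighbors_of <- function(net, layer, v) {
  e <- net$edges[net$edges$layer == layer, ]
  sort(unique(c(e$to[e$from == v], e$from[e$to == v])))
}

oracle_pa <- function(net, layer, i, j) {
  length(neighbors_of(net, layer, i)) * length(neighbors_of(net, layer, j))
}

oracle_cn <- function(net, layer, i, j) {
  length(intersect(neighbors_of(net, layer, i), neighbors_of(net, layer, j)))
}

oracle_car <- function(net, layer, i, j) {
  cn <- intersect(neighbors_of(net, layer, i), neighbors_of(net, layer, j))
  if (length(cn) < 2) return(0)
  e <- net$edges[net$edges$layer == layer, ]
  lcl <- sum(e$from %in% cn & e$to %in% cn)
  length(cn) * lcl
}

oracle_cjc <- function(net, layer, i, j) {
  uni <- union(neighbors_of(net, layer, i), neighbors_of(net, layer, j))
  if (length(uni) == 0) return(0)
  oracle_car(net, layer, i, j) / length(uni)
}

# line-by-line execution of the weighted-common-neighbors pseudocode
oracle_wcn <- function(net, layer, coords, i, j) {
  e <- net$edges[net$edges$layer == layer, ]
  H <- function(u, v) {
    hyperbolic_distance(coords$r[u], coords$theta[u],
                        coords$r[v], coords$theta[v])
  }
  h <- mean(mapply(H, e$from, e$to))
  wcn <- 0
  for (k in intersect(neighbors_of(net, layer, i),
                      neighbors_of(net, layer, j))) {
    for (tie in list(c(i, k), c(k, j))) {
      d <- H(tie[1], tie[2])
      wcn <- wcn + if (d < h) 1 + 1 / max(d, 1e-9) else 1
    }
  }
  wcn
}

# Borda by explicit counting of strictly-worse elements
oracle_borda <- function(score_lists) {
  n <- length(score_lists[[1]])
  sapply(seq_len(n), function(x) {
    sum(sapply(score_lists, function(sc) sum(sc < sc[x])))
  })
}

oracle_link_overlap <- function(net, a, b) {
  ea <- layer_edges(net, a); eb <- layer_edges(net, b)
  ka <- paste(ea$from, ea$to); kb <- paste(eb$from, eb$to)
  2 * length(intersect(ka, kb)) / (length(ka) + length(kb))
}

# score lookup in a score table
score_of <- function(tab, i, j) {
  tab$score[tab$i == min(i, j) & tab$j == max(i, j)]
}

# thin shim so parameterized tests can dispatch scorers by name
.score_measure_public <- function(measure, net, pairs, coords = NULL) {
  switch(measure,
    pa = score_pa(net, pairs = pairs),
    cn = score_cn(net, pairs = pairs),
    car = score_car(net, pairs = pairs),
    cjc = score_cjc(net, pairs = pairs),
    wcn = score_wcn(net, coords, pairs = pairs))
}

# sample from a discrete power law P(K = k) ~ k^-gamma, k >= k_min, by
# inverse transform on an explicit normalized pmf (truncated far in the tail)
rpowerlaw_discrete <- function(n, gamma, k_min, k_max = 1e6) {
  k <- k_min:k_max
  cdf <- cumsum(k^(-gamma))
  cdf <- cdf / cdf[length(cdf)]
  k[findInterval(runif(n), cdf) + 1L]
}
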