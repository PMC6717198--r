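#' Score tables
#'
#' All scorers return a *score table*: a tibble with columns `i`, `j`
#' (`i < j`) and `score`, carrying attributes `measure` and `orientation`
#' (`"higher_is_link"` for similarity-like scores, `"lower_is_link"` only for
#' the raw hyperbolic distance).
#'
#' @param pairs A tibble with columns `i`, `j`.
#' @param score Numeric scores, one per pair.
#' @param measure Measure label.
#' @param orientation `"higher_is_link"` or `"lower_is_link"`.
#' @return A `score_table` tibble.
#' @export
new_score_table <- function(pairs, score, measure,
                            orientation = c("higher_is_link",
                                            "lower_is_link")) {
  orientation <- match.arg(orientation)
  out <- tibble::tibble(i = pairs$i, j = pairs$j, score = score)
  attr(out, "measure") <- measure
  attr(out, "orientation") <- orientation
  class(out) <- c("score_table", class(out))
  out
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("# score table: %s (%s), %d pairs\n",
              attr(x, "measure"), attr(x, "orientation"), nrow(x)))
  NextMethod()
}

.score_setup <- function(net, layer, pairs, need_coords = NULL) {
  A <- layer_adjacency(net, layer)
  if (is.null(pairs)) pairs <- all_pairs(n_nodes(net))
  pairs <- .check_pairs(pairs, n_nodes(net))
  list(A = A, pairs = pairs)
}

#' Preferential attachment score
#'
#' \eqn{s^{PA}_{ij} = |\Gamma_i| \cdot |\Gamma_j|}: the product of the two
#' degrees — pure popularity.
#'
#' @param net A `multiplex` object.
#' @param layer Layer index.
#' @param pairs Pairs to score (tibble `i`, `j`); default all unordered pairs.
#' @return A score table, `higher_is_link`.
#' @export
score_pa <- function(net, layer = 1L, pairs = NULL) {
  s <- .score_setup(net, layer, pairs)
  deg <- colSums(s$A)
  new_score_table(s$pairs, deg[s$pairs$i] * deg[s$pairs$j], "pa")
}

#' Common-neighbors score
#'
#' \eqn{s^{CN}_{ij} = |\Gamma_i \cap \Gamma_j|}.
#'
#' @inheritParams score_pa
#' @return A score table, `higher_is_link`.
#' @export
score_cn <- function(net, layer = 1L, pairs = NULL) {
  s <- .score_setup(net, layer, pairs)
  CN <- s$A %*% s$A
  new_score_table(s$pairs, CN[cbind(s$pairs$i, s$pairs$j)], "cn")
}

#' CAR score
#'
#' \eqn{s^{CAR}_{ij} = s^{CN}_{ij} \cdot s^{LCL}_{ij}}, where LCL is the
#' number of links among the common neighbors of the pair (local community
#' links). Pairs with fewer than two common neighbors score 0.
#'
#' @inheritParams score_pa
#' @return A score table, `higher_is_link`.
#' @export
score_car <- function(net, layer = 1L, pairs = NULL) {
  s <- .score_setup(net, layer, pairs)
  A <- s$A
  CN <- A %*% A
  sc <- vapply(seq_len(nrow(s$pairs)), function(q) {
    i <- s$pairs$i[q]; j <- s$pairs$j[q]
    cn <- which(A[i, ] & A[j, ])
    if (length(cn) < 2L) return(0)
    CN[i, j] * sum(A[cn, cn]) / 2
  }, 0)
  new_score_table(s$pairs, sc, "car")
}

#' CJC score
#'
#' A CAR-modified Jaccard index:
#' \eqn{s^{CJC}_{ij} = s^{CAR}_{ij} / |\Gamma_i \cup \Gamma_j|}; 0 when the
#' neighbor union is empty.
#'
#' @inheritParams score_pa
#' @return A score table, `higher_is_link`.
#' @export
score_cjc <- function(net, layer = 1L, pairs = NULL) {
  s <- .score_setup(net, layer, pairs)
  car <- score_car(net, layer, s$pairs)
  uni <- vapply(seq_len(nrow(s$pairs)), function(q) {
    sum(s$A[s$pairs$i[q], ] | s$A[s$pairs$j[q], ])
  }, 0)
  sc <- ifelse(uni > 0, car$score / uni, 0)
  new_score_table(s$pairs, sc, "cjc")
}

#' Hyperbolic-distance score
#'
#' The exact hyperbolic distance of each pair under an embedding: small
#' distance means popular and/or similar, hence link-like. Orientation is
#' `lower_is_link`.
#'
#' @param coords A coordinate tibble ([embed_layer()] or [grow_pso()]).
#' @param pairs Pairs to score; default all pairs.
#' @return A score table, `lower_is_link`.
#' @export
score_hp <- function(coords, pairs = NULL) {
  out <- distance_matrix(coords, pairs)
  attr(out, "measure") <- "hp"
  out
}

#' Weighted common neighbors (WCN)
#'
#' A hybrid of common neighbors (popularity) and hyperbolic proximity
#' (similarity). Let `H(u,v)` be the exact hyperbolic distance and `h` the
#' mean of `H` over the *observed edges* of the layer. For a candidate pair
#' `(i,j)`, every common neighbor `k` contributes through its two ties:
#' a tie `(i,k)` with `H(i,k) < h` is *strong* and contributes
#' `1 + 1/H(i,k)`; otherwise it is weak and contributes 1; likewise `(k,j)`.
#' Hence `WCN(i,j) >= 2 CN(i,j)`, with equality when every involved tie is
#' weak. Ties with near-zero distance (coincident coordinates) have their
#' `1/H` term capped at `1/eps`.
#'
#' @inheritParams score_pa
#' @param coords Coordinate tibble covering the layer's nodes.
#' @param eps Cap for near-zero tie distances (default 1e-9).
#' @return A score table, `higher_is_link`.
#' @export
score_wcn <- function(net, coords, layer = 1L, pairs = NULL, eps = 1e-9) {
  s <- .score_setup(net, layer, pairs)
  A <- s$A
  coords <- .check_coords(coords)
  if (nrow(coords) != nrow(A)) {
    stop("coordinates do not cover the layer's nodes", call. = FALSE)
  }
  H <- .hyperbolic_distance_full(coords$r, coords$theta)
  edges <- layer_edges(net, layer)
  if (nrow(edges) == 0L) stop("layer has no edges: h is undefined",
                              call. = FALSE)
  h <- mean(H[cbind(edges$from, edges$to)])
  # per-tie weight: 1 + strong * 1/H, zero off-edges
  n_capped <- sum(A[upper.tri(A)] & H[upper.tri(H)] < eps)
  if (n_capped > 0L) {
    message(n_capped, " edge(s) at near-zero distance; 1/H capped at 1/eps")
  }
  W <- A * (1 + (H < h) / pmax(H, eps))
  # WCN(i,j) = sum_k A_ik A_kj (w_ik + w_kj) = (W A + A W)_ij
  WA <- W %*% A
  S <- WA + t(WA)
  new_score_table(s$pairs, S[cbind(s$pairs$i, s$pairs$j)], "wcn")
}

#' Borda rank aggregation of score tables
#'
#' Combines two or more score tables over the same pair set into one
#' consensus table. Within each input list the Borda credit of a pair is the
#' number of pairs ranked strictly below it (ties share the same credit);
#' credits are summed across lists with equal weight. Orientation of each
#' input is respected (`lower_is_link` tables credit *larger* distances
#' less), and the aggregate is `higher_is_link`.
#'
#' @param tables A list of score tables sharing one pair set.
#' @return A score table with measure `"borda"`, `higher_is_link`.
#' @export
borda_aggregate <- function(tables) {
  stopifnot(is.list(tables), length(tables) >= 2L)
  ref <- tables[[1L]]
  key <- paste(ref$i, ref$j)
  total <- numeric(nrow(ref))
  for (tb in tables) {
    if (nrow(tb) != nrow(ref)) stop("pair sets differ", call. = FALSE)
    idx <- match(key, paste(tb$i, tb$j))
    if (anyNA(idx)) stop("pair sets differ", call. = FALSE)
    sc <- tb$score[idx]
    if (identical(attr(tb, "orientation"), "lower_is_link")) sc <- -sc
    # count of strictly-worse pairs = min-rank - 1
    total <- total + (rank(sc, ties.method = "min") - 1)
  }
  new_score_table(ref[c("i", "j")], total, "borda")
}

#' Rank-CN-HP score
#'
#' Borda aggregation of the common-neighbors ranking and the hyperbolic
#' distance ranking over the candidate pairs, weighting popularity (CN) and
#' similarity (HP) equally. Where the two orderings agree the aggregate
#' reproduces them; where they conflict it averages their rank credit.
#'
#' @inheritParams score_wcn
#' @return A score table, `higher_is_link`.
#' @export
score_rank_cn_hp <- function(net, coords, layer = 1L, pairs = NULL) {
  s <- .score_setup(net, layer, pairs)
  cn <- score_cn(net, layer, s$pairs)
  hp <- score_hp(coords, s$pairs)
  out <- borda_aggregate(list(cn, hp))
  attr(out, "measure") <- "rank_cn_hp"
  out
}

# dispatch a measure name to its scorer; coords may be NULL for topological
# measures
.score_measure <- function(measure, net, layer, pairs, coords = NULL) {
  switch(measure,
    pa = score_pa(net, layer, pairs),
    cn = score_cn(net, layer, pairs),
    car = score_car(net, layer, pairs),
    cjc = score_cjc(net, layer, pairs),
    hp = score_hp(coords, pairs),
    wcn = score_wcn(net, coords, layer, pairs),
    rank_cn_hp = score_rank_cn_hp(net, coords, layer, pairs),
    stop("unknown measure: ", measure, call. = FALSE))
}

.coordinate_measures <- c("hp", "wcn", "rank_cn_hp")

#' @rdname new_score_table
#' @param x A score table.
#' @export
score_orientation <- function(x) attr(x, "orientation")
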