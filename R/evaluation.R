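#' Precision of the top-L of a ranking
#'
#' \eqn{Precision = |TP| / (|TP| + |FP|)} over the `L` highest-ranked
#' candidates: the fraction of the top `L` that are true positives.
#'
#' @param ranked_pairs A tibble of pairs (`i`, `j`) in ranked order, best
#'   first.
#' @param positives A tibble of positive pairs (`i`, `j`).
#' @param L Cutoff, `1 <= L <= nrow(ranked_pairs)`.
#' @return Precision in `[0, 1]`.
#' @export
precision_at <- function(ranked_pairs, positives, L) {
  if (L < 1L) stop("L must be >= 1", call. = FALSE)
  if (L > nrow(ranked_pairs)) stop("L exceeds the ranking length",
                                   call. = FALSE)
  top <- paste(pmin(ranked_pairs$i, ranked_pairs$j),
               pmax(ranked_pairs$i, ranked_pairs$j))[seq_len(L)]
  pos <- paste(pmin(positives$i, positives$j),
               pmax(positives$i, positives$j))
  sum(top %in% pos) / L
}

# deterministic ranking of a score table; direction "link_like" puts the most
# link-like pair first, "unlink_like" the least link-like (spurious protocol)
.rank_pairs <- function(table, direction = c("link_like", "unlink_like")) {
  direction <- match.arg(direction)
  sc <- table$score
  if (identical(score_orientation(table), "lower_is_link")) sc <- -sc
  if (direction == "unlink_like") sc <- -sc
  table[order(-sc, table$i, table$j), c("i", "j")]
}

# cycled k-fold splitter over edge indices: folds within one cycle are
# disjoint and cover the edge set; a fresh shuffle starts each cycle
.fold_stream <- function(n_edges, k) {
  state <- new.env(parent = emptyenv())
  state$folds <- list()
  state$ptr <- 0L
  function() {
    if (state$ptr == 0L || state$ptr >= length(state$folds)) {
      perm <- sample.int(n_edges)
      state$folds <- split(perm, cut(seq_len(n_edges), k, labels = FALSE))
      state$ptr <- 0L
    }
    state$ptr <- state$ptr + 1L
    state$folds[[state$ptr]]
  }
}

.densest_layer <- function(net) which.max(layer_stats(net)$density)

# replace the target layer's edge table inside a multiplex
.set_layer_edges <- function(net, layer, edges) {
  keep <- dplyr::filter(net$edges, .data$layer != !!layer)
  net$edges <- dplyr::arrange(
    dplyr::bind_rows(keep, tibble::tibble(layer = layer, from = edges$from,
                                          to = edges$to)),
    .data$layer, .data$from, .data$to)
  net
}

# embeddings of non-target layers from their full (never perturbed) topology
.embed_others <- function(net, others, gamma, temperature, grid_size,
                          sweeps) {
  stats::setNames(lapply(others, function(b) {
    embed_layer(net, b, gamma = gamma, temperature = temperature,
                grid_size = grid_size, sweeps = sweeps)
  }), as.character(others))
}

# resolve gamma/temperature for the target layer (estimate once, reused)
.resolve_model_params <- function(net, layer, gamma, temperature, seed) {
  if (is.null(gamma)) {
    gamma <- tryCatch(estimate_gamma(net, layer), error = function(e) {
      warning("power-law tail not identifiable; falling back to gamma = 2.5",
              call. = FALSE)
      2.5
    })
    if (gamma <= 2) {
      warning("estimated gamma <= 2; falling back to gamma = 2.5",
              call. = FALSE)
      gamma <- 2.5
    }
  }
  if (is.null(temperature)) {
    temperature <- estimate_temperature(net, layer, gamma = gamma,
                                        seed = seed)
  }
  list(gamma = gamma, temperature = temperature)
}

.new_link_eval <- function(protocol, results, params) {
  structure(list(protocol = protocol, results = results, params = params),
            class = "link_eval")
}

#' @export
print.link_eval <- function(x, ...) {
  cat(sprintf("<%s-link evaluation: %d repetition(s), target layer %d>\n",
              x$protocol, x$params$repetitions, x$params$target_layer))
  print(glance(x))
  invisible(x)
}

#' Missing-link prediction experiment
#'
#' Per repetition: hide a fraction of the target layer's edges (cycled
#' k-fold with `k = round(1/holdout_fraction)`: folds within one cycle are
#' disjoint and cover the edge set, a fresh shuffle starts each cycle);
#' re-embed the perturbed target layer when any requested measure needs
#' coordinates (non-target layers are embedded once from their full
#' topology); score every non-observed pair of the perturbed layer; fuse
#' across layers per the multiplex similarity when `eta > 0`; rank and take
#' the precision of the top `L`, with `L` = the number of hidden links.
#'
#' All requested measures share each repetition's perturbation and
#' embedding, so their precisions are directly comparable.
#'
#' @param net A `multiplex` object.
#' @param measures Character vector from `"pa"`, `"cn"`, `"car"`, `"cjc"`,
#'   `"hp"`, `"wcn"`, `"rank_cn_hp"`.
#' @param target_layer Target layer; default the densest layer.
#' @param holdout_fraction Fraction of target edges hidden per repetition
#'   (default 0.15).
#' @param repetitions Number of independent repetitions (default 20).
#' @param eta Interlayer weight; 0 (default) is single-layer mode.
#' @param relevance_method `"lo"`, `"pearson"` or `"spearman"`.
#' @param gamma,temperature Embedding parameters for all layers; `NULL`
#'   estimates them once from the unperturbed target layer.
#' @param grid_size,sweeps Passed to [embed_layer()].
#' @param seed Master seed; the full report is reproducible from it.
#' @return A `link_eval` object; see [tidy.link_eval()] and
#'   [glance.link_eval()].
#' @export
run_missing <- function(net, measures = "cn", target_layer = NULL,
                        holdout_fraction = 0.15, repetitions = 20L,
                        eta = 0, relevance_method = "lo",
                        gamma = NULL, temperature = NULL,
                        grid_size = NULL, sweeps = 1L, seed = 1L) {
  stopifnot(inherits(net, "multiplex"),
            holdout_fraction > 0, holdout_fraction < 1, repetitions >= 1L)
  measures <- match.arg(measures, c("pa", "cn", "car", "cjc", "hp", "wcn",
                                    "rank_cn_hp"), several.ok = TRUE)
  if (is.null(target_layer)) target_layer <- .densest_layer(net)
  edges <- layer_edges(net, target_layer)
  if (nrow(edges) < 20L) stop("target layer needs at least 20 edges",
                              call. = FALSE)
  need_coords <- any(measures %in% .coordinate_measures)
  mp <- if (need_coords) {
    .resolve_model_params(net, target_layer, gamma, temperature, seed)
  } else list(gamma = gamma, temperature = temperature)
  others <- setdiff(seq_len(n_layers(net)), target_layer)
  use_fusion <- eta > 0 && length(others) > 0L

  other_coords <- if (need_coords && use_fusion) {
    .embed_others(net, others, mp$gamma, mp$temperature, grid_size, sweeps)
  }

  k <- max(2L, round(1 / holdout_fraction))
  results <- .with_seed(seed, {
    next_fold <- .fold_stream(nrow(edges), k)
    purrr::map_dfr(seq_len(repetitions), function(rep) {
      hidden_idx <- next_fold()
      hidden <- edges[hidden_idx, ]
      perturbed <- .set_layer_edges(net, target_layer, edges[-hidden_idx, ])
      cand <- candidate_pairs(perturbed, target_layer, "non_edges")
      coords <- if (need_coords) {
        tryCatch(
          embed_layer(perturbed, target_layer, gamma = mp$gamma,
                      temperature = mp$temperature, grid_size = grid_size,
                      sweeps = sweeps),
          error = function(e) {
            warning(sprintf("repetition %d skipped: %s", rep,
                            conditionMessage(e)), call. = FALSE)
            NULL
          })
      }
      if (need_coords && is.null(coords)) return(NULL)
      mu <- if (use_fusion) {
        vapply(others, function(b) {
          if (relevance_method == "lo") link_overlap(perturbed,
                                                     target_layer, b)
          else layer_correlation(perturbed, target_layer, b,
                                 relevance_method)
        }, 0)
      }
      purrr::map_dfr(measures, function(ms) {
        tab <- .score_measure(ms, perturbed, target_layer, cand, coords)
        if (use_fusion) {
          oth <- lapply(others, function(b) {
            .score_measure(ms, perturbed, b, cand,
                           other_coords[[as.character(b)]])
          })
          tab <- fuse_scores(tab, oth, mu, eta = eta)
        }
        ranked <- .rank_pairs(tab, "link_like")
        tibble::tibble(
          measure = ms, repetition = rep,
          precision = precision_at(ranked,
                                   tibble::tibble(i = hidden$from,
                                                  j = hidden$to),
                                   nrow(hidden)),
          n_positive = nrow(hidden), n_candidates = nrow(cand))
      })
    })
  })
  .new_link_eval("missing", results,
                 list(measures = measures, target_layer = target_layer,
                      holdout_fraction = holdout_fraction,
                      repetitions = repetitions, eta = eta,
                      relevance_method = relevance_method,
                      gamma = mp$gamma, temperature = mp$temperature,
                      seed = seed))
}

#' Spurious-link identification experiment
#'
#' Per repetition: add uniformly random non-edges to the target layer
#' (`added_fraction` of its edge count), re-embed the perturbed layer for
#' coordinate-based measures, score every *observed* link, rank with the
#' orientation reversed (least link-like first), and take the precision of
#' the top `L`, with `L` = the number of added links.
#'
#' @inheritParams run_missing
#' @param added_fraction Spurious links added per repetition as a fraction
#'   of the target layer's edge count (default 0.15).
#' @return A `link_eval` object.
#' @export
run_spurious <- function(net, measures = "cn", target_layer = NULL,
                         added_fraction = 0.15, repetitions = 20L,
                         eta = 0, relevance_method = "lo",
                         gamma = NULL, temperature = NULL,
                         grid_size = NULL, sweeps = 1L, seed = 1L) {
  stopifnot(inherits(net, "multiplex"), added_fraction > 0,
            repetitions >= 1L)
  measures <- match.arg(measures, c("pa", "cn", "car", "cjc", "hp", "wcn",
                                    "rank_cn_hp"), several.ok = TRUE)
  if (is.null(target_layer)) target_layer <- .densest_layer(net)
  edges <- layer_edges(net, target_layer)
  if (nrow(edges) < 20L) stop("target layer needs at least 20 edges",
                              call. = FALSE)
  L <- round(added_fraction * nrow(edges))
  if (L < 1L) stop("added_fraction adds no links (L = 0)", call. = FALSE)
  non_edges <- candidate_pairs(net, target_layer, "non_edges")
  if (nrow(non_edges) < L) stop("not enough non-edges to add", call. = FALSE)
  need_coords <- any(measures %in% .coordinate_measures)
  mp <- if (need_coords) {
    .resolve_model_params(net, target_layer, gamma, temperature, seed)
  } else list(gamma = gamma, temperature = temperature)
  others <- setdiff(seq_len(n_layers(net)), target_layer)
  use_fusion <- eta > 0 && length(others) > 0L
  other_coords <- if (need_coords && use_fusion) {
    .embed_others(net, others, mp$gamma, mp$temperature, grid_size, sweeps)
  }

  results <- .with_seed(seed, {
    purrr::map_dfr(seq_len(repetitions), function(rep) {
      added <- non_edges[sample.int(nrow(non_edges), L), ]
      perturbed <- .set_layer_edges(
        net, target_layer,
        tibble::tibble(from = c(edges$from, added$i),
                       to = c(edges$to, added$j)))
      cand <- candidate_pairs(perturbed, target_layer, "edges")
      coords <- if (need_coords) {
        embed_layer(perturbed, target_layer, gamma = mp$gamma,
                    temperature = mp$temperature, grid_size = grid_size,
                    sweeps = sweeps)
      }
      mu <- if (use_fusion) {
        vapply(others, function(b) {
          if (relevance_method == "lo") link_overlap(perturbed,
                                                     target_layer, b)
          else layer_correlation(perturbed, target_layer, b,
                                 relevance_method)
        }, 0)
      }
      purrr::map_dfr(measures, function(ms) {
        tab <- .score_measure(ms, perturbed, target_layer, cand, coords)
        if (use_fusion) {
          oth <- lapply(others, function(b) {
            .score_measure(ms, perturbed, b, cand,
                           other_coords[[as.character(b)]])
          })
          tab <- fuse_scores(tab, oth, mu, eta = eta)
        }
        ranked <- .rank_pairs(tab, "unlink_like")
        tibble::tibble(
          measure = ms, repetition = rep,
          precision = precision_at(ranked, added, L),
          n_positive = L, n_candidates = nrow(cand))
      })
    })
  })
  .new_link_eval("spurious", results,
                 list(measures = measures, target_layer = target_layer,
                      added_fraction = added_fraction,
                      repetitions = repetitions, eta = eta,
                      relevance_method = relevance_method,
                      gamma = mp$gamma, temperature = mp$temperature,
                      seed = seed))
}

#' Link probability as a function of hyperbolic distance
#'
#' Sorts all unordered node pairs by their hyperbolic distance, splits them
#' into `n_bins` equal-count bins, and reports the fraction of linked pairs
#' per bin. On a well-embedded (or generated) geometric network the curve
#' decreases with distance. The size-weighted mean of the bin probabilities
#' equals the layer density exactly (every pair sits in exactly one bin).
#'
#' @param net A `multiplex` object.
#' @param coords Coordinate tibble for the layer.
#' @param layer Layer index.
#' @param n_bins Number of equal-count bins (`>= 2`).
#' @return A `bin_curve` tibble: `bin`, `d_lo`, `d_hi`, `n_pairs`, `n_links`,
#'   `p_link`.
#' @export
distance_bin_curve <- function(net, coords, layer = 1L, n_bins = 20L) {
  stopifnot(n_bins >= 2L)
  n <- n_nodes(net)
  pairs <- all_pairs(n)
  if (n_bins > nrow(pairs)) stop("more bins than node pairs", call. = FALSE)
  coords <- .check_coords(coords)
  d <- hyperbolic_distance(coords$r[pairs$i], coords$theta[pairs$i],
                           coords$r[pairs$j], coords$theta[pairs$j])
  A <- layer_adjacency(net, layer)
  linked <- A[cbind(pairs$i, pairs$j)] == 1L
  ord <- order(d, pairs$i, pairs$j)
  P <- nrow(pairs)
  base <- P %/% n_bins
  sizes <- rep(base, n_bins)
  extra <- P - base * n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  bin_id <- rep(seq_len(n_bins), times = sizes)
  out <- tibble::tibble(bin = bin_id, d = d[ord], linked = linked[ord]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(d_lo = min(.data$d), d_hi = max(.data$d),
                     n_pairs = dplyr::n(), n_links = sum(.data$linked),
                     p_link = mean(.data$linked), .groups = "drop")
  class(out) <- c("bin_curve", class(out))
  out
}
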