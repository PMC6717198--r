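#' Link overlap between two layers
#'
#' \eqn{O^{\alpha\beta} = 2|E^\alpha \cap E^\beta| / (|E^\alpha| +
#' |E^\beta|)}: the fraction of links the two layers share, normalized by
#' their mean edge count. Symmetric, in `[0, 1]`; 0 for edge-disjoint layers,
#' 1 for identical edge sets.
#'
#' @param net A `multiplex` object.
#' @param a,b Layer indices.
#' @return A number in `[0, 1]`.
#' @export
link_overlap <- function(net, a, b) {
  ea <- layer_edges(net, a)
  eb <- layer_edges(net, b)
  if (nrow(ea) + nrow(eb) == 0L) {
    stop("both layers are empty: link overlap undefined", call. = FALSE)
  }
  common <- nrow(dplyr::inner_join(ea, eb, by = c("from", "to")))
  2 * common / (nrow(ea) + nrow(eb))
}

#' Correlation between two layers' adjacency indicators
#'
#' Pearson or Spearman correlation of the vectorized upper-triangular 0/1
#' adjacency indicators over the shared node universe.
#'
#' @inheritParams link_overlap
#' @param method `"pearson"` or `"spearman"`.
#' @return A number in `[-1, 1]`.
#' @export
layer_correlation <- function(net, a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  Aa <- layer_adjacency(net, a)
  Ab <- layer_adjacency(net, b)
  stats::cor(Aa[upper.tri(Aa)], Ab[upper.tri(Ab)], method = method)
}

#' Pairwise interlayer relevance matrix
#'
#' @param net A `multiplex` object.
#' @param method `"lo"` (link overlap; default and the method used
#'   throughout), `"pearson"` or `"spearman"`.
#' @return A symmetric `M x M` matrix; unit diagonal for link overlap on
#'   nonempty layers.
#' @export
layer_relevance <- function(net, method = c("lo", "pearson", "spearman")) {
  method <- match.arg(method)
  M <- n_layers(net)
  out <- diag(1, M)
  if (M >= 2L) {
    for (a in 1:(M - 1)) for (b in (a + 1):M) {
      v <- if (method == "lo") link_overlap(net, a, b) else
        layer_correlation(net, a, b, method)
      out[a, b] <- out[b, a] <- v
    }
  }
  dimnames(out) <- list(net$layer_names, net$layer_names)
  attr(out, "method") <- method
  out
}

#' Fuse per-layer score tables into a multiplex score
#'
#' The multiplex similarity of a pair in target layer \eqn{\alpha} is
#' \deqn{S_{ij} = s^\alpha_{ij} + \sum_{\beta \ne \alpha}
#'   \eta\,\mu^{\alpha\beta}\, s^\beta_{ij},}
#' a linear combination of the target layer's score with every other layer's
#' score for the same pair, weighted by the interlayer relevance
#' \eqn{\mu^{\alpha\beta}} (link overlap) and the global knob \eqn{\eta}.
#' With `eta = 0` the output equals the target table (single-layer mode).
#'
#' All tables must share one pair set, measure and orientation. Tables with
#' orientation `lower_is_link` (raw distances) are negated before fusion so
#' that "higher = more link-like" holds uniformly; the output is then
#' `higher_is_link`.
#'
#' Scores are combined raw, as the formula is written. Because score scales
#' can differ across layers (counts vs weighted counts vs distances), an
#' optional extension `rank_normalize = TRUE` replaces each table's scores
#' with normalized mid-ranks in `[0, 1]` before combining; it is off by
#' default.
#'
#' @param target_scores Score table of the target layer.
#' @param other_scores List of score tables, one per non-target layer.
#' @param relevance Numeric vector \eqn{\mu^{\alpha\beta}}, one per element
#'   of `other_scores`, or a full relevance matrix (then `target_layer` and
#'   `other_layers` pick the entries).
#' @param eta Interlayer weight \eqn{\eta \ge 0} (default 1).
#' @param target_layer,other_layers Indices into a matrix `relevance`.
#' @param rank_normalize Replace every table's scores by normalized
#'   mid-ranks before combining (default `FALSE`: raw scores, as the
#'   formula is written).
#' @return A fused score table.
#' @export
fuse_scores <- function(target_scores, other_scores, relevance, eta = 1,
                        target_layer = NULL, other_layers = NULL,
                        rank_normalize = FALSE) {
  stopifnot(is.list(other_scores))
  if (is.matrix(relevance)) {
    if (is.null(target_layer) || is.null(other_layers)) {
      stop("matrix relevance needs target_layer and other_layers",
           call. = FALSE)
    }
    relevance <- relevance[target_layer, other_layers]
  }
  if (length(relevance) != length(other_scores)) {
    stop("one relevance value per non-target score table required",
         call. = FALSE)
  }
  orient <- score_orientation(target_scores)
  key <- paste(target_scores$i, target_scores$j)
  flip <- identical(orient, "lower_is_link")
  norm <- function(sc) {
    if (rank_normalize) rank(sc, ties.method = "average") / length(sc)
    else sc
  }
  total <- norm(if (flip) -target_scores$score else target_scores$score)
  for (q in seq_along(other_scores)) {
    tb <- other_scores[[q]]
    if (!identical(score_orientation(tb), orient)) {
      stop("orientation mismatch between score tables", call. = FALSE)
    }
    idx <- match(key, paste(tb$i, tb$j))
    if (anyNA(idx)) stop("pair sets differ across layers", call. = FALSE)
    sc <- tb$score[idx]
    if (flip) sc <- -sc
    total <- total + eta * relevance[q] * norm(sc)
  }
  out <- new_score_table(target_scores[c("i", "j")], total,
                         paste0("fused_", attr(target_scores, "measure")))
  attr(out, "eta") <- eta
  out
}
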