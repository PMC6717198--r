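#' Build a multiplex network from an edge table
#'
#' A multiplex network is an ordered set of layers over one shared node
#' universe: every layer has the same `N` nodes (isolated nodes are kept) and
#' its own set of undirected, unweighted intra-layer edges.
#'
#' Node labels from the input are preserved but normalized internally to a
#' contiguous `1..N` index (numeric-aware sorted order), so layers whose edge
#' lists mention different subsets of labels still share one universe.
#' Duplicate edges and self-loops are dropped with a warning reporting the
#' counts.
#'
#' @param edges A data frame with columns `layer`, `from`, `to` (extra columns,
#'   e.g. weights, are ignored). `layer` may be integer or character.
#' @param nodes Optional vector of node labels fixing the universe; defaults to
#'   the union of all edge endpoints.
#' @param layer_names Optional character vector naming the layers in order.
#' @return An object of class `multiplex`: a list with tibbles `edges`
#'   (internal indices, `from < to`) and `nodes` (`node`, `label`), plus
#'   `layer_names`.
#' @examples
#' net <- as_multiplex(data.frame(layer = c(1, 1, 2), from = c(1, 2, 1),
#'                                to = c(2, 3, 3)))
#' net
#' @export
as_multiplex <- function(edges, nodes = NULL, layer_names = NULL) {
  stopifnot(is.data.frame(edges))
  need <- c("layer", "from", "to")
  if (!all(need %in% names(edges))) {
    stop("`edges` must have columns layer, from, to", call. = FALSE)
  }
  edges <- tibble::as_tibble(edges)[need]

  layer_labels <- unique(as.character(edges$layer))
  if (is.null(layer_names)) {
    layer_names <- layer_labels
  } else {
    layer_names <- as.character(layer_names)
    if (!all(layer_labels %in% layer_names)) {
      stop("edge table mentions layers absent from `layer_names`",
           call. = FALSE)
    }
  }
  lyr <- match(as.character(edges$layer), layer_names)

  labels <- .sort_labels(unique(c(as.character(edges$from),
                                  as.character(edges$to),
                                  if (!is.null(nodes)) as.character(nodes))))
  if (length(labels) == 0L) stop("network has no nodes", call. = FALSE)
  from <- match(as.character(edges$from), labels)
  to <- match(as.character(edges$to), labels)

  u <- pmin(from, to)
  v <- pmax(from, to)
  self <- u == v
  n_self <- sum(self)
  key <- paste(lyr, u, v)
  dup <- duplicated(key) & !self
  n_dup <- sum(dup)
  keep <- !self & !dup
  if (n_self + n_dup > 0L) {
    warning(sprintf("dropped %d self-loop(s) and %d duplicate record(s)",
                    n_self, n_dup), call. = FALSE)
  }

  edge_tbl <- tibble::tibble(layer = lyr[keep], from = u[keep], to = v[keep])
  edge_tbl <- dplyr::arrange(edge_tbl, .data$layer, .data$from, .data$to)

  structure(
    list(edges = edge_tbl,
         nodes = tibble::tibble(node = seq_along(labels), label = labels),
         layer_names = as.character(layer_names)),
    class = "multiplex")
}

# numeric-aware deterministic label ordering
.sort_labels <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) x[order(num)] else sort(x, method = "radix")
}

#' @export
print.multiplex <- function(x, ...) {
  cat(sprintf("<multiplex network: %d nodes, %d layers>\n",
              n_nodes(x), n_layers(x)))
  e <- dplyr::count(x$edges, .data$layer)
  for (m in seq_len(n_layers(x))) {
    ne <- e$n[match(m, e$layer)]
    cat(sprintf("  layer %d (%s): %d edges\n", m, x$layer_names[m],
                ifelse(is.na(ne), 0L, ne)))
  }
  invisible(x)
}

#' Number of nodes / layers in a multiplex network
#' @param net A `multiplex` object.
#' @return An integer count.
#' @export
n_nodes <- function(net) nrow(net$nodes)

#' @rdname n_nodes
#' @export
n_layers <- function(net) length(net$layer_names)

#' Edge table of one layer
#' @param net A `multiplex` object.
#' @param layer Layer index (1-based).
#' @return A tibble with columns `from`, `to` (internal node indices,
#'   `from < to`).
#' @export
layer_edges <- function(net, layer = 1L) {
  stopifnot(inherits(net, "multiplex"), layer >= 1L, layer <= n_layers(net))
  dplyr::select(dplyr::filter(net$edges, .data$layer == !!layer),
                "from", "to")
}

#' Dense adjacency matrix of one layer
#' @inheritParams layer_edges
#' @return An `N x N` symmetric 0/1 integer matrix.
#' @export
layer_adjacency <- function(net, layer = 1L) {
  e <- layer_edges(net, layer)
  n <- n_nodes(net)
  A <- matrix(0L, n, n)
  if (nrow(e)) {
    A[cbind(e$from, e$to)] <- 1L
    A[cbind(e$to, e$from)] <- 1L
  }
  A
}

.layer_igraph <- function(net, layer = 1L) {
  e <- layer_edges(net, layer)
  igraph::graph_from_edgelist(as.matrix(e), directed = FALSE) |>
    igraph::add_vertices(max(0L, n_nodes(net) -
      ifelse(nrow(e), max(e$from, e$to), 0L)))
}

#' Read a multiplex edge list file
#'
#' Accepts whitespace-separated records `layer u v` (canonical) or
#' `layer u v w` (4-column; the weight is validated as numeric then
#' discarded — all networks are treated as unweighted). Lines starting with
#' `#` are comments; `# layer <name>` headers declare layers (possibly empty)
#' and `# nodes <labels...>` declares the node universe, which otherwise
#' defaults to the union of endpoints. Duplicate records and self-loops are
#' dropped with a warning.
#'
#' @param path Path to the file.
#' @return A `multiplex` object.
#' @seealso [write_multiplex()] for the canonical writer; the pair round-trips.
#' @export
read_multiplex <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty multiplex file: ", path, call. = FALSE)

  header_layers <- character()
  header_nodes <- NULL
  is_comment <- startsWith(trimws(lines), "#")
  for (cl in trimws(lines[is_comment])) {
    toks <- strsplit(sub("^#\\s*", "", cl), "\\s+")[[1]]
    if (length(toks) >= 2 && toks[1] == "layer") {
      header_layers <- c(header_layers, toks[2])
    } else if (length(toks) >= 2 && toks[1] == "nodes") {
      header_nodes <- toks[-1]
    }
  }

  data_idx <- which(!is_comment & nzchar(trimws(lines)))
  if (length(data_idx) == 0L && length(header_layers) == 0L) {
    stop("no records in multiplex file: ", path, call. = FALSE)
  }
  recs <- strsplit(trimws(lines[data_idx]), "\\s+")
  nf <- lengths(recs)
  bad <- which(nf < 3L | nf > 4L)
  if (length(bad)) {
    stop(sprintf("malformed record at line %d of %s (expected 3 or 4 fields)",
                 data_idx[bad[1]], path), call. = FALSE)
  }
  w_bad <- which(nf == 4L &
                 is.na(suppressWarnings(as.numeric(vapply(recs, function(r)
                   r[4], "")[nf == 4L]))))
  if (length(w_bad)) {
    ln <- data_idx[which(nf == 4L)[w_bad[1]]]
    stop(sprintf("non-numeric weight at line %d of %s", ln, path),
         call. = FALSE)
  }

  edges <- tibble::tibble(
    layer = vapply(recs, `[`, "", 1L),
    from = vapply(recs, `[`, "", 2L),
    to = vapply(recs, `[`, "", 3L))
  lnames <- if (length(header_layers)) {
    c(header_layers, setdiff(unique(edges$layer), header_layers))
  } else NULL
  as_multiplex(edges, nodes = header_nodes, layer_names = lnames)
}

#' Write a multiplex network in canonical form
#'
#' Emits a deterministic, diff-able text file: a header declaring the node
#' universe and every layer (so empty layers survive a round-trip), then one
#' `layer u v` record per edge with `u < v`, sorted by layer then endpoints.
#'
#' @param net A `multiplex` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_multiplex <- function(net, path) {
  stopifnot(inherits(net, "multiplex"))
  lab <- net$nodes$label
  hdr <- c("# multiplex edge list (layer u v)",
           paste("# nodes", paste(lab, collapse = " ")),
           paste("# layer", net$layer_names))
  e <- net$edges
  body <- sprintf("%s %s %s", net$layer_names[e$layer], lab[e$from],
                  lab[e$to])
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Per-layer descriptive statistics
#'
#' Computes, for each layer: node and edge counts, mean degree
#' \eqn{\langle k \rangle = 2E/N}, density \eqn{S = 2E/(N(N-1))}, degree
#' heterogeneity \eqn{H = \langle k^2\rangle / \langle k\rangle^2} (1 for a
#' regular graph, larger for broader degree distributions), and the mean local
#' clustering coefficient (nodes of degree < 2 contribute 0). Values are
#' returned at full precision; any truncation for display is the caller's
#' concern.
#'
#' @param net A `multiplex` object (all layers are summarized).
#' @return A tibble with one row per layer and columns `layer`, `layer_name`,
#'   `n_nodes`, `n_edges`, `mean_degree`, `density`, `heterogeneity`,
#'   `mean_clustering`.
#' @examples
#' net <- as_multiplex(data.frame(layer = 1, from = c(1, 1, 2),
#'                                to = c(2, 3, 3)))
#' layer_stats(net)
#' @export
layer_stats <- function(net) {
  stopifnot(inherits(net, "multiplex"))
  n <- n_nodes(net)
  if (n < 2L) stop("layer statistics need at least 2 nodes", call. = FALSE)
  purrr::map_dfr(seq_len(n_layers(net)), function(m) {
    e <- layer_edges(net, m)
    deg <- tabulate(c(e$from, e$to), nbins = n)
    E <- nrow(e)
    kbar <- 2 * E / n
    g <- .layer_igraph(net, m)
    cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
    tibble::tibble(
      layer = m, layer_name = net$layer_names[m],
      n_nodes = n, n_edges = E,
      mean_degree = kbar,
      density = 2 * E / (n * (n - 1)),
      heterogeneity = if (E > 0) mean(deg^2) / kbar^2 else NA_real_,
      mean_clustering = if (E > 0) cc else 0)
  })
}

#' Candidate node pairs of a layer
#'
#' @param net A `multiplex` object.
#' @param layer Layer index.
#' @param type `"non_edges"` (pairs not observed — the missing-link candidate
#'   set), `"edges"` (observed links — the spurious-link candidate set) or
#'   `"all"` (every unordered pair).
#' @return A tibble with columns `i`, `j` (`i < j`, internal indices).
#' @export
candidate_pairs <- function(net, layer = 1L,
                            type = c("non_edges", "edges", "all")) {
  type <- match.arg(type)
  n <- n_nodes(net)
  e <- layer_edges(net, layer)
  if (type == "edges") return(tibble::tibble(i = e$from, j = e$to))
  ap <- all_pairs(n)
  if (type == "all") return(ap)
  dplyr::anti_join(ap, tibble::tibble(i = e$from, j = e$to),
                   by = c("i", "j"))
}

#' All unordered node pairs on 1..n
#' @param n Number of nodes.
#' @return A tibble with columns `i`, `j`, `i < j`.
#' @export
all_pairs <- function(n) {
  stopifnot(n >= 2L)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  tibble::tibble(i = idx[, 1L], j = idx[, 2L]) |>
    dplyr::arrange(.data$i, .data$j)
}
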