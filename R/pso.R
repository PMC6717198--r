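#' Grow a network with the popularity-x-similarity optimization (PSO) model
#'
#' Nodes are born one at a time on the hyperbolic disk. Node `t` receives
#' radius \eqn{r_t = 2\ln t} (popularity: early nodes sit deep in the disk)
#' and an angle drawn uniformly on \eqn{[0, 2\pi)} (similarity) — or, in the
#' nonuniform (N-PSO) mode, from a mixture of `communities` equal-weight
#' wrapped-normal components with centers equally spaced on the circle and
#' spread \eqn{\sigma = \pi/(2C)}. All earlier nodes drift outward
#' ("popularity fading"): at time `t` node `s` sits at
#' \eqn{r_s(t) = \beta r_s + (1-\beta) r_t} with \eqn{\beta = 1/(\gamma-1)},
#' which yields a power-law degree distribution with exponent `gamma`.
#'
#' The newcomer connects to `min(m, t-1)` distinct existing nodes: the `m`
#' hyperbolically nearest when `temperature = 0`, otherwise `m` sampled
#' without replacement with probability proportional to the Fermi-Dirac
#' factor \eqn{1/(1+e^{(x - R_t)/(2T)})}, where the cutoff \eqn{R_t} is set by
#' bisection so the expected number of connections equals `m`. Either way the
#' final edge count is exactly \eqn{\sum_t \min(m, t-1)} and the mean degree
#' is close to `2m`.
#'
#' @param n_nodes Final network size `N`.
#' @param m Links added per new node (`N > m + 1`, `m >= 1`); mean degree
#'   is approximately `2m`.
#' @param gamma Target power-law exponent, `> 2`.
#' @param temperature Model temperature `T >= 0`; low `T` gives strong
#'   clustering.
#' @param seed Integer seed; the same parameters and seed reproduce the
#'   network byte-for-byte.
#' @param communities Optional community count `C` switching on the
#'   nonuniform angular mode.
#' @return A list with `net` (a one-layer `multiplex`) and `coords` (tibble
#'   `node`, `r`, `theta` of the true final coordinates, with attributes
#'   `R = 2 log N`, `temperature`, `gamma`, `provenance = "generator"`).
#' @examples
#' g <- grow_pso(50, m = 2, gamma = 2.5, temperature = 0.3, seed = 1)
#' layer_stats(g$net)
#' @export
grow_pso <- function(n_nodes, m, gamma, temperature = 0.3, seed = 1L,
                     communities = NULL) {
  if (gamma <= 2) stop("gamma must be > 2", call. = FALSE)
  if (temperature < 0) stop("temperature must be >= 0", call. = FALSE)
  if (m < 1 || n_nodes <= m + 1) {
    stop("need n_nodes > m + 1 with m >= 1 (the network must be larger ",
         "than the per-node link budget)", call. = FALSE)
  }
  beta <- 1 / (gamma - 1)

  .with_seed(seed, {
    theta <- if (is.null(communities)) {
      stats::runif(n_nodes, 0, 2 * pi)
    } else {
      .npso_angles(n_nodes, communities)
    }
    r_birth <- 2 * log(seq_len(n_nodes))
    from <- integer(0); to <- integer(0)
    for (t in 2:n_nodes) {
      s <- seq_len(t - 1L)
      r_s <- beta * r_birth[s] + (1 - beta) * r_birth[t]
      x <- hyperbolic_distance(r_birth[t], theta[t], r_s, theta[s])
      k <- min(m, t - 1L)
      tgt <- if (t - 1L <= m) {
        s
      } else if (temperature == 0) {
        s[order(x, s)][seq_len(k)]
      } else {
        Rt <- .calibrate_cutoff(x, k, temperature)
        w <- fermi_dirac_probability(x, Rt, temperature)
        sample(s, k, prob = pmax(w, 1e-300))
      }
      from <- c(from, rep.int(t, k)); to <- c(to, tgt)
    }
    coords <- tibble::tibble(node = seq_len(n_nodes),
                             r = beta * r_birth +
                               (1 - beta) * 2 * log(n_nodes),
                             theta = theta)
    attr(coords, "R") <- 2 * log(n_nodes)
    attr(coords, "temperature") <- temperature
    attr(coords, "gamma") <- gamma
    attr(coords, "provenance") <- "generator"
    net <- as_multiplex(tibble::tibble(layer = 1L, from = from, to = to),
                        nodes = seq_len(n_nodes))
    list(net = net, coords = coords)
  })
}

# bisection: find R with sum_j p(x_j; R, T) = k
.calibrate_cutoff <- function(x, k, T_) {
  lo <- min(x) - 40 * T_ - 1
  hi <- max(x) + 40 * T_ + 1
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (sum(fermi_dirac_probability(x, mid, T_)) < k) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# equal-weight wrapped-normal mixture, centers equally spaced, sd = pi/(2C)
.npso_angles <- function(n, C) {
  centers <- 2 * pi * (seq_len(C) - 1) / C
  comp <- sample.int(C, n, replace = TRUE)
  wrap_angle(stats::rnorm(n, mean = centers[comp], sd = pi / (2 * C)))
}

# evaluate expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Grow a correlated synthetic multiplex
#'
#' Layer 1 is a PSO network; every further layer copies layer 1 and rewires a
#' fraction of its edges to uniformly random non-edges. `rewire_fraction`
#' tunes the interlayer link overlap monotonically: 0 gives identical layers
#' (overlap 1), 1 gives nearly edge-disjoint layers on sparse networks. Edge
#' counts are preserved in every layer. Used to study how interlayer
#' information helps link prediction when layers are partially redundant.
#'
#' @inheritParams grow_pso
#' @param n_layers Number of layers (`>= 1`).
#' @param rewire_fraction Fraction of layer-1 edges rewired in each copy,
#'   in `[0, 1]`.
#' @return A list with `net` (a `multiplex` with `n_layers` layers) and
#'   `coords` (true coordinates of layer 1).
#' @export
grow_multiplex <- function(n_nodes, m, gamma, temperature = 0.3,
                           n_layers = 2L, rewire_fraction = 0.3, seed = 1L,
                           communities = NULL) {
  stopifnot(n_layers >= 1L, rewire_fraction >= 0, rewire_fraction <= 1)
  base <- grow_pso(n_nodes, m, gamma, temperature, seed = seed,
                   communities = communities)
  e1 <- layer_edges(base$net, 1L)
  layers <- list(e1)
  .with_seed(seed + 1L, {
    for (l in seq_len(n_layers - 1L)) {
      layers[[l + 1L]] <- .rewire_edges(e1, n_nodes, rewire_fraction)
    }
  })
  edges <- purrr::map_dfr(seq_along(layers), function(l) {
    tibble::tibble(layer = l, from = layers[[l]]$from, to = layers[[l]]$to)
  })
  net <- as_multiplex(edges, nodes = seq_len(n_nodes),
                      layer_names = as.character(seq_len(n_layers)))
  list(net = net, coords = base$coords)
}

.rewire_edges <- function(e, n, frac) {
  E <- nrow(e)
  n_rw <- round(frac * E)
  if (n_rw == 0L) return(e)
  key <- function(i, j) (pmin(i, j) - 1) * n + pmax(i, j)
  present <- new.env(hash = TRUE)
  for (k in key(e$from, e$to)) assign(as.character(k), TRUE, present)
  drop <- sample.int(E, n_rw)
  keep_from <- e$from[-drop]; keep_to <- e$to[-drop]
  for (k in key(e$from[drop], e$to[drop])) rm(list = as.character(k),
                                              envir = present)
  new_from <- integer(n_rw); new_to <- integer(n_rw)
  for (q in seq_len(n_rw)) {
    repeat {
      ij <- sample.int(n, 2L)
      k <- as.character(key(ij[1], ij[2]))
      if (!exists(k, present, inherits = FALSE)) {
        assign(k, TRUE, present)
        new_from[q] <- min(ij); new_to[q] <- max(ij)
        break
      }
    }
  }
  out <- tibble::tibble(from = c(keep_from, new_from),
                        to = c(keep_to, new_to))
  dplyr::arrange(out, .data$from, .data$to)
}
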