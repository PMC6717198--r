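#' Estimate the power-law degree exponent (discrete MLE)
#'
#' Clauset-style maximum-likelihood estimate of the tail exponent of the
#' degree distribution,
#' \deqn{\hat\gamma = 1 + n \left[\sum_i \ln\frac{k_i}{k_{\min} - 1/2}\right]^{-1},}
#' over the `n` degrees with \eqn{k_i \ge k_{\min}}. When `k_min` is `NULL`
#' it is chosen by minimizing the Kolmogorov-Smirnov distance between the
#' empirical tail and the fitted power law over all candidate cutoffs (the
#' standard continuous approximation
#' \eqn{P(K \ge k) = ((k - 1/2)/(k_{\min} - 1/2))^{1-\gamma}} is used for the
#' model CDF).
#'
#' @param net A `multiplex` object.
#' @param layer Layer index.
#' @param k_min Tail cutoff; `NULL` selects it by KS minimization.
#' @return The estimate \eqn{\hat\gamma > 1} (a single number).
#' @export
estimate_gamma <- function(net, layer = 1L, k_min = NULL) {
  e <- layer_edges(net, layer)
  deg <- tabulate(c(e$from, e$to), nbins = n_nodes(net))
  .gamma_mle(deg, k_min)
}

.gamma_mle <- function(deg, k_min = NULL) {
  deg <- deg[deg >= 1]
  if (!is.null(k_min)) {
    tail_deg <- deg[deg >= k_min]
    .check_tail(tail_deg)
    return(1 + length(tail_deg) / sum(log(tail_deg / (k_min - 0.5))))
  }
  cands <- sort(unique(deg))
  cands <- cands[vapply(cands, function(k) sum(deg >= k) >= 10, TRUE)]
  if (length(cands) == 0L) {
    stop("fewer than 10 tail degrees at every cutoff; pass k_min explicitly",
         call. = FALSE)
  }
  ks <- vapply(cands, function(km) {
    td <- sort(deg[deg >= km])
    if (length(unique(td)) < 2L) return(Inf)
    g <- 1 + length(td) / sum(log(td / (km - 0.5)))
    emp <- seq_along(td) / length(td)
    model <- 1 - ((td - 0.5) / (km - 0.5))^(1 - g)
    max(abs(emp - model))
  }, 0)
  if (all(!is.finite(ks))) {
    stop("degenerate degree tail (all degrees equal); exponent diverges",
         call. = FALSE)
  }
  km <- cands[which.min(ks)]
  td <- deg[deg >= km]
  .check_tail(td)
  1 + length(td) / sum(log(td / (km - 0.5)))
}

.check_tail <- function(td) {
  if (length(td) < 10L) {
    stop("fewer than 10 degrees above k_min; pass a smaller k_min",
         call. = FALSE)
  }
  if (length(unique(td)) < 2L) {
    stop("degenerate degree tail (all degrees equal); exponent diverges",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Embed one layer in the hyperbolic disk by likelihood maximization
#'
#' A HyperMap-style embedding. Radial coordinates encode popularity: nodes
#' are sorted by decreasing degree (ties by ascending id) and the node of
#' rank `t` gets \eqn{r_t = 2\beta\ln t + 2(1-\beta)\ln N} with
#' \eqn{\beta = 1/(\gamma - 1)} — the replay of the generator's fading
#' schedule implied by \eqn{r_i \sim \ln N - \ln k_i}. The disk radius is
#' \eqn{R = 2\ln N} (overridable). Angular coordinates encode similarity and
#' are inferred by coordinate ascent on the global log-likelihood
#' \deqn{\log L = \sum_{i<j} a_{ij}\log p(x_{ij}) +
#'   (1-a_{ij})\log(1 - p(x_{ij})),}
#' with the Fermi-Dirac `p`. Angles are initialized deterministically from
#' the two leading non-trivial eigenvectors of the symmetrically normalized
#' adjacency matrix (\eqn{\theta_i = \mathrm{atan2}(v_{3i}, v_{2i})}, rotated
#' so the highest-degree node sits at \eqn{\theta = 0}); a purely sequential
#' greedy placement proved prone to poor local optima, whereas the spectral
#' start recovers the coarse angular order and the likelihood then refines
#' it. Refinement: `sweeps` full passes re-optimize every node's angle in
#' turn over a uniform grid of `grid_size` candidate angles, maximizing the
#' node's local log-likelihood against all other placed nodes. Ties on the
#' grid are broken toward the smallest angle, so the embedding is fully
#' deterministic. The global log-likelihood is non-decreasing across sweeps
#' (each update is a conditional maximization and the current angle is
#' always among the candidates).
#'
#' Nodes of degree 0 carry no angular information; they are pinned at
#' \eqn{r = 2\ln N, \theta = 0} and flagged. They never affect the relative
#' ranking of link candidates among observed nodes.
#'
#' @param net A `multiplex` object.
#' @param layer Layer index to embed.
#' @param gamma Power-law exponent (`> 2`), e.g. from [estimate_gamma()].
#' @param temperature Temperature `T > 0`, e.g. from [estimate_temperature()].
#' @param grid_size Number of candidate angles; default `max(360, N)`.
#' @param sweeps Refinement passes after the spectral initialization
#'   (default 1).
#' @param R Disk radius override; default \eqn{2\ln N}.
#' @return A coordinate tibble (`node`, `r`, `theta`, `flagged`) with
#'   attributes `R`, `temperature`, `gamma`, `provenance = "inferred"`, and
#'   `log_likelihood` (the trajectory across sweeps).
#' @export
embed_layer <- function(net, layer = 1L, gamma, temperature,
                        grid_size = NULL, sweeps = 1L, R = NULL) {
  if (gamma <= 2) stop("gamma must be > 2", call. = FALSE)
  if (temperature <= 0) stop("temperature must be > 0", call. = FALSE)
  n <- n_nodes(net)
  if (is.null(grid_size)) grid_size <- max(360L, n)
  if (is.null(R)) R <- 2 * log(n)
  beta <- 1 / (gamma - 1)

  A <- layer_adjacency(net, layer)
  deg <- colSums(A)
  ord <- order(-deg, seq_len(n))          # decreasing degree, ties by id
  rank_of <- match(seq_len(n), ord)
  r <- 2 * beta * log(rank_of) + 2 * (1 - beta) * log(n)
  flagged <- deg == 0
  r[flagged] <- 2 * log(n)

  grid <- 2 * pi * (seq_len(grid_size) - 1) / grid_size
  active <- ord[!flagged[ord]]
  theta <- .spectral_angles(A)
  theta[flagged] <- 0
  # canonical rotation: highest-degree node at theta = 0
  if (length(active) >= 1L) {
    theta <- wrap_angle(theta - theta[active[1L]])
  }

  ll_trace <- .total_ll(r, theta, A, R, temperature)
  if (sweeps > 0L && length(active) >= 2L) {
    for (s in seq_len(sweeps)) {
      for (i in active) {
        others <- setdiff(active, i)
        ll <- ll_candidate_angles(grid, r[i], r[others], theta[others],
                                  as.integer(A[i, others]), R, temperature)
        theta[i] <- grid[which.max(ll)]
      }
      ll_trace <- c(ll_trace, .total_ll(r, theta, A, R, temperature))
    }
  }

  coords <- tibble::tibble(node = seq_len(n), r = r, theta = theta,
                           flagged = flagged)
  attr(coords, "R") <- R
  attr(coords, "temperature") <- temperature
  attr(coords, "gamma") <- gamma
  attr(coords, "provenance") <- "inferred"
  attr(coords, "log_likelihood") <- ll_trace
  coords
}

# deterministic angular initialization: atan2 over the two leading
# non-trivial eigenvectors of D^{-1/2} A D^{-1/2} (mapped back to the
# random-walk eigenvectors); constant 0 for graphs too small to have them
.spectral_angles <- function(A) {
  n <- nrow(A)
  if (n < 3L || sum(A) == 0) return(numeric(n))
  dg <- pmax(colSums(A), 1)
  S <- t(A / sqrt(dg)) / sqrt(dg)
  ev <- eigen(S, symmetric = TRUE)
  v <- ev$vectors[, 2:3, drop = FALSE] / sqrt(dg)
  wrap_angle(atan2(v[, 2L], v[, 1L]))
}

# global Bernoulli log-likelihood of an embedding (upper triangle)
.total_ll <- function(r, theta, A, R, T_) {
  x <- .hyperbolic_distance_full(r, theta)
  lp <- .fd_logp(x[upper.tri(x)], R, T_)
  a <- A[upper.tri(A)]
  sum(a * lp$logp + (1 - a) * lp$log1mp)
}

#' Estimate the model temperature by synthetic matching
#'
#' For each candidate temperature, grows `replicates` PSO networks matched to
#' the layer's size, mean degree (`m = round(mean degree / 2)`) and exponent
#' `gamma`, and measures the discrepancy
#' `|mean clustering difference| + KS distance between degree distributions`
#' (equal weights). Returns the candidate with the smallest mean discrepancy;
#' ties go to the smaller temperature.
#'
#' @param net A `multiplex` object.
#' @param layer Layer index.
#' @param gamma Power-law exponent used for the matched synthetic networks.
#' @param t_grid Candidate temperatures in (0, 1]; default `seq(0.1, 0.9, 0.1)`.
#' @param replicates Synthetic networks grown per candidate (default 3).
#' @param seed Integer seed for the synthetic growth.
#' @return The selected temperature (one of `t_grid`).
#' @export
estimate_temperature <- function(net, layer = 1L, gamma,
                                 t_grid = seq(0.1, 0.9, by = 0.1),
                                 replicates = 3L, seed = 1L) {
  stopifnot(length(t_grid) >= 1L, all(t_grid > 0), all(t_grid <= 1))
  t_grid <- sort(t_grid)
  n <- n_nodes(net)
  if (n < 3L) stop("layer too small for temperature matching", call. = FALSE)
  st <- layer_stats(net)[layer, ]
  if (st$n_edges == 0L) stop("empty layer: no clustering/degrees to match",
                             call. = FALSE)
  m <- max(1L, round(st$mean_degree / 2))
  e <- layer_edges(net, layer)
  deg_obs <- tabulate(c(e$from, e$to), nbins = n)
  cc_obs <- st$mean_clustering

  disc <- vapply(seq_along(t_grid), function(ti) {
    mean(vapply(seq_len(replicates), function(rep) {
      g <- grow_pso(n, m, gamma, t_grid[ti],
                    seed = seed + 1000L * ti + rep)
      gs <- layer_stats(g$net)
      eg <- layer_edges(g$net, 1L)
      deg_syn <- tabulate(c(eg$from, eg$to), nbins = n)
      abs(gs$mean_clustering - cc_obs) + .ks_distance(deg_obs, deg_syn)
    }, 0))
  }, 0)
  t_grid[which.min(disc)]
}

# two-sample KS distance between empirical CDFs (integer samples)
.ks_distance <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  Fa <- stats::ecdf(a)(grid)
  Fb <- stats::ecdf(b)(grid)
  max(abs(Fa - Fb))
}

#' Read / write a coordinate table
#'
#' Plain-text format: comment header lines `# R <v>`, `# temperature <v>`,
#' `# gamma <v>`, `# provenance <v>`, then `node r theta` records (angles in
#' radians).
#'
#' @param path File path.
#' @return For `read_coordinates`, a coordinate tibble as produced by
#'   [embed_layer()].
#' @export
read_coordinates <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  recs <- strsplit(trimws(body), "\\s+")
  if (any(lengths(recs) < 3L)) stop("malformed coordinate record",
                                    call. = FALSE)
  coords <- tibble::tibble(
    node = as.integer(vapply(recs, `[`, "", 1L)),
    r = as.numeric(vapply(recs, `[`, "", 2L)),
    theta = as.numeric(vapply(recs, `[`, "", 3L)))
  for (h in hdr) {
    toks <- strsplit(sub("^#\\s*", "", h), "\\s+")[[1]]
    if (length(toks) >= 2 && toks[1] %in% c("R", "temperature", "gamma")) {
      attr(coords, toks[1]) <- as.numeric(toks[2])
    } else if (length(toks) >= 2 && toks[1] == "provenance") {
      attr(coords, "provenance") <- toks[2]
    }
  }
  coords
}

#' @rdname read_coordinates
#' @param coords A coordinate tibble.
#' @export
write_coordinates <- function(coords, path) {
  hdr <- c("# node coordinate table (node r theta)",
           sprintf("# R %.12g", attr(coords, "R") %||% NA_real_),
           sprintf("# temperature %.12g",
                   attr(coords, "temperature") %||% NA_real_),
           sprintf("# gamma %.12g", attr(coords, "gamma") %||% NA_real_),
           sprintf("# provenance %s",
                   attr(coords, "provenance") %||% "unknown"))
  body <- sprintf("%d %.12g %.12g", coords$node, coords$r, coords$theta)
  writeLines(c(hdr, body), path)
  invisible(path)
}
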