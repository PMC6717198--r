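#' Angular separation of two angles on the circle
#'
#' \eqn{\Delta\theta_{ij} = \pi - |\pi - |\theta_i - \theta_j||}, the shorter
#' arc between two directions. Inputs are wrapped into \eqn{[0, 2\pi)} first;
#' the result lies in \eqn{[0, \pi]} and is symmetric.
#'
#' @param theta_i,theta_j Angles in radians (vectorized).
#' @return Angular separation(s) in \eqn{[0, \pi]}.
#' @export
angular_separation <- function(theta_i, theta_j) {
  d <- abs(wrap_angle(theta_i) - wrap_angle(theta_j))
  pi - abs(pi - d)
}

#' Wrap angles into [0, 2*pi)
#' @param theta Angles in radians.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(theta) theta %% (2 * pi)

#' Circular rank correlation between two angle sets
#'
#' Mardia's rank statistic \eqn{\Pi} for circular-circular association:
#' both angle sets are replaced by their uniform circular ranks
#' \eqn{\beta_i = 2\pi R_i / n} and
#' \eqn{\Pi = \max(A^2 + B^2, A'^2 + B'^2)/n^2} with
#' \eqn{A = \sum\cos(\beta_{a,i} - \beta_{b,i})},
#' \eqn{B = \sum\sin(\beta_{a,i} - \beta_{b,i})} (primed: sums of the
#' angle *sums*, covering reflections). The result is in `[0, 1]`,
#' invariant to rotation and reflection, and — unlike moment-based circular
#' correlations — robust to monotone warping of either angular marginal,
#' which likelihood embeddings routinely introduce. 1 means the circular
#' arrangement is identical.
#'
#' @param a,b Angle vectors in radians, same length.
#' @return A number in `[0, 1]`.
#' @export
circular_rank_correlation <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3)
  n <- length(a)
  ra <- 2 * pi * rank(wrap_angle(a), ties.method = "first") / n
  rb <- 2 * pi * rank(wrap_angle(b), ties.method = "first") / n
  direct <- sum(cos(ra - rb))^2 + sum(sin(ra - rb))^2
  reflected <- sum(cos(ra + rb))^2 + sum(sin(ra + rb))^2
  max(direct, reflected) / n^2
}

#' Hyperbolic distance between points of the hyperbolic disk
#'
#' Points are given in native polar coordinates (radius, angle). The exact
#' geodesic distance is
#' \deqn{x_{ij} = \mathrm{arccosh}(\cosh r_i \cosh r_j -
#'   \sinh r_i \sinh r_j \cos\Delta\theta_{ij}),}
#' small when the two nodes are popular (small radii) and/or similar (small
#' angular separation). Two large-distance approximations are provided for
#' study (the scoring functions always use the exact form):
#' `mode = "approx"` is \eqn{r_i + r_j + 2\ln\sin(\Delta\theta/2)} and
#' `mode = "approx_log"` the cruder \eqn{r_i + r_j + 2\ln(\Delta\theta/2)};
#' both can go negative for tiny \eqn{\Delta\theta} (not clamped), and at
#' \eqn{\Delta\theta = 0}, where they are undefined, the exact value is
#' returned instead (with a message).
#'
#' @param r_i,theta_i,r_j,theta_j Polar coordinates (vectorized).
#' @param mode `"exact"` (default), `"approx"` or `"approx_log"`.
#' @return Distance(s); exact mode is symmetric and nonnegative.
#' @export
hyperbolic_distance <- function(r_i, theta_i, r_j, theta_j,
                                mode = c("exact", "approx", "approx_log")) {
  mode <- match.arg(mode)
  dth <- angular_separation(theta_i, theta_j)
  # stable rearrangement of cosh r_i cosh r_j - sinh r_i sinh r_j cos(dth):
  # cosh(r_i - r_j) + sinh r_i sinh r_j (1 - cos dth) avoids catastrophic
  # cancellation at small separations and is >= 1 analytically
  arg <- cosh(r_i - r_j) + sinh(r_i) * sinh(r_j) * 2 * sin(dth / 2)^2
  exact <- acosh(pmax(1, arg))
  if (mode == "exact") return(exact)
  ang <- if (mode == "approx") sin(dth / 2) else dth / 2
  out <- r_i + r_j + 2 * log(ang)
  zero <- dth == 0
  if (any(zero)) {
    message("approx mode undefined at Δθ = 0 for ", sum(zero),
            " pair(s); exact value substituted")
    out <- rep_len(out, length(exact))
    out[zero] <- exact[zero]
  }
  out
}

#' Fermi-Dirac connection probability
#'
#' \eqn{p(x) = 1 / (1 + e^{(x - R)/(2T)})}: the probability that a pair at
#' hyperbolic distance `x` is linked, given disk radius `R` and temperature
#' `T`. Strictly decreasing in `x` with \eqn{p(R) = 1/2}; `T` controls how
#' sharp the connection boundary is (and hence the clustering of the model).
#'
#' @param x Hyperbolic distance(s).
#' @param R Disk radius (the half-probability distance).
#' @param T_ Temperature, strictly positive. The `T = 0` step-function limit
#'   must be handled by the caller (nearest-neighbor attachment); it is an
#'   error here.
#' @return Probabilities in (0, 1).
#' @export
fermi_dirac_probability <- function(x, R, T_) {
  if (any(T_ <= 0)) stop("temperature must be > 0 (T = 0 is the step limit)",
                         call. = FALSE)
  1 / (1 + exp((x - R) / (2 * T_)))
}

# stable log p and log(1 - p) for the Fermi-Dirac form
.fd_logp <- function(x, R, T_) {
  z <- (x - R) / (2 * T_)
  logp <- ifelse(z > 0, -z - log1p(exp(-z)), -log1p(exp(z)))
  list(logp = logp, log1mp = logp + z)
}

#' Pairwise hyperbolic distances from a coordinate table
#'
#' @param coords A coordinate table as returned by [embed_layer()] or
#'   [grow_pso()]: columns `node`, `r`, `theta`.
#' @param pairs Optional tibble of pairs (`i`, `j`); default all unordered
#'   pairs of the coordinate table's nodes.
#' @return A score table tibble (`i`, `j`, `score`) of exact distances, with
#'   `orientation = "lower_is_link"` (small distance means link-like).
#' @export
distance_matrix <- function(coords, pairs = NULL) {
  coords <- .check_coords(coords)
  if (is.null(pairs)) pairs <- all_pairs(nrow(coords))
  pairs <- .check_pairs(pairs, nrow(coords))
  d <- hyperbolic_distance(coords$r[pairs$i], coords$theta[pairs$i],
                           coords$r[pairs$j], coords$theta[pairs$j])
  new_score_table(pairs, d, measure = "hyperbolic_distance",
                  orientation = "lower_is_link")
}

# full N x N exact distance matrix (dense; used by scorers and binning);
# same cancellation-free rearrangement as hyperbolic_distance()
.hyperbolic_distance_full <- function(r, theta) {
  sh <- sinh(r)
  dr <- outer(r, r, "-")
  hs <- sin(outer(theta, theta, "-") / 2)^2
  arg <- cosh(dr) + tcrossprod(sh) * 2 * hs
  arg[arg < 1] <- 1
  x <- acosh(arg)
  diag(x) <- 0
  x
}

.check_coords <- function(coords) {
  stopifnot(is.data.frame(coords),
            all(c("node", "r", "theta") %in% names(coords)))
  coords <- tibble::as_tibble(coords)
  if (any(!is.finite(coords$r)) || any(coords$r < 0)) {
    stop("radii must be finite and >= 0", call. = FALSE)
  }
  coords$theta <- wrap_angle(coords$theta)
  coords[order(coords$node), ]
}

.check_pairs <- function(pairs, n) {
  if (is.matrix(pairs)) pairs <- tibble::tibble(i = pairs[, 1], j = pairs[, 2])
  stopifnot(is.data.frame(pairs), all(c("i", "j") %in% names(pairs)))
  pairs <- tibble::as_tibble(pairs)[c("i", "j")]
  ii <- pmin(pairs$i, pairs$j); jj <- pmax(pairs$i, pairs$j)
  if (any(ii < 1 | jj > n)) stop("pair refers to unknown node id",
                                 call. = FALSE)
  if (any(ii == jj)) stop("self-pairs are not allowed", call. = FALSE)
  tibble::tibble(i = ii, j = jj)
}
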