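#' @title Wind loads and fracture
#' @description Winds are uniform and horizontal. Every foliage feels a
#'   drag `0.5 * C_Y * (U/U0)^2 * S_fol` (drag coefficient 1) at its
#'   center and every segment a drag proportional to its frontal area and
#'   the squared sine of the angle to the wind, at its midpoint. Loads are
#'   folded from the leaves to the root; the surface bending stress at a
#'   segment base is `(32/pi) * |M_base x t| / d^3`. Stresses are in
#'   units of the wood strength `sigma0`, so fracture statistics depend on
#'   the wind only through the Cauchy number.
#' @name wind-mechanics
NULL

#' Wind forces on a tree
#'
#' Per-foliage and per-segment drag forces and their application points,
#' for a wind of speed `U` along the horizontal unit vector `u`.
#'
#' @param tree a `wt_tree`.
#' @param U wind speed in units of `U0`.
#' @param u horizontal unit 3-vector (wind direction).
#' @param params a [wt_params()] object.
#' @return A list with `foliage` (twig index, force matrix, application
#'   points) and `segment` (force matrix, midpoints).
#' @export
wind_forces <- function(tree, U, u, params = wt_params()) {
  if (abs(sum(u^2) - 1) > 1e-9 || abs(u[3]) > 1e-9)
    stop("u must be a horizontal unit vector")
  q <- 0.5 * params$C_Y * (U / params$U0)^2
  fol <- foliage_centers(tree, params)
  Ffol <- matrix(q * params$S_fol * u, length(fol$twig), 3, byrow = TRUE)
  tcu <- cbind(tree$t[, 2] * u[3] - tree$t[, 3] * u[2],
               tree$t[, 3] * u[1] - tree$t[, 1] * u[3],
               tree$t[, 1] * u[2] - tree$t[, 2] * u[1])
  s <- sqrt(rowSums(tcu^2))
  nv <- tcu / ifelse(s > 1e-12, s, 1)
  nxt <- cbind(nv[, 2] * tree$t[, 3] - nv[, 3] * tree$t[, 2],
               nv[, 3] * tree$t[, 1] - nv[, 1] * tree$t[, 3],
               nv[, 1] * tree$t[, 2] - nv[, 2] * tree$t[, 1])
  mag <- ifelse(s > 1e-12, q * tree$d * params$L * s^2, 0)
  list(
    foliage = list(twig = fol$twig, force = Ffol, point = fol$center),
    segment = list(force = nxt * mag,
                   point = tree$base + 0.5 * params$L * tree$t))
}

#' Propagate wind loads to every segment base
#'
#' Leaf-to-root accumulation of forces and moments: `F_base = F_segment +
#' F_top` and `M_base = M_segment + M_top + L t x F_top`, where the `top`
#' quantities sum the children's base loads and the foliage drag of
#' twigs.
#'
#' @inheritParams wind_forces
#' @return A list (`LoadState`) with `F_base`, `M_base` (`n x 3`
#'   matrices) and `sigma` (bending stress per segment, units `sigma0`).
#' @export
propagate_loads <- function(tree, U, u, params = wt_params()) {
  cpp_tree_loads(tree$parent, tree$t, tree$d, is_twig(tree),
                 U / params$U0, as.numeric(u), params$C_Y, params$S_fol,
                 params$L)
}

#' Surface bending stress at a segment base
#' @param M_base moment 3-vector at the base (units `sigma0 L^3`).
#' @param t unit axis vector of the segment.
#' @param d segment diameter.
#' @return `sigma = (32/pi) |M_base x t| / d^3`.
#' @export
bending_stress <- function(M_base, t, d) {
  if (d <= 0) stop("d must be positive")
  mxt <- c(M_base[2] * t[3] - M_base[3] * t[2],
           M_base[3] * t[1] - M_base[1] * t[3],
           M_base[1] * t[2] - M_base[2] * t[1])
  (32 / pi) * sqrt(sum(mxt^2)) / d^3
}

#' Maximal sensed stress over wind orientations
#'
#' The stress input of the secondary-growth policy: the maximum bending
#' stress over `n_wind_orientations` azimuths (45 degrees apart by
#' default) at the reference speed `U0`. The result and the associated
#' bending-moment norm are cached on the tree (`sigma_rel`, `m_bend`).
#'
#' @param tree a `wt_tree`.
#' @param params a [wt_params()] object.
#' @return The tree with updated `sigma_rel` and `m_bend` fields.
#' @export
max_stress <- function(tree, params = wt_params()) {
  ms <- cpp_max_stress(tree$parent, tree$t, tree$d, is_twig(tree),
                       params$C_Y, params$S_fol, params$L,
                       params$n_wind_orientations)
  tree$sigma_rel <- ms$sigma_max
  tree$m_bend <- ms$m_bend
  tree
}

#' Sample a yearly storm
#'
#' Storm speed is exponential, calibrated so winds exceeding
#' `gust_factor * U0` have the configured return period:
#' `P(U > gust_factor * U0) = 1 / return_period`, i.e. rate
#' `log(return_period) / (gust_factor * U0)`. The azimuth is uniform.
#'
#' @param params a [wt_params()] object.
#' @return A list with `U` (speed) and `azimuth` (radians).
#' @export
sample_wind <- function(params = wt_params()) {
  rate <- log(params$return_period) / (params$gust_factor * params$U0)
  list(U = rexp(1, rate), azimuth = runif(1, 0, 2 * pi))
}

#' Weibull fracture probability of a segment
#'
#' `P = 1 - exp(-(V / V0) * (sigma / strength_factor)^m)`: the weakest-
#' link volume effect of brittle fracture. Maintenance weakening divides
#' the effective strength by the segment's strength factor.
#'
#' @param sigma bending stress in units of `sigma0` (vectorised).
#' @param V segment volume (vectorised).
#' @param strength_factor maintenance weakening state in `(0, 1]`.
#' @param params a [wt_params()] object.
#' @return Fracture probability in `[0, 1]`.
#' @examples
#' fracture_probability(1, wt_params()$V0) # 1 - exp(-1)
#' @export
fracture_probability <- function(sigma, V, strength_factor = 1,
                                 params = wt_params()) {
  if (any(sigma < 0) || any(V < 0)) stop("sigma and V must be >= 0")
  1 - exp(-(V / params$V0) * (sigma / strength_factor)^params$m)
}

#' Apply one storm to a tree
#'
#' Stresses are evaluated once at the storm speed and azimuth; each
#' segment then fractures independently with its Weibull probability, and
#' segments weakened below the shedding threshold fall regardless of the
#' load. The root-most fractured segments take their whole subtrees down
#' (no load redistribution within a single storm); losing the trunk kills
#' the tree.
#'
#' @param tree a `wt_tree`.
#' @param U storm speed.
#' @param azimuth storm azimuth in radians.
#' @param params a [wt_params()] object.
#' @return A list with the pruned `tree`, the removed wood `volume` and
#'   `n_removed` segments.
#' @export
apply_storm_tree <- function(tree, U, azimuth, params = wt_params()) {
  n <- n_segments(tree)
  u <- c(cos(azimuth), sin(azimuth), 0)
  lo <- propagate_loads(tree, U, u, params)
  V <- pi * params$L * tree$d^2 / 4
  P <- fracture_probability(lo$sigma, V, tree$strength, params)
  broken <- (runif(n) < P) | tree$strength <= params$strength_shed_threshold
  if (!any(broken))
    return(list(tree = tree, volume = 0, n_removed = 0L))
  res <- drop_segments(tree, which(broken), params)
  list(tree = res$tree, volume = res$volume,
       n_removed = n - n_segments(res$tree))
}
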