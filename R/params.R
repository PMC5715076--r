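#' Simulation parameters
#'
#' Collects every model constant of the simulator in one validated list.
#' Lengths are measured in units of the segment length `L`, wind speeds in
#' units of the average yearly-maximal wind `U0`, and stresses in units of
#' the wood strength `sigma0`; all three are therefore 1 internally and the
#' only mechanical constant that matters is the Cauchy number
#' `C_Y = rho * U0^2 / sigma0`.
#'
#' @param L segment length (reference length; keep at 1).
#' @param d0 diameter of newly grown twigs.
#' @param alpha_fol optical transparency of a foliage, in `[0, 1]`.
#' @param C_Y Cauchy number, ratio of dynamic wind pressure to wood
#'   strength.
#' @param prod_coeff photosynthate volume produced by a fully lit foliage,
#'   in units of `V0` (production is `prod_coeff * V0 * l`).
#' @param e thickness of the outer layer renewed yearly by maintenance.
#' @param S_fol foliage sail area in strong winds.
#' @param m Weibull modulus of wood fracture.
#' @param R island (forest) radius.
#' @param p_mut per-gene mutation probability.
#' @param delta_g mutation amplitude.
#' @param delta_theta standard deviation of branching-angle noise, degrees.
#' @param U0 average yearly-maximal wind speed (reference; keep at 1).
#' @param gust_factor storms exceeding `gust_factor * U0` have return
#'   period `return_period`.
#' @param return_period return period (years) used to calibrate the
#'   exponential storm-speed distribution.
#' @param max_age age at which a tree dies of senescence.
#' @param juvenile_age age above which the minimum-size death rule applies.
#' @param min_segments minimum segment count for trees older than
#'   `juvenile_age`.
#' @param seed_cost carbon cost of one seed, in volume units (initial
#'   reserve + first sprout + dissemination).
#' @param initial_reserve reserve volume of a freshly germinated seedling.
#' @param n_sky_angles number of equal solid angles tiling the upper
#'   hemisphere for light interception.
#' @param n_wind_orientations number of wind azimuths scanned when
#'   computing the maximal sensed stress.
#' @param nn_gain gain of the tanh hidden layer of both growth networks.
#' @param strength_decay multiplier applied to the strength factor of an
#'   unmaintained segment (linearly relaxed towards 1 with the maintenance
#'   fraction).
#' @param strength_recovery multiplier applied when maintenance is fully
#'   paid (capped at 1).
#' @param strength_shed_threshold strength factor below which a branch
#'   falls regardless of the load.
#'
#' @return An object of class `wt_params`: a named list of constants, with
#'   the derived twig volume `V0 = pi * L * d0^2 / 4`.
#' @examples
#' p <- wt_params()
#' p$V0 # about 0.0079 L^3
#' @export
wt_params <- function(L = 1, d0 = 0.1 * L, alpha_fol = 0.5, C_Y = 2e-5,
                      prod_coeff = 4, e = 0.02 * L, S_fol = 0.25 * L^2,
                      m = 10, R = 40 * L, p_mut = 0.05, delta_g = 0.005,
                      delta_theta = 10, U0 = 1, gust_factor = 1.5,
                      return_period = 100, max_age = 1000,
                      juvenile_age = 6, min_segments = 10,
                      seed_cost = 5, initial_reserve = 2,
                      n_sky_angles = 32, n_wind_orientations = 8,
                      nn_gain = 5, strength_decay = 0.5,
                      strength_recovery = 1.25,
                      strength_shed_threshold = 0.05) {
  p <- list(L = L, d0 = d0, V0 = pi * L * d0^2 / 4, alpha_fol = alpha_fol,
            C_Y = C_Y, prod_coeff = prod_coeff, e = e, S_fol = S_fol,
            m = m, R = R, p_mut = p_mut, delta_g = delta_g,
            delta_theta = delta_theta, U0 = U0, gust_factor = gust_factor,
            return_period = return_period, max_age = max_age,
            juvenile_age = juvenile_age, min_segments = min_segments,
            seed_cost = seed_cost, initial_reserve = initial_reserve,
            n_sky_angles = n_sky_angles,
            n_wind_orientations = n_wind_orientations, nn_gain = nn_gain,
            strength_decay = strength_decay,
            strength_recovery = strength_recovery,
            strength_shed_threshold = strength_shed_threshold)
  scalars <- setdiff(names(p), character(0))
  for (nm in scalars) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar")
  }
  if (p$alpha_fol < 0 || p$alpha_fol > 1)
    stop("alpha_fol must lie in [0, 1]")
  if (p$d0 >= p$L) stop("twig diameter d0 must be smaller than L")
  pos <- c("L", "d0", "C_Y", "prod_coeff", "e", "S_fol", "m", "R",
           "delta_theta", "U0", "gust_factor", "return_period", "max_age",
           "seed_cost", "initial_reserve", "n_sky_angles",
           "n_wind_orientations", "nn_gain")
  for (nm in pos) if (p[[nm]] <= 0) stop("parameter '", nm,
                                         "' must be strictly positive")
  class(p) <- "wt_params"
  p
}

#' @export
print.wt_params <- function(x, ...) {
  cat("Simulation parameters (lengths in L, speeds in U0, stresses in",
      "sigma0)\n")
  cat(sprintf("  twig diameter d0 = %.3g, twig volume V0 = %.4g L^3\n",
              x$d0, x$V0))
  cat(sprintf("  foliage: transparency %.2f, sail area %.3g L^2\n",
              x$alpha_fol, x$S_fol))
  cat(sprintf("  Cauchy number %.3g, Weibull modulus %g\n", x$C_Y, x$m))
  cat(sprintf("  island radius %g L; mutation p = %.3g, amplitude %.3g\n",
              x$R, x$p_mut, x$delta_g))
  invisible(x)
}
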