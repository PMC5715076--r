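#' @title Analytical scaling model
#' @description A closed-form counterpart of the simulator, built from
#'   three of its emergent properties: tree skeletons are self-similar
#'   with branching ratio `R_n` and fractal dimension `D` (so the length
#'   ratio is `R_l = R_n^(1/D)`); and the wind safety factor `S` is
#'   constant, which pins the relative bending stress of every branch at
#'   `S^(-3/2)` and hence fixes the diameter ratio
#'   `R_d = R_n^((D+1)/(3D))`. From these, the allometric exponents and
#'   prefactors linking height, foliage number and stem biomass to trunk
#'   diameter follow in closed form.
#' @name analytical-scaling-model
NULL

#' Parameters of the analytical scaling model
#'
#' @param alpha1 ratio of the base-to-foliage distance to the path
#'   length.
#' @param alpha2 mean wind-projection factor of randomly oriented
#'   branches (the vertical trunk is `alpha2^(-1/3)` thicker than
#'   predicted for a random orientation).
#' @param R_n Strahler branching ratio.
#' @param D fractal dimension of the skeleton, in `(1, 3]`.
#' @param S wind safety factor.
#' @param S_fol foliage sail area, units `L^2`.
#' @param C_Y Cauchy number.
#' @param L_m segment length in metres (for SI conversions).
#' @param rho_wood dry wood density, kg m^-3.
#' @param m_fol dry mass of one foliage, kg.
#' @return A `wt_asm_params` list.
#' @export
asm_params <- function(alpha1 = 0.5, alpha2 = 0.5, R_n = 3.5, D = 2.5,
                       S = 3, S_fol = 0.25, C_Y = 2e-5, L_m = 0.1,
                       rho_wood = 613, m_fol = 0.0018) {
  if (D <= 1 || D > 3) stop("D must lie in (1, 3]")
  if (R_n <= 1) stop("R_n must exceed 1")
  if (S < 1) stop("S must be >= 1")
  structure(list(alpha1 = alpha1, alpha2 = alpha2, R_n = R_n, D = D,
                 S = S, S_fol = S_fol, C_Y = C_Y, L_m = L_m,
                 rho_wood = rho_wood, m_fol = m_fol),
            class = "wt_asm_params")
}

#' Allometric exponents predicted from the fractal dimension
#'
#' `beta_H = 3/(D+1)`, `beta_N = 3D/(D+1)`, `beta_B = (2D+5)/(D+1)` and
#' `beta_ML = 3D/(2D+5)`; note `beta_ML = beta_N / beta_B` identically.
#'
#' @param D fractal dimension.
#' @return Named vector of the four exponents.
#' @examples
#' round(asm_exponents(2.5), 2) # 0.86 2.14 2.86 0.75
#' @export
asm_exponents <- function(D) {
  if (D <= -1) stop("D must exceed -1")
  c(beta_H = 3 / (D + 1), beta_N = 3 * D / (D + 1),
    beta_B = (2 * D + 5) / (D + 1), beta_ML = 3 * D / (2 * D + 5))
}

#' Self-similar ratios predicted from `R_n` and `D`
#'
#' `R_l = R_n^(1/D)`, `R_d = R_n^((D+1)/(3D))`, `R_a = R_d^2`.
#'
#' @param R_n branching ratio.
#' @param D fractal dimension.
#' @return Named vector `c(R_l, R_d, R_a)`.
#' @export
asm_ratios <- function(R_n = 3.5, D = 2.5) {
  if (R_n <= 1) stop("R_n must exceed 1")
  R_l <- R_n^(1 / D)
  R_d <- R_n^((D + 1) / (3 * D))
  c(R_l = R_l, R_d = R_d, R_a = R_d^2)
}

#' Rank-1 branch diameter and trunk-corrected value
#'
#' The thinnest (rank-1) branch diameter satisfying the constant-safety
#' condition, `d_1^3 = (16 alpha S^(3/2) / pi) C_Y S_fol R_l L /
#' (R_l - 1)` with `alpha = alpha1 alpha2`; the always-vertical trunk is
#' `alpha2^(-1/3)` thicker, `d_1' = alpha2^(-1/3) d_1`.
#'
#' @param params an [asm_params()] object.
#' @return Named vector `c(d1, d1prime)` in units of `L`.
#' @export
asm_base_diameter <- function(params = asm_params()) {
  rt <- asm_ratios(params$R_n, params$D)
  R_l <- rt[["R_l"]]
  if (R_l <= 1) stop("R_l must exceed 1")
  alpha <- params$alpha1 * params$alpha2
  d1 <- ((16 * alpha * params$S^1.5 / pi) * params$C_Y * params$S_fol *
           R_l / (R_l - 1))^(1 / 3)
  c(d1 = d1, d1prime = params$alpha2^(-1 / 3) * d1)
}

#' Branch diameters per Strahler rank
#' @param params an [asm_params()] object.
#' @param k rank(s).
#' @return `d_k = d_1 R_d^(k-1)` in units of `L`.
#' @export
asm_rank_diameter <- function(params = asm_params(), k = 1) {
  d1 <- asm_base_diameter(params)[["d1"]]
  d1 * asm_ratios(params$R_n, params$D)[["R_d"]]^(k - 1)
}

#' Relative bending stress per rank (closed-loop consistency)
#'
#' Evaluates `sigma_k / sigma0 = (16 alpha / pi) C_Y S_fol N_k l_k /
#' d_k^3` with `N_k = R_n^(k-1)`, the self-similar path length
#' `l_k = L R_l^k / (R_l - 1)` and the constant-safety diameters; the
#' result equals `S^(-3/2)` at every rank.
#'
#' @param params an [asm_params()] object.
#' @param k rank(s).
#' @return `sigma_k / sigma0`.
#' @export
asm_stress_consistency <- function(params = asm_params(), k = 1) {
  rt <- asm_ratios(params$R_n, params$D)
  R_l <- rt[["R_l"]]
  alpha <- params$alpha1 * params$alpha2
  N_k <- params$R_n^(k - 1)
  ell_k <- R_l^k / (R_l - 1)
  d_k <- asm_rank_diameter(params, k)
  (16 * alpha / pi) * params$C_Y * params$S_fol * N_k * ell_k / d_k^3
}

#' Allometric prefactors of the closed-form model
#'
#' Prefactors `c_H`, `c_N`, `c_B` of `H = c_H L (d/L)^beta_H`,
#' `N = c_N (d/L)^beta_N` and `B = c_B L^3 (d/L)^beta_B`, with `d` the
#' trunk diameter. The reference diameter dividing the trunk diameter in
#' the closed forms may be the plain rank-1 diameter `d1` (the default,
#' which reproduces the model's printed numeric prefactors) or the
#' trunk-corrected `d1prime`.
#'
#' @param params an [asm_params()] object.
#' @param reference `"d1"` or `"d1prime"`.
#' @return Named vector `c(c_H, c_N, c_B)`.
#' @export
asm_prefactors <- function(params = asm_params(),
                           reference = c("d1", "d1prime")) {
  reference <- match.arg(reference)
  rt <- asm_ratios(params$R_n, params$D)
  R_l <- rt[["R_l"]]
  R_d <- rt[["R_d"]]
  if (R_d^2 * R_l <= params$R_n)
    stop("divergent geometric sum: R_d^2 R_l must exceed R_n")
  be <- asm_exponents(params$D)
  dd <- asm_base_diameter(params)
  d1 <- dd[["d1"]]
  dref <- dd[[reference]]
  c(c_H = (R_l / (R_l - 1)) * dref^(-be[["beta_H"]]),
    c_N = dref^(-be[["beta_N"]]),
    c_B = (pi / 4) * d1^2 * R_d^2 * R_l / (R_d^2 * R_l - params$R_n) *
      dref^(-be[["beta_B"]]))
}

#' Stem volume of a K-rank tree: explicit sum and closed form
#'
#' The explicit rank sum `B = (pi/4) sum_k R_n^(K-k) d_k^2 l_k` is a
#' geometric series; the closed form keeps its dominant term, so the two
#' differ by the relative amount `(R_n / (R_d^2 R_l))^K`, which decays
#' as `R_n^(K (D-5)/(3D))`.
#'
#' @param params an [asm_params()] object.
#' @param K number of Strahler ranks.
#' @return Named vector with `sum` (explicit), `closed` (power-law
#'   form) and `rel_diff` (units of `L^3`).
#' @export
asm_biomass <- function(params = asm_params(), K = 8) {
  rt <- asm_ratios(params$R_n, params$D)
  dd <- asm_base_diameter(params)
  d1 <- dd[["d1"]]
  ks <- seq_len(K)
  dk <- d1 * rt[["R_d"]]^(ks - 1)
  lk <- rt[["R_l"]]^(ks - 1)
  expl <- (pi / 4) * sum(params$R_n^(K - ks) * dk^2 * lk)
  be <- asm_exponents(params$D)
  x <- rt[["R_d"]]^2 * rt[["R_l"]]
  d_trunk <- dd[["d1prime"]] * rt[["R_d"]]^(K - 1)
  closed <- (pi / 4) * d1^2 * x / (x - params$R_n) *
    (d_trunk / dd[["d1prime"]])^be[["beta_B"]]
  c(sum = expl, closed = closed, rel_diff = (closed - expl) / closed)
}

#' SI-unit allometric relations
#'
#' Converts the closed forms to metres and kilograms: the coefficients
#' of `H = cH_si d^beta_H`, `M_L = cML_si d^beta_N` (leaf mass from
#' `m_fol` per foliage) and `M_L = cMLMS_si M_S^beta_ML` (stem dry mass
#' `M_S = rho_wood B`).
#'
#' @param params an [asm_params()] object.
#' @param reference reference diameter, as in [asm_prefactors()].
#' @return Named vector `c(cH_si, cML_si, cMLMS_si, beta_H, beta_N,
#'   beta_ML)`.
#' @export
asm_si <- function(params = asm_params(), reference = c("d1", "d1prime")) {
  reference <- match.arg(reference)
  be <- asm_exponents(params$D)
  cf <- asm_prefactors(params, reference)
  L <- params$L_m
  cH <- cf[["c_H"]] * L^(1 - be[["beta_H"]])
  cML <- params$m_fol * cf[["c_N"]] * L^(-be[["beta_N"]])
  cB_si <- params$rho_wood * cf[["c_B"]] * L^(3 - be[["beta_B"]])
  cMLMS <- cML * cB_si^(-be[["beta_ML"]])
  c(cH_si = cH, cML_si = cML, cMLMS_si = cMLMS,
    beta_H = be[["beta_H"]], beta_N = be[["beta_N"]],
    beta_ML = be[["beta_ML"]])
}

#' Elasticities of the closed-form constants to model parameters
#'
#' Dimensionless sensitivities `s = (p / y) dy/dp` of the four exponents
#' and three prefactors with respect to the Cauchy number and the
#' foliage transparency, taking the fractal dimension to depend linearly
#' on transparency, `D = 2 + alpha_fol`. Exponents depend on the
#' parameters only through `D`, so their Cauchy-number sensitivities
#' vanish; derivatives are evaluated analytically for the exponents and
#' by central differences of the exact closed forms for the prefactors.
#'
#' @param params an [asm_params()] object; its `D` is overridden by
#'   `2 + alpha_fol`.
#' @param alpha_fol reference foliage transparency.
#' @return A matrix of sensitivities (rows: beta_H, beta_N, beta_B,
#'   beta_ML, c_H, c_N, c_B; columns: C_Y, alpha_fol).
#' @export
asm_sensitivities <- function(params = asm_params(), alpha_fol = 0.5) {
  D0 <- 2 + alpha_fol
  p0 <- params
  p0$D <- D0
  be <- asm_exponents(D0)
  dbe_dD <- c(beta_H = -3 / (D0 + 1)^2, beta_N = 3 / (D0 + 1)^2,
              beta_B = -3 / (D0 + 1)^2,
              beta_ML = 15 / (2 * D0 + 5)^2)
  s_beta_a <- alpha_fol * dbe_dD / be      # dD/dalpha_fol = 1
  pref <- function(CY, af) {
    p <- p0
    p$C_Y <- CY
    p$D <- 2 + af
    asm_prefactors(p)
  }
  h <- 1e-6
  dc_dCY <- (pref(params$C_Y * (1 + h), alpha_fol) -
               pref(params$C_Y * (1 - h), alpha_fol)) /
    (2 * h * params$C_Y)
  dc_da <- (pref(params$C_Y, alpha_fol + h) -
              pref(params$C_Y, alpha_fol - h)) / (2 * h)
  c0 <- pref(params$C_Y, alpha_fol)
  out <- rbind(cbind(C_Y = rep(0, 4), alpha_fol = s_beta_a),
               cbind(C_Y = params$C_Y * dc_dCY / c0,
                     alpha_fol = alpha_fol * dc_da / c0))
  rownames(out) <- c(names(be), names(c0))
  out
}

#' Exponent/ratio/prefactor table of the analytical model
#'
#' A compact comparison table of the model's predictions, handy for
#' printing or export.
#'
#' @param params an [asm_params()] object.
#' @return A one-row `data.frame` with exponents, ratios, base diameters
#'   and prefactors.
#' @export
asm_table <- function(params = asm_params()) {
  be <- asm_exponents(params$D)
  rt <- asm_ratios(params$R_n, params$D)
  dd <- asm_base_diameter(params)
  cf <- asm_prefactors(params)
  si <- asm_si(params)
  data.frame(as.list(c(be, rt, dd, cf, si[1:3])))
}
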