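#' Macroscopic summary of a tree
#'
#' Height is the highest segment distal end; crown radius is
#' `sqrt(var_x + var_y)` of the foliage centers projected onto the
#' ground (population variances); biomass is the total wood volume.
#'
#' @param tree a `wt_tree`.
#' @param params a [wt_params()] object.
#' @return A one-row `data.frame` with `H`, `C`, `N`, `B`, `d_trunk`,
#'   `age`, `x`, `y`.
#' @export
tree_summary <- function(tree, params = wt_params()) {
  fol <- foliage_centers(tree, params)
  nf <- length(fol$twig)
  pvar <- function(v) mean((v - mean(v))^2)
  C <- if (nf > 0) sqrt(pvar(fol$center[, 1]) + pvar(fol$center[, 2]))
       else NA_real_
  data.frame(
    H = if (n_segments(tree)) max(distal_ends(tree, params)[, 3]) else 0,
    C = C, N = nf, B = tree_volume(tree, params),
    d_trunk = if (n_segments(tree)) tree$d[1] else NA_real_,
    age = tree$age, x = tree$pos[1], y = tree$pos[2])
}

#' Per-rank branch table
#'
#' Branches are maximal runs of contiguous equal-rank segments. For every
#' Strahler rank: the number of branches, their mean length (segments
#' times `L`), mean diameter and mean cross-sectional area, with standard
#' deviations.
#'
#' @param tree a `wt_tree`.
#' @param params a [wt_params()] object.
#' @return A `data.frame` with one row per rank.
#' @export
rank_table <- function(tree, params = wt_params()) {
  so <- strahler_orders(tree)
  br <- so$branch
  len <- tabulate(br) * params$L
  dmean <- as.vector(tapply(tree$d, br, mean))
  amean <- as.vector(tapply(pi * tree$d^2 / 4, br, mean))
  brank <- as.vector(tapply(so$rank, br, `[`, 1))
  out <- do.call(rbind, lapply(sort(unique(brank)), function(k) {
    sel <- brank == k
    data.frame(rank = k, n = sum(sel),
               length = mean(len[sel]), length_sd = stats::sd(len[sel]),
               d = mean(dmean[sel]), d_sd = stats::sd(dmean[sel]),
               a = mean(amean[sel]), a_sd = stats::sd(amean[sel]))
  }))
  out
}

#' Self-similar ratios and fractal dimension of a tree
#'
#' Fits geometric progressions (linear regressions of log quantity
#' against rank, over the first `max_rank` ranks) to the per-rank branch
#' counts, lengths, diameters and areas, giving the branching ratio
#' `R_n`, length ratio `R_l`, diameter ratio `R_d` and area ratio `R_a`.
#' The fractal dimension is `D = log(R_n) / log(R_l)`, with a confidence
#' interval propagated from the two slope standard errors (independent
#' normal propagation).
#'
#' @param tree a `wt_tree`.
#' @param max_rank use at most this many leading ranks (default 7).
#' @param level coverage of the confidence interval for `D` (default
#'   0.8).
#' @param params a [wt_params()] object.
#' @return A list with `R_n`, `R_l`, `R_d`, `R_a`, `D`, `D_ci`,
#'   `n_ranks` and the underlying `table`; all `NA` (and `ok = FALSE`)
#'   with fewer than 3 ranks.
#' @export
self_similar_ratios <- function(tree, max_rank = 7, level = 0.8,
                                params = wt_params()) {
  tab <- rank_table(tree, params)
  tab <- tab[tab$rank <= max_rank, ]
  if (nrow(tab) < 3)
    return(list(ok = FALSE, R_n = NA, R_l = NA, R_d = NA, R_a = NA,
                D = NA, D_ci = c(NA, NA), n_ranks = nrow(tab),
                table = tab))
  slope <- function(y) {
    fit <- lm(log(y) ~ tab$rank)
    # vcov is NaN-free but warns on numerically perfect fits
    se <- suppressWarnings(sqrt(vcov(fit)[2, 2]))
    c(unname(coef(fit)[2]), se)
  }
  sn <- slope(tab$n)
  sl <- slope(tab$length)
  sd_ <- slope(tab$d)
  sa <- slope(tab$a)
  a <- -sn[1]          # log R_n
  b <- sl[1]           # log R_l
  D <- a / b
  varD <- (sn[2] / b)^2 + (a * sl[2] / b^2)^2
  z <- qnorm(1 - (1 - level) / 2)
  list(ok = TRUE, R_n = exp(a), R_l = exp(b), R_d = exp(sd_[1]),
       R_a = exp(sa[1]), D = D,
       D_ci = D + c(-1, 1) * z * sqrt(varD),
       n_ranks = nrow(tab), table = tab)
}

#' Tapering profile of a tree
#'
#' For every segment, the mean path length to its descendant foliages
#' (number of segments along each path times `L`, measured from the
#' segment base) against its diameter.
#'
#' @param tree a `wt_tree`.
#' @param params a [wt_params()] object.
#' @return A `data.frame` with `mean_path` and `d` per segment.
#' @export
tapering_profile <- function(tree, params = wt_params()) {
  n <- n_segments(tree)
  depth <- cpp_cum_from_root(tree$parent, matrix(1, n, 1))[, 1]
  tw <- as.numeric(is_twig(tree))
  acc <- cpp_acc_to_root(tree$parent, cbind(tw * depth, tw))
  mean_depth <- acc[, 1] / acc[, 2]
  data.frame(mean_path = params$L * (mean_depth - depth + 1), d = tree$d)
}

#' Leonardo's rule: area ratios across branching nodes
#'
#' For every two-child node, the ratio of the children's summed
#' cross-sectional area to the parent's, together with the parent's mean
#' path length to its foliages. Mean ratios are reported for parents
#' farther than 1.5 and 10 segment lengths from their foliages.
#'
#' @param tree a `wt_tree`.
#' @param params a [wt_params()] object.
#' @return A list with the per-node `table` and the threshold means
#'   `mean_above_1.5` and `mean_above_10`.
#' @export
leonardo_ratios <- function(tree, params = wt_params()) {
  nodes <- which(child_counts(tree) == 2L)
  tp <- tapering_profile(tree, params)
  child_a <- vapply(nodes, function(i)
    sum(tree$d[tree$parent == i]^2), numeric(1))
  tab <- data.frame(node = nodes, mean_path = tp$mean_path[nodes],
                    ratio = child_a / tree$d[nodes]^2)
  list(table = tab,
       mean_above_1.5 = mean(tab$ratio[tab$mean_path > 1.5 * params$L]),
       mean_above_10 = mean(tab$ratio[tab$mean_path > 10 * params$L]))
}

#' Effective number and effective biomass of a stand
#'
#' `N_eff = (sum B)^2 / sum B^2` is the inverse probability that two
#' units of mass taken at random come from the same tree; `M_eff = sum
#' B^2 / sum B` is the biomass-weighted mean biomass. For `n` equal
#' trees these reduce to the count and the common biomass.
#'
#' @param biomasses positive biomass vector, one entry per tree.
#' @return Named vector `c(N_eff, M_eff)`.
#' @examples
#' effective_numbers(c(1, 3)) # 1.6, 2.5
#' @export
effective_numbers <- function(biomasses) {
  if (length(biomasses) == 0) stop("empty biomass vector")
  tot <- sum(biomasses)
  b2 <- sum(biomasses^2)
  c(N_eff = tot^2 / b2, M_eff = b2 / tot)
}

wstats <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x)
  my <- sum(w * y)
  list(mx = mx, my = my,
       sxx = sum(w * (x - mx)^2), syy = sum(w * (y - my)^2),
       sxy = sum(w * (x - mx) * (y - my)),
       n_eff = 1 / sum(w^2))
}

new_allofit <- function(slope, intercept, se, n_eff, r, method,
                        level) {
  ci <- slope + c(-1, 1) * qt(1 - (1 - level) / 2,
                              max(n_eff - 2, 1)) * se
  structure(list(slope = slope, intercept = intercept, se = se,
                 ci = ci, r = r, n_eff = n_eff, method = method,
                 level = level),
            class = "wt_allofit")
}

#' Weighted reduced-major-axis and least-squares line fits
#'
#' The standard symmetric fit of allometry: the RMA slope is the signed
#' ratio of the weighted standard deviations, `sign(cov) * sd_y / sd_x`;
#' the least-squares slope is the weighted regression slope. Confidence
#' intervals use the usual slope standard errors with the effective
#' sample size `(sum w)^2 / sum w^2`. Fits are invariant to input order
#' and to uniform rescaling of the weights. Callers pass
#' log-transformed data when fitting power laws.
#'
#' @param x,y numeric vectors.
#' @param w optional positive weights.
#' @param level confidence level (default 0.95).
#' @return A `wt_allofit` with `slope`, `intercept`, `se`, `ci`, `r`,
#'   `n_eff`, `method`.
#' @export
rma_fit <- function(x, y, w = NULL, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (is.null(w)) w <- rep(1, length(x)) else w <- w[ok]
  if (length(x) < 3) stop("need at least 3 points")
  s <- wstats(x, y, w)
  r <- s$sxy / sqrt(s$sxx * s$syy)
  slope <- sign(s$sxy) * sqrt(s$syy / s$sxx)
  if (s$sxy == 0) slope <- sqrt(s$syy / s$sxx)
  se <- abs(slope) * sqrt(max(0, 1 - r^2) / max(s$n_eff - 2, 1))
  new_allofit(slope, s$my - slope * s$mx, se, s$n_eff, r, "RMA", level)
}

#' @rdname rma_fit
#' @export
ls_fit <- function(x, y, w = NULL, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (is.null(w)) w <- rep(1, length(x)) else w <- w[ok]
  if (length(x) < 3) stop("need at least 3 points")
  s <- wstats(x, y, w)
  r <- s$sxy / sqrt(s$sxx * s$syy)
  slope <- s$sxy / s$sxx
  se <- sqrt(max(0, s$syy - slope * s$sxy) / max(s$n_eff - 2, 1) / s$sxx)
  new_allofit(slope, s$my - slope * s$mx, se, s$n_eff, r, "LS", level)
}

#' @export
print.wt_allofit <- function(x, ...) {
  cat(sprintf("%s fit: slope %.4g [%.4g, %.4g] (%d%% CI), intercept %.4g, r = %.3f, n_eff = %.1f\n",
              x$method, x$slope, x$ci[1], x$ci[2],
              round(100 * x$level), x$intercept, x$r, x$n_eff))
  invisible(x)
}

#' Forest-level allometric fits
#'
#' Reduced-major-axis fits of `log10 H`, `log10 C`, `log10 N` and
#' `log10 B` against `log10 d_trunk`, restricted to trees whose trunk
#' lies inside the central fraction of the island radius (edge trees grow
#' unrepresentatively large) and weighted by foliage count. The leaf-mass
#' exponent `beta_ML` comes from the RMA fit of `log10 N` on `log10 B`,
#' taking leaf mass proportional to the number of foliages.
#'
#' @param summaries a `data.frame` of [tree_summary()] rows.
#' @param R island radius used in the simulation.
#' @param central_fraction keep trunks with radius below
#'   `central_fraction * R`.
#' @param level confidence level for the fits.
#' @return A list of `wt_allofit`s: `H`, `C`, `N`, `B`, `ML`, plus
#'   `n_used`.
#' @export
forest_allometry <- function(summaries, R, central_fraction = 0.9,
                             level = 0.95) {
  rad <- sqrt(summaries$x^2 + summaries$y^2)
  s <- summaries[rad <= central_fraction * R & summaries$N >= 1 &
                   summaries$B > 0 & summaries$d_trunk > 0, ]
  ld <- log10(s$d_trunk)
  w <- s$N
  fit <- function(v) rma_fit(ld, log10(v), w, level)
  list(H = fit(s$H), C = fit(ifelse(s$C > 0, s$C, NA)),
       N = fit(s$N), B = fit(s$B),
       ML = rma_fit(log10(s$B), log10(s$N), w, level),
       n_used = nrow(s))
}

#' Self-thinning exponent from a stand trajectory
#'
#' Pooled weighted least-squares fit of `log10 M_eff` against `log10
#' N_eff` with `N_eff` as weight, as used for the stand-density/biomass
#' relation (slope near -3/2 for classical self-thinning).
#'
#' @param N_eff,M_eff effective numbers and biomasses (pooled over years
#'   and forests).
#' @param level confidence level.
#' @return A `wt_allofit`; its `slope` is the self-thinning exponent.
#' @export
self_thinning_fit <- function(N_eff, M_eff, level = 0.95) {
  ok <- is.finite(N_eff) & is.finite(M_eff) & N_eff > 0 & M_eff > 0
  if (sum(ok) < 3) stop("need at least 3 points")
  if (stats::sd(log10(N_eff[ok])) == 0)
    stop("degenerate trajectory: stand density never changes")
  ls_fit(log10(N_eff[ok]), log10(M_eff[ok]), w = N_eff[ok],
         level = level)
}

#' Sensitivity of an allometric constant to a model parameter
#'
#' The dimensionless elasticity `s = (p / beta) * d beta / d p` at a
#' reference parameter value, with the derivative estimated by linear
#' regression of the swept values.
#'
#' @param p swept parameter values.
#' @param beta corresponding allometric constants.
#' @param p_ref reference parameter value (default: median of the
#'   sweep).
#' @param beta_ref reference constant (default: the fit's prediction at
#'   `p_ref`).
#' @return The sensitivity `s`.
#' @export
sensitivity <- function(p, beta, p_ref = stats::median(p),
                        beta_ref = NULL) {
  if (length(p) < 2) stop("need at least 2 sweep points")
  fit <- lm(beta ~ p)
  slope <- coef(fit)[[2]]
  if (is.null(beta_ref)) beta_ref <- coef(fit)[[1]] + slope * p_ref
  p_ref * slope / beta_ref
}
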