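#' @title Carbon economy
#' @description Each foliage produces a photosynthate volume proportional
#'   to its intercepted light. Each segment expresses a sink: the volume
#'   still needed to reach its thigmomorphogenetic target (safety factor
#'   times the fracture volume) plus a yearly maintenance volume. Sinks
#'   are requested in equal shares from all foliages above; foliages pay
#'   in full when they can (banking the surplus in the tree's reserve) and
#'   proportionally otherwise. Received carbon pays maintenance first and
#'   thickens the segment with the remainder. Unmaintained segments lose
#'   strength and are eventually shed by the next storm.
#' @name carbon-economy
NULL

#' Photosynthate production of a foliage
#' @param l intercepted light in `[0, 1]` (vectorised).
#' @param params a [wt_params()] object.
#' @return Produced volume `prod_coeff * V0 * l`.
#' @export
production <- function(l, params = wt_params()) {
  if (any(l < 0 | l > 1)) stop("light must lie in [0, 1]")
  params$prod_coeff * params$V0 * l
}

#' Sink strength of every segment
#'
#' The fracture diameter satisfies `d_fract^3 = (32/pi) |M x t| /
#' sigma0` at the current worst-azimuth bending moment; the growth need
#' is the volume gap to `S` times the fracture volume, and maintenance
#' renews an outer layer of thickness `e`: `V_maint = pi L d e`.
#'
#' @param tree a `wt_tree` with current `m_bend` (see [max_stress()]).
#' @param S safety factor per segment (from [secondary_policy()]).
#' @param params a [wt_params()] object.
#' @return A list with vectors `need`, `maintenance` and `sink` (their
#'   sum).
#' @export
segment_sink <- function(tree, S, params = wt_params()) {
  d_fract <- ((32 / pi) * tree$m_bend)^(1 / 3)
  v_fract <- pi * params$L * d_fract^2 / 4
  v_now <- pi * params$L * tree$d^2 / 4
  need <- pmax(0, S * v_fract - v_now)
  maint <- pi * params$L * tree$d * params$e
  list(need = need, maintenance = maint, sink = need + maint)
}

#' Secondary growth: allocate photosynthates to maintenance and diameter
#'
#' Every segment splits its sink into equal requests to each of its
#' descendant foliages. A foliage whose production covers the total
#' requests it receives pays them in full and banks the leftover in the
#' reserve; otherwise it pays each request proportionally. What a segment
#' receives pays its maintenance first; the remainder grows its diameter.
#' Carbon is conserved exactly: total production equals maintenance paid
#' plus diameter-growth volume plus the reserve increase.
#'
#' @param tree a `wt_tree`.
#' @param prod production volume per foliage, aligned with
#'   `which(is_twig(tree))`.
#' @param S safety factor per segment.
#' @param params a [wt_params()] object.
#' @return A list with the updated `tree` and a `budget` record
#'   (`production`, `maintenance_paid`, `growth`, `reserve_gain`,
#'   `maintenance_fraction` per segment).
#' @export
allocate_secondary <- function(tree, prod, S, params = wt_params()) {
  n <- n_segments(tree)
  tw <- which(is_twig(tree))
  twig_ind <- matrix(0, n, 1)
  twig_ind[tw, 1] <- 1
  n_above <- cpp_acc_to_root(tree$parent, twig_ind)[, 1]
  sk <- segment_sink(tree, S, params)
  q <- sk$sink / n_above
  req <- cpp_cum_from_root(tree$parent, matrix(q, n, 1))[, 1]
  req_f <- req[tw]
  frac_f <- ifelse(req_f > 0, pmin(1, prod / req_f), 1)
  surplus <- sum(pmax(0, prod - req_f))
  fr <- matrix(0, n, 1)
  fr[tw, 1] <- frac_f
  received <- q * cpp_acc_to_root(tree$parent, fr)[, 1]
  maint_paid <- pmin(received, sk$maintenance)
  mfrac <- maint_paid / sk$maintenance
  growth <- received - maint_paid
  tree$d <- sqrt(tree$d^2 + 4 * growth / (pi * params$L))
  tree$reserve <- tree$reserve + surplus
  tree$strength <- update_strength(tree$strength, mfrac, params)
  list(tree = tree,
       budget = list(production = sum(prod),
                     maintenance_paid = sum(maint_paid),
                     growth = sum(growth),
                     reserve_gain = surplus,
                     maintenance_fraction = mfrac))
}

#' Update the maintenance-weakening state of segments
#'
#' A fully maintained segment recovers strength by the factor
#' `strength_recovery` (capped at 1); an under-maintained one decays by
#' `strength_decay + (1 - strength_decay) * fraction`. A few fully
#' unmaintained years push the factor below the shedding threshold.
#'
#' @param strength current strength factors in `(0, 1]`.
#' @param fraction maintenance fraction paid this year, in `[0, 1]`.
#' @param params a [wt_params()] object.
#' @return Updated strength factors.
#' @export
update_strength <- function(strength, fraction, params = wt_params()) {
  a <- params$strength_decay
  ifelse(fraction >= 1, pmin(1, strength * params$strength_recovery),
         strength * (a + (1 - a) * fraction))
}

# Pick `k` twigs without replacement: each slot takes the best-lit unused
# twig with probability p, otherwise a uniformly random unused twig.
select_twigs <- function(twigs, light, k, p) {
  chosen <- integer(k)
  avail <- seq_along(twigs)
  for (i in seq_len(k)) {
    if (runif(1) < p) {
      j <- avail[which.max(light[avail])]
    } else {
      j <- avail[sample.int(length(avail), 1)]
    }
    chosen[i] <- twigs[j]
    avail <- avail[avail != j]
  }
  chosen
}

#' Primary growth: spend the reserve on new segments and seeds
#'
#' `n_seg = floor(P_seg * V_res / V0)` segments and `n_seed =
#' floor(P_seed * V_res / seed_cost)` seeds are funded from the reserve.
#' Segments are added in pairs to twigs selected by the photosensitivity
#' rule (an odd remainder grows a single child); a twig branches at most
#' once per year, so segment growth is capped at twice the twig count.
#' Seed twigs are selected by the same rule, independently and with
#' replacement.
#'
#' @param tree a `wt_tree`.
#' @param policy output of [primary_policy()].
#' @param params a [wt_params()] object.
#' @return A list with the grown `tree`, `n_seg`, `n_seed` and
#'   `seed_twigs` (segment indices whose foliage sheds each seed).
#' @export
primary_growth <- function(tree, policy, params = wt_params()) {
  V0 <- params$V0
  n_seg <- floor(policy[["P_seg"]] * tree$reserve / V0)
  n_seed <- floor(policy[["P_seed"]] * tree$reserve / (params$seed_cost * V0))
  p <- policy[["p"]]
  twigs <- which(is_twig(tree))
  n_seg <- min(n_seg, 2 * length(twigs))
  tree$reserve <- tree$reserve - n_seg * V0 -
    n_seed * params$seed_cost * V0
  seed_twigs <- integer(0)
  if (n_seed > 0) {
    light <- tree$light[twigs]
    seed_twigs <- vapply(seq_len(n_seed), function(i)
      select_twigs(twigs, light, 1, p), integer(1))
  }
  if (n_seg > 0) {
    light <- tree$light[twigs]
    n_sites <- ceiling(n_seg / 2)
    sites <- select_twigs(twigs, light, n_sites, p)
    n_child <- rep(2L, n_sites)
    if (n_seg %% 2 == 1) n_child[n_sites] <- 1L
    for (i in seq_len(n_sites))
      tree <- attach_children(tree, sites[i], n_child[i], params)
  }
  list(tree = tree, n_seg = n_seg, n_seed = n_seed,
       seed_twigs = seed_twigs)
}

#' Disperse a seed from a twig
#'
#' Seeds fall at 45 degrees from the vertical: the landing point lies at
#' a horizontal distance equal to the release height, at a uniformly
#' random azimuth. Seeds landing outside the island radius are lost.
#'
#' @param origin 3-vector, the releasing foliage center.
#' @param params a [wt_params()] object.
#' @return Landing position `c(x, y)`, or `NULL` if it falls outside the
#'   island.
#' @export
disperse_seed <- function(origin, params = wt_params()) {
  phi <- runif(1, 0, 2 * pi)
  h <- origin[3]
  pos <- origin[1:2] + h * c(cos(phi), sin(phi))
  if (sum(pos^2) > params$R^2) NULL else pos
}
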