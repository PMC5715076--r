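# Shared fixtures and independent pure-R oracles. The oracles deliberately
# use different algorithms from the package internals (recursion, explicit
# path walks, per-load summation) so that agreement is informative.

# Random tree grown by repeatedly branching random twigs; diameters get
# random (non-decreasing) thickening so loads are heterogeneous.
random_test_tree <- function(n_target, params = wt_params(),
                             genome = NULL) {
  if (is.null(genome)) genome <- random_genome()
  tr <- new_tree(genome, c(0, 0), params)
  while (n_segments(tr) < n_target) {
    tw <- which(is_twig(tr))
    pick <- tw[sample.int(length(tw), 1)]
    k <- if (n_segments(tr) + 2 <= n_target && runif(1) < 0.8) 2L else 1L
    tr <- attach_children(tr, pick, k, params)
  }
  tr$d <- tr$d * (1 + rexp(n_segments(tr), 2))
  # thicken ancestors so diameters are non-decreasing towards the root
  for (i in rev(seq_len(n_segments(tr)))) {
    p <- tr$parent[i]
    if (p > 0) tr$d[p] <- max(tr$d[p], tr$d[i])
  }
  tr
}

# Recursive Strahler definition, straight from the ordering rule.
oracle_strahler <- function(parent) {
  n <- length(parent)
  kids <- lapply(seq_len(n), function(i) which(parent == i))
  rec <- function(i) {
    ks <- kids[[i]]
    if (length(ks) == 0) return(1L)
    r <- vapply(ks, rec, integer(1))
    if (length(r) == 2 && r[1] == r[2]) r[1] + 1L else max(r)
  }
  vapply(seq_len(n), rec, integer(1))
}

# Brute-force base moments: for every applied load (foliage drag at its
# center, segment drag at its midpoint), walk up the ancestor chain and
# add (r - base_ancestor) x F.
oracle_moments <- function(tree, U, u, params = wt_params()) {
  wf <- wind_forces(tree, U, u, params)
  n <- n_segments(tree)
  M <- matrix(0, n, 3)
  add_load <- function(M, j, point, force) {
    i <- j
    while (i > 0) {
      r <- point - tree$base[i, ]
      M[i, ] <- M[i, ] + c(r[2] * force[3] - r[3] * force[2],
                           r[3] * force[1] - r[1] * force[3],
                           r[1] * force[2] - r[2] * force[1])
      i <- tree$parent[i]
    }
    M
  }
  for (j in seq_len(n))
    M <- add_load(M, j, wf$segment$point[j, ], wf$segment$force[j, ])
  for (k in seq_along(wf$foliage$twig))
    M <- add_load(M, wf$foliage$twig[k], wf$foliage$point[k, ],
                  wf$foliage$force[k, ])
  M
}

# Exhaustive path enumeration for the mean base-to-foliage path length.
oracle_mean_path <- function(tree, params = wt_params()) {
  n <- n_segments(tree)
  tw <- which(is_twig(tree))
  paths <- matrix(0, n, 2) # sum of path lengths, count
  for (f in tw) {
    chain <- integer(0)
    i <- f
    while (i > 0) {
      chain <- c(chain, i)
      i <- tree$parent[i]
    }
    # path length from ancestor a to foliage of twig f counts the
    # segments between a's base and the twig's distal end
    for (k in seq_along(chain)) {
      a <- chain[k]
      paths[a, 1] <- paths[a, 1] + k * params$L
      paths[a, 2] <- paths[a, 2] + 1
    }
  }
  paths[, 1] / paths[, 2]
}

# Per-direction occlusion oracle for light interception: explicit O(N^2)
# comparison of foliage pairs within each grid column.
oracle_light <- function(centers, params = wt_params(), sky = NULL) {
  if (is.null(sky)) sky <- sky_directions(params$n_sky_angles)
  n <- nrow(centers)
  l <- numeric(n)
  for (k in seq_len(nrow(sky$dir))) {
    d <- sky$dir[k, ]
    base <- windtree:::plane_basis(d)
    rot <- centers %*% base
    cx <- floor(rot[, 1] / params$L)
    cy <- floor(rot[, 2] / params$L)
    for (i in seq_len(n)) {
      above <- sum(cx == cx[i] & cy == cy[i] &
                     (rot[, 3] > rot[i, 3] |
                        (rot[, 3] == rot[i, 3] & seq_len(n) < i)))
      l[i] <- l[i] + sky$weight * params$alpha_fol^above
    }
  }
  l
}
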