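#' @title Tree architecture
#' @description Trees are rooted assemblies of cylindrical segments of
#'   common length `L` and varying diameter, each holding a unit axis
#'   vector `t` and a unit branching-plane normal `b`. Segments are stored
#'   in topological order (every parent precedes its children), which the
#'   growth and pruning operations preserve.
#' @name tree-architecture
NULL

unit3 <- function(v) v / sqrt(sum(v^2))

#' Rotate a vector about an axis
#'
#' Right-handed (counter-clockwise when looking down the axis towards the
#' origin) Rodrigues rotation; this sign convention is used for every
#' branching-angle rotation in the package.
#'
#' @param v 3-vector to rotate.
#' @param axis unit 3-vector rotation axis.
#' @param angle_deg rotation angle in degrees.
#' @return The rotated 3-vector.
#' @export
rotate_about <- function(v, axis, angle_deg) {
  th <- angle_deg * pi / 180
  k <- axis
  v * cos(th) + c(k[2] * v[3] - k[3] * v[2],
                  k[3] * v[1] - k[1] * v[3],
                  k[1] * v[2] - k[2] * v[1]) * sin(th) +
    k * sum(k * v) * (1 - cos(th))
}

#' Construct the local frames of two child segments
#'
#' Children grow in the plane normal to the parent's branching normal `b`:
#' their axes are `t` rotated about `b` by `theta1 + eps[1] * delta_theta`
#' and `theta2 + eps[2] * delta_theta`. The next-generation branching
#' normals are `b` rotated about each child axis by
#' `gamma + eps[3] * delta_theta`.
#'
#' @param t unit axis of the parent segment.
#' @param b unit branching-plane normal of the parent, orthogonal to `t`.
#' @param theta1,theta2 branching angles of the two children, degrees.
#' @param gamma phyllotactic rotation of the branching plane, degrees.
#' @param delta_theta standard deviation of the angle noise, degrees.
#' @param eps three standard-normal draws (drawn from the session RNG when
#'   missing).
#' @return A list of two frames, each `list(t = , b = )` with unit,
#'   mutually orthogonal vectors.
#' @examples
#' fr <- make_child_frames(c(0, 0, 1), c(1, 0, 0), 30, -30, 90,
#'                         delta_theta = 0)
#' fr[[1]]$t
#' @export
make_child_frames <- function(t, b, theta1, theta2, gamma,
                              delta_theta = 0, eps = NULL) {
  if (abs(sum(t^2) - 1) > 1e-9 || abs(sum(b^2) - 1) > 1e-9)
    stop("t and b must be unit vectors")
  if (abs(sum(t * b)) > 1e-9) stop("t and b must be orthogonal")
  if (is.null(eps)) eps <- rnorm(3)
  t1 <- unit3(rotate_about(t, b, theta1 + eps[1] * delta_theta))
  t2 <- unit3(rotate_about(t, b, theta2 + eps[2] * delta_theta))
  g <- gamma + eps[3] * delta_theta
  b1 <- unit3(rotate_about(b, t1, g))
  b2 <- unit3(rotate_about(b, t2, g))
  list(list(t = t1, b = b1), list(t = t2, b = b2))
}

#' Create a seedling
#'
#' A freshly germinated tree: one vertical segment of twig diameter with a
#' uniformly random horizontal branching normal.
#'
#' @param genome numeric vector of 34 genes in `[0, 1]`.
#' @param position ground position `c(x, y)` of the trunk.
#' @param params a [wt_params()] object.
#' @param lineage integer species marker inherited unchanged from the
#'   founding individual.
#' @param id integer tree identifier.
#' @return A `wt_tree` object.
#' @export
new_tree <- function(genome, position = c(0, 0), params = wt_params(),
                     lineage = 1L, id = 1L) {
  phi <- runif(1, 0, 2 * pi)
  tr <- list(
    parent = 0L,
    t = matrix(c(0, 0, 1), 1, 3),
    b = matrix(c(cos(phi), sin(phi), 0), 1, 3),
    base = matrix(c(position[1], position[2], 0), 1, 3),
    d = params$d0,
    year_created = 0L,
    strength = 1,
    light = 0,
    sigma_rel = 0,
    m_bend = 0,
    genome = genome,
    pos = c(position[1], position[2]),
    age = 0L,
    reserve = params$initial_reserve * params$V0,
    alive = TRUE,
    lineage = as.integer(lineage),
    id = as.integer(id)
  )
  class(tr) <- "wt_tree"
  tr
}

#' Number of segments of a tree
#' @param tree a `wt_tree`.
#' @return Integer count.
#' @export
n_segments <- function(tree) length(tree$parent)

#' Number of children of each segment
#' @param tree a `wt_tree`.
#' @return Integer vector of child counts (0, 1 or 2).
#' @export
child_counts <- function(tree) {
  tabulate(tree$parent, nbins = n_segments(tree))
}

#' Which segments are twigs (and therefore carry a foliage)
#' @param tree a `wt_tree`.
#' @return Logical vector.
#' @export
is_twig <- function(tree) child_counts(tree) == 0L

#' Distal end of every segment
#' @param tree a `wt_tree`.
#' @param params a [wt_params()] object.
#' @return `n x 3` matrix `base + L * t`.
#' @export
distal_ends <- function(tree, params = wt_params()) {
  tree$base + params$L * tree$t
}

#' Foliage centers of a tree
#'
#' One foliage sits at the distal end of every twig.
#'
#' @inheritParams distal_ends
#' @return List with `twig` (segment indices) and `center` (matrix).
#' @export
foliage_centers <- function(tree, params = wt_params()) {
  tw <- which(is_twig(tree))
  list(twig = tw, center = distal_ends(tree, params)[tw, , drop = FALSE])
}

#' Attach one or two child segments to a twig
#'
#' New segments of twig diameter are added at the distal end of a twig,
#' with frames from [make_child_frames()] decoded from the tree's genome
#' (the first frame when a single child is grown). The parent's foliage is
#' replaced by one foliage per child.
#'
#' @param tree a `wt_tree`.
#' @param twig_id index of the target segment, which must be a twig.
#' @param n_children 1 or 2.
#' @param params a [wt_params()] object.
#' @param eps optional three standard-normal draws for the angle noise.
#' @return The tree with the new segments appended.
#' @export
attach_children <- function(tree, twig_id, n_children = 2,
                            params = wt_params(), eps = NULL) {
  if (!n_children %in% c(1L, 2L)) stop("n_children must be 1 or 2")
  if (child_counts(tree)[twig_id] != 0L)
    stop("segment ", twig_id, " is not a twig")
  ang <- decode_genome(tree$genome)$angles
  fr <- make_child_frames(tree$t[twig_id, ], tree$b[twig_id, ],
                          ang[1], ang[2], ang[3],
                          delta_theta = params$delta_theta, eps = eps)
  base <- tree$base[twig_id, ] + params$L * tree$t[twig_id, ]
  for (k in seq_len(n_children)) {
    tree$parent <- c(tree$parent, as.integer(twig_id))
    tree$t <- rbind(tree$t, fr[[k]]$t)
    tree$b <- rbind(tree$b, fr[[k]]$b)
    tree$base <- rbind(tree$base, base)
    tree$d <- c(tree$d, params$d0)
    tree$year_created <- c(tree$year_created, tree$age)
    tree$strength <- c(tree$strength, 1)
    tree$light <- c(tree$light, 0)
    tree$sigma_rel <- c(tree$sigma_rel, 0)
    tree$m_bend <- c(tree$m_bend, 0)
  }
  dimnames(tree$t) <- dimnames(tree$b) <- dimnames(tree$base) <- NULL
  tree
}

#' Strahler orders and branch partition
#'
#' Terminal segments get rank 1; a parent whose two children share rank
#' `r` gets `r + 1`, otherwise the maximum child rank. A branch is a
#' maximal run of contiguous equal-rank segments.
#'
#' @param tree a `wt_tree`.
#' @return List with integer vectors `rank` and `branch` (branch id per
#'   segment).
#' @export
strahler_orders <- function(tree) {
  n <- n_segments(tree)
  rank <- cpp_strahler(tree$parent)
  branch <- integer(n)
  nb <- 0L
  for (i in seq_len(n)) {
    p <- tree$parent[i]
    if (p == 0L || rank[i] != rank[p]) {
      nb <- nb + 1L
      branch[i] <- nb
    } else {
      branch[i] <- branch[p]
    }
  }
  list(rank = rank, branch = branch)
}

subtree_members <- function(tree, segment_id) {
  flag <- matrix(0, n_segments(tree), 1)
  flag[segment_id, 1] <- 1
  which(cpp_cum_from_root(tree$parent, flag)[, 1] > 0)
}

#' Remove a segment and all its descendants
#'
#' The parent of the removed subtree becomes a twig and regains a foliage.
#' Removing the trunk empties the tree and marks it dead.
#'
#' @param tree a `wt_tree`.
#' @param segment_id index of the subtree root to remove.
#' @param params a [wt_params()] object.
#' @return List with the updated `tree` and the removed wood `volume`.
#' @export
remove_subtree <- function(tree, segment_id, params = wt_params()) {
  drop_segments(tree, segment_id, params)
}

# Remove the subtrees rooted at each of root_ids (assumed root-most, i.e.
# none is a descendant of another; extra descendants are harmless).
drop_segments <- function(tree, root_ids, params = wt_params()) {
  n <- n_segments(tree)
  if (any(root_ids < 1 | root_ids > n)) stop("no such segment")
  flag <- matrix(0, n, 1)
  flag[root_ids, 1] <- 1
  gone <- cpp_cum_from_root(tree$parent, flag)[, 1] > 0
  volume <- sum(pi * params$L * tree$d[gone]^2 / 4)
  keep <- !gone
  if (gone[1]) {
    tree$alive <- FALSE
    keep[] <- FALSE
  }
  remap <- cumsum(keep)
  old_par <- tree$parent[keep]
  new_par <- integer(length(old_par))
  nz <- old_par != 0L
  new_par[nz] <- remap[old_par[nz]]
  tree$parent <- new_par
  for (f in c("d", "year_created", "strength", "light", "sigma_rel",
              "m_bend"))
    tree[[f]] <- tree[[f]][keep]
  for (f in c("t", "b", "base"))
    tree[[f]] <- tree[[f]][keep, , drop = FALSE]
  list(tree = tree, volume = volume)
}

#' Total wood volume of a tree
#' @inheritParams distal_ends
#' @return Sum of `pi * L * d^2 / 4` over segments.
#' @export
tree_volume <- function(tree, params = wt_params()) {
  sum(pi * params$L * tree$d^2 / 4)
}

#' @export
print.wt_tree <- function(x, ...) {
  cat(sprintf(
    "<tree #%d> %d segments, %d foliages, age %d, reserve %.3g L^3%s\n",
    x$id, n_segments(x), sum(is_twig(x)), x$age, x$reserve,
    if (x$alive) "" else " (dead)"))
  invisible(x)
}

#' Serialise a tree's segment table
#'
#' One row per segment: index, parent index, axis, branching normal, base
#' position, diameter, creation year and strength factor. Reading back
#' restores topology exactly and floating-point fields to better than
#' 1e-12 relative.
#'
#' @param tree a `wt_tree`.
#' @return A `data.frame`.
#' @export
tree_to_table <- function(tree) {
  data.frame(
    id = seq_len(n_segments(tree)), parent = tree$parent,
    tx = tree$t[, 1], ty = tree$t[, 2], tz = tree$t[, 3],
    bx = tree$b[, 1], by = tree$b[, 2], bz = tree$b[, 3],
    x = tree$base[, 1], y = tree$base[, 2], z = tree$base[, 3],
    d = tree$d, year = tree$year_created, strength = tree$strength)
}

#' Rebuild a tree from its segment table
#' @param df a `data.frame` as produced by [tree_to_table()].
#' @param genome,position,params,lineage,id tree-level attributes, as in
#'   [new_tree()].
#' @return A `wt_tree`.
#' @export
tree_from_table <- function(df, genome = rep(0.5, 34),
                            position = c(df$x[1], df$y[1]),
                            params = wt_params(), lineage = 1L, id = 1L) {
  tr <- new_tree(genome, position, params, lineage, id)
  tr$parent <- as.integer(df$parent)
  tr$t <- as.matrix(df[, c("tx", "ty", "tz")])
  tr$b <- as.matrix(df[, c("bx", "by", "bz")])
  tr$base <- as.matrix(df[, c("x", "y", "z")])
  dimnames(tr$t) <- dimnames(tr$b) <- dimnames(tr$base) <- NULL
  tr$d <- df$d
  tr$year_created <- as.integer(df$year)
  tr$strength <- df$strength
  n <- nrow(df)
  tr$light <- tr$sigma_rel <- tr$m_bend <- numeric(n)
  tr
}

#' Write / read a segment table as CSV
#' @param tree a `wt_tree`.
#' @param path file path.
#' @return `write_tree_csv` returns `path` invisibly; `read_tree_csv`
#'   returns a `wt_tree`.
#' @export
write_tree_csv <- function(tree, path) {
  df <- tree_to_table(tree)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tree_csv
#' @param ... passed to [tree_from_table()].
#' @export
read_tree_csv <- function(path, ...) {
  tree_from_table(read.csv(path), ...)
}
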