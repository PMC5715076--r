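test_that("child frames follow the stated rotation convention", {
  t <- c(0, 0, 1)
  b <- c(1, 0, 0)
  # zero angles: identity
  fr <- make_child_frames(t, b, 0, 0, 0, delta_theta = 0)
  expect_equal(fr[[1]]$t, t)
  expect_equal(fr[[2]]$t, t)
  expect_equal(fr[[1]]$b, b)
  # right-handed 90-degree rotation of z about x gives -y
  fr <- make_child_frames(t, b, 90, -90, 0, delta_theta = 0)
  expect_equal(fr[[1]]$t, c(0, -1, 0), tolerance = 1e-12)
  expect_equal(fr[[2]]$t, c(0, 1, 0), tolerance = 1e-12)
  # independent Rodrigues oracle on random frames and angles
  set.seed(42)
  rodrigues <- function(v, k, th) {
    th <- th * pi / 180
    kx <- rbind(c(0, -k[3], k[2]), c(k[3], 0, -k[1]), c(-k[2], k[1], 0))
    as.vector((diag(3) + sin(th) * kx + (1 - cos(th)) * kx %*% kx) %*% v)
  }
  for (i in 1:25) {
    v <- rnorm(3)
    t0 <- v / sqrt(sum(v^2))
    w <- rnorm(3)
    w <- w - sum(w * t0) * t0
    b0 <- w / sqrt(sum(w^2))
    th <- runif(3, -180, 180)
    fr <- make_child_frames(t0, b0, th[1], th[2], th[3], delta_theta = 0)
    expect_equal(fr[[1]]$t, rodrigues(t0, b0, th[1]), tolerance = 1e-9)
    expect_equal(fr[[2]]$t, rodrigues(t0, b0, th[2]), tolerance = 1e-9)
    for (f in fr) {
      expect_equal(sum(f$t^2), 1, tolerance = 1e-9)
      expect_lt(abs(sum(f$t * f$b)), 1e-9)
    }
  }
  expect_error(make_child_frames(c(0, 0, 2), b, 0, 0, 0), "unit")
  expect_error(make_child_frames(t, t, 0, 0, 0), "orthogonal")
})

test_that("attaching children keeps counts, geometry and frame rule", {
  set.seed(1)
  p <- wt_params()
  tr <- new_tree(rep(0.5, 34), c(0, 0), p)
  expect_equal(sum(is_twig(tr)), 1)
  tr2 <- attach_children(tr, 1, 2, p, eps = c(0, 0, 0))
  expect_equal(n_segments(tr2), 3)
  expect_equal(sum(is_twig(tr2)), 2)
  # children sprout at the parent distal end with twig diameter
  expect_equal(tr2$base[2, ], distal_ends(tr, p)[1, ])
  expect_equal(tr2$d[2:3], rep(p$d0, 2))
  # single child takes the first frame of the rule
  ang <- decode_genome(tr$genome)$angles
  fr <- make_child_frames(tr$t[1, ], tr$b[1, ], ang[1], ang[2], ang[3],
                          delta_theta = 0)
  tr1 <- attach_children(tr, 1, 1, p, eps = c(0, 0, 0))
  expect_equal(tr1$t[2, ], fr[[1]]$t, tolerance = 1e-12)
  # internal segments refuse children
  expect_error(attach_children(tr2, 1, 2, p), "not a twig")
})

test_that("distal-end continuity holds after simulated growth", {
  set.seed(7)
  p <- wt_params(R = 5)
  fo <- init_forest(3, p)
  fo <- yearly_cycle(fo)
  fo <- yearly_cycle(fo)
  fo <- yearly_cycle(fo)
  for (tr in fo$trees) {
    ends <- distal_ends(tr, p)
    for (i in seq_len(n_segments(tr))) {
      pa <- tr$parent[i]
      if (pa > 0)
        expect_lt(max(abs(tr$base[i, ] - ends[pa, ])), 1e-9 * p$L)
    }
    expect_true(all(tabulate(tr$parent) <= 2))
  }
})

test_that("Strahler ranks match the recursive oracle", {
  p <- wt_params()
  # chain of 3: all rank 1, one branch
  tr <- new_tree(rep(0.5, 34), c(0, 0), p)
  tr <- attach_children(tr, 1, 1, p)
  tr <- attach_children(tr, 2, 1, p)
  so <- strahler_orders(tr)
  expect_equal(so$rank, c(1L, 1L, 1L))
  expect_equal(length(unique(so$branch)), 1L)
  # a fork of two rank-1 children promotes the root to rank 2
  tr <- new_tree(rep(0.5, 34), c(0, 0), p)
  tr <- attach_children(tr, 1, 2, p)
  expect_equal(strahler_orders(tr)$rank, c(2L, 1L, 1L))
  # mixed ranks take the maximum
  tr <- attach_children(tr, 2, 2, p)
  expect_equal(strahler_orders(tr)$rank[1], 2L)
  # randomized equivalence with the recursive definition
  set.seed(11)
  for (i in 1:150) {
    tr <- random_test_tree(sample(1:60, 1), p)
    expect_identical(strahler_orders(tr)$rank, oracle_strahler(tr$parent))
  }
})

test_that("subtree removal restores foliages and accounts volume", {
  set.seed(3)
  p <- wt_params()
  tr <- new_tree(rep(0.5, 34), c(0, 0), p)
  tr <- attach_children(tr, 1, 2, p)
  # removing a twig turns the parent's other side into the only foliage
  res <- remove_subtree(tr, 3, p)
  expect_equal(n_segments(res$tree), 2)
  expect_equal(res$volume, p$V0)
  expect_equal(sum(is_twig(res$tree)), 1)
  # removing an internal segment removes its whole subtree
  res2 <- remove_subtree(tr, 1, p)
  expect_equal(n_segments(res2$tree), 0)
  expect_false(res2$tree$alive)
  expect_equal(res2$volume, 3 * p$V0)
  # pruning never changes surviving segments' geometry or diameters
  tr3 <- random_test_tree(40, p)
  tw <- which(child_counts(tr3) == 1)[1]
  res3 <- remove_subtree(tr3, which(tr3$parent == tw)[1], p)
  keep <- setdiff(seq_len(n_segments(tr3)), subtree_ids <-
                    windtree:::subtree_members(tr3, which(tr3$parent == tw)[1]))
  expect_equal(res3$tree$base, tr3$base[keep, , drop = FALSE])
  expect_equal(res3$tree$d, tr3$d[keep])
})

test_that("multi-subtree pruning preserves topological order", {
  set.seed(8)
  p <- wt_params()
  for (rep in 1:100) {
    tr <- random_test_tree(sample(3:40, 1), p)
    n <- n_segments(tr)
    roots <- sample(seq_len(n), sample(1:3, 1))
    tr2 <- windtree:::drop_segments(tr, roots, p)$tree
    m <- n_segments(tr2)
    if (m == 0) next
    expect_true(all(tr2$parent < seq_len(m)))
    expect_true(all(tr2$parent >= 0))
    expect_equal(sum(tr2$parent == 0), 1)
    # every segment still reaches at least one twig
    acc <- windtree:::cpp_acc_to_root(
      tr2$parent, matrix(as.numeric(is_twig(tr2)), m, 1))[, 1]
    expect_true(all(acc >= 1))
  }
})

test_that("segment tables round-trip through CSV", {
  set.seed(5)
  p <- wt_params()
  tr <- random_test_tree(30, p)
  path <- tempfile(fileext = ".csv")
  write_tree_csv(tr, path)
  tr2 <- read_tree_csv(path, genome = tr$genome, params = p)
  expect_identical(tr2$parent, tr$parent)
  expect_equal(tr2$t, tr$t, tolerance = 1e-12)
  expect_equal(tr2$base, tr$base, tolerance = 1e-12)
  expect_equal(tr2$d, tr$d, tolerance = 1e-12)
  expect_identical(tr2$year_created, tr$year_created)
  unlink(path)
})
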