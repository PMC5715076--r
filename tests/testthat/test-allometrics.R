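# Build an exactly self-similar tree: a rank-k branch is a chain of
# 2^(k-1) segments ending in two rank-(k-1) children, with one extra
# side rank-(k-1) branch at its first joint. Every rank-k branch thus
# feeds exactly 3 rank-(k-1) branches (R_n = 3) and doubles in length
# (R_l = 2); diameters are assigned d0 * R_d^(rank-1).
make_fractal_tree <- function(K, R_d = 1.8, params = wt_params()) {
  parent <- integer(0)
  rank <- integer(0)
  add <- function(p, r) {
    parent[length(parent) + 1L] <<- p
    rank[length(rank) + 1L] <<- r
    length(parent)
  }
  rec <- function(k, p) {
    len <- 2^(k - 1)
    head <- add(p, k)
    cur <- head
    if (k > 1) {
      for (j in seq_len(len - 1)) {
        if (j == 1) rec(k - 1, cur) # side branch at the first joint
        cur <- add(cur, k)
      }
      rec(k - 1, cur)
      rec(k - 1, cur)
    }
    invisible(NULL)
  }
  rec(K, 0L)
  n <- length(parent)
  tr <- new_tree(rep(0.5, 34), c(0, 0), params)
  tr$parent <- parent
  tr$t <- matrix(rep(c(0, 0, 1), each = n), n, 3)
  tr$b <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  tr$base <- matrix(0, n, 3)
  tr$d <- params$d0 * R_d^(rank - 1)
  tr$year_created <- integer(n)
  tr$strength <- rep(1, n)
  tr$light <- tr$sigma_rel <- tr$m_bend <- numeric(n)
  tr
}

test_that("tree summaries reduce to closed forms", {
  set.seed(71)
  p <- wt_params()
  tr <- new_tree(rep(0.5, 34), c(0, 0), p)
  s <- tree_summary(tr, p)
  expect_equal(s$H, p$L)
  expect_equal(s$N, 1)
  expect_equal(s$B, p$V0)
  expect_equal(s$d_trunk, p$d0)
  expect_equal(s$C, 0)
  # symmetric fork: crown radius is the half-spread of the two foliages
  g <- rep(0.5, 34)
  g[1] <- g[2] <- 2 / 3 # theta1 = 60, theta2 = -60
  tr2 <- new_tree(g, c(0, 0), p)
  tr2 <- attach_children(tr2, 1, 2, p, eps = c(0, 0, 0))
  s2 <- tree_summary(tr2, p)
  expect_equal(s2$C, sin(60 * pi / 180), tolerance = 1e-12)
  expect_equal(s2$H, 1 + cos(60 * pi / 180), tolerance = 1e-12)
  expect_equal(s2$N, 2)
  expect_equal(s2$B, 3 * p$V0)
})

test_that("an exact fractal yields its construction ratios", {
  p <- wt_params()
  tr <- make_fractal_tree(5, R_d = 1.8, p)
  tab <- rank_table(tr, p)
  expect_equal(tab$rank, 1:5)
  expect_equal(tab$n, 3^(4:0))
  expect_equal(tab$length, 2^(0:4) * p$L)
  ss <- self_similar_ratios(tr, params = p)
  expect_true(ss$ok)
  expect_equal(ss$R_n, 3, tolerance = 1e-9)
  expect_equal(ss$R_l, 2, tolerance = 1e-9)
  expect_equal(ss$R_d, 1.8, tolerance = 1e-9)
  expect_equal(ss$R_a, 1.8^2, tolerance = 1e-9)
  expect_equal(ss$D, log(3) / log(2), tolerance = 1e-9)
  expect_true(ss$D_ci[1] <= ss$D && ss$D <= ss$D_ci[2])
  # fewer than 3 ranks: flagged as undefined
  tr2 <- make_fractal_tree(2, params = p)
  expect_false(self_similar_ratios(tr2, params = p)$ok)
})

test_that("mean path lengths match exhaustive enumeration", {
  set.seed(72)
  p <- wt_params()
  # chain of 3: root sees its single foliage 3 segments away
  tr <- new_tree(rep(0.5, 34), c(0, 0), p)
  tr <- attach_children(tr, 1, 1, p)
  tr <- attach_children(tr, 2, 1, p)
  expect_equal(tapering_profile(tr, p)$mean_path, c(3, 2, 1) * p$L)
  for (i in 1:40) {
    tr <- random_test_tree(sample(2:80, 1), p)
    expect_equal(tapering_profile(tr, p)$mean_path,
                 oracle_mean_path(tr, p), tolerance = 1e-12)
  }
})

test_that("area conservation ratios are exact on constructed nodes", {
  set.seed(73)
  p <- wt_params()
  tr <- new_tree(rep(0.5, 34), c(0, 0), p)
  tr <- attach_children(tr, 1, 2, p)
  # equal diameters: ratio 2; children at d / sqrt(2): ratio 1
  leo <- leonardo_ratios(tr, p)
  expect_equal(leo$table$ratio, 2)
  tr$d[2:3] <- p$d0 / sqrt(2)
  tr$d[1] <- p$d0
  expect_equal(leonardo_ratios(tr, p)$table$ratio, 1, tolerance = 1e-12)
})

test_that("effective numbers collapse correctly", {
  expect_equal(effective_numbers(c(1, 3)),
               c(N_eff = 1.6, M_eff = 2.5))
  expect_equal(effective_numbers(rep(2.5, 7)),
               c(N_eff = 7, M_eff = 2.5))
  expect_equal(effective_numbers(4.2), c(N_eff = 1, M_eff = 4.2))
  expect_error(effective_numbers(numeric(0)), "empty")
})

test_that("RMA and LS fits satisfy their defining identities", {
  set.seed(74)
  x <- runif(50)
  # exact line: both methods recover it
  y <- 2 * x + 1
  expect_equal(rma_fit(x, y)$slope, 2, tolerance = 1e-12)
  expect_equal(ls_fit(x, y)$slope, 2, tolerance = 1e-12)
  expect_equal(ls_fit(x, y)$intercept, 1, tolerance = 1e-12)
  # noisy data: RMA = LS / r; LS agrees with lm (independent route)
  y <- 2 * x + rnorm(50, 0, 0.3)
  w <- runif(50, 0.5, 2)
  fr <- rma_fit(x, y, w)
  fl <- ls_fit(x, y, w)
  expect_equal(fr$slope, fl$slope / fl$r, tolerance = 1e-12)
  lmfit <- lm(y ~ x, weights = w)
  expect_equal(fl$slope, unname(coef(lmfit)[2]), tolerance = 1e-12)
  expect_equal(fl$intercept, unname(coef(lmfit)[1]), tolerance = 1e-12)
  # invariances: input order and uniform weight rescaling
  o <- sample(50)
  expect_equal(rma_fit(x[o], y[o], w[o])$slope, fr$slope,
               tolerance = 1e-12)
  expect_equal(rma_fit(x, y, 17 * w)$slope, fr$slope, tolerance = 1e-12)
  # weights concentrated on a subset reproduce that subset's fit
  w2 <- c(rep(1, 20), rep(1e-14, 30))
  expect_equal(rma_fit(x, y, w2)$slope, rma_fit(x[1:20], y[1:20])$slope,
               tolerance = 1e-6)
  expect_error(rma_fit(1:2, 1:2), "3 points")
  # CI brackets the estimate
  expect_true(fr$ci[1] <= fr$slope && fr$slope <= fr$ci[2])
})

test_that("synthetic cohorts recover their construction exponents", {
  set.seed(75)
  p <- asm_params()
  be <- asm_exponents(p$D)
  cf <- asm_prefactors(p)
  n <- 400
  d <- 10^runif(n, -1, 1)
  noise <- function() exp(rnorm(n, 0, 0.1))
  sm <- data.frame(
    H = cf[["c_H"]] * d^be[["beta_H"]] * noise(),
    C = 0.5 * cf[["c_H"]] * d^be[["beta_H"]] * noise(),
    N = cf[["c_N"]] * d^be[["beta_N"]] * noise(),
    B = cf[["c_B"]] * d^be[["beta_B"]] * noise(),
    d_trunk = d, x = runif(n, -1, 1), y = runif(n, -1, 1))
  fits <- forest_allometry(sm, R = 1e3)
  expect_equal(fits$H$slope, be[["beta_H"]], tolerance = 0.05)
  expect_equal(fits$N$slope, be[["beta_N"]], tolerance = 0.05)
  expect_equal(fits$B$slope, be[["beta_B"]], tolerance = 0.05)
  expect_equal(fits$ML$slope, be[["beta_ML"]], tolerance = 0.05)
  # peripheral trees are excluded from the fit
  sm2 <- sm
  sm2$x <- c(rep(0, n - 50), rep(1e3, 50))
  expect_equal(forest_allometry(sm2, R = 1e3)$n_used, n - 50)
})

test_that("self-thinning fits recover constructed slopes", {
  N <- 10^seq(4, 1, length.out = 30)
  M <- 10^(2 - 1.5 * log10(N))
  expect_equal(self_thinning_fit(N, M)$slope, -1.5, tolerance = 1e-12)
  expect_error(self_thinning_fit(rep(10, 5), rep(1, 5)), "degenerate")
  expect_error(self_thinning_fit(c(1, 2), c(1, 2)), "3 points")
})

test_that("sensitivities reduce to closed forms", {
  p <- seq(0.8, 1.2, length.out = 7)
  expect_equal(sensitivity(p, 3 * p), 1, tolerance = 1e-12)
  expect_equal(sensitivity(p, rep(2, 7)), 0, tolerance = 1e-12)
  # symmetric sweep of a quadratic: regression slope equals the exact
  # derivative at the sweep center
  p0 <- 1
  expect_equal(sensitivity(p, p^2, p_ref = p0, beta_ref = p0^2),
               p0 * 2 * p0 / p0^2, tolerance = 1e-9)
  expect_error(sensitivity(1, 2), "2 sweep")
})
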