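test_that("drag forces match hand-evaluated magnitudes", {
  set.seed(41)
  p <- wt_params()
  tr <- new_tree(rep(0.5, 34), c(0, 0), p)
  wf <- wind_forces(tr, 1, c(1, 0, 0), p)
  # vertical segment, d = 0.1: |F| = 0.5 * 2e-5 * 0.1 = 1e-6
  expect_equal(sqrt(sum(wf$segment$force[1, ]^2)), 1e-6)
  expect_equal(wf$segment$force[1, ], c(1e-6, 0, 0))
  # foliage: |F| = 0.5 * 2e-5 * 0.25 = 2.5e-6, along the wind
  expect_equal(wf$foliage$force[1, ], c(2.5e-6, 0, 0))
  # quadratic in U, zero at U = 0
  wf2 <- wind_forces(tr, 2, c(0, 1, 0), p)
  expect_equal(wf2$foliage$force[1, 2], 4 * 2.5e-6)
  wf0 <- wind_forces(tr, 0, c(1, 0, 0), p)
  expect_equal(sum(abs(wf0$segment$force)), 0)
  expect_equal(sum(abs(wf0$foliage$force)), 0)
  # a segment parallel to the wind feels no drag
  tr$t[1, ] <- c(1, 0, 0)
  tr$b[1, ] <- c(0, 0, 1)
  expect_equal(sum(abs(wind_forces(tr, 1, c(1, 0, 0), p)$segment$force)), 0)
})

test_that("single-trunk loads give the closed-form moment and stress", {
  set.seed(42)
  p <- wt_params()
  tr <- new_tree(rep(0.5, 34), c(0, 0), p)
  lo <- propagate_loads(tr, 1, c(1, 0, 0), p)
  # M = 2.5e-6 * 1 + 1e-6 * 0.5 about y
  expect_equal(lo$M_base[1, ], c(0, 3.0e-6, 0), tolerance = 1e-15)
  expect_equal(lo$sigma[1], 32 / pi * 3.0e-6 / 0.1^3, tolerance = 1e-12)
  expect_equal(bending_stress(lo$M_base[1, ], tr$t[1, ], tr$d[1]),
               lo$sigma[1], tolerance = 1e-12)
  # pure torsion bends nothing; stress falls as d^-3
  expect_equal(bending_stress(c(0, 0, 5), c(0, 0, 1), 0.1), 0)
  expect_equal(bending_stress(c(0, 1, 0), c(0, 0, 1), 0.2),
               bending_stress(c(0, 1, 0), c(0, 0, 1), 0.1) / 8)
  expect_error(bending_stress(c(0, 1, 0), c(0, 0, 1), 0), "positive")
})

test_that("propagated moments equal the brute-force load summation", {
  set.seed(43)
  p <- wt_params()
  for (i in 1:30) {
    tr <- random_test_tree(sample(2:60, 1), p)
    a <- runif(1, 0, 2 * pi)
    u <- c(cos(a), sin(a), 0)
    U <- runif(1, 0.2, 2)
    lo <- propagate_loads(tr, U, u, p)
    M <- oracle_moments(tr, U, u, p)
    expect_lt(max(abs(lo$M_base - M)), 1e-12 * max(abs(M)))
  }
})

test_that("stress is dimensionless in the Cauchy number and monotone in d", {
  set.seed(44)
  p <- wt_params()
  tr <- random_test_tree(25, p)
  u <- c(1, 0, 0)
  s1 <- propagate_loads(tr, 1, u, p)$sigma
  # scaling C_Y by k and U by 1/sqrt(k) leaves every stress unchanged
  p2 <- wt_params(C_Y = 8 * p$C_Y)
  s2 <- propagate_loads(tr, 1 / sqrt(8), u, p2)$sigma
  expect_equal(s1, s2, tolerance = 1e-12)
  # thickening one loaded segment strictly lowers its stress
  tr2 <- tr
  j <- which(s1 > 0)[1]
  tr2$d[j] <- tr2$d[j] * 1.5
  expect_lt(propagate_loads(tr2, 1, u, p)$sigma[j], s1[j])
})

test_that("8-azimuth maximum approximates the dense sweep", {
  set.seed(45)
  p <- wt_params()
  tr <- new_tree(rep(0.5, 34), c(0, 0), p)
  # a vertical trunk is axisymmetric: all azimuths agree
  sig <- vapply(seq(0, 2 * pi, length.out = 9)[1:8], function(a)
    propagate_loads(tr, 1, c(cos(a), sin(a), 0), p)$sigma[1], numeric(1))
  expect_equal(max(sig), min(sig), tolerance = 1e-12)
  # random trees vs a 240-orientation sweep: the stress is close to the
  # square root of a quadratic form in the wind direction, so 45-degree
  # sampling can undershoot by at most about cos(22.5 deg) = 0.924 in the
  # degenerate case; typical segments sit much closer
  ratios <- c()
  for (i in 1:6) {
    tr <- random_test_tree(sample(20:50, 1), p)
    tr <- max_stress(tr, p)
    dense <- rep(0, n_segments(tr))
    for (a in seq(0, 2 * pi, length.out = 241)[1:240]) {
      s <- propagate_loads(tr, 1, c(cos(a), sin(a), 0), p)$sigma
      dense <- pmax(dense, s)
    }
    sel <- dense > 1e-12
    expect_true(all(tr$sigma_rel[sel] >= dense[sel] * 0.90))
    expect_true(all(tr$sigma_rel[sel] <= dense[sel] * (1 + 1e-9)))
    ratios <- c(ratios, tr$sigma_rel[sel] / dense[sel])
  }
  expect_gt(median(ratios), 0.98)
})

test_that("storm sampler matches its closed-form calibration", {
  p <- wt_params()
  set.seed(46)
  U <- replicate(2e5, sample_wind(p)$U)
  exceed <- mean(U > p$gust_factor * p$U0)
  ptrue <- 1 / p$return_period
  expect_lt(abs(exceed - ptrue), 3 * sqrt(ptrue * (1 - ptrue) / 2e5))
  med_true <- p$gust_factor * log(2) / log(p$return_period) * p$U0
  expect_equal(median(U), med_true, tolerance = 0.02)
  expect_equal(med_true, 0.2258, tolerance = 1e-3)
})

test_that("fracture probability follows the Weibull closed forms", {
  p <- wt_params()
  expect_equal(fracture_probability(1, p$V0, 1, p), 1 - exp(-1))
  expect_equal(fracture_probability(0, p$V0, 1, p), 0)
  expect_equal(fracture_probability(0.5, p$V0, 1, p),
               1 - exp(-2^-10), tolerance = 1e-12)
  # volume effect: doubling V doubles the Weibull exponent
  expect_equal(log(1 - fracture_probability(0.8, 2 * p$V0, 1, p)),
               2 * log(1 - fracture_probability(0.8, p$V0, 1, p)),
               tolerance = 1e-9)
  # weakening scales the effective stress
  expect_equal(fracture_probability(0.5, p$V0, 0.5, p),
               fracture_probability(1, p$V0, 1, p))
  expect_error(fracture_probability(-1, p$V0), ">= 0")
})

test_that("storms prune as the fracture law predicts", {
  p <- wt_params()
  set.seed(47)
  # calm storm, healthy tree: nothing happens
  tr <- new_tree(rep(0.5, 34), c(0, 0), p)
  st <- apply_storm_tree(tr, 0, 1, p)
  expect_equal(n_segments(st$tree), 1)
  expect_equal(st$volume, 0)
  # weakened below threshold: falls regardless of load
  trw <- tr
  trw$strength <- 0.04
  stw <- apply_storm_tree(trw, 0, 1, p)
  expect_equal(n_segments(stw$tree), 0)
  expect_false(stw$tree$alive)
  # Monte-Carlo fracture rate of a single trunk at fixed storm speed
  U <- 2.2
  sig <- propagate_loads(tr, U, c(1, 0, 0), p)$sigma[1]
  ptrue <- fracture_probability(sig, p$V0, 1, p)
  nrep <- 4000
  falls <- sum(replicate(nrep, {
    n_segments(apply_storm_tree(tr, U, 0, p)$tree) == 0
  }))
  expect_lt(abs(falls / nrep - ptrue),
            3 * sqrt(ptrue * (1 - ptrue) / nrep))
})
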