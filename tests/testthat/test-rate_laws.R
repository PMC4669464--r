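# Rate laws: MME, bounds, VCMME, Taylor series, exact ensemble average.

test_that("MME evaluates the hyperbolic law and rejects bad input", {
  rp <- rate_params(2)
  expect_equal(mme(c(0, 2, 6), rp), c(0, 0.5, 0.75))
  expect_equal(mme(100, rate_params(100)), 0.5)
  expect_error(mme(-1, rp), "nonnegative")
  expect_error(rate_params(-1))
  expect_error(rate_params(1, v_max = 0))
})

test_that("Jensen upper bound depends on the mean alone and majorizes the exact average", {
  rp <- rate_params(3)
  expect_equal(jensen_upper_bound(conc_moments(3, 100), rp), 0.5)
  # two-point distribution {0, 2K} w.p. 1/2 each: mean K, exact average 1/3
  d <- conc_dist(c(0, 6), c(0.5, 0.5))
  expect_equal(exact_ensemble_rate(d, rp), 1 / 3)
  expect_lt(exact_ensemble_rate(d, rp), jensen_upper_bound(dist_moments(d), rp))
  # degenerate distribution attains the bound
  d0 <- conc_dist(4.2, 1)
  expect_equal(exact_ensemble_rate(d0, rp),
               jensen_upper_bound(dist_moments(d0), rp))
})

test_that("lower bound reduces to MME at zero variance and sandwiches two-point cases", {
  rp <- rate_params(5)
  expect_equal(optimal_lower_bound(conc_moments(7, 0), rp), mme(7, rp))
  d <- conc_dist(c(0, 10), c(0.5, 0.5))  # mean K_M, exact = 1/3
  lo <- optimal_lower_bound(dist_moments(d), rp)
  expect_lte(lo, exact_ensemble_rate(d, rp))
  expect_lte(exact_ensemble_rate(d, rp), 0.5)
})

test_that("VCMME substitutes moments exactly and reduces to MME deterministically", {
  rp <- rate_params(1)
  expect_equal(vcmme(conc_moments(1, 1), rp), 0.375)
  V <- c(0.1, 0.5, 2)
  expect_equal(vcmme(conc_moments(rep(1, 3), V), rp), 0.5 - V / 8)
  expect_equal(vcmme(conc_moments(2.5, 0), rp), mme(2.5, rp))
  # 0.375 lies between the bounds for mean = K_M = 1, var = 1
  expect_gt(0.375, optimal_lower_bound(conc_moments(1, 1), rp))
  expect_lt(0.375, jensen_upper_bound(conc_moments(1, 1), rp))
})

test_that("VCMME equals the bound midpoint exactly at mean = K_M and only there", {
  for (K in c(0.3, 1, 42)) {
    rp <- rate_params(K)
    for (V in c(0.01 * K^2, K^2, 10 * K^2)) {
      mom <- conc_moments(K, V)
      mid <- (jensen_upper_bound(mom, rp) + optimal_lower_bound(mom, rp)) / 2
      expect_equal(vcmme(mom, rp), mid)
    }
    mom2 <- conc_moments(2 * K, K^2)
    mid2 <- (jensen_upper_bound(mom2, rp) + optimal_lower_bound(mom2, rp)) / 2
    expect_false(isTRUE(all.equal(vcmme(mom2, rp), mid2)))
  }
})

test_that("bound sandwich holds for randomized nonnegative distributions", {
  set.seed(401)
  rp <- rate_params(8)
  for (i in 1:2000) {
    d <- random_dist()
    mom <- dist_moments(d)
    ex <- exact_ensemble_rate(d, rp)
    expect_true(optimal_lower_bound(mom, rp) <= ex + 1e-12)
    expect_true(ex <= jensen_upper_bound(mom, rp) + 1e-12)
  }
})

test_that("Jensen equality holds iff the distribution is degenerate", {
  set.seed(402)
  rp <- rate_params(3)
  for (i in 1:200) {
    d <- random_dist()
    gap <- jensen_upper_bound(dist_moments(d), rp) - exact_ensemble_rate(d, rp)
    expect_gt(gap, 1e-12)  # genuinely spread distributions have a gap
  }
  d0 <- conc_dist(7, 1)
  expect_lt(jensen_upper_bound(dist_moments(d0), rp) -
              exact_ensemble_rate(d0, rp), 1e-12)
})

test_that("Taylor series: order 2 is the VCMME, symmetric third moments drop out", {
  rp <- rate_params(4)
  d <- conc_dist(c(2, 6), c(0.5, 0.5))  # symmetric about the mean 4 = K_M
  mom <- dist_moments(d, order = 4)
  expect_equal(taylor_rate(mom, rp, 2), vcmme(mom, rp))
  expect_equal(taylor_rate(mom, rp, 3), taylor_rate(mom, rp, 2))
  expect_error(taylor_rate(conc_moments(4, 1), rp, 4), "central moments")
})

test_that("Taylor series alternates for right-skewed cases and converges on small support", {
  rp <- rate_params(4)
  # right-skewed two-point distribution
  d <- conc_dist(c(1, 13), c(0.8, 0.2))
  mom <- dist_moments(d, order = 8)
  terms <- diff(vapply(2:8, function(n) taylor_rate(mom, rp, n), numeric(1)))
  expect_true(all(sign(terms) == rep(c(1, -1), length.out = 6) *
                    sign(terms[1])))
  # summed far enough, the series reproduces the exact average (support
  # within the convergence radius |rho - mu| < mu + K_M)
  d2 <- conc_dist(c(2, 4, 6), c(0.3, 0.4, 0.3))
  mom2 <- dist_moments(d2, order = 30)
  expect_equal(taylor_rate(mom2, rp, 30), exact_ensemble_rate(d2, rp),
               tolerance = 1e-10)
})

test_that("exact ensemble rate validates inputs", {
  expect_error(conc_dist(c(1, 2), c(0.6, 0.6)), "sum to 1")
  expect_error(conc_dist(c(-1, 2), c(0.5, 0.5)), "nonnegative")
  expect_error(conc_dist(c(2, 2), c(0.5, 0.5)), "distinct")
  expect_equal(exact_ensemble_rate(conc_dist(5, 1), rate_params(5)), 0.5)
})

test_that("moments constructor enforces consistency", {
  expect_error(conc_moments(-1, 0), "nonnegative")
  expect_error(conc_moments(1, -1), "nonnegative")
  expect_error(conc_moments(0, 1), "zero mean")
})
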