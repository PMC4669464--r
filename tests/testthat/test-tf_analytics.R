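# Analytical TF model: Laplace functional, moments, occupancy estimators.

test_that("Laplace functional satisfies its boundary and monotonicity laws", {
  m <- tf_test_model()
  lam <- c(0, 0.005, 0.02, 0.08, 0.3)
  tt <- c(0, 200, 900, 3600)
  L <- tf_laplace(lam, tt, m)
  expect_equal(dim(L), c(4L, 5L))
  expect_equal(L[, 1], rep(1, 4))        # lambda = 0
  expect_equal(L[1, ], rep(1, 5))        # t = 0 (causality)
  expect_true(all(L > 0 & L <= 1))
  # nonincreasing and convex in lambda at each positive time
  for (i in 2:4) {
    expect_true(all(diff(L[i, ]) < 0))
    grid_l <- seq(0.001, 0.3, length.out = 9)
    Lg <- tf_laplace(grid_l, tt[i], m)
    expect_true(all(diff(Lg, differences = 2) > -1e-10))
  }
})

test_that("mean time course: causality, stationary limit and triple-convolution shape", {
  m <- tf_test_model()
  expect_equal(tf_mean(0, m), 0)
  st <- tf_stationary(m)
  expect_equal(st$mean, with(m, a_tf * burst_size / (gamma_p * volume)))
  expect_equal(tf_mean(18 / m$gamma_p, m), st$mean, tolerance = 1e-6)
  mu <- tf_mean(c(60, 300, 900, 2400), m)
  expect_true(all(diff(mu) > 0) && all(mu > 0))
})

test_that("small-time growth exponent is kappa + 2 and each step adds one", {
  slopes <- vapply(1:3, function(kap) {
    m <- tf_model(a_tf = 0.004, gamma_m = 1 / 120, v_tf = 0.05,
                  delay = maturation_delay(rep(0.02, kap)),
                  gamma_p = 2e-4, volume = 1, binding_K = 0.08)
    ts <- exp(seq(log(0.5), log(2), length.out = 5))
    unname(stats::coef(stats::lm(log(tf_mean(ts, m)) ~ log(ts)))[2])
  }, numeric(1))
  expect_equal(slopes, 3:5, tolerance = 0.05 / 3)
  expect_equal(diff(slopes), c(1, 1), tolerance = 0.05)
})

test_that("variance: causality, sigmoidal rise, exact stationary law", {
  m <- tf_test_model()
  expect_equal(tf_variance(0, m), 0)
  va <- tf_variance(c(100, 400, 1200, 3600, 18 / m$gamma_p), m)
  expect_true(all(diff(va) > 0))
  st <- tf_stationary(m)
  expect_equal(va[5], st$variance, tolerance = 1e-6)
})

test_that("no-delay instantaneous-burst limit reduces to the geometric-burst shot noise", {
  # gamma_m, v_tf large at fixed b: Var(t) -> a b (2b + 1)/(2 gp V^2) (1 - e^{-2 gp t})
  a <- 0.01; b <- 6; gm <- 2; gp <- 1 / 500; V <- 1
  m <- tf_model(a_tf = a, gamma_m = gm, v_tf = b * gm,
                delay = maturation_delay(), gamma_p = gp, volume = V,
                binding_K = 0.1)
  tt <- c(200, 600, 1500, 4000)
  limit <- a * b * (2 * b + 1) / (2 * gp * V^2) * (1 - exp(-2 * gp * tt))
  expect_equal(tf_variance(tt, m), limit, tolerance = 2e-3)
})

test_that("stationary variance grows like b^2 at fixed transcription rate", {
  a <- 0.01; gm <- 1 / 120; gp <- 2e-4
  v1 <- tf_stationary(tf_model(a_tf = a, gamma_m = gm, v_tf = 50 * gm,
                               gamma_p = gp, binding_K = 0.1))$variance
  v2 <- tf_stationary(tf_model(a_tf = a, gamma_m = gm, v_tf = 100 * gm,
                               gamma_p = gp, binding_K = 0.1))$variance
  # closed form: var = a b (1/2 + b gm/(gm + gp)) / (gp V^2)
  pred <- function(b) a * b * (0.5 + b * gm / (gm + gp)) / gp
  expect_equal(v1, pred(50), tolerance = 1e-10)
  expect_equal(v2, pred(100), tolerance = 1e-10)
  expect_equal(v2 / v1, 4, tolerance = 0.01)
  # quadrature agrees with the closed form
  m <- tf_model(a_tf = a, gamma_m = gm, v_tf = 50 * gm, gamma_p = gp,
                binding_K = 0.1)
  expect_equal(tf_variance(18 / gp, m), v1, tolerance = 1e-6)
})

test_that("lambda-derivatives of the Laplace functional reproduce mean and variance", {
  m <- tf_test_model()
  tt <- c(150, 600, 1800)
  fd <- tf_moments_fd(tt, m)
  ctl <- tf_control(n_grid = 16384)
  expect_equal(fd$mean, tf_mean(tt, m, ctl), tolerance = 1e-4)
  expect_equal(fd$variance, tf_variance(tt, m, ctl), tolerance = 1e-4)
})

test_that("occupancy integral is exact for a degenerate concentration", {
  # with the Laplace transform replaced by exp(-lambda rho0) the damped
  # Gauss-Legendre nodes must return K rho0 / (1 + K rho0)
  ctl <- tf_control()
  pan <- ctl$occ_panels
  xs <- ws <- numeric(0)
  for (i in seq_len(length(pan) - 1)) {
    gl <- pracma::gaussLegendre(ctl$occ_nodes, pan[i], pan[i + 1])
    xs <- c(xs, gl$x); ws <- c(ws, gl$w)
  }
  for (kr in c(0.05, 0.8, 4, 15)) {
    val <- 1 - sum(ws * exp(-xs) * exp(-xs * kr))
    expect_equal(val, kr / (1 + kr), tolerance = 1e-8)
  }
})

test_that("occupancy estimators: causality, ordering, monotonicity in K", {
  m <- tf_test_model()
  tt <- c(0, 120, 600, 1800, 3600)
  oe <- occupancy_exact(tt, m)
  om <- occupancy_mme(tt, m)
  ov <- occupancy_vcmme(tt, m)
  expect_equal(oe[1], 0)
  expect_equal(om[1], 0)
  expect_true(all(oe >= 0 & oe <= 1))
  expect_true(all(ov <= om + 1e-12))       # nonnegative correction term
  expect_true(all(oe <= om + 1e-9))        # Jensen
  m2 <- tf_test_model(); m2$binding_K <- m2$binding_K * 2
  expect_true(all(occupancy_exact(tt[-1], m2) > oe[-1]))
})

test_that("occupancy sandwich: exact value between lower bound and MME", {
  m <- tf_test_model()
  tt <- seq(120, 3600, by = 240)
  mu <- tf_mean(tt, m); va <- tf_variance(tt, m)
  rp <- rate_params(1 / m$binding_K)
  lo <- optimal_lower_bound(conc_moments(mu, va), rp)
  oe <- occupancy_exact(tt, m)
  expect_true(all(lo <= oe + 1e-6))
  expect_true(all(oe <= occupancy_mme(tt, m) + 1e-6))
})

test_that("Poisson occupancy matches direct summation and its strong-binding limit", {
  m <- tf_test_model()
  tt <- c(300, 1200, 3600)
  op <- occupancy_poisson(tt, m)
  mu <- tf_mean(tt, m)
  for (j in seq_along(tt)) {
    mm <- mu[j] * m$volume
    n <- 0:ceiling(mm + 20 * sqrt(mm) + 20)
    direct <- sum(stats::dpois(n, mm) *
                    (m$binding_K * n / m$volume) /
                    (1 + m$binding_K * n / m$volume))
    expect_equal(op[j], direct, tolerance = 1e-10)
  }
  mK <- tf_test_model(); mK$binding_K <- 1e8
  expect_equal(occupancy_poisson(tt, mK), 1 - exp(-mu * m$volume),
               tolerance = 1e-5)
})

test_that("correction difference and ratio behave at the boundaries", {
  m <- tf_test_model()
  expect_equal(correction_difference(0, m), 0)
  expect_true(is.nan(correction_ratio(0, m)))
  tt <- c(60, 300, 900, 3600)
  expect_true(all(correction_difference(tt, m) > 0))
  rr <- correction_ratio(tt, m)
  expect_true(all(rr > 0 & rr < 1))
})

test_that("unapproximated occupancy law accounts for the intermediate state", {
  expect_equal(p0_occupancy(2, K = 0.5), 0.5)
  # finite K_SP diverts weight to the nonspecific state
  expect_lt(p0_occupancy(2, K = 0.5, K_sp = 5), p0_occupancy(2, K = 0.5))
  m_inf <- tf_test_model()
  m_fin <- tf_test_model(); m_fin$K_sp <- 20
  tt <- c(600, 3600)
  expect_true(all(occupancy_exact(tt, m_fin) < occupancy_exact(tt, m_inf)))
})

test_that("analytic moments match a continuous-dilution SSA ensemble", {
  fx <- get_fixture("fig1b_like")
  spec <- fx$spec; spec$binding_model <- "none"; spec$dilution <- "continuous"
  tg <- c(100, 300, 600, 1200, 2400, 3600)
  ens <- cached("cont_ens",
                run_ensemble(spec, 3600, 2000, base_seed = 42, time_grid = tg))
  st <- ensemble_stats(ens)
  mu <- tf_mean(tg, fx$model); va <- tf_variance(tg, fx$model)
  z_mu <- (st$mean - mu) / sqrt(st$variance / st$n_runs)
  expect_true(all(abs(z_mu) < 3))
  z_va <- vapply(seq_along(tg), function(j) {
    x <- ens$states$rho[, j]
    (stats::var(x) - va[j]) / se_of_variance(x)
  }, numeric(1))
  expect_true(mean(abs(z_va) < 3) >= 5 / 6)
  expect_true(all(abs(z_va) < 4))
})
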