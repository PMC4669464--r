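# Gillespie simulators: exactness, bookkeeping, reproducibility.

test_that("empty enzyme system produces nothing and idles to the horizon", {
  spec <- enzyme_system(k_on = 0.05, k_off = 4, k_cat = 1, batch_size = 10,
                        input_rate = 0, s0 = 0)
  run <- simulate_enzyme(spec, 500, seed = 1)
  expect_true(all(run$S == 0) && all(run$SE == 0) && all(run$P == 0))
  expect_equal(run$n_events, 0)
})

test_that("with zero catalysis the complex absorbs and no product forms", {
  spec <- enzyme_system(k_on = 0.05, k_off = 1, k_cat = 0, batch_size = 5,
                        input_rate = 0.2)
  run <- simulate_enzyme(spec, 1000, seed = 2, record = "events")
  expect_true(all(run$P == 0))
  total <- run$events$S + run$events$SE
  expect_true(all(diff(total) >= 0))  # substrate only enters
})

test_that("enzyme bookkeeping: substrate balance and enzyme conservation", {
  spec <- enzyme_system(k_on = 0.05, k_off = 4, k_cat = 1, batch_size = 7,
                        input_rate = 0.1, n_enzymes = 3L)
  run <- simulate_enzyme(spec, 2000, seed = 3, record = "events")
  ev <- run$events
  expect_true(all(ev$SE >= 0 & ev$SE <= 3))
  expect_true(all(ev$S >= 0))
  steps <- diff(ev$S + ev$SE + ev$P)
  expect_true(all(steps %in% c(0, 7)))  # only batch arrivals add substrate
})

test_that("ensembles are reproducible from the base seed and runs differ", {
  spec <- enzyme_system(k_on = 0.05, k_off = 4, k_cat = 1, batch_size = 5,
                        input_rate = 0.1)
  e1 <- run_ensemble(spec, 500, 5, base_seed = 99)
  e2 <- run_ensemble(spec, 500, 5, base_seed = 99)
  expect_identical(e1$states, e2$states)
  expect_false(identical(e1$states$S[1, ], e1$states$S[2, ]))
  expect_error(run_ensemble(spec, 500, 1, base_seed = 1), "at least 2")
  expect_error(simulate_enzyme(spec, 100, 1, time_grid = c(50, 200)),
               "beyond the simulated horizon")
})

test_that("pure-birth transcript counts are Poisson (mean equals variance)", {
  spec <- genereg_system(a_tf = 0.05, gamma_m = 0, v_tf = 0, gamma_p = 0,
                         binding_model = "none")
  ens <- run_ensemble(spec, 100, 500, base_seed = 7, time_grid = 100)
  x <- ens$states$mRNA[, 1]
  expect_lt(abs(mean(x) - 5), 3 * sqrt(5 / 500))
  expect_lt(abs(stats::var(x) - 5), 3 * se_of_variance(x))
})

test_that("silent gene stays silent", {
  spec <- genereg_system(a_tf = 0, gamma_m = 0.01, v_tf = 0.1,
                         maturation_rates = 0.02, gamma_p = 1e-4,
                         binding_model = "none")
  run <- simulate_genereg(spec, 2000, seed = 4)
  expect_true(all(run$mRNA == 0) && all(run$rho == 0) &&
                all(run$matured_total == 0))
})

test_that("mature-TF mean matches the integrated two-stage expression law", {
  # kappa = 0, no dilution, no binding:
  # <N(t)> = v a / gamma_m * (t - (1 - exp(-gamma_m t)) / gamma_m)
  a <- 0.05; gm <- 0.01; v <- 0.1; t_end <- 300
  spec <- genereg_system(a_tf = a, gamma_m = gm, v_tf = v, gamma_p = 0,
                         binding_model = "none")
  ens <- run_ensemble(spec, t_end, 600, base_seed = 12, time_grid = t_end)
  x <- ens$states$mature_free[, 1]
  expected <- v * a / gm * (t_end - (1 - exp(-gm * t_end)) / gm)
  expect_lt(abs(mean(x) - expected), 3 * stats::sd(x) / sqrt(length(x)))
})

test_that("stationary TF concentration approaches a_tf b_tf / (gamma_p V)", {
  spec <- genereg_system(a_tf = 0.004, gamma_m = 1 / 120, v_tf = 0.05,
                         maturation_rates = c(0.02, 0.02), gamma_p = 2e-4,
                         volume = 1, binding_model = "none")
  ens <- run_ensemble(spec, 40000, 400, base_seed = 21,
                      time_grid = c(35000, 40000))
  x <- c(ens$states$rho[, 1], ens$states$rho[, 2])  # ~1 correlation time apart
  target <- 0.004 * (0.05 * 120) / (2e-4 * 1)
  expect_lt(abs(mean(x) - target), 3 * stats::sd(x) / sqrt(400))
})

test_that("immigration-death stationary law passes a chi-square test against Poisson", {
  a <- 0.2; gm <- 0.01
  spec <- genereg_system(a_tf = a, gamma_m = gm, v_tf = 0, gamma_p = 0,
                         binding_model = "none")
  ens <- run_ensemble(spec, 800, 10000, base_seed = 31, time_grid = 800)
  x <- ens$states$mRNA[, 1]
  mu <- a / gm
  ks <- 0:60
  p <- stats::dpois(ks, mu)
  # pool tails so all expected counts are >= 5
  lo <- min(which(cumsum(p) * length(x) >= 5))
  hi <- max(which((1 - cumsum(p)) * length(x) >= 5))
  bins <- c(-Inf, ks[lo:hi], Inf)
  obs <- table(cut(x, bins))
  pr <- diff(c(0, cumsum(p)[lo:hi], 1))
  pval <- stats::chisq.test(as.vector(obs), p = pr)$p.value
  expect_gt(pval, 0.01)
})

test_that("TF molecules are conserved through binding and unbinding", {
  fx <- get_fixture("fig1b_like")
  run <- simulate_genereg(fx$spec, 1500, seed = 17, record = "events")
  ev <- run$events
  total <- ev$mature_free + as.numeric(ev$operator > 0)
  steps <- diff(total)
  expect_true(all(steps %in% c(-1, 0, 1)))
  # binding-state changes never create or destroy TF
  op_change <- diff(ev$operator) != 0
  expect_true(all(steps[op_change] == 0))
})

test_that("large-copy control collapses all estimators onto the MME", {
  tab <- run_experiment(list(scenario = "enzyme_burst",
                             fixture = "deterministic_limit",
                             base_seed = 5))$stationary
  expect_lt(tab$mme - tab$vcmme, 1e-3)
  expect_lt(tab$mme - tab$lower, 1e-3)
  expect_lt(abs(tab$dev_mme), 1e-3)
  expect_lt(abs(tab$dev_vcmme), 3 * tab$vcmme_diff_se + 1e-3)
})

test_that("ensemble statistics implement the (n-1) variance and occupancy fraction", {
  spec <- enzyme_system(k_on = 0, k_off = 0, k_cat = 0, batch_size = 1,
                        input_rate = 0, s0 = 5)
  ens <- run_ensemble(spec, 10, 2, base_seed = 1, time_grid = c(5, 10))
  # both runs are frozen at s0: zero variance, occupancy 0
  st <- ensemble_stats(ens)
  expect_equal(st$variance, c(0, 0))
  expect_equal(st$mean, c(5, 5))
  expect_equal(st$occupancy, c(0, 0))
  # two-run variance equals (a - b)^2 / 2
  ens$states$S[1, ] <- c(3, 3); ens$states$S[2, ] <- c(7, 9)
  st2 <- ensemble_stats(ens)
  expect_equal(st2$variance, c((3 - 7)^2 / 2, (3 - 9)^2 / 2))
})
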