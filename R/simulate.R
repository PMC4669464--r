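# Gillespie simulation drivers and ensemble statistics.

run_seed <- function(base_seed, i) {
  # fixed affine counter scheme: order-independent, reproducible, < 2^31
  as.integer((as.double(base_seed) + 1000003 * as.double(i)) %% 2147483629 + 1)
}

check_grid <- function(time_grid, horizon) {
  stopifnot(is.numeric(time_grid), length(time_grid) >= 1L,
            all(is.finite(time_grid)), all(diff(time_grid) > 0),
            time_grid[1] >= 0)
  if (max(time_grid) > horizon)
    stop("time grid extends beyond the simulated horizon")
  time_grid
}

#' Simulate one bursty-substrate enzyme trajectory
#'
#' Exact direct-method Gillespie realisation of an [enzyme_system()]. With
#' `record = "events"` the full event-resolved path is returned in addition to
#' the grid samples.
#'
#' @param spec An [enzyme_system()].
#' @param horizon Simulation end time (> 0).
#' @param seed Integer RNG seed for this run.
#' @param time_grid Strictly increasing sampling times within `[0, horizon]`;
#'   default 201 equispaced points.
#' @param record `"grid"` (default) or `"events"`.
#' @return Object of class `ssa_run`: a list with `time`, state columns
#'   sampled right-continuously on the grid (`S`, `SE`, `P` cumulative
#'   products), `n_events`, the spec, the seed and (optionally) `events`.
#' @export
simulate_enzyme <- function(spec, horizon, seed,
                            time_grid = seq(0, horizon, length.out = 201),
                            record = c("grid", "events")) {
  stopifnot(inherits(spec, "enzyme_system"), horizon > 0)
  record <- match.arg(record)
  time_grid <- check_grid(time_grid, horizon)
  set.seed(as.integer(seed))
  res <- cpp_ssa_enzyme(spec$k_on, spec$k_off, spec$k_cat, spec$batch_size,
                        spec$input_rate, spec$n_enzymes, spec$volume,
                        spec$s0, horizon, time_grid, record == "events")
  structure(list(time = time_grid, S = res$S, SE = res$SE, P = res$P,
                 n_events = res$n_events, events = res$events,
                 spec = spec, seed = as.integer(seed), horizon = horizon),
            class = "ssa_run")
}

#' Simulate one TF gene-regulation trajectory
#'
#' Exact direct-method Gillespie realisation of a [genereg_system()], started
#' from the switched-on initial condition (no transcripts, no protein,
#' operator free).
#'
#' @param spec A [genereg_system()].
#' @inheritParams simulate_enzyme
#' @return Object of class `ssa_run` with grid-sampled columns `mRNA`,
#'   `immature`, `mature_free`, `operator` (0 free / 1 nonspecific /
#'   2 specific), `rho` (TF concentration available for binding) and
#'   `matured_total` (cumulative matured proteins).
#' @export
simulate_genereg <- function(spec, horizon, seed,
                             time_grid = seq(0, horizon, length.out = 201),
                             record = c("grid", "events")) {
  stopifnot(inherits(spec, "genereg_system"), horizon > 0)
  record <- match.arg(record)
  time_grid <- check_grid(time_grid, horizon)
  bm <- match(spec$binding_model, c("none", "sequential", "independent")) - 1L
  set.seed(as.integer(seed))
  res <- cpp_ssa_genereg(spec$a_tf, spec$gamma_m, spec$v_tf,
                         spec$maturation_rates, spec$gamma_p, spec$volume,
                         spec$ns_on, spec$ns_off, spec$sp_on, spec$sp_off,
                         spec$d_on, spec$d_off, bm,
                         spec$dilution == "continuous",
                         horizon, time_grid, record == "events")
  structure(list(time = time_grid, mRNA = res$M, immature = res$I,
                 mature_free = res$PF, operator = res$OP, rho = res$RHO,
                 matured_total = res$CUM, n_events = res$n_events,
                 events = res$events, spec = spec, seed = as.integer(seed),
                 horizon = horizon),
            class = "ssa_run")
}

#' @export
print.ssa_run <- function(x, ...) {
  cat("SSA run (", class(x$spec)[1], "), ", x$n_events, " events, horizon ",
      x$horizon, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Run an ensemble of independent SSA realisations
#'
#' Repeats [simulate_enzyme()] or [simulate_genereg()] with per-run seeds
#' derived from `base_seed` by a fixed counter scheme, so the ensemble is
#' reproducible and order-independent. States are grid-sampled
#' (right-continuous); each run's full state is kept as a row of per-variable
#' matrices.
#'
#' @param spec An [enzyme_system()] or [genereg_system()].
#' @param horizon Simulation end time.
#' @param n_runs Number of independent runs (>= 2).
#' @param base_seed Integer master seed.
#' @param time_grid Sampling times (default 201 equispaced points).
#' @return Object of class `trajectory_ensemble`: `time`, a named list
#'   `states` of `n_runs x length(time)` matrices, `seeds`, `spec`.
#' @export
run_ensemble <- function(spec, horizon, n_runs, base_seed,
                         time_grid = seq(0, horizon, length.out = 201)) {
  stopifnot(inherits(spec, "reaction_system"))
  if (n_runs < 2) stop("n_runs must be at least 2")
  time_grid <- check_grid(time_grid, horizon)
  seeds <- vapply(seq_len(n_runs), function(i) run_seed(base_seed, i),
                  integer(1))
  sim1 <- function(sd) {
    if (inherits(spec, "enzyme_system"))
      simulate_enzyme(spec, horizon, sd, time_grid)
    else simulate_genereg(spec, horizon, sd, time_grid)
  }
  first <- sim1(seeds[1])
  vars <- setdiff(names(first),
                  c("time", "n_events", "events", "spec", "seed", "horizon"))
  states <- lapply(vars, function(v) {
    m <- matrix(0, n_runs, length(time_grid))
    m[1, ] <- first[[v]]
    m
  })
  names(states) <- vars
  for (i in 2:n_runs) {
    run <- sim1(seeds[i])
    for (v in vars) states[[v]][i, ] <- run[[v]]
  }
  structure(list(time = time_grid, states = states, seeds = seeds,
                 spec = spec, n_runs = n_runs, base_seed = base_seed,
                 horizon = horizon),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("SSA ensemble: ", x$n_runs, " runs of ", class(x$spec)[1], ", ",
      length(x$time), " grid times on [0, ", x$horizon, "]\n", sep = "")
  invisible(x)
}

# Substrate concentration tracked for an enzyme ensemble. The rate law's
# concentration variable is the free substrate; for a single enzyme the
# quasi-steady-state occupancy is exact in the total substrate count (the
# complexed molecule included), so that is what gets averaged there.
enzyme_conc <- function(ens) {
  if (ens$spec$n_enzymes == 1L)
    (ens$states$S + ens$states$SE) / ens$spec$volume
  else ens$states$S / ens$spec$volume
}

#' Ensemble summary statistics
#'
#' Per-grid-time mean and unbiased (n-1) variance of the tracked
#' concentration (for the enzyme system: total substrate when there is a
#' single enzyme, free substrate otherwise), the occupancy (mean
#' complexed-enzyme fraction for the enzyme system; fraction of runs with a
#' specifically bound operator for the gene-regulation system), and the rate
#' estimate (central difference of the mean cumulative product/matured
#' count).
#'
#' @param ens A [run_ensemble()] result.
#' @return `data.frame` of class `ensemble_summary` with columns `time`,
#'   `mean`, `variance`, `occupancy`, `rate`, `n_runs`.
#' @export
ensemble_stats <- function(ens) {
  stopifnot(inherits(ens, "trajectory_ensemble"))
  tg <- ens$time
  if (inherits(ens$spec, "enzyme_system")) {
    conc <- enzyme_conc(ens)
    occ <- colMeans(ens$states$SE) / ens$spec$n_enzymes
    cum <- ens$states$P
  } else {
    conc <- ens$states$rho
    occ <- colMeans(ens$states$operator == 2)
    cum <- ens$states$matured_total
  }
  mu <- colMeans(conc)
  va <- apply(conc, 2, stats::var)
  cmean <- colMeans(cum)
  nt <- length(tg)
  rate <- rep(NA_real_, nt)
  if (nt >= 3) {
    rate[2:(nt - 1)] <- (cmean[3:nt] - cmean[1:(nt - 2)]) /
      (tg[3:nt] - tg[1:(nt - 2)])
    rate[1] <- (cmean[2] - cmean[1]) / (tg[2] - tg[1])
    rate[nt] <- (cmean[nt] - cmean[nt - 1]) / (tg[nt] - tg[nt - 1])
  }
  out <- data.frame(time = tg, mean = mu, variance = va, occupancy = occ,
                    rate = rate, n_runs = ens$n_runs)
  class(out) <- c("ensemble_summary", "data.frame")
  out
}
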