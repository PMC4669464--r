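# Named fixture parameter sets.
#
# Representative parameter sets, chosen once for the regimes where
# concentration fluctuations matter: a single enzyme fed substrate in batches
# up to size 40 at half-saturating mean influx, an E. coli-like TF cascade
# with bursty expression, minute-scale maturation and strong operator
# binding, and a large-copy control. Quantities that depend on the exact
# parameter values (stationary copy numbers, peak occupancy errors) are
# outputs of these choices, not literature constants; the methods vignette
# explains each choice.

fixture_registry <- function() {
  list(
    fig1a_like = function() {
      base <- function(batch, influx = 0.5)
        enzyme_system(k_on = 0.05, k_off = 4, k_cat = 1, batch_size = batch,
                      input_rate = influx / batch, n_enzymes = 1L, volume = 1)
      list(
        name = "fig1a_like",
        scenario = "enzyme_burst",
        description = paste(
          "Single-enzyme Michaelis-Menten reaction (K_M = 100 copies/um^3)",
          "with bursty substrate input at fixed mean influx 0.5/s split into",
          "batches of 1-40; half-saturated stationary state."),
        batch_sizes = c(1L, 5L, 10L, 20L, 40L),
        make_spec = base,
        influx = 0.5,
        horizon = 6000,
        snapshot_times = c(3000, 4000, 5000, 6000),
        rate_window = c(3000, 6000),
        n_runs = 500L)
    },
    fig1b_like = function() {
      spec <- genereg_system(
        a_tf = 0.004, gamma_m = 1 / 120, v_tf = 0.05,
        maturation_rates = c(0.02, 0.02), gamma_p = 2e-4, volume = 1,
        ns_on = 0.4, ns_off = 1000, sp_on = 10, sp_off = 0.05,
        binding_model = "sequential")
      list(
        name = "fig1b_like",
        scenario = "genereg_analytics",
        description = paste(
          "E. coli-like TF cascade: one transcript per 250 s, burst size",
          "b_TF = 6, two maturation steps of mean 50 s each, dilution",
          "2e-4 /s (stationary mean 120 copies/um^3), strong operator",
          "binding K = 0.08 um^3 (K_NS = 4e-4, K_SP = 200); stationary",
          "occupancy about 0.9."),
        spec = spec,
        model = genereg_tf_model(spec),
        horizon = 3600,
        time_grid = seq(0, 3600, by = 30),
        n_runs = 500L)
    },
    deterministic_limit = function() {
      list(
        name = "deterministic_limit",
        scenario = "enzyme_burst",
        description = paste(
          "Large-copy control: 100 enzymes in a 10 um^3 volume with",
          "single-molecule substrate input at 50/s (half saturation at",
          "K_M = 100 copies/um^3 with ~1000 substrate copies and negligible",
          "relative fluctuations); all moment-based estimators collapse onto",
          "the MME."),
        batch_sizes = 1L,
        make_spec = function(batch, influx = 50)
          enzyme_system(k_on = 0.05, k_off = 4, k_cat = 1, batch_size = batch,
                        input_rate = influx / batch, n_enzymes = 100L,
                        volume = 10),
        influx = 50,
        horizon = 400,
        snapshot_times = c(250, 300, 350, 400),
        rate_window = c(200, 400),
        n_runs = 200L)
    })
}

#' Names of the built-in fixture parameter sets
#'
#' @return Character vector of fixture names.
#' @export
fixture_names <- function() names(fixture_registry())

#' Retrieve a built-in fixture
#'
#' Fixtures bundle a fully specified reaction system (and, for the
#' gene-regulation fixture, the matching analytical [tf_model()]) together
#' with the simulation settings used by [run_experiment()].
#'
#' @param name One of [fixture_names()].
#' @return A named list describing the fixture.
#' @export
get_fixture <- function(name) {
  reg <- fixture_registry()
  if (!name %in% names(reg))
    stop("unknown fixture '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  reg[[name]]()
}
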