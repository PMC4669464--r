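# Stochastic reaction-network specifications.

#' Bursty-substrate enzymatic reaction system
#'
#' Complete parameterization of the single-compartment Michaelis-Menten scheme
#' with bursty substrate input: substrate molecules enter the reaction volume
#' in batches of `batch_size` at Poisson-distributed event times (rate
#' `input_rate`), bind free enzymes (`k_on`), unbind (`k_off`) or are
#' catalysed into product (`k_cat`). Catalysis is the only pathway removing
#' substrate. The implied Michaelis constant is
#' \eqn{K_M = (k_{off}+k_{cat})/k_{on}} (concentration units) and the maximal
#' rate \eqn{v_{max} = k_{cat}\, n_{enzymes}}.
#'
#' @param k_on Binding rate constant (volume per time; propensity
#'   `k_on * S * E / volume`).
#' @param k_off Unbinding rate (per time).
#' @param k_cat Catalytic rate (per time).
#' @param batch_size Substrate molecules per input event (integer >= 1).
#' @param input_rate Batch arrival rate (events per time; may be 0).
#' @param n_enzymes Number of enzyme molecules (integer >= 1).
#' @param volume Reaction volume (cubic micrometres).
#' @param s0 Initial free-substrate copy number (default 0).
#' @return Object of class `enzyme_system`.
#' @export
enzyme_system <- function(k_on, k_off, k_cat, batch_size, input_rate,
                          n_enzymes = 1L, volume = 1, s0 = 0L) {
  stopifnot(k_on >= 0, k_off >= 0, k_cat >= 0, input_rate >= 0, volume > 0,
            batch_size >= 1, batch_size == as.integer(batch_size),
            n_enzymes >= 1, n_enzymes == as.integer(n_enzymes), s0 >= 0)
  structure(list(k_on = k_on, k_off = k_off, k_cat = k_cat,
                 batch_size = as.integer(batch_size), input_rate = input_rate,
                 n_enzymes = as.integer(n_enzymes), volume = volume,
                 s0 = as.integer(s0)),
            class = c("enzyme_system", "reaction_system"))
}

#' Rate parameters implied by an enzyme system
#'
#' @param spec An [enzyme_system()].
#' @return A [rate_params()] with \eqn{K_M = (k_{off}+k_{cat})/k_{on}} and
#'   \eqn{v_{max} = k_{cat} n_{enzymes}}.
#' @export
enzyme_rate_params <- function(spec) {
  stopifnot(inherits(spec, "enzyme_system"))
  rate_params((spec$k_off + spec$k_cat) / spec$k_on,
              v_max = spec$k_cat * spec$n_enzymes)
}

#' @export
print.enzyme_system <- function(x, ...) {
  cat("Bursty-substrate enzyme system\n")
  cat(sprintf("  k_on = %g, k_off = %g, k_cat = %g  (K_M = %g)\n",
              x$k_on, x$k_off, x$k_cat, (x$k_off + x$k_cat) / x$k_on))
  cat(sprintf("  input: batches of %d at rate %g /s; %d enzyme(s), V = %g\n",
              x$batch_size, x$input_rate, x$n_enzymes, x$volume))
  invisible(x)
}

#' TF gene-regulation reaction system
#'
#' Full stochastic parameterization of the TF expression cascade plus
#' operator binding: transcription at constant rate `a_tf` switched on at
#' time zero (initial condition: no mRNA, no protein, operator free), mRNA
#' decay, translation, `kappa` sequential maturation steps, dilution of the
#' mature TF pool, and TF-DNA binding at one operator.
#'
#' Binding models: `"sequential"` (specific binding only through the
#' nonspecifically bound intermediate, as in facilitated diffusion),
#' `"independent"` (additionally a direct specific route with rates satisfying
#' detailed balance, so the equilibrium occupancy is unchanged but binding
#' equilibrates much faster), or `"none"`.
#'
#' Dilution models: `"stochastic"` (a first-order death reaction on free
#' mature TF, the physical SSA) or `"continuous"` (the mature-TF
#' concentration decays deterministically at rate `gamma_p` between events,
#' which is an exact Monte-Carlo realisation of the analytic kernel model of
#' [tf_model()]; requires `binding_model = "none"`).
#'
#' @param a_tf Transcription rate (per time).
#' @param gamma_m mRNA decay rate (per molecule per time).
#' @param v_tf Translation rate (per mRNA per time).
#' @param maturation_rates Vector of maturation stage rates (may be empty).
#' @param gamma_p Dilution rate of mature TF (per molecule per time).
#' @param volume Cell volume (cubic micrometres).
#' @param ns_on,ns_off Nonspecific TF-DNA binding rates at the operator region
#'   (`ns_on` in volume/time: propensity `ns_on * N_TF / volume`).
#' @param sp_on,sp_off Interconversion rates between the nonspecifically and
#'   specifically bound states (per time).
#' @param d_on,d_off Direct specific binding rates used by the
#'   `"independent"` model; defaults satisfy detailed balance with
#'   `d_off = ns_off`.
#' @param binding_model `"sequential"`, `"independent"` or `"none"`.
#' @param dilution `"stochastic"` or `"continuous"`.
#' @return Object of class `genereg_system`.
#' @export
genereg_system <- function(a_tf, gamma_m, v_tf, maturation_rates = numeric(),
                           gamma_p, volume = 1,
                           ns_on = 0, ns_off = 0, sp_on = 0, sp_off = 0,
                           d_on = NULL, d_off = NULL,
                           binding_model = c("sequential", "independent", "none"),
                           dilution = c("stochastic", "continuous")) {
  binding_model <- match.arg(binding_model)
  dilution <- match.arg(dilution)
  stopifnot(a_tf >= 0, gamma_m >= 0, v_tf >= 0, gamma_p >= 0, volume > 0,
            all(maturation_rates > 0), ns_on >= 0, ns_off >= 0,
            sp_on >= 0, sp_off >= 0)
  if (binding_model != "none" && (ns_on <= 0 || ns_off <= 0))
    stop("binding_model '", binding_model, "' requires nonspecific rates")
  if (dilution == "continuous" && binding_model != "none")
    stop("continuous dilution is only defined without binding reactions")
  if (binding_model == "independent") {
    if (is.null(d_off)) d_off <- ns_off
    if (is.null(d_on)) {
      # detailed balance: d_on/d_off = K_NS * K_SP (volume units)
      k_comb <- (ns_on / ns_off) * (sp_on / sp_off)
      d_on <- k_comb * d_off
    }
  } else {
    d_on <- 0; d_off <- 0
  }
  structure(list(a_tf = a_tf, gamma_m = gamma_m, v_tf = v_tf,
                 maturation_rates = as.numeric(maturation_rates),
                 gamma_p = gamma_p, volume = volume,
                 ns_on = ns_on, ns_off = ns_off, sp_on = sp_on,
                 sp_off = sp_off, d_on = d_on, d_off = d_off,
                 binding_model = binding_model, dilution = dilution),
            class = c("genereg_system", "reaction_system"))
}

#' @export
print.genereg_system <- function(x, ...) {
  cat("TF gene-regulation system\n")
  cat(sprintf("  a_TF = %g, gamma_m = %g, v_TF = %g (b_TF = %g)\n",
              x$a_tf, x$gamma_m, x$v_tf,
              if (x$gamma_m > 0) x$v_tf / x$gamma_m else NA))
  cat(sprintf("  maturation: kappa = %d; gamma_P = %g; V = %g\n",
              length(x$maturation_rates), x$gamma_p, x$volume))
  cat(sprintf("  binding: %s; dilution: %s\n", x$binding_model, x$dilution))
  invisible(x)
}

#' Analytical model matching a gene-regulation system
#'
#' Builds the [tf_model()] whose Laplace functional, moments and occupancy
#' describe the given simulation spec (with the continuous-dilution reading of
#' the kernel). The combined binding constant is
#' \eqn{K = K_{NS} K_{SP} = (ns_{on}/ns_{off})(sp_{on}/sp_{off})} and
#' \eqn{K_{SP} = sp_{on}/sp_{off}}.
#'
#' @param spec A [genereg_system()].
#' @param strong_binding If `TRUE` (default) use the strong-binding
#'   approximation (`K_sp = Inf`) in the occupancy law.
#' @return A [tf_model()].
#' @export
genereg_tf_model <- function(spec, strong_binding = TRUE) {
  stopifnot(inherits(spec, "genereg_system"))
  if (spec$ns_off <= 0 || spec$sp_off <= 0)
    stop("binding constants undefined: zero off-rates")
  K <- (spec$ns_on / spec$ns_off) * (spec$sp_on / spec$sp_off)
  tf_model(a_tf = spec$a_tf, gamma_m = spec$gamma_m, v_tf = spec$v_tf,
           delay = maturation_delay(spec$maturation_rates),
           gamma_p = spec$gamma_p, volume = spec$volume,
           binding_K = K,
           K_sp = if (strong_binding) Inf else spec$sp_on / spec$sp_off)
}
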