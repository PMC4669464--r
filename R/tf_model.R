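# TF analytical model: parameter bundle, diffusion kernel, occupancy law.

#' Homogeneous (well-mixed) dilution kernel
#'
#' Concentration contribution of a single mature TF molecule that emerged at
#' time zero, under fast diffusion in a homogeneous cell and first-order
#' dilution: \eqn{\phi(t) = e^{-\gamma_P t}/V_{Cell}} for \eqn{t \ge 0} and 0
#' otherwise (causality).
#'
#' @param gamma_p Dilution rate \eqn{\gamma_P} (per second) lumping efflux,
#'   growth and division.
#' @param volume Average cell volume \eqn{V_{Cell}} (cubic micrometres).
#' @return Object of class `diffusion_kernel`.
#' @export
homogeneous_kernel <- function(gamma_p, volume) {
  stopifnot(gamma_p > 0, volume > 0)
  fn <- function(t) ifelse(t < 0, 0, exp(-gamma_p * t) / volume)
  structure(list(fn = fn, type = "homogeneous", gamma_p = gamma_p,
                 volume = volume, integral = 1 / (gamma_p * volume)),
            class = "diffusion_kernel")
}

#' Custom diffusion kernel
#'
#' Wrap an arbitrary causal, nonnegative, integrable concentration kernel
#' \eqn{\phi(t)}. The evaluator must return 0 for `t < 0`.
#'
#' @param fn Function of time returning the concentration contribution.
#' @param integral Optional known value of \eqn{\int_0^\infty \phi}; if `NA`
#'   it is computed numerically when needed.
#' @return Object of class `diffusion_kernel`.
#' @export
custom_kernel <- function(fn, integral = NA_real_) {
  stopifnot(is.function(fn))
  structure(list(fn = fn, type = "custom", integral = integral),
            class = "diffusion_kernel")
}

kernel_integral <- function(kernel) {
  if (is.finite(kernel$integral)) return(kernel$integral)
  integrate(kernel$fn, 0, Inf, rel.tol = 1e-10)$value
}

#' Operator-occupancy law as a function of TF concentration
#'
#' Equilibrium probability that the operator is specifically bound given the
#' local TF concentration \eqn{\rho}. With a combined binding constant
#' \eqn{K = K_{NS} K_{SP}} (units of volume) and strong specific binding
#' (\eqn{K_{SP} \gg 1}) this is the Michaelis-Menten-type saturation
#' \eqn{p_0 = K\rho/(1 + K\rho)}; for finite `K_sp` the unapproximated form
#' \eqn{p_0 = K\rho/(1 + K\rho(1 + 1/K_{SP}))} is used, which accounts for the
#' weight of the nonspecifically bound intermediate.
#'
#' @param rho TF concentration(s), nonnegative.
#' @param K Combined binding constant (volume units).
#' @param K_sp Specific-binding equilibrium constant; `Inf` (default) selects
#'   the strong-binding approximation.
#' @return Occupancy probability in `[0, 1]`.
#' @export
p0_occupancy <- function(rho, K, K_sp = Inf) {
  stopifnot(K > 0, K_sp > 0)
  K * rho / (1 + K * rho * (1 + 1 / K_sp))
}

#' Analytical TF expression model
#'
#' Parameter bundle for the exact model of the TF concentration: transcription
#' switched on at time zero at rate `a_tf` (mRNA birth-death with decay
#' `gamma_m`), translation at rate `v_tf` per transcript (mean translational
#' burst size \eqn{b_{TF} = v_{TF}/\gamma_m}), a `kappa`-step maturation delay,
#' and a diffusion/dilution kernel mapping mature-protein emergence events to
#' the concentration at the operator.
#'
#' @param a_tf Transcription rate (mRNA per second, for t >= 0).
#' @param gamma_m mRNA degradation rate (per molecule per second).
#' @param v_tf Translation rate (proteins per mRNA per second).
#' @param delay A [maturation_delay()]; `maturation_delay()` (kappa = 0) for
#'   instantaneous maturation.
#' @param gamma_p Protein dilution rate (per second).
#' @param volume Cell volume (cubic micrometres).
#' @param binding_K Combined TF-operator binding constant \eqn{K} (volume
#'   units), see [p0_occupancy()].
#' @param K_sp Specific-binding equilibrium constant (default `Inf`: strong
#'   binding approximation).
#' @param kernel Optional [custom_kernel()]; default is the
#'   [homogeneous_kernel()] built from `gamma_p` and `volume`.
#' @return Object of class `tf_model`.
#' @examples
#' m <- tf_model(a_tf = 0.002, gamma_m = 1/120, v_tf = 0.05,
#'               delay = maturation_delay(c(0.02, 0.02)),
#'               gamma_p = 2e-4, volume = 1, binding_K = 0.15)
#' tf_stationary(m)$mean  # a_tf * b_tf / (gamma_p * V) = 60
#' @export
tf_model <- function(a_tf, gamma_m, v_tf, delay = maturation_delay(),
                     gamma_p, volume = 1, binding_K, K_sp = Inf,
                     kernel = NULL) {
  stopifnot(a_tf > 0, gamma_m > 0, v_tf > 0, gamma_p > 0, volume > 0,
            binding_K > 0, K_sp > 0, inherits(delay, "maturation_delay"))
  if (is.null(kernel)) kernel <- homogeneous_kernel(gamma_p, volume)
  stopifnot(inherits(kernel, "diffusion_kernel"))
  structure(list(a_tf = a_tf, gamma_m = gamma_m, v_tf = v_tf,
                 burst_size = v_tf / gamma_m, delay = delay,
                 gamma_p = gamma_p, volume = volume,
                 binding_K = binding_K, K_sp = K_sp, kernel = kernel),
            class = "tf_model")
}

#' @export
print.tf_model <- function(x, ...) {
  cat("TF expression model\n")
  cat(sprintf("  transcription a_TF = %g /s, mRNA decay gamma_m = %g /s\n",
              x$a_tf, x$gamma_m))
  cat(sprintf("  translation v_TF = %g /s  (burst size b_TF = %g)\n",
              x$v_tf, x$burst_size))
  print(x$delay)
  cat(sprintf("  dilution gamma_P = %g /s, volume = %g um^3, kernel: %s\n",
              x$gamma_p, x$volume, x$kernel$type))
  cat(sprintf("  binding K = %g um^3 (K_SP = %g)\n", x$binding_K, x$K_sp))
  invisible(x)
}

#' Numerical controls for the TF analytics
#'
#' @param n_grid Number of grid intervals for the trapezoidal convolution
#'   machinery, or `NULL` to choose automatically from the model rates (grid
#'   spacing about 0.05 of the fastest timescale, between 2048 and 2^18
#'   intervals). All quadratures are Richardson-extrapolated from grids `n`
#'   and `2n`.
#' @param occ_panels Panel boundaries for the composite Gauss-Legendre
#'   evaluation of the semi-infinite occupancy integral (integrand is damped
#'   by \eqn{e^{-x}}; truncation at the last boundary).
#' @param occ_nodes Gauss-Legendre nodes per panel.
#' @param lambda_rel Step for the small-\eqn{\lambda} polynomial fit used by
#'   [tf_moments_fd()], relative to the reciprocal stationary mean.
#' @return List of class `tf_control`.
#' @export
tf_control <- function(n_grid = NULL,
                       occ_panels = c(0, 0.5, 1, 2, 3, 4, 6, 8, 12, 16, 24, 40),
                       occ_nodes = 16L, lambda_rel = 0.05) {
  structure(list(n_grid = n_grid, occ_panels = occ_panels,
                 occ_nodes = occ_nodes, lambda_rel = lambda_rel),
            class = "tf_control")
}
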