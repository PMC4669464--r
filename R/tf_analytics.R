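# Exact analytical model of the TF concentration and operator occupancy.
#
# The TF concentration is a shot-noise functional of the protein synthesis
# point process: synthesis events occur as a Poisson process with stochastic
# intensity v_TF * N_mRNA(t) (N_mRNA an immigration-death process started at
# zero when transcription switches on), each event is delayed by an
# independent maturation delay with density f_Delta, and a molecule that
# matured at time s contributes phi(t - s) to the concentration at the
# operator. Conditioning on the mRNA path (Campbell's formula) and averaging
# over the independent mRNA lifetimes (an M/M/infinity property) gives the
# closed Laplace functional
#   <exp(-lambda rho(t))> = exp(-a_TF int_0^t (1 - G(tau)) dtau),
#   F(lambda, x) = (f_Delta * (1 - e^{-lambda phi}))(x),
#   G(tau) = e^{-v Fhat(tau)} [gamma_m int_0^tau e^{-gamma_m (tau-y)}
#                              e^{v Fhat(y)} dy + e^{-gamma_m tau}],
# with Fhat the running integral of F. G is evaluated by a stable log-space
# Volterra recursion (compiled); everything else is FFT trapezoid quadrature
# with Richardson extrapolation.

#' Laplace functional of the TF concentration
#'
#' Evaluates \eqn{\langle e^{-\lambda\rho(t)}\rangle} for the delayed,
#' burst-driven expression model. Equals 1 at \eqn{\lambda = 0} and at
#' \eqn{t = 0} (the concentration starts at zero by causality), and is
#' completely monotone (nonincreasing, convex) in \eqn{\lambda}.
#'
#' @param lambda Nonnegative Laplace variable(s) (reciprocal concentration).
#' @param t Nonnegative time(s) (seconds).
#' @param model A [tf_model()].
#' @param control A [tf_control()].
#' @return Matrix `length(t) x length(lambda)` (dropped to a vector when
#'   either argument is scalar) of values in `(0, 1]`. If the quadrature
#'   fails to produce finite values the error reports the achieved Richardson
#'   tolerance.
#' @export
tf_laplace <- function(lambda, t, model, control = tf_control()) {
  stopifnot(inherits(model, "tf_model"), all(lambda >= 0), all(t >= 0))
  hn <- tf_horizon_n(model, t, control)
  y <- tf_richardson(function(n) tf_core_loglap(model, lambda, hn$horizon, n),
                     hn$horizon, hn$n, t)
  tol <- attr(y, "tol_est")
  y <- matrix(y, nrow = length(t), ncol = length(lambda))
  y[t == 0, ] <- 0
  y[, lambda == 0] <- 0
  out <- exp(y)
  if (any(!is.finite(out)))
    stop("Laplace-functional quadrature failed to converge (tol ", tol, ")")
  drop(out)
}

#' Mean TF concentration time course
#'
#' The mean concentration is the triple convolution
#' \eqn{\langle\rho(t)\rangle = a_{TF} b_{TF}\,
#' (1 - e^{-\gamma_m \cdot}) * f_\Delta * \phi\,(t)}: transcript-pool
#' equilibration, maturation delay and dilution kernel in series. At small
#' times it grows like \eqn{t^{\kappa+2}} (each maturation step adds one power
#' of time), and for the homogeneous kernel it approaches the stationary value
#' \eqn{a_{TF} b_{TF}/(\gamma_P V_{Cell})}.
#'
#' @inheritParams tf_laplace
#' @return Mean concentration(s) at `t`.
#' @export
tf_mean <- function(t, model, control = tf_control()) {
  stopifnot(inherits(model, "tf_model"), all(t >= 0))
  hn <- tf_horizon_n(model, t, control)
  y <- as.numeric(tf_richardson(function(n)
    tf_core_moments(model, hn$horizon, n)$mean, hn$horizon, hn$n, t))
  y[t == 0] <- 0
  pmax(y, 0)
}

#' Variance of the TF concentration
#'
#' Exact variance time course of the shot-noise expression model. Unlike the
#' mean it is not a single convolution: conditioning on the mRNA path splits
#' it into a filtered-Poisson part \eqn{a_{TF} b_{TF}\,(1-e^{-\gamma_m\cdot}) *
#' f_\Delta * \phi^2} and an mRNA-covariance part proportional to
#' \eqn{v_{TF}^2}. Both are sigmoidal in time; the result matches the second
#' \eqn{\lambda}-derivative of [tf_laplace()] at \eqn{\lambda \to 0} (see
#' [tf_moments_fd()]). In the limit of instantaneous translational bursts and
#' no maturation delay it reduces to the compound-Poisson (geometric-burst)
#' form with stationary value \eqn{a_{TF} b_{TF}(2 b_{TF}+1)/(2\gamma_P V^2)}.
#'
#' @inheritParams tf_laplace
#' @return Variance(s) of the concentration at `t`.
#' @export
tf_variance <- function(t, model, control = tf_control()) {
  stopifnot(inherits(model, "tf_model"), all(t >= 0))
  hn <- tf_horizon_n(model, t, control)
  y <- as.numeric(tf_richardson(function(n)
    tf_core_moments(model, hn$horizon, n)$var, hn$horizon, hn$n, t))
  y[t == 0] <- 0
  pmax(y, 0)
}

#' Stationary mean and variance (closed form, homogeneous kernel)
#'
#' Exact long-time limits obtained by exponential-term algebra: the mean is
#' \eqn{a_{TF} b_{TF}/(\gamma_P V)}; the variance is
#' \eqn{a_{TF} b_{TF}/(2\gamma_P V^2)} (filtered-Poisson floor) plus the
#' burst term \eqn{2 a_{TF} v_{TF}^2/\gamma_m \int_0^\infty q A} with
#' \eqn{q = f_\Delta * \phi}, \eqn{A = e^{-\gamma_m\cdot} * q}, both reduced to
#' closed form. Serves as an independent oracle for [tf_variance()] at large
#' times.
#'
#' @param model A [tf_model()] with the homogeneous kernel.
#' @return List with `mean` and `variance`.
#' @export
tf_stationary <- function(model) {
  stopifnot(inherits(model, "tf_model"))
  if (model$kernel$type != "homogeneous")
    stop("closed-form stationary moments require the homogeneous kernel; ",
         "evaluate tf_mean()/tf_variance() at a large time instead")
  a <- model$a_tf; b <- model$burst_size; v <- model$v_tf
  gm <- model$gamma_m; gp <- model$gamma_p; V <- model$volume
  # q = f_Delta * phi as exponential terms
  if (model$delay$kappa > 0L) {
    q <- conv_terms_exp(delay_terms(model$delay$rates), gp)
    q$coef <- q$coef / (gp * V)
  } else {
    q <- data.frame(coef = 1 / V, pow = 0, rate = gp)
  }
  A <- conv_terms_exp(q, gm)
  A$coef <- A$coef / gm
  term2 <- 2 * a * v^2 / gm * integrate_terms(multiply_terms(q, A))
  list(mean = a * b / (gp * V),
       variance = a * b / (2 * gp * V^2) + term2)
}

#' Moments from the Laplace functional (derivative cross-check)
#'
#' Extracts the mean and variance of the concentration from the cumulant
#' expansion \eqn{\log\langle e^{-\lambda\rho}\rangle = -\mu\lambda +
#' \mathrm{Var}\,\lambda^2/2 - \dots} by fitting a degree-6 polynomial (no
#' constant term) to the log Laplace functional at six small positive
#' \eqn{\lambda} values. Because the functional is evaluated only for
#' \eqn{\lambda \ge 0}, this one-sided fit replaces central differences; its
#' truncation error is of the same (higher) order.
#'
#' @inheritParams tf_laplace
#' @return List of vectors `mean` and `variance` at `t`.
#' @export
tf_moments_fd <- function(t, model, control = tf_control()) {
  stopifnot(inherits(model, "tf_model"), all(t >= 0))
  scale_mean <- model$a_tf * model$burst_size * kernel_integral(model$kernel)
  lh <- control$lambda_rel / scale_mean
  lam <- lh * (1:6)
  hn <- tf_horizon_n(model, t, control)
  # the quadratic lambda-coefficient is small against log LT itself, so the
  # derivative extraction needs a finer grid than the moment quadratures
  if (is.null(control$n_grid)) hn$n <- as.integer(min(2^18, 8L * hn$n))
  L <- tf_richardson(function(n) tf_core_loglap(model, lam, hn$horizon, n),
                     hn$horizon, hn$n, t)
  L <- matrix(L, nrow = length(t), ncol = 6L)
  U <- outer(1:6, 1:6, `^`)        # Vandermonde in scaled lambda, powers 1..6
  cf <- t(solve(U, t(L)))          # rows: coefficients c1..c6 per time
  mu <- -cf[, 1] / lh
  va <- 2 * cf[, 2] / lh^2
  mu[t == 0] <- 0; va[t == 0] <- 0
  list(mean = mu, variance = va)
}

occ_lambda_nodes <- function(control) {
  pan <- control$occ_panels
  nn <- control$occ_nodes
  xs <- numeric(0); ws <- numeric(0)
  for (i in seq_len(length(pan) - 1L)) {
    gl <- pracma::gaussLegendre(nn, pan[i], pan[i + 1L])
    xs <- c(xs, gl$x); ws <- c(ws, gl$w)
  }
  list(x = xs, w = ws * exp(-xs))
}

occ_scaling <- function(model) {
  if (is.finite(model$K_sp)) {
    list(Keff = model$binding_K * (1 + 1 / model$K_sp),
         cfac = model$K_sp / (1 + model$K_sp))
  } else list(Keff = model$binding_K, cfac = 1)
}

#' Exact mean operator occupancy
#'
#' The population-averaged probability that the operator is specifically
#' bound, \eqn{\langle p_0(\rho(t))\rangle}, computed from the identity
#' \eqn{\langle K\rho/(1+K\rho)\rangle = 1 - \int_0^\infty e^{-x}
#' \langle e^{-xK\rho}\rangle dx} by integrating the Laplace functional over a
#' fixed set of damped Gauss-Legendre nodes (shared across the whole time
#' course). Monotone nondecreasing in the binding constant.
#'
#' @inheritParams tf_laplace
#' @return Occupancy probability(ies) in `[0, 1]` at `t`.
#' @export
occupancy_exact <- function(t, model, control = tf_control()) {
  stopifnot(inherits(model, "tf_model"), all(t >= 0))
  sc <- occ_scaling(model)
  nodes <- occ_lambda_nodes(control)
  lam <- nodes$x * sc$Keff
  hn <- tf_horizon_n(model, t, control)
  fun <- function(n) {
    L <- tf_core_loglap(model, lam, hn$horizon, n)
    sc$cfac * (1 - as.vector(exp(L) %*% nodes$w))
  }
  y <- as.numeric(tf_richardson(fun, hn$horizon, hn$n, t))
  y[t == 0] <- 0
  pmin(pmax(y, 0), 1)
}

#' Deterministic (MME) occupancy approximation
#'
#' Occupancy law evaluated at the mean concentration,
#' \eqn{p_0(\langle\rho(t)\rangle)}: the Jensen upper bound on the exact mean
#' occupancy.
#'
#' @inheritParams tf_laplace
#' @return Occupancy approximation at `t`.
#' @export
occupancy_mme <- function(t, model, control = tf_control()) {
  p0_occupancy(tf_mean(t, model, control), model$binding_K, model$K_sp)
}

#' Variance-corrected (VCMME) occupancy approximation
#'
#' Applies the variance-corrected Michaelis-Menten equation to the occupancy
#' law (a Michaelis-Menten-type saturation with Michaelis constant
#' \eqn{1/K}), using the exact analytic mean and variance of the TF
#' concentration. Never exceeds [occupancy_mme()].
#'
#' @inheritParams tf_laplace
#' @return Variance-corrected occupancy at `t` (not clamped below at 0).
#' @export
occupancy_vcmme <- function(t, model, control = tf_control()) {
  sc <- occ_scaling(model)
  km <- 1 / sc$Keff
  mu <- tf_mean(t, model, control)
  va <- tf_variance(t, model, control)
  sc$cfac * (mu / (mu + km) - km * va / (mu + km)^3)
}

#' Poisson-fluctuation occupancy approximation
#'
#' Mean occupancy under the surrogate assumption that the TF copy number is
#' Poisson distributed with mean \eqn{m(t) = \langle\rho(t)\rangle V}:
#' \eqn{\langle p_0\rangle = 1 - c\int_0^1 x^{c-1} e^{-m(1-x)}dx} with
#' \eqn{c = V/K} (from the probability generating function of the Poisson
#' law), evaluated after integrating by parts as
#' \eqn{m\int_0^1 x^{c} e^{-m(1-x)}dx} so the integrand stays bounded for all
#' binding strengths. Captures copy-number discreteness but not translational
#' bursting. In the strong-binding limit \eqn{K \to \infty} it tends to
#' \eqn{1 - e^{-m}}, the probability of at least one TF molecule.
#'
#' @inheritParams tf_laplace
#' @return Poisson-model occupancy at `t`.
#' @export
occupancy_poisson <- function(t, model, control = tf_control()) {
  sc <- occ_scaling(model)
  m <- tf_mean(t, model, control) * model$volume
  cc <- model$volume / sc$Keff
  one <- function(mi) {
    if (mi <= 0) return(0)
    mi * stats::integrate(function(x) x^cc * exp(-mi * (1 - x)),
                          0, 1, rel.tol = 1e-10, abs.tol = 1e-12)$value
  }
  sc$cfac * vapply(m, one, numeric(1))
}

#' Difference between the MME and exact occupancy
#'
#' \eqn{p_0(\langle\rho(t)\rangle) - \langle p_0(\rho(t))\rangle}: the error
#' committed by the deterministic occupancy law. Nonnegative for all times
#' (Jensen). Its initial rise is proportional to the concentration variance
#' (leading coefficient \eqn{K^2} from the quadratic term of the occupancy
#' law), it attains an interior maximum at intermediate times, and relaxes to
#' a small stationary value.
#'
#' @inheritParams tf_laplace
#' @return Signed difference(s) at `t`.
#' @export
correction_difference <- function(t, model, control = tf_control()) {
  occupancy_mme(t, model, control) - occupancy_exact(t, model, control)
}

#' Ratio of exact to MME occupancy
#'
#' \eqn{\langle p_0(\rho(t))\rangle / p_0(\langle\rho(t)\rangle)}, in
#' `[0, 1]`. Undefined at `t = 0` where both occupancies vanish; `NaN` is
#' returned there.
#'
#' @inheritParams tf_laplace
#' @return Ratio(s) at `t`; `NaN` where the MME occupancy is zero.
#' @export
correction_ratio <- function(t, model, control = tf_control()) {
  num <- occupancy_exact(t, model, control)
  den <- occupancy_mme(t, model, control)
  out <- ifelse(den > 0, num / den, NaN)
  as.numeric(out)
}
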