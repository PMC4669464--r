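#' Michaelis-Menten rate parameters
#'
#' Bundle of the Michaelis constant \eqn{K_M} and the maximal rate
#' \eqn{v_{max}}. All rate-law functions in this package work with the
#' normalised rate \eqn{v_0 = v/v_{max} \in [0,1)}; `v_max` is only used to
#' de-normalise at the presentation layer.
#'
#' @param michaelis_constant Michaelis constant \eqn{K_M > 0}, in the same
#'   units as the substrate concentration (e.g. copies per cubic micrometre).
#' @param v_max Maximal rate \eqn{v_{max} > 0} (reactions per unit time).
#' @return Object of class `rate_params`.
#' @examples
#' rp <- rate_params(100)
#' mme(100, rp)  # 0.5 at the half-saturation point
#' @export
rate_params <- function(michaelis_constant, v_max = 1) {
  stopifnot(is.numeric(michaelis_constant), length(michaelis_constant) == 1L,
            is.finite(michaelis_constant), michaelis_constant > 0,
            is.numeric(v_max), length(v_max) == 1L, is.finite(v_max), v_max > 0)
  structure(list(michaelis_constant = michaelis_constant, v_max = v_max),
            class = "rate_params")
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Michaelis-Menten rate parameters\n")
  cat("  K_M  :", x$michaelis_constant, "\n")
  cat("  v_max:", x$v_max, "\n")
  invisible(x)
}

#' Moments of a fluctuating concentration
#'
#' Mean, variance and (optionally) higher central moments of a nonnegative
#' random concentration, as consumed by the moment-based rate laws. `mean` and
#' `variance` may be equal-length vectors (e.g. a time course).
#'
#' @param mean Mean concentration(s), nonnegative.
#' @param variance Variance(s) of the concentration, nonnegative; a mean of
#'   zero forces a variance of zero.
#' @param central Optional list of higher central moments, ordered from order 3
#'   upward; each element a vector conformable with `mean`.
#' @return Object of class `conc_moments`.
#' @export
conc_moments <- function(mean, variance = 0, central = NULL) {
  stopifnot(is.numeric(mean), all(is.finite(mean)),
            is.numeric(variance), all(is.finite(variance)))
  n <- max(length(mean), length(variance))
  mean <- rep_len(mean, n); variance <- rep_len(variance, n)
  if (any(mean < 0)) stop("mean concentration must be nonnegative")
  if (any(variance < 0)) stop("variance must be nonnegative")
  if (any(mean == 0 & variance > 0))
    stop("a zero mean concentration forces zero variance")
  if (!is.null(central)) {
    stopifnot(is.list(central))
    central <- lapply(central, function(m) rep_len(as.numeric(m), n))
  }
  structure(list(mean = mean, variance = variance, central = central),
            class = "conc_moments")
}

as_conc_moments <- function(x) {
  if (inherits(x, "conc_moments")) return(x)
  if (is.list(x) && !is.null(x$mean))
    return(conc_moments(x$mean, if (is.null(x$variance)) 0 else x$variance,
                        x$central))
  stop("expected a 'conc_moments' object (see conc_moments())")
}

#' Discrete concentration distribution
#'
#' A finite distribution over nonnegative concentrations, used as input for
#' the brute-force ensemble-averaged rate [exact_ensemble_rate()] that anchors
#' the bound and series checks.
#'
#' @param support Distinct nonnegative concentration values.
#' @param prob Probability weights; must be nonnegative and sum to 1 within
#'   `1e-12`.
#' @return Object of class `conc_dist`.
#' @export
conc_dist <- function(support, prob) {
  stopifnot(is.numeric(support), is.numeric(prob),
            length(support) == length(prob), length(support) >= 1L)
  if (any(!is.finite(support)) || any(support < 0))
    stop("support values must be finite and nonnegative")
  if (anyDuplicated(support)) stop("support values must be distinct")
  if (any(!is.finite(prob)) || any(prob < 0)) stop("weights must be nonnegative")
  if (abs(sum(prob) - 1) > 1e-12) stop("weights must sum to 1 (tolerance 1e-12)")
  structure(list(support = as.numeric(support), prob = as.numeric(prob)),
            class = "conc_dist")
}

#' Central moments of a discrete concentration distribution
#'
#' @param dist A [conc_dist()] object.
#' @param order Highest central-moment order to return (>= 2).
#' @return A [conc_moments()] object with central moments up to `order`.
#' @export
dist_moments <- function(dist, order = 2L) {
  stopifnot(inherits(dist, "conc_dist"), order >= 2L)
  mu <- sum(dist$prob * dist$support)
  cm <- vapply(2:order, function(k) sum(dist$prob * (dist$support - mu)^k),
               numeric(1))
  conc_moments(mu, cm[1L],
               central = if (order > 2L) as.list(cm[-1L]) else NULL)
}

#' Michaelis-Menten equation (normalised)
#'
#' The hyperbolic rate law \eqn{v_0(\rho) = \rho/(\rho + K_M)} evaluated at a
#' (mean) substrate concentration. Multiply by `params$v_max` for the
#' dimensional rate.
#'
#' @param mean Substrate concentration(s), nonnegative.
#' @param params A [rate_params()] object.
#' @return Normalised rate(s) in `[0, 1)`.
#' @examples
#' rp <- rate_params(2)
#' mme(c(0, 2, 6), rp)  # 0, 0.5, 0.75
#' @export
mme <- function(mean, params) {
  stopifnot(inherits(params, "rate_params"), is.numeric(mean))
  if (any(!is.finite(mean)) || any(mean < 0))
    stop("substrate concentration must be finite and nonnegative")
  mean / (mean + params$michaelis_constant)
}

#' Jensen upper bound on the ensemble-averaged rate
#'
#' Because the Michaelis-Menten law is concave in the concentration, the rate
#' evaluated at the mean bounds the ensemble-averaged rate from above
#' (Jensen's inequality): \eqn{\langle v_0(\rho)\rangle \le v_0(\langle\rho\rangle)}.
#' The bound depends on the mean alone and is attained exactly for a
#' degenerate (deterministic) concentration.
#'
#' @param moments A [conc_moments()] object (only the mean is used).
#' @inheritParams mme
#' @return Upper bound(s) on the normalised ensemble-averaged rate.
#' @export
jensen_upper_bound <- function(moments, params) {
  moments <- as_conc_moments(moments)
  mme(moments$mean, params)
}

#' Optimal two-moment lower bound on the ensemble-averaged rate
#'
#' Exact lower bound obtained from the integral form of the Taylor remainder
#' of the Michaelis-Menten law about the mean, using only the nonnegativity of
#' the concentration:
#' \deqn{\langle v_0 \rangle \ge \frac{\mu}{\mu+K_M} - \frac{\mathrm{Var}\,\rho}{(\mu+K_M)^2}.}
#' It is the sharpest bound expressible through the mean and variance alone
#' via this remainder, reduces to [mme()] for zero variance, and together with
#' [jensen_upper_bound()] sandwiches the exact average for every nonnegative
#' distribution.
#'
#' @inheritParams jensen_upper_bound
#' @return Lower bound(s) on the normalised ensemble-averaged rate (may be
#'   negative for extreme variance; no clamping is applied).
#' @export
optimal_lower_bound <- function(moments, params) {
  moments <- as_conc_moments(moments)
  K <- params$michaelis_constant
  mu <- moments$mean
  mme(mu, params) - moments$variance / (mu + K)^2
}

#' Variance-corrected Michaelis-Menten equation (VCMME)
#'
#' Second-order Taylor correction of the Michaelis-Menten law for a
#' fluctuating substrate concentration:
#' \deqn{v_0 \approx \frac{\mu}{\mu+K_M} - \frac{K_M\,\mathrm{Var}\,\rho}{(\mu+K_M)^3}.}
#' The value always lies between [optimal_lower_bound()] and
#' [jensen_upper_bound()], reduces to [mme()] in the deterministic limit, and
#' equals the midpoint of the two bounds exactly at \eqn{\mu = K_M}. The raw
#' formula is returned without clamping: for extreme variance it can be
#' negative, and the bounds -- not a clamp -- are the stated validity guard.
#'
#' @inheritParams jensen_upper_bound
#' @return Variance-corrected normalised rate(s).
#' @examples
#' rp <- rate_params(1)
#' vcmme(conc_moments(1, 1), rp)  # 0.375 = 1/2 - 1/8
#' @export
vcmme <- function(moments, params) {
  moments <- as_conc_moments(moments)
  K <- params$michaelis_constant
  mu <- moments$mean
  mme(mu, params) - K * moments$variance / (mu + K)^3
}

#' Taylor-series rate of arbitrary order
#'
#' Truncation of the full Taylor series of the ensemble-averaged
#' Michaelis-Menten rate about the mean,
#' \deqn{\langle v_0\rangle = \frac{\mu}{\mu+K_M} +
#'   \sum_{n\ge2} (-1)^{n+1} \frac{K_M\,\langle(\rho-\mu)^n\rangle}{(\mu+K_M)^{n+1}},}
#' truncated so that the last term has the requested order. For right-skewed
#' concentration distributions the series is typically alternating, and the
#' order-3/4 truncations can be poorer than the order-2 (VCMME) truncation.
#'
#' @inheritParams jensen_upper_bound
#' @param order Order of the last retained term (integer, >= 2). Order 2
#'   coincides with [vcmme()]. Central moments up to `order` must be present in
#'   `moments` (orders 3+ in `moments$central`).
#' @return Truncated-series normalised rate(s).
#' @export
taylor_rate <- function(moments, params, order = 2L) {
  moments <- as_conc_moments(moments)
  stopifnot(length(order) == 1L, order >= 2L, order == as.integer(order))
  order <- as.integer(order)
  n_have <- 2L + length(moments$central)
  if (order > n_have)
    stop("central moments up to order ", order, " required, have ", n_have)
  K <- params$michaelis_constant
  mu <- moments$mean
  out <- mme(mu, params)
  for (n in 2:order) {
    mn <- if (n == 2L) moments$variance else moments$central[[n - 2L]]
    out <- out + (-1)^(n + 1) * K * mn / (mu + K)^(n + 1)
  }
  out
}

#' Exact ensemble-averaged rate over a discrete distribution
#'
#' Brute-force oracle: the exact weighted average
#' \eqn{\langle v_0\rangle = \sum_i p_i\, \rho_i/(\rho_i + K_M)} of the
#' Michaelis-Menten law over a finite concentration distribution. Used to
#' anchor the bound sandwich and the Taylor-series checks.
#'
#' @param dist A [conc_dist()] object.
#' @inheritParams mme
#' @return Exact normalised ensemble-averaged rate.
#' @export
exact_ensemble_rate <- function(dist, params) {
  stopifnot(inherits(dist, "conc_dist"))
  sum(dist$prob * mme(dist$support, params))
}
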