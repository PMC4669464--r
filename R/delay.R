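# Maturation delay: sum of kappa independent exponential stages.
# The density is represented internally as a list of terms
#   coef * t^pow * exp(-rate * t),
# built by convolving exponentials one stage at a time. The term algebra is
# exact for repeated rates (Erlang) and for arbitrary mixtures; rates closer
# than a relative 1e-6 are merged into the confluent (equal-rate) branch to
# avoid catastrophic cancellation in the partial-fraction coefficients.

EQUAL_RATE_RTOL <- 1e-6

# convolve a term table (data.frame coef,pow,rate) with delta*exp(-delta t)
conv_terms_exp <- function(terms, delta) {
  out <- list()
  for (i in seq_len(nrow(terms))) {
    cf <- terms$coef[i]; p <- terms$pow[i]; d <- terms$rate[i]
    a <- d - delta
    if (abs(a) <= EQUAL_RATE_RTOL * max(d, delta)) {
      # equal-rate (confluent) branch: c t^p e^{-dt} * de^{-dt} -> c d t^{p+1}/(p+1) e^{-dt}
      out[[length(out) + 1L]] <-
        data.frame(coef = cf * delta / (p + 1), pow = p + 1, rate = delta)
    } else {
      # int_0^t x^p e^{-ax} dx = p!/a^{p+1} (1 - e^{-at} sum_j (at)^j/j!)
      base <- cf * delta * factorial(p) / a^(p + 1)
      j <- 0:p
      out[[length(out) + 1L]] <- rbind(
        data.frame(coef = base, pow = 0, rate = delta),
        data.frame(coef = -base * a^j / factorial(j), pow = j, rate = d))
    }
  }
  tt <- do.call(rbind, out)
  # merge identical (pow, rate) terms to keep the table small
  key <- paste(tt$pow, signif(tt$rate, 12))
  agg <- rowsum(tt$coef, key)
  parts <- strsplit(rownames(agg), " ", fixed = TRUE)
  data.frame(coef = as.numeric(agg),
             pow = as.numeric(vapply(parts, `[`, "", 1L)),
             rate = as.numeric(vapply(parts, `[`, "", 2L)))
}

delay_terms <- function(rates) {
  terms <- data.frame(coef = rates[1L], pow = 0, rate = rates[1L])
  for (d in rates[-1L]) terms <- conv_terms_exp(terms, d)
  terms
}

eval_terms <- function(terms, t) {
  out <- numeric(length(t))
  pos <- t >= 0
  tp <- t[pos]
  acc <- numeric(length(tp))
  for (i in seq_len(nrow(terms)))
    acc <- acc + terms$coef[i] * tp^terms$pow[i] * exp(-terms$rate[i] * tp)
  out[pos] <- acc
  out
}

# integral over [0, Inf) of a term table (used for stationary moments)
integrate_terms <- function(terms) {
  sum(terms$coef * factorial(terms$pow) / terms$rate^(terms$pow + 1))
}

# product of two term tables (another term table)
multiply_terms <- function(a, b) {
  grid <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  data.frame(coef = a$coef[grid$i] * b$coef[grid$j],
             pow = a$pow[grid$i] + b$pow[grid$j],
             rate = a$rate[grid$i] + b$rate[grid$j])
}

#' Multi-step protein maturation delay
#'
#' The maturation of a freshly translated protein is modelled as `kappa`
#' sequential memoryless steps with rates \eqn{\delta_1, \dots, \delta_\kappa};
#' the total delay is the sum of independent exponentials (hypoexponential;
#' Erlang when all rates are equal). An empty rate vector means no maturation
#' delay (the delay is identically zero).
#'
#' @param rates Vector of positive per-time stage rates (possibly empty).
#' @return Object of class `maturation_delay`.
#' @examples
#' d <- maturation_delay(c(0.02, 0.02))
#' delay_density(d, 50)  # Erlang-2 density at t = 50
#' @export
maturation_delay <- function(rates = numeric()) {
  rates <- as.numeric(rates)
  if (length(rates) && (any(!is.finite(rates)) || any(rates <= 0)))
    stop("maturation rates must be finite and positive")
  structure(list(rates = rates, kappa = length(rates)),
            class = "maturation_delay")
}

#' @export
print.maturation_delay <- function(x, ...) {
  if (x$kappa == 0L) cat("maturation delay: none (kappa = 0)\n")
  else cat("maturation delay: kappa =", x$kappa,
           "steps, rates =", paste(signif(x$rates, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Probability density of the total maturation delay
#'
#' Density of the sum of the `kappa` independent exponential stage durations;
#' zero for negative times. Repeated (or nearly repeated) rates are handled by
#' the exact Erlang/confluent branch of the term algebra, so no rate
#' configuration is an error.
#'
#' @param delay A [maturation_delay()] with `kappa >= 1`.
#' @param t Time(s) at which to evaluate the density.
#' @return Density value(s) (per unit time).
#' @export
delay_density <- function(delay, t) {
  stopifnot(inherits(delay, "maturation_delay"))
  if (delay$kappa == 0L)
    stop("kappa = 0 has no density (the delay is a point mass at zero)")
  stopifnot(is.numeric(t), all(is.finite(t)))
  eval_terms(delay_terms(delay$rates), t)
}

#' Mean and variance of the maturation delay
#'
#' @inheritParams delay_density
#' @return List with elements `mean` (\eqn{\sum 1/\delta_i}) and `variance`
#'   (\eqn{\sum 1/\delta_i^2}).
#' @export
delay_moments <- function(delay) {
  stopifnot(inherits(delay, "maturation_delay"))
  list(mean = sum(1 / delay$rates), variance = sum(1 / delay$rates^2))
}
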