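# Internal grid machinery for the TF analytics.
#
# All convolutions are causal convolutions on a uniform grid evaluated by FFT
# with trapezoidal end-point correction; cumulative integrals are cumulative
# trapezoids. Public functions evaluate every quantity on grids with n and 2n
# intervals and Richardson-extrapolate (the trapezoid error is O(h^2), so the
# extrapolant is O(h^4)), then spline-interpolate onto the requested times.

cumtrapz_vec <- function(y, h) {
  n <- length(y)
  c(0, cumsum((y[-1] + y[-n]) / 2)) * h
}

cumtrapz_mat <- function(Y, h) {
  n <- nrow(Y)
  inc <- (Y[-1, , drop = FALSE] + Y[-n, , drop = FALSE]) / 2
  rbind(0, apply(inc, 2, cumsum)) * h
}

# trapezoid causal convolution of two sampled functions on the same grid
grid_conv <- function(f, g, h) {
  n <- length(f)
  np <- stats::nextn(2L * n)
  Ff <- stats::fft(c(f, rep(0, np - n)))
  Fg <- stats::fft(c(g, rep(0, np - n)))
  raw <- Re(stats::fft(Ff * Fg, inverse = TRUE))[seq_len(n)] / np
  h * raw - (h / 2) * (f[1] * g + g[1] * f)
}

# same, vectorized over the columns of G
grid_conv_mat <- function(f, G, h) {
  n <- length(f)
  np <- stats::nextn(2L * n)
  Ff <- stats::fft(c(f, rep(0, np - n)))
  FG <- stats::mvfft(rbind(G, matrix(0, np - n, ncol(G))))
  raw <- Re(stats::mvfft(FG * Ff, inverse = TRUE))[seq_len(n), , drop = FALSE] / np
  h * raw - (h / 2) * (f[1] * G + outer(f, G[1, ]))
}

tf_auto_n <- function(model, horizon) {
  rmax <- max(model$gamma_m, model$gamma_p, model$delay$rates, 0)
  if (rmax <= 0) rmax <- 1 / horizon
  n <- horizon / (0.05 / rmax)
  n <- 2^ceiling(log2(max(2048, min(n, 2^18))))
  as.integer(n)
}

tf_grid_setup <- function(model, horizon, n) {
  x <- seq(0, horizon, length.out = n + 1L)
  h <- horizon / n
  phi <- model$kernel$fn(x)
  fD <- if (model$delay$kappa > 0L) eval_terms(delay_terms(model$delay$rates), x)
        else NULL
  convd <- function(g) if (is.null(fD)) g else grid_conv(fD, g, h)
  convd_mat <- function(G) if (is.null(fD)) G else grid_conv_mat(fD, G, h)
  list(x = x, h = h, phi = phi, fD = fD, convd = convd, convd_mat = convd_mat)
}

# mean and variance time courses on one grid
tf_core_moments <- function(model, horizon, n) {
  gs <- tf_grid_setup(model, horizon, n)
  a <- model$a_tf; v <- model$v_tf; gm <- model$gamma_m; b <- model$burst_size
  q <- gs$convd(gs$phi)
  q2 <- gs$convd(gs$phi^2)
  u <- 1 - exp(-gm * gs$x)
  egm <- exp(-gm * gs$x)
  mean_t <- a * b * grid_conv(u, q, gs$h)
  A <- grid_conv(egm, q, gs$h)
  qA <- q * A
  var_t <- a * b * grid_conv(u, q2, gs$h) +
    (2 * a * v^2 / gm) * (cumtrapz_vec(qA, gs$h) - grid_conv(egm, qA, gs$h))
  list(x = gs$x, mean = mean_t, var = var_t)
}

# log Laplace transform on one grid; lambda a vector (lambda = 0 handled
# exactly). Returns (n+1) x length(lambda) matrix of log <exp(-lambda rho(t))>.
tf_core_loglap <- function(model, lambda, horizon, n) {
  gs <- tf_grid_setup(model, horizon, n)
  a <- model$a_tf; v <- model$v_tf; gm <- model$gamma_m
  pos <- lambda > 0
  out <- matrix(0, n + 1L, length(lambda))
  if (any(pos)) {
    W <- 1 - exp(-outer(gs$phi, lambda[pos]))
    Fm <- gs$convd_mat(W)
    Fint <- cumtrapz_mat(Fm, gs$h)
    G <- cpp_volterra_G(Fint, gm, v, gs$h)
    out[, pos] <- -a * cumtrapz_mat(1 - G, gs$h)
  }
  out
}

# Richardson-extrapolated evaluation at arbitrary times t of a grid functional.
# fun(n) must return a vector (or matrix) on the grid seq(0, horizon, n+1).
tf_richardson <- function(fun, horizon, n, t) {
  v1 <- fun(n)
  v2 <- fun(2L * n)
  interp <- function(vals, nn) {
    x <- seq(0, horizon, length.out = nn + 1L)
    if (is.matrix(vals))
      vapply(seq_len(ncol(vals)),
             function(j) stats::spline(x, vals[, j], xout = t, method = "natural")$y,
             numeric(length(t)))
    else stats::spline(x, vals, xout = t, method = "natural")$y
  }
  y1 <- interp(v1, n); y2 <- interp(v2, 2L * n)
  y <- (4 * y2 - y1) / 3
  if (!is.matrix(y) && length(t) == 1L) y <- unname(y)
  attr(y, "tol_est") <- max(abs(y2 - y1)) / 3
  y
}

tf_horizon_n <- function(model, t, control) {
  horizon <- max(t)
  if (horizon <= 0) horizon <- 1
  n <- if (is.null(control$n_grid)) tf_auto_n(model, horizon)
       else as.integer(control$n_grid)
  list(horizon = horizon, n = n)
}
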