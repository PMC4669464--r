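# Shared fixtures and small utilities for the test suite. Heavy shared
# computations are cached lazily so each is done at most once per run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# the gene-regulation study model (same parameters as the fig1b_like fixture)
tf_test_model <- function() get_fixture("fig1b_like")$model

# random nonnegative discrete concentration distributions for property tests
random_dist <- function(k_max = 6) {
  k <- sample(2:k_max, 1)
  support <- sort(stats::runif(k, 0, 50))
  if (stats::runif(1) < 0.3) support[1] <- 0
  p <- stats::rgamma(k, 1)
  conc_dist(support, p / sum(p))
}

# standard error of a sample variance via the fourth central moment
se_of_variance <- function(x) {
  n <- length(x)
  m4 <- mean((x - mean(x))^4)
  s2 <- stats::var(x)
  sqrt(pmax(m4 - (n - 3) / (n - 1) * s2^2, 0) / n)
}

binom_se <- function(p, n) sqrt(pmax(p * (1 - p), 1e-12) / n)

# independent-binding variant of a sequential genereg spec (detailed balance)
independent_variant <- function(spec) {
  spec$binding_model <- "independent"
  spec$d_off <- spec$ns_off
  spec$d_on <- (spec$ns_on / spec$ns_off) * (spec$sp_on / spec$sp_off) *
    spec$d_off
  spec
}
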