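---
title: "Variance-corrected Michaelis-Menten kinetics: model, numerics and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-corrected Michaelis-Menten kinetics: model, numerics and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcmme)
```

## The problem

The Michaelis-Menten equation (MME) gives the rate of an enzyme-catalysed
reaction as a hyperbolic function of the substrate concentration,
$v_0(\rho) = \rho/(\rho + K_M)$ in normalised form. Its derivation is
deterministic: concentrations are parameters, not random variables. In a
bacterial cell many "substrates" — in particular transcription factors (TFs)
regulating a target gene — are present in tens of copies, produced in
translational bursts, delayed by multi-step protein maturation, and diluted
by growth. Their concentration $\rho(t)$ is a stochastic process with large,
skewed fluctuations. The population-level rate is then the ensemble average
$\langle v_0(\rho(t))\rangle$, and because $v_0$ is concave, it is always
*below* the naive value $v_0(\langle\rho\rangle)$.

This package provides (i) sharp two-moment bounds and a variance-corrected
rate law for this situation, (ii) exact Gillespie simulators for the two
reaction networks used to probe it, and (iii) the exact analytical model of
the TF concentration and operator occupancy under delayed, bursty expression.

## Rate laws and bounds

By Jensen's inequality, $\langle v_0(\rho)\rangle \le
v_0(\langle\rho\rangle)$: the MME at the mean is an upper bound
(`jensen_upper_bound()`). For the lower bound, the integral-form Taylor
remainder of $v_0$ about the mean $\mu$ can be evaluated in closed form,

$$v_0(\rho) - v_0(\mu) - v_0'(\mu)(\rho-\mu)
  = -\frac{K_M\,(\rho-\mu)^2}{(\rho + K_M)(\mu+K_M)^2},$$

and bounding $1/(\rho+K_M) \le 1/K_M$ — which uses only $\rho \ge 0$ — gives
after averaging

$$\langle v_0\rangle \;\ge\; \frac{\mu}{\mu+K_M} -
  \frac{\mathrm{Var}\,\rho}{(\mu+K_M)^2}$$

(`optimal_lower_bound()`). The second-order Taylor truncation is the
variance-corrected MME (`vcmme()`),

$$v_0^{\mathrm{VC}} = \frac{\mu}{\mu+K_M} -
  \frac{K_M\,\mathrm{Var}\,\rho}{(\mu+K_M)^3},$$

which lies between the bounds for every mean and variance and equals their
midpoint exactly when $\mu = K_M$ (equate $K_M/(\mu+K_M)^3$ with
$1/\,2(\mu+K_M)^2$). Higher-order truncations (`taylor_rate()`) use central
moments supplied by the caller; for the right-skewed concentration
distributions typical of bursty expression the series alternates, and orders
3-4 can be worse than order 2 — one reason the variance truncation is the
practical choice, the other being that only the mean and variance are
experimentally accessible.

Two design points are deliberate. First, **no clamping**: `vcmme()` can go
negative for extreme variance; the bounds, not a clamp, delimit its validity,
and silently clamping would hide exactly the regime where the user should
switch to the bounds. Second, **normalisation**: every rate-law computation
works with $v_0 = v/v_{max}$; `v_max` enters only when de-normalising, since
the theory from the Jensen bound onward is stated for $v_0$.

`exact_ensemble_rate()` averages the MME over an explicit discrete
distribution and is the brute-force oracle behind the sandwich and series
tests (10^4 randomised nonnegative distributions, tolerance 1e-12 — these
are closed forms, no quadrature).

## Stochastic simulators

Both simulators are exact direct-method Gillespie implementations (compiled;
no tau-leaping — the networks are small, so exactness is cheap). Ensembles
derive per-run seeds from a base seed by a fixed affine counter, making them
reproducible and order-independent; zero total propensity idles the clock to
the horizon rather than erroring.

**Bursty-substrate enzyme** (`enzyme_system()`): substrate arrives in batches
of size $m$ at Poisson times, binds/unbinds a small pool of enzymes, and
leaves the volume only through catalysis. At fixed mean influx, batch input
makes the stationary substrate variance grow linearly in $m$, so the MME
evaluated at the measured mean overshoots the true (influx-pinned) rate by an
amount $\propto m$, while the VCMME tracks it — the central property the
acceptance suite measures. One accounting subtlety: for a single enzyme the
quasi-steady-state occupancy is exact in the *total* substrate count
$n$ (complexed molecule included), $p = n/(n + K_M V)$, whereas the
mean-field law for many enzymes is stated in the free concentration.
`ensemble_stats()` therefore averages total substrate when `n_enzymes == 1`
and free substrate otherwise; at 500-run resolution the distinction is
visible at batch size 1.

**TF expression cascade** (`genereg_system()`): transcription switches on at
$t=0$ (no transcripts, no protein, operator free), mRNA is a birth-death
process, each transcript translates at rate $v_{TF}$ (burst size
$b_{TF} = v_{TF}/\gamma_m$), proteins mature through $\kappa$ sequential
exponential steps, the mature pool dilutes at $\gamma_P$, and the TF binds
DNA nonspecifically before reaching the operator (`"sequential"`), or
additionally by a direct detailed-balance route (`"independent"`, which
equilibrates binding much faster without changing the equilibrium).
Immature proteins are not diluted — only the mature pool carries $\gamma_P$
— mirroring the analytic model in which the kernel acts from the moment of
mature-TF emergence.

**Two dilution conventions.** The analytic model treats each mature
molecule's concentration contribution as decaying deterministically,
$\phi(t) = e^{-\gamma_P t}/V_{Cell}$; a Gillespie dilution reaction instead
removes whole molecules stochastically. The two agree in the mean but differ
in the variance floor (count Fano factor $\tfrac12 + b$ versus $1 + b$ for
$\gamma_m \gg \gamma_P$). The simulator exposes both:
`dilution = "stochastic"` is the physical SSA; `dilution = "continuous"`
realises the kernel model exactly (the concentration decays deterministically
between events) and is the right Monte-Carlo oracle for the Laplace
functional and moment formulas. For occupancy the difference is
$\lesssim 10^{-2}$ in this regime, below the resolution of ensembles of a
few hundred cells.

## The analytical TF model

The TF concentration is a shot-noise functional: synthesis events form a
Poisson process with stochastic intensity $v_{TF} N_{mRNA}(t)$, each event is
delayed by an independent maturation delay $\Delta$ with hypoexponential
density $f_\Delta$ (`delay_density()`; the equal-rate Erlang and near-equal
confluent cases are handled by an exact term algebra rather than
partial-fraction formulas, switching branches at a relative rate gap of
1e-6), and a molecule maturing at time $s$ contributes $\phi(t-s)$.
Conditioning on the mRNA path (Campbell's formula) and using the independence
of individual transcript lifetimes (an M/M/$\infty$ property) yields a closed
Laplace functional

$$\langle e^{-\lambda\rho(t)}\rangle =
  \exp\!\Big(-a_{TF}\!\int_0^t \big(1 - G(\tau)\big)\,d\tau\Big),\qquad
  F(\lambda, x) = \big(f_\Delta * (1 - e^{-\lambda\phi})\big)(x),$$

$$G(\tau) = e^{-v_{TF}\hat F(\tau)}\Big[\gamma_m\!\int_0^\tau
  e^{-\gamma_m(\tau - y)}\,e^{v_{TF}\hat F(y)}\,dy + e^{-\gamma_m\tau}\Big],$$

with $\hat F$ the running integral of $F$. Differentiating at $\lambda = 0$
gives the mean as the triple convolution
$a_{TF} b_{TF}\,(1-e^{-\gamma_m\cdot}) * f_\Delta * \phi$ — transcript
equilibration, maturation, dilution — with stationary value
$a_{TF} b_{TF}/(\gamma_P V)$ and small-time growth $\propto t^{\kappa+2}$
(each maturation step adds one power of $t$, which is how $\kappa$ can be
read off response data). The variance is not a single convolution; the law of
total variance over the mRNA path splits it into a filtered-Poisson term
$a b\,(1-e^{-\gamma_m\cdot}) * f_\Delta * \phi^2$ and an mRNA-covariance term
$\propto v_{TF}^2$. Both routes (cumulants of the functional; direct
conditioning) give the same expression, and `tf_stationary()` reduces the
$t\to\infty$ limit to closed form by the same exponential term algebra,
yielding the stationary law $\mathrm{Var} = a b(\tfrac12 + b\,
\gamma_m/(\gamma_m+\gamma_P))/(\gamma_P V^2)$ for the homogeneous kernel —
the geometric-burst shot-noise form $a b(2b+1)/(2\gamma_P V^2)$ in the
instantaneous-burst limit. At fixed transcription rate the stationary
variance thus grows like $b^2$; note that fixing the *mean* instead (halving
$a$ while doubling $b$) only doubles it, since the mean scales with $ab$.

**Occupancy.** Mapping TF-operator binding onto the MM scheme, the occupancy
is $p_0(\rho) = K\rho/(1+K\rho)$ with $K = K_{NS}K_{SP}$ under strong
specific binding; the unapproximated form
$K\rho/(1 + K\rho(1 + 1/K_{SP}))$ is available via `K_sp`. The exact mean
occupancy uses the identity
$\langle K\rho/(1+K\rho)\rangle = 1 - \int_0^\infty e^{-x}
\langle e^{-xK\rho}\rangle\,dx$. `occupancy_mme()`, `occupancy_vcmme()` and
`occupancy_poisson()` are the deterministic, variance-corrected and
Poisson-copy-number approximations; `correction_difference()` and
`correction_ratio()` quantify the deterministic error, whose initial rise is
$\approx K^2\,\mathrm{Var}\,\rho(t)$ (the quadratic term of $p_0$; the
residual is the $O(K\cdot\mathrm{skewness})$ term, so the ratio plateaus
slightly below 1), whose maximum sits at intermediate times, and which decays
to a small stationary value set by the stationary VCMME correction.

## Numerics

* All convolutions and cumulative integrals are trapezoidal on a uniform
  grid, evaluated by FFT; every public quantity is computed on grids of $n$
  and $2n$ intervals and Richardson-extrapolated ($O(h^4)$). The grid is
  chosen automatically at about 20 points per fastest model timescale
  (2048-2^18 intervals), and `tf_control(n_grid=)` overrides it.
* $G$ is evaluated by a Volterra recursion in shifted (log-space) form so
  that every factor is $\le 1$; the naive form overflows since
  $v_{TF}\hat F(\tau)$ grows linearly in $\tau$.
* The semi-infinite occupancy integral uses fixed damped Gauss-Legendre
  panels on $x\in[0,40]$ (176 nodes; truncation error below $e^{-40}$,
  point-mass check exact to 1e-8). Fixed shared nodes — rather than the
  equally valid exponential substitution plus adaptive quadrature — let one
  grid evaluation of the Laplace functional serve an entire time course.
* Moment extraction from the functional (`tf_moments_fd()`) fits a degree-6
  polynomial without constant term to $\log\langle e^{-\lambda\rho}\rangle$
  at six small positive $\lambda$; one-sided because the stable recursion
  requires $\lambda \ge 0$, with truncation error of the same order as
  Richardson-extrapolated central differences. Working on the *log* scale
  makes the extraction a cumulant read-off and avoids catastrophic
  cancellation near $\lambda = 0$.
* The Poisson occupancy integral is integrated by parts to
  $m\int_0^1 x^{c}e^{-m(1-x)}dx$, removing the $x^{c-1}$ singularity so the
  same code covers arbitrarily strong binding.
* Stationary checks evaluate time courses at $t = 18/\gamma_P$ (residual
  transient $\sim e^{-18}$), against the closed-form term-algebra values.

## Fixtures: what they emulate, and what they do not

The shipped fixtures are representative parameter sets chosen once for the
regimes where the variance correction matters; quantities such as the
stationary substrate count at batch size 40 or the peak deterministic
occupancy error are parameter-dependent outputs of these choices, not
literature constants.

* `fig1a_like`: one enzyme, $K_M = 100$ copies/µm³, mean influx 0.5/s split
  into batches of 1-40, so the stationary state sits at half saturation where
  the variance correction is largest relative to the bounds. Stationary
  statistics use four snapshots at 3000-6000 s (several relaxation times of
  the substrate pool, $\tau \approx 400$ s) and rates are measured per run
  over the 3000-6000 s window; 500 runs per batch size.
* `fig1b_like`: an E. coli-like cascade — one transcript per 250 s, 2-minute
  mRNA lifetime, burst size 6, two 50 s maturation steps, dilution
  $2\times10^{-4}$/s, $V = 1$ µm³ (stationary mean 120 copies), and strong
  operator binding $K = 0.08$ µm³ ($K_{NS} = 4\times10^{-4}$ µm³,
  $K_{SP} = 200$, so the strong-binding approximation holds to ~0.5%). The
  interconversion rates ($sp_{on} = 10$/s against $ns_{off} = 1000$/s,
  $sp_{off} = 0.05$/s) make the effective operator kinetics slow enough that
  the sequential model's intermediate-state non-equilibrium is resolvable in
  the first ~4 minutes, yet fast enough that binding is equilibrated over the
  rest of the transient.
* `deterministic_limit`: 100 enzymes in 10 µm³ with single-molecule input —
  the large-copy control in which all estimators collapse onto the MME to
  within 1e-3.

The generator emulates intrinsic expression noise, bursting, maturation
delay, dilution and binding-state stochasticity. It does **not** emulate
explicit cell-division partitioning (dilution is a constant-rate proxy),
extrinsic parameter variability between cells, nucleoid structure or any
spatial inhomogeneity (the kernel interface accepts a user-supplied
$\phi(t)$, but the shipped kernel is well-mixed), or multi-operator and
cooperative (Hill-type) binding — for non-concave response laws the Jensen
bound itself fails, which is a stated limitation of the approach. Passing
tests therefore certify the mathematics and the implementation in this
idealised regime, not the full biology of any particular promoter.

## Known limitations

* The VCMME degrades when fluctuations are very large or strongly skewed
  relative to $\mu + K_M$ (early transient, tiny copy numbers); the bounds
  remain valid and are the recommended guard.
* The analytic occupancy assumes binding equilibrates instantaneously; the
  sequential simulator quantifies when that fails (early times, slow
  interconversion).
* Quadrature accuracy targets are ~1e-6 relative for moment time courses and
  ~1e-7 absolute for occupancies with default controls; pathological kernels
  (non-smooth, heavy-tailed) would need a custom `n_grid`.
* An ensemble's memory is (runs x grid) per tracked variable; event-resolved
  paths are kept only for single runs (`record = "events"`).

## Worked example

```{r example, eval = FALSE}
library(vcmme)
fx <- get_fixture("fig1b_like")
tg <- seq(0, 3600, by = 120)
tab <- compare_methods(list(fixture = "fig1b_like", n_runs = 500,
                            base_seed = 1, time_grid = tg))
attr(tab, "summary")
```

The table aligns the exact, MME, VCMME and Poisson occupancy curves with an
SSA ensemble; the summary reports each estimator's maximal deviation from
the exact curve and the time at which the deterministic error peaks. The
same quantities, together with the rate-law and Laplace-functional checks,
are recomputed from scratch by `scripts/acceptance.R`.
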