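# vcmme

Kinetics of enzymatic reactions and transcription-factor (TF) gene
regulation when the substrate concentration *fluctuates*. In bacteria, many
regulators are present in tens of copies, produced in translational bursts,
delayed by multi-step protein maturation and diluted by growth, so the
concentration seen by an enzyme or an operator is a strongly stochastic
process. The deterministic Michaelis–Menten equation (MME) then
systematically overestimates reaction rates and operator occupancies. This
package is for modellers and quantitative experimentalists who want to
quantify — and correct — that error using only measurable moments of the
concentration.

## What it computes

For a normalised Michaelis–Menten law `v0(ρ) = ρ/(ρ + K_M)` and a random
concentration with mean `μ` and variance `Var ρ`:

* **Jensen upper bound** — concavity gives `⟨v0(ρ)⟩ ≤ μ/(μ + K_M)`.
* **Optimal lower bound** — the integral-form Taylor remainder plus `ρ ≥ 0`
  give `⟨v0(ρ)⟩ ≥ μ/(μ + K_M) − Var ρ/(μ + K_M)²`.
* **Variance-corrected MME (VCMME)** —
  `v0 ≈ μ/(μ + K_M) − K_M·Var ρ/(μ + K_M)³`, which always lies between the
  bounds, reduces to the MME for zero variance, and equals the midpoint of
  the bounds exactly at `μ = K_M`. Higher-order Taylor truncations and an
  exact discrete-distribution average are included as cross-checks.
* **Exact Gillespie simulators** (compiled) for a bursty-substrate enzyme
  system and for a TF expression cascade — transcription switched on at
  t = 0, mRNA birth–death, translation (burst size `b_TF = v_TF/γ_m`),
  κ-step maturation, dilution, and sequential or independent operator
  binding — with reproducible seeded ensembles and summary statistics.
* **The exact analytical TF model** — hypoexponential maturation-delay
  density, the closed Laplace functional `⟨exp(−λρ(t))⟩` of the delayed
  shot-noise concentration, mean and variance time courses (mean
  `= a_TF b_TF (1−e^{−γ_m·}) * f_Δ * φ`, stationary value
  `a_TF b_TF/(γ_P V)`, small-time growth `t^{κ+2}`), and the operator
  occupancy `⟨Kρ/(1+Kρ)⟩` computed exactly from the Laplace functional,
  alongside its MME, VCMME and Poisson-copy-number approximations.

See `vignettes/vcmme-methods.Rmd` for the model, the numerics and the design
decisions, and `?vcmme` for the function index.

## Worked example

Bounds and correction for a concentration with mean 100, variance 5000 at
`K_M = 100` (the MME would report the half-maximal rate 0.5):

```r
library(vcmme)
rp  <- rate_params(michaelis_constant = 100)
mom <- conc_moments(mean = 100, variance = 5000)
jensen_upper_bound(mom, rp)   # 0.5
vcmme(mom, rp)                # 0.4375
optimal_lower_bound(mom, rp)  # 0.375
```

The true averaged rate is guaranteed to lie in [0.375, 0.5]; the VCMME
estimate 0.4375 says the deterministic law overestimates it by about 12%.

Occupancy estimators against a 2000-cell Gillespie ensemble for the built-in
E. coli-like fixture (`fig1b_like`: burst size 6, two 50 s maturation steps,
stationary mean 120 copies/µm³, binding constant 0.08 µm³):

```r
tab <- compare_methods(list(fixture = "fig1b_like", n_runs = 2000,
                            base_seed = 1, time_grid = seq(0, 3600, by = 120)))
tab[c(4, 7, 16, 31), ]
#  time exact   mme vcmme poisson simulation
#   360 0.175 0.228 0.159   0.217      0.160
#   720 0.388 0.477 0.379   0.466      0.384
#  1800 0.670 0.722 0.676   0.718      0.678
#  3600 0.804 0.825 0.806   0.823      0.794
attr(tab, "summary")
# max_dev_mme 0.0892 (at t = 720 s), max_dev_vcmme 0.0178,
# max_dev_poisson 0.0785, max_dev_simulation 0.025
```

The deterministic (MME) occupancy overshoots the exact transient by up to
0.089 around 12 minutes after induction; the VCMME tracks the exact curve
about five times more closely, and also beats the Poisson-fluctuation model.
The simulation column is the stochastic full model at Monte-Carlo resolution.

A thin command-line interface over the same functions ships in
`inst/cli/vcmme-tool.R` (verbs `simulate`, `analytics`, `compare`,
`fixtures list|show`), reading YAML/JSON experiment configs and writing TSV
tables with YAML sidecars.

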