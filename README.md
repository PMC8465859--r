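# nessflow

Turn stochastic equations of motion into an explicit nonequilibrium
steady-state (NESS) density — and read the statistics of "things" off it.

Many systems in biology and physics are described by a Langevin equation
`dx/dt = f(x) + w` with fluctuation variance `2Γ`, whose long-run behaviour
is a NESS density `p(x) ∝ exp(−ℑ(x))`. `nessflow` implements the
generalised Helmholtz decomposition of the expected flow,

    f(x) = Q(x) ∇ℑ(x) − Γ ∇ℑ(x) − Λ(x),      Λ_i = Σ_j ∂Ω_ij/∂x_j,  Ω = Q − Γ,

with the surprisal `ℑ` and the skew-symmetric solenoidal operator `Q`
expanded in a truncated polynomial basis. Estimating the coefficients from
samples of a flow field yields the steady-state density in closed form. At
quadratic order (the Laplace regime) the NESS is Gaussian with constant
precision `H = ∇²ℑ`, and zero entries of `H` are exact conditional
independencies — from which the package derives Markov boundaries,
particular partitions (external / sensory / active / internal states),
synchronisation maps between internal and external conditional
expectations, and variational free-energy gradient flows. It also
estimates expected local Lyapunov exponents and the Kaplan–Yorke dimension
under the fitted density, and integrates the Fokker–Planck equation on a
grid (with information length) to watch a density relax to its steady
state.

The chaotic Lorenz system and two coupled Lorenz systems are built in as
worked examples and as the test-fixture generators; the package is aimed at
researchers in stochastic dynamics, self-organisation and Bayesian
mechanics who want these constructions executable and testable.

## A worked example

Fit the canonical quadratic (Laplace) system to the Lorenz flow — diagonal
flow-operator blocks fixed so the noise variance is exactly
`2Γ = (1/8, 1/16, 1/32)`, 4³ sample points spanning ±8 about (0, 0, 28) —
then inspect its Gaussian steady state:

```r
library(nessflow)
lp <- laplace_lorenz_system()
lp
#> Helmholtz decomposition: n = 3 states, order m = 2
#>   nonzero h: h3 = 1.907, h5 = -1.406, h6 = 1.399, h7 = -77.98, h10 = 1.681
#>   Gamma: 0.0625, 0.03125, 0.01562  (noise variance 2*Gamma)
#>   fit: rms residual 25 after 57 iterations (converged)

ness <- gaussian_from_potential(lp)
round(ness$H, 3)
#>        [,1]   [,2]  [,3]
#> [1,]  1.907 -1.406 0.000
#> [2,] -1.406  1.399 0.000
#> [3,]  0.000  0.000 1.681
```

The precision (Hessian) is positive definite — a proper Gaussian NESS
centred at (0, 0, 46.4) — and its zeros say the third state is
conditionally independent of the first two: it has no Markov blanket
(`markov_boundary(ness, 3)` is empty). The `h` coefficients are the
potential's polynomial coefficients in the package's documented basis
ordering (`h5` ↔ x1·x2, `h7` ↔ x3, `h10` ↔ ½x3²).

Expected local Lyapunov exponents under the fitted density, and the
dimension estimates:

```r
lam <- expected_jacobian_eigenvalues(lp)
round(lam, 4)
#> [1]  0.1423 -0.0506 -0.2809
kaplan_yorke_dimension(lam)
#> [1] 2.327
lorenz_analytic_dimension(10, 32, 8/3)
#> [1] 2.429
```

A positive leading expected exponent with a fractal dimension between 2
and 3: stochastic chaos carried almost entirely by solenoidal flow around
a Gaussian density. Coupling two Lorenz systems through their first states
produces a blanket:

```r
cp <- make_fixture("coupled-laplace")
cp$reference$partition
#> Particular partition:
#>   external  eta: 2,3
#>   sensory     s: 1
#>   active      a: 4
#>   internal   mu: 5,6
```

so the internal pair (5, 6) sees the external pair (2, 3) only through the
blanket states 1 and 4 — and `synchronisation_map()`,
`variational_free_energy()` and `autonomous_flow()` express the internal
dynamics as inference about the external states.

A thin command-line wrapper over the same functions lives at
`inst/cli/nessflow.R` (subcommands `fit`, `simulate`, `partition`,
`lyapunov`, `density`, `partial-corr`, `free-energy`, `fixtures`).

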