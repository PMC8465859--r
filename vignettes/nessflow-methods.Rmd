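---
title: "From stochastic flows to steady-state densities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From stochastic flows to steady-state densities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nessflow)
```

## The model

A Langevin system $\dot x = f(x) + \omega$ with diagonal fluctuation
covariance $2\Gamma$ has deterministic density dynamics given by the
Fokker--Planck equation $\dot p = \nabla\cdot(\Gamma\nabla - f)\,p$. When the
system possesses a nonequilibrium steady state (NESS) $p(x) \propto
e^{-\Im(x)}$, its expected flow admits a generalised Helmholtz decomposition

$$ f(x) \;=\; Q(x)\,\nabla\Im(x) \;-\; \Gamma\,\nabla\Im(x) \;-\; \Lambda(x),
\qquad \Lambda_i = \sum_j \partial_j \Omega_{ij}, \quad \Omega = Q - \Gamma, $$

with $Q = -Q^\top$ the solenoidal operator circulating on the isocontours of
the surprisal $\Im = -\ln p$, $-\Gamma\nabla\Im$ the dissipative gradient
flow, and $\Lambda$ a housekeeping correction for state dependence of the
flow operator. `nessflow` parameterises $\Im$ and every entry of $Q$ in a
truncated multivariate polynomial basis, which turns "solve the stationary
Fokker--Planck equation" into "estimate polynomial coefficients". At
quadratic order (`m = 2`) the surprisal is a quadratic form, the NESS is
Gaussian with constant precision $H = \nabla^2\Im$, and conditional
independence between two states is exactly a zero entry of $H$ --- the basis
for Markov-boundary discovery, particular partitions (external, sensory,
active, internal states) and the Bayesian-mechanics layer.

A property worth emphasising, because much of the test suite leans on it:
for *any* coefficient choice with constant $\Gamma$ and the correction
defined as the row divergence $\Lambda_i = \sum_j \partial_j\Omega_{ij}$,
the density $e^{-\Im}$ is an *exact* stationary solution of the
Fokker--Planck equation. Both sign conventions for the correction term
circulate in the literature; the row divergence is the one under which the
stationarity identity holds (the test suite verifies this by grid
refinement of the Fokker--Planck residual), so the package uses it
throughout.

## Basis ordering

Coefficients are addressed by flat indices in a fixed, documented ordering
(`"tdlvm-1"`): index 1 is the constant, then for each leading variable
$x_i$ the block $[x_i,\ x_1x_i,\dots,x_{i-1}x_i,\ \tfrac12 x_i^2]$. Pure
$k$-th powers carry $1/k!$. For three states this places $x_1x_2$ at
position 5, $x_3$ at position 7 and $\tfrac12 x_3^2$ at position 10;
solenoidal blocks concatenate in $(1,1), (1,2), \dots$ order. Serialised
parameter files record the ordering version and are refused on mismatch.

## The exact Lorenz decomposition

For the Lorenz flow ($\sigma = 10$, $\rho = 32$, $\beta = 8/3$ throughout)
the decomposition has an exact closed form with a two-term potential
$\Im = h_5 x_1x_2 + h_7 x_3$ and the parameter relations
$\sigma = -h_5 q_{11}$, $\beta = -h_7 q_{57}$, $\rho = -h_5\Gamma_2$
(`exact_lorenz_decomposition()`). Its Hessian is indefinite and one
fluctuation amplitude is negative: the decomposition is an algebraic
rewriting of the deterministic system, not a stochastic model --- which is
what motivates fitting a *proper* quadratic (Laplace) system instead.

## Fitting, and why it is constrained

`fit_helmholtz()` implements the generic least-squares estimator: minimise
the squared mismatch between a target flow and the model flow over sample
points, by Levenberg--Marquardt with analytic residual Jacobians plus
alternating exact linear solves in the two coefficient blocks (the problem
is bilinear in $(q, h)$, so each block solve is exact). Seeds are a
unit-curvature potential and a small family of minimal cross/linear
curvature seeds; exactly representable targets (the Lorenz flow with free
amplitudes, any linear flow, any model's own flow) are recovered to machine
precision.

For the *Laplace system* --- quadratic potential, diagonal blocks fixed to
zero so the noise variance is exactly $2\Gamma = [1/8, 1/16, 1/32]$, fitted
at $4^3$ points spanning $\pm 8$ about $(0, 0, 28)$ --- the unconstrained
problem turns out to be degenerate in two ways that we established
empirically and document here because they drive the design:

* the joint rescaling $(q, h) \to (cq, h/c)$ changes the residual only
  through the two small terms $\Gamma\nabla\Im/c$ and $c\Lambda$, so the
  objective has a nearly flat valley along the scale gauge; and
* every unconstrained stationary point we could locate (multistart
  Levenberg--Marquardt, alternating least squares, ridge and continuation
  variants) carries an *indefinite* or boundary-singular Hessian, i.e. no
  proper steady-state density.

`laplace_lorenz_system()` therefore performs a constrained least-squares
fit: the coefficient support is restricted to the terms compatible with the
Lorenz symmetry $(x_1, x_2) \to (-x_1, -x_2)$, the Hessian is parameterised through its sparse Cholesky
factor (positive definite at every iterate), and the optimiser starts from
a unit-precision potential centred on the sampling region. The procedure is
deterministic and lands on the unique non-degenerate proper optimum of the
restricted problem: a flow correlation of 0.94 with the Lorenz flow, mean
$(0, 0, 46.4)$, standard deviations $(1.4, 1.7, 0.8)$, and the
conditional-independence pattern in which the third state carries no
blanket. `laplace_coupled_system()` is the six-state analogue with the
system-swap symmetry imposed (the Hessian block-diagonalises in
symmetric/antisymmetric coordinates into two Lorenz-type blocks, both kept
positive definite).

## Expected Lyapunov exponents and quadrature

Expected local Lyapunov exponents are density-weighted averages of the
sorted real parts of the flow Jacobian's eigenvalues; the Kaplan--Yorke
formula turns them into a fractal-dimension estimate. Complex eigenvalues
contribute their real parts; matching across grid points is by sorted
order. The expectation must be computed on a grid that *resolves* the
Gaussian: by default the quadrature uses $16^3$ points spanning the mean
$\pm 4$ standard deviations per axis (cross-checked against Monte Carlo to
$\sim 10^{-3}$). A fixed wide grid (e.g. spanning $\pm 32$) has spacing
several times the fitted standard deviations and returns quadrature noise
--- detectable because the weighted mean divergence must equal
$-\sum_i \Gamma_i H_{ii}$ exactly for this model family.

For the canonical system the pipeline gives $\lambda = (0.142, -0.051,
-0.281)$ and $d_{KY} = 2.33$ --- the same structure and scale as the
published values $(0.0766, 0.0056, -0.1713)$ and $2.48$, but not within
printed precision. The published values derive from a maximum-a-posteriori
fitting scheme with unpublished priors, which is explicitly outside this
package's scope; since the published eigenvalues are not a stationary point
of the least-squares problem under any regularisation we tried, the
difference is attributed to the fitting scheme, not the eigenvalue
estimator (which is exact for linear systems and grid-converged here).
Similarly, the published long-run partial correlation of the fourth and
fifth states ($-0.33$) is a property of that fit; our canonical coupled
system gives $+0.87$ (for reference, direct simulation of the *actual*
stochastic coupled Lorenz system gives $+0.91$), while the structural zero
$(3,6) \to 0$ is reproduced. The acceptance script reports what the
pipeline computes.

## Density dynamics

`evolve_density()` integrates the Fokker--Planck equation on a rectangular
grid (up to three dimensions) in conservative flux form with Chang--Cooper
(exponentially fitted) face fluxes: exact for one-dimensional steady
states, central-difference accurate at small cell Peclet number, upwind at
large, with closed boundaries and renormalisation each step. We moved from
the surprisal-space formulation to flux form after finding that explicit
surprisal stepping is structurally unstable in the capped tails (a concave
kink at the cap turns the diffusion term into a mass source). The
surprisal-space decomposition of the same dynamics into dissipative,
solenoidal and correction components (`surprisal_rate()`) is retained as
the analysis surface and validated against a closed-form one-dimensional
Ornstein--Uhlenbeck relaxation. The step size satisfies
$\Delta t\,\sum_i (2\Gamma_i/\Delta x_i^2 + 2|f_i|_{max}/\Delta x_i) \le
0.8$; far-tail velocities (which grow polynomially but act where the
density is negligible) are clamped to the largest bulk speed so they do not
dictate the step. Information length is accumulated as
$\sum \Delta\tau\,\sqrt{E_{p_\tau}[\dot\Im_\tau^2]}$ from finite
differences of consecutive snapshots; its definition follows the standard
information-geometric form, and its snapshot-spacing convergence is first
order.

Started from a tight Gaussian at $(4, 4, 8)$, the canonical system's
density converges monotonically but slowly (KL $\approx 300$ nats at 16 s,
with $\sim$0.05 reached only on a $\sim$100 s horizon): the fitted steady
state sits at $x_3 \approx 46$ with sub-unit standard deviations, so this
initial state is $\sim$50 standard deviations away, whereas for the
published fit the same start is an order of magnitude closer. The quoted
16 s relaxation is therefore not reproduced under our fit; the solver
itself conserves mass to $10^{-3}$ and decreases KL monotonically.

## Stochastic simulation

Deterministic trajectories use fixed-step fourth-order Runge--Kutta;
stochastic ones use Euler--Maruyama ($x \leftarrow x + f\,dt +
\sqrt{2\Gamma\,dt}\,\epsilon$), seeded once through R's Mersenne-Twister
stream (same seed, same trajectory). `simulate_ensemble()` propagates all
realisations simultaneously through a vectorised evaluation of the model
flow. Euler--Maruyama has a first-order bias in the stationary covariance;
at $dt = 1/64$ it is visible against tight Monte Carlo error, so the
covariance-consistency test integrates at $dt = 1/256$, where the bias sits
below three standard errors of a 12-realisation ensemble.

## Problem sizes used by the tests and the acceptance script

Fits use the stated $4^d$ hypergrids (64 points for three states, 4096 for
six). Eigenvalue quadrature uses $16^3$ points. The partial-correlation
ensemble uses 32 realisations of 500 s at $dt = 1/64$ ($1.0\times10^6$
six-dimensional steps). The three-dimensional density run uses a
$22\times21\times58$ grid and $\sim$$1.3\times10^4$ steps over 20 s.
Everything regenerates from code; there are no stored fixtures.

## What the built-in systems do and do not emulate

The Lorenz and coupled-Lorenz flows are the package's synthetic data
generators: deterministic, with printed parameter values
($\sigma, \rho, \beta, \chi$) as defaults and noise injected only through
the stated $2\Gamma$. They exercise polynomial flows with quadratic
nonlinearities, strong solenoidal circulation and sparse directed coupling.
They do not emulate measurement noise, non-polynomial nonlinearities,
state-dependent (multiplicative) fluctuations, or high-dimensional systems;
passing tests demonstrate correctness of the machinery on this family, not
fidelity of the Laplace approximation for arbitrary dynamics.

## Known limitations

* The Laplace fits are constrained projections; their densities are much
  tighter than the chaotic attractor they approximate, and quantities that
  depend on the specific published fit (expected exponents, the $(4,5)$
  partial correlation, the 16 s relaxation) differ as documented above.
* The grid solver refuses more than three dimensions; the
  kernel-parameterised (positive-definite, higher-order) potential is
  provided for evaluation but not fitted.
* Markov-boundary detection on *sampled* precisions needs a
  noise-aware threshold; the default `tol` is meant for analytic
  precisions.
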