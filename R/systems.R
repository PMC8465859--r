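#' Built-in flow fields
#'
#' `lorenz()` returns the classical Lorenz flow
#' \deqn{f(x) = (\sigma(x_2 - x_1),\; \rho x_1 - x_2 - x_1 x_3,\;
#'              x_1 x_2 - \beta x_3)}
#' with its exact Jacobian; defaults are the chaotic regime used throughout
#' the worked examples (\eqn{\sigma = 10}, \eqn{\rho = 32},
#' \eqn{\beta = 8/3}).
#'
#' @param sigma,rho,beta Lorenz parameters.
#' @return An object of class `flow_spec`: list with `name`, `n`,
#'   `parameters`, `flow(x)` and `jacobian(x)`.
#' @export
lorenz <- function(sigma = 10, rho = 32, beta = 8 / 3) {
  structure(list(
    name = "lorenz", n = 3L,
    parameters = c(sigma = sigma, rho = rho, beta = beta),
    flow = function(x) c(sigma * (x[2] - x[1]),
                         rho * x[1] - x[2] - x[1] * x[3],
                         x[1] * x[2] - beta * x[3]),
    jacobian = function(x) matrix(c(-sigma, sigma, 0,
                                    rho - x[3], -1, -x[1],
                                    x[2], x[1], -beta),
                                  3, 3, byrow = TRUE)
  ), class = "flow_spec")
}

#' Two Lorenz systems coupled through their first states
#'
#' The six-state flow couples two copies of the Lorenz system symmetrically
#' via their first states with coupling parameter \eqn{\chi} (default
#' \eqn{-1/2}): the first equation of each system becomes
#' \eqn{\sigma x_2 - \sigma(\chi x_4 - x_1(\chi - 1))} (and symmetrically
#' with \eqn{1 \leftrightarrow 4}), i.e. the usual flow plus a prediction
#' error \eqn{\sigma\chi(x_4 - x_1)} between homologous states. At
#' \eqn{\chi = 0} the halves decouple; on the synchronisation manifold
#' \eqn{(x_1,x_2,x_3) = (x_4,x_5,x_6)} the prediction error vanishes and the
#' joint flow restricts to identical synchronised Lorenz dynamics.
#'
#' @param sigma,rho,beta Lorenz parameters; @param chi coupling parameter.
#' @return A `flow_spec` with `n = 6`.
#' @export
coupled_lorenz <- function(sigma = 10, rho = 32, beta = 8 / 3, chi = -1 / 2) {
  flow <- function(x) c(
    sigma * x[2] - sigma * (chi * x[4] - x[1] * (chi - 1)),
    rho * x[1] - x[2] - x[1] * x[3],
    x[1] * x[2] - beta * x[3],
    sigma * x[5] - sigma * (chi * x[1] - x[4] * (chi - 1)),
    rho * x[4] - x[5] - x[4] * x[6],
    x[4] * x[5] - beta * x[6])
  jacobian <- function(x) {
    J <- matrix(0, 6, 6)
    J[1, ] <- c(sigma * (chi - 1), sigma, 0, -sigma * chi, 0, 0)
    J[2, ] <- c(rho - x[3], -1, -x[1], 0, 0, 0)
    J[3, ] <- c(x[2], x[1], -beta, 0, 0, 0)
    J[4, ] <- c(-sigma * chi, 0, 0, sigma * (chi - 1), sigma, 0)
    J[5, ] <- c(0, 0, 0, rho - x[6], -1, -x[4])
    J[6, ] <- c(0, 0, 0, x[5], x[4], -beta)
    J
  }
  structure(list(
    name = "coupled_lorenz", n = 6L,
    parameters = c(sigma = sigma, rho = rho, beta = beta, chi = chi),
    flow = flow, jacobian = jacobian
  ), class = "flow_spec")
}

flow_fn <- function(flow) {
  if (inherits(flow, "flow_spec")) return(flow$flow)
  if (inherits(flow, "helmholtz_params"))
    return(function(x) model_flow(flow, x)$f)
  if (is.function(flow)) return(flow)
  stop("`flow` must be a flow_spec, helmholtz_params, or function")
}

flow_dim <- function(flow, x0) {
  if (inherits(flow, "flow_spec")) flow$n
  else if (inherits(flow, "helmholtz_params")) flow$basis$n
  else length(x0)
}

new_trajectory <- function(times, states, dt, scheme, seed = NA,
                           noise_variance = NULL) {
  colnames(states) <- paste0("x", seq_len(ncol(states)))
  structure(list(times = times, states = states, dt = dt,
                 scheme = scheme, seed = seed,
                 noise_variance = noise_variance),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: %d steps of dt = %g s (%g s), %d states\n",
              x$scheme, length(x$times) - 1L, x$dt,
              max(x$times), ncol(x$states)))
  invisible(x)
}

#' Deterministic integration (fixed-step 4th-order Runge-Kutta)
#'
#' @param flow a `flow_spec`, [helmholtz_params()], or function of the state.
#' @param x0 initial state; @param dt time step in seconds (default 1/64 s);
#' @param T total integration time in seconds.
#' @return A `trajectory` object (times, states matrix, metadata).
#' @export
integrate_deterministic <- function(flow, x0, dt = 1 / 64, T = 64) {
  stopifnot(dt > 0, T > 0)
  f <- flow_fn(flow)
  n <- length(x0)
  nsteps <- round(T / dt)
  states <- matrix(NA_real_, nsteps + 1L, n)
  states[1L, ] <- x0
  x <- as.numeric(x0)
  for (s in seq_len(nsteps)) {
    k1 <- f(x)
    k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2)
    k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (any(!is.finite(x)))
      stop(sprintf("trajectory blew up at t = %g s", s * dt))
    states[s + 1L, ] <- x
  }
  new_trajectory(seq(0, by = dt, length.out = nsteps + 1L), states, dt,
                 "deterministic")
}

#' Stochastic integration (Euler-Maruyama)
#'
#' Integrates \eqn{\dot x = f(x) + \omega} with diagonal fluctuation
#' variance `2 * Gamma`, i.e. per step
#' \eqn{x \leftarrow x + f(x)\,dt + \sqrt{2\Gamma\,dt}\,\epsilon},
#' \eqn{\epsilon \sim N(0, I)}. Reproducible given `seed` (a single R RNG
#' stream; draws are taken state-by-state within each step).
#'
#' @inheritParams integrate_deterministic
#' @param Gamma numeric vector of per-state noise half-amplitudes
#'   (\eqn{\Gamma_i \ge 0}); the Langevin variance is `2 * Gamma`.
#' @param seed integer RNG seed.
#' @return A `trajectory` object with `noise_variance = 2 * Gamma`.
#' @export
integrate_stochastic <- function(flow, Gamma, x0, dt = 1 / 64, T = 64,
                                 seed = 1L) {
  stopifnot(dt > 0, T > 0, all(Gamma >= 0))
  f <- flow_fn(flow)
  n <- length(x0)
  Gamma <- rep_len(Gamma, n)
  nsteps <- round(T / dt)
  states <- matrix(NA_real_, nsteps + 1L, n)
  states[1L, ] <- x0
  x <- as.numeric(x0)
  sd_step <- sqrt(2 * Gamma * dt)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  for (s in seq_len(nsteps)) {
    x <- x + f(x) * dt + sd_step * stats::rnorm(n)
    if (any(!is.finite(x)))
      stop(sprintf("trajectory blew up at t = %g s", s * dt))
    states[s + 1L, ] <- x
  }
  new_trajectory(seq(0, by = dt, length.out = nsteps + 1L), states, dt,
                 "stochastic", seed = seed, noise_variance = 2 * Gamma)
}

# Affine representation f(x) = f0 + F1 x + quadratic remainder is not enough
# for Helmholtz flows in general; the ensemble integrator instead evaluates
# the model flow for a whole batch of states at once through the basis.
ensemble_flow_ingredients <- function(params) {
  basis <- params$basis
  n <- basis$n; N <- basis$size
  # W maps basis values to the n^2 entries of Omega (column-major u + (v-1)n)
  W <- matrix(0, n * n, N)
  gamma_vec <- numeric(n * n)
  for (i in seq_len(n)) {
    W[i + (i - 1L) * n, ] <- get_q_block(params, i, i)
    gamma_vec[i + (i - 1L) * n] <- params$Gamma[i]
    if (i < n) for (j in seq((i + 1L), n)) {
      blk <- get_q_block(params, i, j)
      W[i + (j - 1L) * n, ] <- blk
      W[j + (i - 1L) * n, ] <- -blk
    }
  }
  # For m = 2 the correction term is affine: Lambda(x) = lam0 + Lam1 x
  if (basis$m == 2L) {
    lam0 <- correction_term(params, numeric(n))
    Lam1 <- matrix(0, n, n)
    for (v in seq_len(n)) {
      ev <- numeric(n); ev[v] <- 1
      Lam1[, v] <- correction_term(params, ev) - lam0
    }
    lam <- list(order = 2L, lam0 = lam0, Lam1 = Lam1)
  } else lam <- list(order = basis$m)
  pot0 <- potential_eval(params, numeric(n))
  list(W = W, gamma_vec = gamma_vec, lam = lam,
       H = pot0$hessian, b_lin = pot0$gradient)
}

batch_model_flow <- function(params, ing, X) {
  # X: n x R matrix of states; returns n x R flows
  n <- params$basis$n
  B <- eval_basis_matrix(params$basis, X)
  Om <- ing$W %*% B                      # (n*n) x R
  Om <- Om - ing$gamma_vec               # recycled down columns
  G <- ing$H %*% X + ing$b_lin           # gradient of quadratic potential
  FF <- matrix(0, n, ncol(X))
  for (v in seq_len(n)) {
    rows <- ((v - 1L) * n + 1L):(v * n)
    FF <- FF + Om[rows, , drop = FALSE] *
      matrix(G[v, ], n, ncol(X), byrow = TRUE)
  }
  if (ing$lam$order == 2L) {
    FF <- FF - (ing$lam$lam0 + ing$lam$Lam1 %*% X)
  } else {
    for (r in seq_len(ncol(X)))
      FF[, r] <- FF[, r] - correction_term(params, X[, r])
  }
  FF
}

#' Ensemble of stochastic solutions of a fitted Helmholtz system
#'
#' Runs `n_real` independent Euler-Maruyama realisations simultaneously
#' (vectorised over realisations), using the model's own noise amplitude
#' `params$Gamma`. Intended for long-run steady-state statistics such as
#' sample covariances and partial correlations.
#'
#' @param params a [helmholtz_params()] with quadratic potential (`m = 2`).
#' @param n_real number of realisations.
#' @param x0 common initial state (or matrix n-by-`n_real` of initial
#'   states).
#' @param dt,T step size and duration in seconds.
#' @param seed integer RNG seed.
#' @param keep_every store every `keep_every`-th step (1 = all).
#' @return List of `trajectory` objects, one per realisation.
#' @export
simulate_ensemble <- function(params, n_real, x0, dt = 1 / 64, T = 500,
                              seed = 1L, keep_every = 1L) {
  stopifnot(inherits(params, "helmholtz_params"), all(params$Gamma >= 0))
  n <- params$basis$n
  X <- if (is.matrix(x0)) x0 else matrix(as.numeric(x0), n, n_real)
  stopifnot(nrow(X) == n, ncol(X) == n_real)
  ing <- ensemble_flow_ingredients(params)
  nsteps <- round(T / dt)
  kept <- seq(0L, nsteps, by = keep_every)
  store <- array(NA_real_, c(length(kept), n, n_real))
  store[1L, , ] <- X
  sd_step <- sqrt(2 * params$Gamma * dt)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed)
  ki <- 1L
  for (s in seq_len(nsteps)) {
    FF <- batch_model_flow(params, ing, X)
    X <- X + FF * dt + sd_step * matrix(stats::rnorm(n * n_real), n, n_real)
    if (any(!is.finite(X)))
      stop(sprintf("ensemble blew up at t = %g s", s * dt))
    if (ki < length(kept) && s == kept[ki + 1L]) {
      ki <- ki + 1L
      store[ki, , ] <- X
    }
  }
  times <- kept * dt
  lapply(seq_len(n_real), function(r)
    new_trajectory(times, store[, , r], dt * keep_every, "stochastic",
                   seed = seed, noise_variance = 2 * params$Gamma))
}
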