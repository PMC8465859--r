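# Shared numerical oracles for the test suite.

# central finite differences of a vector-valued function
fd_jacobian <- function(f, x, eps = 1e-6) {
  n <- length(x)
  f0 <- f(x)
  J <- matrix(0, length(f0), n)
  for (v in seq_len(n)) {
    e <- numeric(n); e[v] <- eps
    J[, v] <- (f(x + e) - f(x - e)) / (2 * eps)
  }
  J
}

fd_gradient <- function(f, x, eps = 1e-6) drop(fd_jacobian(function(z) f(z), x, eps))

# Fokker-Planck residual of p ~ exp(-I) under flow f on a grid:
# sum_i d/dx_i [ Gamma_i dp/dx_i - f_i p ], via central differences.
fp_residual_grid <- function(params, axes) {
  n <- params$basis$n
  X <- as.matrix(expand.grid(axes))
  dims <- vapply(axes, length, integer(1))
  delta <- vapply(axes, function(a) a[2] - a[1], numeric(1))
  surpr <- apply(X, 1L, function(x) potential_eval(params, x)$value)
  p <- array(exp(-(surpr - min(surpr))), dims)
  flux <- vector("list", n)
  for (i in seq_len(n)) {
    fi <- array(apply(X, 1L, function(x) model_flow(params, x)$f[i]), dims)
    dp_i <- nessflow:::array_grad(p, i, delta[i])
    flux[[i]] <- params$Gamma[i] * dp_i - fi * p
  }
  res <- array(0, dims)
  for (i in seq_len(n))
    res <- res + nessflow:::array_grad(flux[[i]], i, delta[i])
  # report max interior residual relative to the density scale
  idx <- lapply(dims, function(k) 2:(k - 1L))
  interior <- do.call(`[`, c(list(res), idx))
  max(abs(interior)) / max(p)
}

# deterministic pseudo-random probe points
probe_points <- function(n_points, n_dim, lo = -8, hi = 8, seed = 42) {
  withr::with_seed(seed, matrix(stats::runif(n_points * n_dim, lo, hi),
                                n_points, n_dim))
}
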