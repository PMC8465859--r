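#' Gridded time-dependent surprisal
#'
#' A `grid_density` tabulates the time-dependent surprisal
#' \eqn{\Im_\tau = -\ln p_\tau} on a rectangular grid (1 to 3 dimensions),
#' normalised so that the trapezoidal integral of \eqn{e^{-\Im_\tau}} is 1.
#'
#' @param axes list of strictly increasing, uniformly spaced coordinate
#'   vectors (one per dimension).
#' @param mean,covariance moments of the initial Gaussian density.
#' @return An object of class `grid_density`: list with `axes`, `surprisal`
#'   (array), `tau` (time), `delta` (grid steps).
#' @export
init_gaussian_grid <- function(axes, mean, covariance) {
  n <- length(axes)
  if (n > 3L) stop("grid solver limited to n <= 3 dimensions")
  delta <- vapply(axes, function(a) {
    d <- diff(a)
    if (any(abs(d - d[1L]) > 1e-9 * abs(d[1L]))) stop("axes must be uniform")
    d[1L]
  }, numeric(1))
  covariance <- as.matrix(covariance)
  ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance must be positive definite")
  sds <- sqrt(diag(covariance))
  for (i in seq_len(n))
    if (mean[i] - 3 * sds[i] < min(axes[[i]]) ||
        mean[i] + 3 * sds[i] > max(axes[[i]]))
      warning(sprintf("grid does not cover +/-3 sd of the initial density along dimension %d", i))
  P <- chol2inv(chol(covariance))
  X <- as.matrix(expand.grid(axes))
  dev <- sweep(X, 2L, mean)
  surpr <- array(0.5 * rowSums((dev %*% P) * dev),
                 dim = vapply(axes, length, integer(1)))
  gd <- structure(list(axes = axes, surprisal = surpr, tau = 0,
                       delta = delta), class = "grid_density")
  renormalise_grid(gd)
}

#' @export
print.grid_density <- function(x, ...) {
  cat(sprintf("grid density: %s grid, tau = %g s, mass %.6f\n",
              paste(vapply(x$axes, length, integer(1)), collapse = " x "),
              x$tau, grid_mass(x)))
  invisible(x)
}

cell_volume <- function(gd) prod(gd$delta)

#' Total probability mass on the grid
#' @param gd a `grid_density`.
#' @return The grid integral of \eqn{e^{-\Im_\tau}}.
#' @export
grid_mass <- function(gd) sum(exp(-gd$surprisal)) * cell_volume(gd)

renormalise_grid <- function(gd) {
  gd$surprisal <- gd$surprisal + log(grid_mass(gd))
  gd
}

# central differences along dimension d (one-sided at the edges)
array_grad <- function(A, d, delta) {
  n <- length(dim(A))
  if (is.null(dim(A))) { A <- array(A, length(A)); n <- 1L }
  perm <- c(d, setdiff(seq_len(n), d))
  B <- aperm(array(A, dim(A)), perm)
  dmB <- dim(B)
  M <- matrix(B, dmB[1L])
  G <- M
  k <- nrow(M)
  if (k >= 3L) {
    G[2:(k - 1L), ] <- (M[3:k, , drop = FALSE] - M[1:(k - 2L), , drop = FALSE]) / (2 * delta)
    G[1L, ] <- (M[2L, ] - M[1L, ]) / delta
    G[k, ] <- (M[k, ] - M[k - 1L, ]) / delta
  } else if (k == 2L) {
    G[1L, ] <- G[2L, ] <- (M[2L, ] - M[1L, ]) / delta
  } else G[] <- 0
  out <- array(G, dmB)
  aperm(out, order(perm))
}

# second central difference along dimension d (quadratic extrapolation at edges)
array_grad2 <- function(A, d, delta) {
  n <- length(dim(A))
  perm <- c(d, setdiff(seq_len(n), d))
  B <- aperm(array(A, dim(A)), perm)
  dmB <- dim(B)
  M <- matrix(B, dmB[1L])
  G <- M
  k <- nrow(M)
  if (k >= 3L) {
    G[2:(k - 1L), ] <- (M[3:k, , drop = FALSE] - 2 * M[2:(k - 1L), , drop = FALSE] +
                          M[1:(k - 2L), , drop = FALSE]) / delta^2
    G[1L, ] <- G[2L, ]
    G[k, ] <- G[k - 1L, ]
  } else G[] <- 0
  out <- array(G, dmB)
  aperm(out, order(perm))
}

# steady-state fields of a quadratic Helmholtz system, tabulated on the grid
steady_fields <- function(params, axes) {
  n <- params$basis$n
  if (length(axes) != n) stop("axes/dimension mismatch")
  dims <- vapply(axes, length, integer(1))
  X <- t(as.matrix(expand.grid(axes)))
  B <- eval_basis_matrix(params$basis, X)
  surpr <- array(drop(crossprod(B, params$h)), dims)
  pot0 <- potential_eval(params, numeric(n))
  H <- pot0$hessian; b <- pot0$gradient
  G <- H %*% X + b                      # analytic gradient of steady surprisal
  ing <- ensemble_flow_ingredients(params)
  Om <- ing$W %*% B - ing$gamma_vec     # n^2 x P, Omega = Q - Gamma
  sol <- vector("list", n)              # (Q grad I)_i
  for (u in seq_len(n)) {
    acc <- numeric(ncol(X))
    for (v in seq_len(n)) {
      Quv <- Om[u + (v - 1L) * n, ]
      if (u == v) Quv <- Quv + params$Gamma[u]   # strip -Gamma from diagonal
      acc <- acc + Quv * G[v, ]
    }
    sol[[u]] <- array(acc, dims)
  }
  lam <- vector("list", n)
  LamM <- ing$lam$lam0 + ing$lam$Lam1 %*% X
  for (u in seq_len(n)) lam[[u]] <- array(LamM[u, ], dims)
  gradI <- lapply(seq_len(n), function(u) array(G[u, ], dims))
  list(surprisal = surpr, grad = gradI, sol = sol, lam = lam,
       Hdiag = diag(H), dims = dims)
}

#' Rate of change of the time-dependent surprisal
#'
#' Evaluates the three named components of the surprisal-form Fokker-Planck
#' equation
#' \deqn{\dot\Im_\tau = (\nabla - \nabla\Im_\tau)\cdot\Gamma\nabla(\Im_\tau-\Im)
#'   \;-\; \nabla\Im_\tau\cdot Q\nabla\Im \;+\; \nabla(\Im_\tau-\Im)\cdot\Lambda}
#' (dissipative, solenoidal, correction) using central differences for the
#' time-dependent field and analytic steady-state fields. At the steady
#' state (\eqn{\Im_\tau = \Im}) every component vanishes.
#'
#' @param gd a `grid_density`.
#' @param params a [helmholtz_params()] with `m = 2` and constant Gamma.
#' @param fields optional precomputed [steady_fields()] (internal reuse).
#' @return List of arrays `dissipative`, `solenoidal`, `correction`, `total`.
#' @export
surprisal_rate <- function(gd, params, fields = NULL) {
  n <- length(gd$axes)
  if (is.null(fields)) fields <- steady_fields(params, gd$axes)
  It <- gd$surprisal
  Gam <- params$Gamma
  diss <- array(0, dim(It)); sol <- array(0, dim(It)); corr <- array(0, dim(It))
  for (i in seq_len(n)) {
    gIt <- array_grad(It, i, gd$delta[i])
    gD <- gIt - fields$grad[[i]]
    g2D <- array_grad2(It, i, gd$delta[i]) - fields$Hdiag[i]
    diss <- diss + Gam[i] * g2D - gIt * Gam[i] * gD
    sol <- sol - gIt * fields$sol[[i]]
    corr <- corr + gD * fields$lam[[i]]
  }
  list(dissipative = diss, solenoidal = sol, correction = corr,
       total = diss + sol + corr)
}

kl_divergence_grid <- function(gd, steady_norm) {
  # KL(p_tau || p_steady) with both normalised on the grid
  p <- exp(-gd$surprisal) * cell_volume(gd)
  sum(p * (steady_norm - gd$surprisal))
}

# flux divergence along the first dimension of a matrix view, with
# Chang-Cooper (exponentially fitted) face fluxes: exact for 1-D steady
# states, reducing to central differencing for small cell Peclet numbers
# and to upwinding for large ones; closed (zero-flux) boundaries
cc_divergence <- function(P, V, delta, Gamma_d) {
  k <- nrow(P)
  if (k < 2L) return(P * 0)
  Vh <- (V[-k, , drop = FALSE] + V[-1L, , drop = FALSE]) / 2
  if (Gamma_d > 1e-14) {
    w <- Vh * delta / Gamma_d
    small <- abs(w) < 1e-8
    c1 <- w / (-expm1(-w)); c1[small] <- 1 + w[small] / 2
    c2 <- w / expm1(w);     c2[small] <- 1 - w[small] / 2
    Fh <- (Gamma_d / delta) * (c1 * P[-k, , drop = FALSE] -
                                 c2 * P[-1L, , drop = FALSE])
  } else {
    Fh <- pmax(Vh, 0) * P[-k, , drop = FALSE] +
      pmin(Vh, 0) * P[-1L, , drop = FALSE]
  }
  zero <- matrix(0, 1L, ncol(P))
  (rbind(Fh, zero) - rbind(zero, Fh)) / delta
}

#' Integrate the density dynamics on a grid
#'
#' Explicit conservative (flux-form) integration of the Fokker-Planck
#' equation \eqn{\dot p = \nabla\cdot(\Gamma\nabla p - f p)} with the model
#' flow \eqn{f = \Omega\nabla\Im - \Lambda} tabulated on the grid, using
#' Chang-Cooper (exponentially fitted) face fluxes, closed (zero-flux)
#' boundaries, and renormalisation every step. Mass is conserved by construction up to boundary clipping. The
#' result is returned in surprisal form (\eqn{\Im_\tau = -\ln p_\tau});
#' [surprisal_rate()] exposes the equivalent surprisal-space decomposition
#' of the same dynamics.
#'
#' The step size must satisfy the combined diffusion/advection bound
#' `dt * sum_i (2 Gamma_i / dx_i^2 + |f_i|_max / dx_i) <= 0.9`; when
#' `dt_density` is `NULL` the largest admissible step is chosen
#' automatically.
#'
#' @param gd initial `grid_density` (see [init_gaussian_grid()]).
#' @param params a [helmholtz_params()] defining the steady state.
#' @param dt_density time step in seconds, or `NULL` for automatic.
#' @param T total integration time in seconds.
#' @param snapshot_every interval between stored snapshots, in seconds.
#' @param tail_clip surprisal offset defining the bulk of the steady state;
#'   flow velocities outside the bulk (steady surprisal more than
#'   `tail_clip` nats above its minimum) are clamped to the largest bulk
#'   speed. The clamped region carries negligible probability; clamping
#'   only prevents the far-tail velocities (which grow polynomially) from
#'   dictating the stable step size.
#' @return List with `snapshots` (list of `grid_density`), `times`,
#'   `kl` (KL divergence to the grid-restricted steady state at every
#'   step), `kl_times`, `mass_drift` (max |mass - 1| observed before
#'   renormalisation), and `dt` used.
#' @export
evolve_density <- function(gd, params, dt_density = NULL, T = 16,
                           snapshot_every = 2, tail_clip = 30) {
  n <- length(gd$axes)
  dims <- vapply(gd$axes, length, integer(1))
  fields <- steady_fields(params, gd$axes)
  Gam <- params$Gamma
  # model flow per axis on the grid: f_i = (Q grad I)_i - Gamma_i grad_i I - Lambda_i
  flow <- lapply(seq_len(n), function(i)
    fields$sol[[i]] - Gam[i] * fields$grad[[i]] - fields$lam[[i]])
  if (is.finite(tail_clip)) {
    bulk <- fields$surprisal <= min(fields$surprisal) + tail_clip
    for (i in seq_len(n)) {
      vcap <- max(abs(flow[[i]][bulk]))
      flow[[i]] <- pmin(pmax(flow[[i]], -vcap), vcap)
    }
  }
  stiffness <- sum(vapply(seq_len(n), function(i)
    2 * Gam[i] / gd$delta[i]^2 + 2 * max(abs(flow[[i]])) / gd$delta[i],
    numeric(1)))
  dt_max <- 0.8 / stiffness
  if (is.null(dt_density)) {
    nst <- ceiling(snapshot_every / dt_max)
    dt_density <- snapshot_every / nst    # land exactly on snapshot times
  } else if (dt_density > dt_max) {
    stop(sprintf(paste0("dt_density = %g violates the stability bound %g; ",
                        "use a smaller step or a coarser grid"),
                 dt_density, dt_max))
  }
  s0 <- min(fields$surprisal)   # shift before exponentiating (overflow-safe)
  steady_norm <- (fields$surprisal - s0) +
    log(sum(exp(-(fields$surprisal - s0))) * cell_volume(gd))
  vol <- cell_volume(gd)
  P <- exp(-gd$surprisal)
  P <- P / (sum(P) * vol)
  perms <- lapply(seq_len(n), function(d) c(d, setdiff(seq_len(n), d)))
  flowm <- lapply(seq_len(n), function(d) {
    V <- aperm(flow[[d]], perms[[d]])
    matrix(V, dims[d])
  })
  kl_of <- function(P) {
    pm <- P * vol
    sum(pm * (steady_norm + log(pmax(pm / vol, 1e-300))))
  }
  as_gd <- function(P, tau) {
    g <- gd
    g$surprisal <- -log(pmax(array(P, dims), 1e-300))
    g$tau <- tau
    renormalise_grid(g)
  }
  nsteps <- ceiling(T / dt_density - 1e-9)
  snap_stride <- max(1L, round(snapshot_every / dt_density))
  snapshots <- list(as_gd(P, 0))
  times <- 0
  kl <- numeric(nsteps + 1L)
  kl[1L] <- kl_of(P)
  mass_drift <- 0
  for (s in seq_len(nsteps)) {
    dP <- array(0, dims)
    for (d in seq_len(n)) {
      Pm <- matrix(aperm(P, perms[[d]]), dims[d])
      div <- cc_divergence(Pm, flowm[[d]], gd$delta[d], Gam[d])
      dP <- dP - aperm(array(div, dims[perms[[d]]]), order(perms[[d]]))
    }
    P <- pmax(P + dt_density * dP, 0)
    mass <- sum(P) * vol
    mass_drift <- max(mass_drift, abs(mass - 1))
    P <- P / mass
    kl[s + 1L] <- kl_of(P)
    if (s %% snap_stride == 0L) {
      snapshots[[length(snapshots) + 1L]] <- as_gd(P, s * dt_density)
      times <- c(times, s * dt_density)
    }
  }
  list(snapshots = snapshots, times = times, kl = kl,
       kl_times = seq(0, by = dt_density, length.out = nsteps + 1L),
       mass_drift = mass_drift, dt = dt_density)
}

#' Marginal density over selected dimensions
#'
#' Sums the gridded probability over the remaining dimensions.
#'
#' @param gd a `grid_density`; @param keep dimensions to keep.
#' @return List with `axes` and `density` (array over the kept dimensions,
#'   normalised to unit mass).
#' @export
marginal_density <- function(gd, keep = c(1L, 2L)) {
  p <- exp(-gd$surprisal)
  drop_dims <- setdiff(seq_along(gd$axes), keep)
  m <- apply(p, keep, sum)
  m <- m / (sum(m) * prod(gd$delta[keep]))
  list(axes = gd$axes[keep], density = m)
}

#' Information length of a density path
#'
#' Accumulates \eqn{L = \sum_k \Delta\tau\,\sqrt{E_{p_\tau}[\dot\Im_\tau^2]}}
#' with \eqn{\dot\Im_\tau} from finite differences of consecutive snapshots
#' and the expectation under the earlier snapshot's density. Zero for a
#' stationary sequence; converges as the snapshot spacing is refined.
#'
#' @param snapshots list of `grid_density` at uniform time spacing (at
#'   least two).
#' @return Nonnegative scalar.
#' @export
information_length <- function(snapshots) {
  if (length(snapshots) < 2L) stop("need at least two snapshots")
  taus <- vapply(snapshots, function(g) g$tau, numeric(1))
  dtau <- diff(taus)
  if (any(dtau <= 0)) stop("snapshot times must be strictly increasing")
  if (any(abs(dtau - dtau[1L]) > 1e-6 * abs(dtau[1L])))
    stop("snapshots must be uniformly spaced in time")
  L <- 0
  for (k in seq_len(length(snapshots) - 1L)) {
    a <- snapshots[[k]]; b <- snapshots[[k + 1L]]
    idot <- (b$surprisal - a$surprisal) / dtau[k]
    p <- exp(-a$surprisal) * cell_volume(a)
    L <- L + dtau[k] * sqrt(sum(p * idot^2))
  }
  L
}
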