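#' Gaussian steady state implied by a quadratic potential
#'
#' For a quadratic (Laplace) potential \eqn{\Im(x) = c + b^T x + \tfrac12
#' x^T H x}, the steady-state density \eqn{p \propto e^{-\Im}} is Gaussian
#' with precision \eqn{H} (the constant Hessian of \eqn{\Im}) and mean
#' \eqn{-H^{-1} b} when \eqn{H} is positive definite. Improper potentials
#' (indefinite Hessian, e.g. the exact Lorenz decomposition) are flagged,
#' not rejected, because their conditional-independence structure is still
#' readable from \eqn{H}.
#'
#' @param params a [helmholtz_params()] with `m = 2`.
#' @return An object of class `gaussian_ness`: list with `H` (precision),
#'   `b` (linear coefficients), `mean`, `Sigma` (covariance, `NULL` when
#'   improper), `proper` (logical) and `n`.
#' @export
gaussian_from_potential <- function(params) {
  stopifnot(inherits(params, "helmholtz_params"))
  if (params$basis$m != 2L)
    stop("gaussian_from_potential requires a quadratic basis (m = 2)")
  n <- params$basis$n
  pot <- potential_eval(params, numeric(n))
  H <- pot$hessian
  b <- pot$gradient
  new_gaussian_ness(H, b = b)
}

new_gaussian_ness <- function(H, b = NULL, mean = NULL) {
  n <- nrow(H)
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  proper <- all(ev > 1e-12 * max(abs(ev), 1))
  Sigma <- NULL
  if (proper) {
    Sigma <- chol2inv(chol(H))
    if (is.null(mean)) mean <- if (is.null(b)) numeric(n) else
      drop(-Sigma %*% b)
  } else if (is.null(mean)) {
    mean <- rep(NA_real_, n)
    if (!is.null(b) && max(abs(b)) > 0) {
      # mean undefined unless b lies in the range of H
      sol <- tryCatch(drop(MASS_ginv(H) %*% -b), error = function(e) NULL)
      if (!is.null(sol) && max(abs(H %*% sol + b)) < 1e-8 * max(abs(b)))
        mean <- sol
    } else mean <- numeric(n)
  }
  structure(list(H = H, b = if (is.null(b)) numeric(n) else as.numeric(b),
                 mean = mean, Sigma = Sigma, proper = proper, n = n),
            class = "gaussian_ness")
}

# Moore-Penrose pseudo-inverse via SVD (small matrices only)
MASS_ginv <- function(A, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * max(sv$d)
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}

#' @export
print.gaussian_ness <- function(x, ...) {
  cat(sprintf("Gaussian NESS: n = %d, %s\n", x$n,
              if (x$proper) "proper (H positive definite)"
              else "IMPROPER (H not positive definite)"))
  cat("  mean:", paste(signif(x$mean, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Gaussian steady state estimated from a sampled trajectory
#'
#' Uses the post-burn-in sample mean and covariance; the precision is the
#' inverse sample covariance, so zero (small) entries flag empirical
#' conditional independence.
#'
#' @param trajectory a `trajectory` (see [integrate_stochastic()]).
#' @param burn_in seconds to discard from the start.
#' @return A `gaussian_ness`.
#' @export
gaussian_from_samples <- function(trajectory, burn_in = 0) {
  keep <- trajectory$times >= burn_in
  S <- trajectory$states[keep, , drop = FALSE]
  n <- ncol(S)
  if (nrow(S) < 10L * n)
    stop("too few post-burn-in samples (need at least 10 per state); use a longer series")
  Sigma <- stats::cov(S)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(ev))
    stop("sample covariance is rank deficient; use a longer series")
  H <- chol2inv(chol(Sigma))
  mu <- colMeans(S)
  structure(list(H = H, b = drop(-H %*% mu), mean = mu, Sigma = Sigma,
                 proper = TRUE, n = n),
            class = "gaussian_ness")
}

#' Conditional Gaussian density
#'
#' Standard Gaussian conditioning: given `values` for the states in
#' `given`, the remaining states have mean
#' \eqn{E[u] + \Sigma_{uv}\Sigma_{vv}^{-1}(v - E[v])} and covariance the
#' Schur complement; computed here from precision blocks, which requires
#' only the retained block of `H` to be positive definite.
#'
#' @param ness a `gaussian_ness`.
#' @param given integer indices being conditioned on (may be empty).
#' @param values numeric values for the conditioned states.
#' @return List with `indices` (the retained states), `mean` and `Sigma`.
#' @export
conditional_gaussian <- function(ness, given, values) {
  n <- ness$n
  given <- as.integer(given)
  if (length(given) != length(values)) stop("given/values length mismatch")
  keep <- setdiff(seq_len(n), given)
  if (length(keep) == 0L) stop("cannot condition on every state")
  Huu <- ness$H[keep, keep, drop = FALSE]
  ev <- eigen(Huu, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12 * max(abs(ev), 1))
    stop("retained precision block is not positive definite (improper conditional)")
  Suu <- chol2inv(chol(Huu))
  if (length(given) == 0L) {
    if (!ness$proper) stop("marginal of an improper density is undefined")
    return(list(indices = keep, mean = ness$mean, Sigma = ness$Sigma))
  }
  if (any(!is.finite(ness$mean)))
    stop("mean undefined for this (improper) density")
  dev <- as.numeric(values) - ness$mean[given]
  mean_u <- ness$mean[keep] -
    drop(Suu %*% ness$H[keep, given, drop = FALSE] %*% dev)
  list(indices = keep, mean = mean_u, Sigma = Suu)
}

#' Conditional independence of a pair, given all remaining states
#'
#' Two states are conditionally independent given the rest iff the
#' corresponding precision (Hessian) entry vanishes; the test is on the
#' normalised magnitude \eqn{|H_{uv}|/\sqrt{H_{uu}H_{vv}}} (the magnitude of
#' the partial correlation).
#'
#' @param ness a `gaussian_ness`.
#' @param u,v distinct state indices.
#' @param tol normalised zero threshold (default 1e-6, suited to analytic
#'   precisions; use a sampling-aware threshold for empirical ones).
#' @return Logical.
#' @export
is_conditionally_independent <- function(ness, u, v, tol = 1e-6) {
  if (u == v) stop("u and v must differ")
  abs(ness$H[u, v]) / sqrt(abs(ness$H[u, u] * ness$H[v, v])) < tol
}

#' Markov boundary of a set of states
#'
#' The minimal set of states outside `subset` carrying a nonzero precision
#' entry to some member of `subset`; under the Gaussian (constant-Hessian)
#' criterion this set is minimal by construction.
#'
#' @param ness a `gaussian_ness`.
#' @param subset nonempty integer index set.
#' @param tol normalised zero threshold on precision entries.
#' @return Integer vector (possibly empty).
#' @export
markov_boundary <- function(ness, subset, tol = 1e-6) {
  subset <- as.integer(subset)
  if (length(subset) == 0L) stop("subset must be nonempty")
  others <- setdiff(seq_len(ness$n), subset)
  d <- sqrt(abs(diag(ness$H)))
  hit <- vapply(others, function(v)
    any(abs(ness$H[v, subset]) / (d[v] * d[subset]) >= tol), logical(1))
  others[hit]
}

#' Particular partition around a set of internal states
#'
#' Applies the blanket rules: the active states `a` are the Markov boundary
#' of the internal states `mu`; the sensory states `s` are the Markov
#' boundary of the autonomous states \eqn{\alpha = \mu \cup a} (minus
#' \eqn{\alpha} itself); everything else is external \eqn{\eta}. The three
#' zero-block conditions \eqn{H_{\mu\eta} = 0}, \eqn{H_{a\eta} = 0},
#' \eqn{H_{s\mu} = 0} are then verified and the construction fails loudly if
#' any is violated (the internal set does not admit a particular partition).
#'
#' @param ness a `gaussian_ness`.
#' @param internal nonempty integer index set of internal states.
#' @param tol normalised zero threshold on precision entries.
#' @return An object of class `particular_partition`: list with `eta`, `s`,
#'   `a`, `mu` and derived sets `b` (blanket), `alpha` (autonomous), `pi`
#'   (particular).
#' @export
particular_partition <- function(ness, internal, tol = 1e-6) {
  mu <- sort(as.integer(internal))
  if (length(mu) == 0L) stop("internal set must be nonempty")
  a <- markov_boundary(ness, mu, tol)
  alpha <- sort(c(mu, a))
  s <- setdiff(markov_boundary(ness, alpha, tol), alpha)
  eta <- setdiff(seq_len(ness$n), c(mu, a, s))
  d <- sqrt(abs(diag(ness$H)))
  block_zero <- function(rows, cols) {
    if (length(rows) == 0L || length(cols) == 0L) return(TRUE)
    all(abs(ness$H[rows, cols, drop = FALSE]) /
          outer(d[rows], d[cols]) < tol)
  }
  ok <- c(mu_eta = block_zero(mu, eta),
          a_eta = block_zero(a, eta),
          s_mu = block_zero(s, mu))
  if (!all(ok))
    stop(paste0("internal set does not admit a particular partition; ",
                "violated zero blocks: ",
                paste(names(ok)[!ok], collapse = ", ")))
  structure(list(eta = eta, s = s, a = a, mu = mu,
                 b = sort(c(s, a)), alpha = alpha,
                 pi = sort(c(s, a, mu)), tol = tol),
            class = "particular_partition")
}

#' @export
print.particular_partition <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ",") else "(empty)"
  cat("Particular partition:\n")
  cat("  external  eta:", fmt(x$eta), "\n")
  cat("  sensory     s:", fmt(x$s), "\n")
  cat("  active      a:", fmt(x$a), "\n")
  cat("  internal   mu:", fmt(x$mu), "\n")
  invisible(x)
}

#' Audit the sparse-coupling conjecture
#'
#' For each ordered pair of distinct states, checks across the supplied
#' points whether the Jacobian entry \eqn{J_{uv}} vanishes identically,
#' whether the solenoidal entry \eqn{Q_{uv}} vanishes, and whether the
#' Hessian entry \eqn{H_{uv}} vanishes, then classifies the pair:
#' `"conjecture-consistent"` (no coupling in either direction, and both Q
#' and H entries zero, as the conjecture predicts), `"edge-case"` (no
#' coupling yet a nonzero Q or H entry: terms must cancel),
#' `"coupled"` (dynamical coupling present; a zero H entry is then
#' independence reached without sparse coupling and is noted in
#' `independent_without_sparse_coupling`).
#'
#' @param params a [helmholtz_params()].
#' @param points matrix or list of probe states (default: 50 points drawn
#'   deterministically from a fixed low-discrepancy-ish lattice in
#'   \eqn{[-8, 8]^n}).
#' @param tol absolute zero threshold relative to the largest entry seen.
#' @return Data frame with one row per ordered pair.
#' @export
sparse_coupling_audit <- function(params, points = NULL, tol = 1e-6) {
  n <- params$basis$n
  if (is.null(points)) {
    k <- 50L
    points <- sapply(seq_len(n), function(i)
      -8 + 16 * ((seq_len(k) * (i + 1) * 0.6180339887) %% 1))
  }
  X <- as_point_matrix(points, n)
  P <- nrow(X)
  Jmax <- Qmax <- Hmax <- matrix(0, n, n)
  for (p in seq_len(P)) {
    mf <- model_flow(params, X[p, ])
    Qm <- solenoidal_operator(params, X[p, ])
    Hm <- potential_eval(params, X[p, ])$hessian
    Jmax <- pmax(Jmax, abs(mf$J))
    Qmax <- pmax(Qmax, abs(Qm))
    Hmax <- pmax(Hmax, abs(Hm))
  }
  sJ <- tol * max(Jmax, 1e-300); sQ <- tol * max(Qmax, 1e-300)
  sH <- tol * max(Hmax, 1e-300)
  rows <- list()
  for (u in seq_len(n)) for (v in seq_len(n)) {
    if (u == v) next
    j0 <- Jmax[u, v] < sJ; j0r <- Jmax[v, u] < sJ
    q0 <- Qmax[u, v] < sQ; h0 <- Hmax[u, v] < sH
    class <- if (j0 && j0r) {
      if (q0 && h0) "conjecture-consistent" else "edge-case"
    } else "coupled"
    rows[[length(rows) + 1L]] <- data.frame(
      u = u, v = v, J_zero = j0, J_zero_reverse = j0r,
      Q_zero = q0, H_zero = h0, class = class,
      independent_without_sparse_coupling = (!(j0 && j0r)) && h0)
  }
  do.call(rbind, rows)
}

#' Expected Jacobian eigenvalues under the steady-state density
#'
#' Evaluates the flow Jacobian on a rectangular grid, takes the real parts
#' of its eigenvalues sorted in descending order at each point, and averages
#' them with weights proportional to the steady-state density
#' \eqn{p \propto e^{-\Im}} renormalised over the grid. These are the
#' expected local Lyapunov exponents used for the Kaplan-Yorke dimension.
#'
#' @param params a [helmholtz_params()] whose implied Gaussian is proper.
#' @param grid_points points per axis (default 16); @param span half-width
#'   of the grid (scalar or per-axis); @param centre grid centre. When
#'   `span`/`centre` are `NULL` (the default) the grid adapts to the
#'   density: centred on the steady-state mean and spanning 4 standard
#'   deviations per axis, which resolves the Gaussian weights (a fixed
#'   wide grid is available by passing `span` and `centre` explicitly, but
#'   under-resolves tight densities and then returns quadrature noise --
#'   see the methods vignette).
#' @return Numeric vector of expected eigenvalues, sorted descending.
#' @export
expected_jacobian_eigenvalues <- function(params, grid_points = 16,
                                          span = NULL, centre = NULL) {
  ness <- gaussian_from_potential(params)
  if (!ness$proper)
    stop("steady-state density is improper; expected eigenvalues undefined")
  n <- params$basis$n
  if (is.null(centre)) centre <- ness$mean
  if (is.null(span)) span <- 4 * sqrt(diag(ness$Sigma))
  span <- rep_len(span, n)
  axes <- lapply(seq_len(n), function(i)
    seq(centre[i] - span[i], centre[i] + span[i], length.out = grid_points))
  X <- t(as.matrix(expand.grid(axes)))
  B <- eval_basis_matrix(params$basis, X)
  surpr <- drop(crossprod(B, params$h))
  w <- exp(-(surpr - min(surpr)))
  w <- w / sum(w)
  lam <- matrix(0, n, ncol(X))
  for (p in seq_len(ncol(X))) {
    J <- model_flow(params, X[, p])$J
    lam[, p] <- sort(Re(eigen(J, only.values = TRUE)$values),
                     decreasing = TRUE)
  }
  drop(lam %*% w)
}

#' Kaplan-Yorke (Lyapunov) dimension
#'
#' \eqn{d = j + (\sum_{i \le j}\lambda_i)/|\lambda_{j+1}|} with \eqn{j} the
#' largest index whose partial sum of descending-ordered exponents is
#' nonnegative; 0 when even the largest exponent is negative, and `n` when
#' every partial sum is nonnegative.
#'
#' @param lambda numeric vector of Lyapunov exponents sorted descending.
#' @return The dimension, in `[0, length(lambda)]`.
#' @export
kaplan_yorke_dimension <- function(lambda) {
  if (is.unsorted(rev(lambda))) stop("`lambda` must be sorted descending")
  if (lambda[1L] < 0) return(0)
  cs <- cumsum(lambda)
  j <- max(which(cs >= 0))
  if (j == length(lambda)) return(length(lambda))
  j + cs[j] / abs(lambda[j + 1L])
}

#' Analytic Lyapunov dimension of the Lorenz system
#'
#' Closed form
#' \eqn{d = 3 - 2(\sigma+\beta+1)/(\sigma+1+\sqrt{(\sigma-1)^2+4\sigma\rho})}.
#'
#' @param sigma,rho,beta Lorenz parameters.
#' @return The dimension (2.43 for the default chaotic regime).
#' @export
lorenz_analytic_dimension <- function(sigma = 10, rho = 32, beta = 8 / 3) {
  disc <- (sigma - 1)^2 + 4 * sigma * rho
  if (disc < 0) stop("complex square root: no real analytic dimension")
  3 - 2 * (sigma + beta + 1) / (sigma + 1 + sqrt(disc))
}

#' Empirical partial correlations over growing windows
#'
#' For each window length, computes the partial-correlation matrix
#' \eqn{P_{uv} = -\Theta_{uv}/\sqrt{\Theta_{uu}\Theta_{vv}}} from the sample
#' precision \eqn{\Theta} of each realisation restricted to that window,
#' then averages over realisations. Convergence of a pair's curve towards
#' zero is the empirical signature of conditional independence.
#'
#' @param trajectories list of `trajectory` objects (realisations).
#' @param window_lengths numeric vector of window lengths in seconds
#'   (default: the full length of the shortest trajectory).
#' @return List with `windows`, `partial` (list of averaged matrices, one
#'   per window) and `curves` (array windows x n x n for convergence plots).
#' @export
empirical_partial_correlation <- function(trajectories,
                                          window_lengths = NULL) {
  if (inherits(trajectories, "trajectory")) trajectories <- list(trajectories)
  if (length(trajectories) == 0L) stop("need at least one trajectory")
  Tmax <- min(vapply(trajectories, function(tr) max(tr$times), numeric(1)))
  if (is.null(window_lengths)) window_lengths <- Tmax
  if (any(window_lengths > Tmax + 1e-9))
    stop("window length exceeds trajectory length")
  n <- ncol(trajectories[[1L]]$states)
  pc_one <- function(S) {
    Sig <- stats::cov(S)
    ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-12 * max(ev)) stop("singular covariance in window")
    Th <- chol2inv(chol(Sig))
    P <- -Th / sqrt(outer(diag(Th), diag(Th)))
    diag(P) <- 1
    P
  }
  curves <- array(NA_real_, c(length(window_lengths), n, n))
  partial <- vector("list", length(window_lengths))
  for (w in seq_along(window_lengths)) {
    acc <- matrix(0, n, n)
    for (tr in trajectories) {
      keep <- tr$times <= window_lengths[w] + 1e-9
      acc <- acc + pc_one(tr$states[keep, , drop = FALSE])
    }
    partial[[w]] <- acc / length(trajectories)
    curves[w, , ] <- partial[[w]]
  }
  list(windows = window_lengths, partial = partial, curves = curves)
}
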