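#' Synchronisation map between internal and external conditional modes
#'
#' Under a particular partition of a Gaussian steady state, conditioning on
#' the sensory states fixes both the expected internal states
#' \eqn{\bar\mu(s)} and the expected external states \eqn{\bar\eta(s)};
#' both maps are linear, so the synchronisation map
#' \eqn{\sigma: \bar\mu \mapsto \bar\eta} is linear as well, computed here
#' as \eqn{\sigma = A_{\eta s} A_{\mu s}^+}. Composition consistency
#' \eqn{\sigma(\bar\mu(s)) = \bar\eta(s)} holds exactly whenever
#' \eqn{A_{\mu s}} has full column rank.
#'
#' @param ness a `gaussian_ness` (proper).
#' @param partition a [particular_partition()].
#' @return An object of class `synchronisation_map`: list with `A_eta_s`,
#'   `A_mu_s`, `A_a_s` (linear response of the conditional expectations to
#'   sensory deviations), `sigma` (the map from \eqn{\bar\mu} to
#'   \eqn{\bar\eta}), and `H_eta_cond` (conditional precision of the
#'   external states given the particular states, equal to the
#'   \eqn{(\eta,\eta)} precision block).
#' @export
synchronisation_map <- function(ness, partition) {
  if (!ness$proper) stop("synchronisation map requires a proper density")
  s <- partition$s; mu <- partition$mu; a <- partition$a; eta <- partition$eta
  if (length(s) == 0L) stop("partition has no sensory states")
  coef_given_s <- function(idx) {
    # E[u | s] = E[u] + Sigma_us Sigma_ss^{-1} (s - E[s])
    ness$Sigma[idx, s, drop = FALSE] %*%
      solve(ness$Sigma[s, s, drop = FALSE])
  }
  A_eta <- coef_given_s(eta)
  A_mu <- coef_given_s(mu)
  A_a <- if (length(a)) coef_given_s(a) else
    matrix(0, 0L, length(s))
  if (qr(A_mu)$rank < ncol(A_mu))
    stop("internal conditional-expectation map A_mu_s is rank deficient: ",
         "no synchronisation map (block effectively decoupled)")
  sigma <- A_eta %*% MASS_ginv(A_mu)
  structure(list(A_eta_s = A_eta, A_mu_s = A_mu, A_a_s = A_a, sigma = sigma,
                 H_eta_cond = ness$H[eta, eta, drop = FALSE],
                 partition = partition),
            class = "synchronisation_map")
}

#' @export
print.synchronisation_map <- function(x, ...) {
  cat("Synchronisation map sigma (eta-bar as a linear map of mu-bar):\n")
  print(x$sigma)
  invisible(x)
}

#' Conditional expectations of external, active and internal states given
#' a sensory value
#'
#' @param ness a `gaussian_ness`.
#' @param partition a [particular_partition()].
#' @param s_value numeric values of the sensory states.
#' @return List with `eta_bar`, `a_bar`, `mu_bar`.
#' @export
conditional_expectations <- function(ness, partition, s_value) {
  sm <- synchronisation_map(ness, partition)
  dev <- as.numeric(s_value) - ness$mean[partition$s]
  list(eta_bar = drop(ness$mean[partition$eta] + sm$A_eta_s %*% dev),
       a_bar = if (length(partition$a))
         drop(ness$mean[partition$a] + sm$A_a_s %*% dev) else numeric(0),
       mu_bar = drop(ness$mean[partition$mu] + sm$A_mu_s %*% dev))
}

# internal: pieces shared by the free-energy routines.
# pi ordering convention: (s, a, mu-and-other-particular) = sorted partition$pi
fe_machinery <- function(ness, partition) {
  pi_idx <- partition$pi
  eta <- partition$eta
  H_pi_cond <- ness$H[pi_idx, pi_idx, drop = FALSE]  # precision of pi | eta
  ev <- eigen(H_pi_cond, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("particular precision block is not positive definite")
  # marginal precision of pi (Schur complement over eta)
  H_pi <- H_pi_cond
  if (length(eta))
    H_pi <- H_pi - ness$H[pi_idx, eta, drop = FALSE] %*%
      solve(ness$H[eta, eta, drop = FALSE]) %*%
      ness$H[eta, pi_idx, drop = FALSE]
  # marginal precision of eta
  H_eta_marg <- if (length(eta))
    chol2inv(chol(ness$Sigma[eta, eta, drop = FALSE])) else matrix(0, 0, 0)
  list(pi_idx = pi_idx, H_pi_cond = H_pi_cond, H_pi = H_pi,
       H_eta_marg = H_eta_marg)
}

# the variational prediction of the particular states: E[pi | eta] evaluated
# at the variational mode eta-bar(s) = E[eta | s]
predict_pi_given_s <- function(ness, partition, pi_value) {
  pi_idx <- partition$pi
  eta <- partition$eta
  s_pos <- match(partition$s, pi_idx)
  s_value <- pi_value[s_pos]
  if (length(eta) == 0L) return(ness$mean[pi_idx])
  eta_bar <- ness$mean[eta] +
    drop(ness$Sigma[eta, partition$s, drop = FALSE] %*%
           solve(ness$Sigma[partition$s, partition$s, drop = FALSE]) %*%
           (s_value - ness$mean[partition$s]))
  ness$mean[pi_idx] +
    drop(ness$Sigma[pi_idx, eta, drop = FALSE] %*%
           chol2inv(chol(ness$Sigma[eta, eta, drop = FALSE])) %*%
           (eta_bar - ness$mean[eta]))
}

#' Variational free energy of a particular state
#'
#' With the variational density over external states defined as the
#' conditional density given the sensory states, the divergence term
#' vanishes identically and the free energy equals the surprisal of the
#' particular states up to an additive constant. The report carries both
#' routes: the accuracy/complexity decomposition (conditional route) and
#' the marginal surprisal \eqn{\Im(\pi) = \tfrac12(\pi - E[\pi])^T H_\pi
#' (\pi - E[\pi])}.
#'
#' @param ness a `gaussian_ness` (proper).
#' @param partition a [particular_partition()].
#' @param pi_value numeric values of the particular states, ordered as
#'   `partition$pi` (sorted indices).
#' @return An object of class `free_energy_report`: list with `F`
#'   (accuracy + complexity), `accuracy`, `complexity`, `surprisal`
#'   (quadratic part of \eqn{\Im(\pi)}), `constant` (`F - surprisal`,
#'   state-independent), `gradient` (over the autonomous states, via the
#'   conditional route) and `gradient_marginal` (via the marginal route;
#'   equal up to numerical precision).
#' @export
variational_free_energy <- function(ness, partition, pi_value) {
  if (!ness$proper) stop("free energy requires a proper density")
  mach <- fe_machinery(ness, partition)
  pi_idx <- mach$pi_idx
  pi_value <- as.numeric(pi_value)
  if (length(pi_value) != length(pi_idx))
    stop(sprintf("pi_value must have length %d (states %s)",
                 length(pi_idx), paste(pi_idx, collapse = ",")))
  m_q <- predict_pi_given_s(ness, partition, pi_value)
  dev_q <- pi_value - m_q
  accuracy <- 0.5 * drop(t(dev_q) %*% mach$H_pi_cond %*% dev_q)
  complexity <- 0
  if (length(partition$eta)) {
    s_pos <- match(partition$s, pi_idx)
    eta_bar <- ness$mean[partition$eta] +
      drop(ness$Sigma[partition$eta, partition$s, drop = FALSE] %*%
             solve(ness$Sigma[partition$s, partition$s, drop = FALSE]) %*%
             (pi_value[s_pos] - ness$mean[partition$s]))
    dev_eta <- eta_bar - ness$mean[partition$eta]
    complexity <- 0.5 * drop(t(dev_eta) %*% mach$H_eta_marg %*% dev_eta)
  }
  dev_m <- pi_value - ness$mean[pi_idx]
  surprisal <- 0.5 * drop(t(dev_m) %*% mach$H_pi %*% dev_m)
  auto_pos <- match(sort(partition$alpha), pi_idx)
  g_cond <- drop(mach$H_pi_cond %*% dev_q)[auto_pos]
  g_marg <- drop(mach$H_pi %*% dev_m)[auto_pos]
  structure(list(F = accuracy + complexity,
                 accuracy = accuracy, complexity = complexity,
                 surprisal = surprisal,
                 constant = accuracy + complexity - surprisal,
                 gradient = g_cond, gradient_marginal = g_marg,
                 autonomous = sort(partition$alpha)),
            class = "free_energy_report")
}

#' @export
print.free_energy_report <- function(x, ...) {
  cat(sprintf("F = %.6g (accuracy %.6g + complexity %.6g); surprisal %.6g\n",
              x$F, x$accuracy, x$complexity, x$surprisal))
  cat("gradient over autonomous states (", paste(x$autonomous, collapse = ","),
      "): ", paste(signif(x$gradient, 6), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Free-energy gradients over the autonomous states
#'
#' Computed by both the conditional route
#' \eqn{H_{\pi|\eta}(\pi - E_q[\pi|\eta])} and the marginal route
#' \eqn{H_\pi(\pi - E[\pi])}; the two agree identically on the autonomous
#' rows (the routes differ only in the sensory row and the external
#' marginalisation, which cancel there).
#'
#' @inheritParams variational_free_energy
#' @return List with `conditional`, `marginal` (numeric gradients over the
#'   autonomous states, in sorted index order) and `max_discrepancy`.
#' @export
free_energy_gradients <- function(ness, partition, pi_value) {
  rep <- variational_free_energy(ness, partition, pi_value)
  list(conditional = rep$gradient, marginal = rep$gradient_marginal,
       max_discrepancy = max(abs(rep$gradient - rep$gradient_marginal)))
}

#' Autonomous flow as a free-energy gradient flow
#'
#' Decomposes the model flow restricted to the autonomous states
#' \eqn{(a, \mu)} into a dissipative part \eqn{-\Gamma_\alpha \nabla_\alpha
#' F}, a solenoidal part \eqn{(Q\nabla\Im)_\alpha} and the correction
#' \eqn{-\Lambda_\alpha}; their sum reproduces [model_flow()] exactly
#' (the free-energy gradient restricted to autonomous rows equals the
#' surprisal gradient there because the autonomous-external precision
#' block vanishes).
#'
#' @param params a [helmholtz_params()] (quadratic, proper).
#' @param partition a [particular_partition()] of its Gaussian steady state.
#' @param x full state vector.
#' @return List with `dissipative`, `solenoidal`, `correction`, `total`
#'   (each over the sorted autonomous states) and `flow` (the matching rows
#'   of [model_flow()]).
#' @export
autonomous_flow <- function(params, partition, x) {
  ness <- gaussian_from_potential(params)
  alpha <- sort(partition$alpha)
  pot <- potential_eval(params, x)
  Q <- solenoidal_operator(params, x)
  Lam <- correction_term(params, x)
  pi_idx <- partition$pi
  fe <- variational_free_energy(ness, partition, x[pi_idx])
  diss <- -params$Gamma[alpha] * fe$gradient
  sol <- drop(Q %*% pot$gradient)[alpha]
  corr <- -Lam[alpha]
  # state-dependent diagonal of Omega (zero when the diagonal is fixed)
  diag_extra <- vapply(alpha, function(i)
    sum(get_q_block(params, i, i) * eval_basis(params$basis, x)) *
      pot$gradient[i], numeric(1))
  total <- diss + sol + corr + diag_extra
  list(dissipative = diss, solenoidal = sol, correction = corr,
       diag_extra = diag_extra, total = total,
       flow = model_flow(params, x)$f[alpha], alpha = alpha)
}

#' Closed-form coefficient checks for the six-state worked system
#'
#' For the coupled system with partition s = 1, external (2,3), active 4,
#' internal (5,6), the conditional-expectation and gradient formulas reduce
#' to ratios of named Hessian coefficients (h5 = H12, h6 = H22, h12 = H14,
#' h15 = H44, h20 = H45, h21 = H55). This helper returns those closed forms
#' for cross-checking the general machinery.
#'
#' @param ness a `gaussian_ness` with the six-state sparsity structure.
#' @return List with `eta_bar_coef` (coefficient of s in
#'   \eqn{\bar\eta_2(s)}), `mu_bar_coef` (in \eqn{\bar\mu_5(s)}),
#'   `a_bar_coef` (in \eqn{\bar a(s)}), `sigma_coef` (the scalar
#'   synchronisation coefficient mapping \eqn{\bar\mu_5} to
#'   \eqn{\bar\eta_2}), and `H_eta_cond` (= h6).
#' @export
coupled_closed_forms <- function(ness) {
  H <- ness$H
  h5 <- H[1, 2]; h6 <- H[2, 2]; h12 <- H[1, 4]
  h15 <- H[4, 4]; h20 <- H[4, 5]; h21 <- H[5, 5]
  den <- h15 * h21 - h20^2
  list(eta_bar_coef = -h5 / h6,
       mu_bar_coef = h12 * h20 / den,
       a_bar_coef = -h12 * h21 / den,
       sigma_coef = (h20^2 - h15 * h21) / (h12 * h20) * (h5 / h6),
       H_eta_cond = h6)
}
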