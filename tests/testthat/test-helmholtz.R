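test_that("flow operator assembles skew plus dissipative structure", {
  b <- monomial_basis(3, 2)
  pr0 <- helmholtz_params(b, numeric(10), list(), c(1, 1, 1))
  expect_equal(flow_operator(pr0, c(2, -1, 5)), -diag(3))

  # exact Lorenz params: Omega_22 = q37*x3 - Gamma2 on the x1 = x2 = 0 axis
  ex <- exact_lorenz_decomposition(10, 32, 8 / 3)
  q37 <- ex$q[["2.2"]][7]
  for (x3 in c(-2, 0, 7)) {
    Om <- flow_operator(ex, c(0, 0, x3))
    expect_equal(Om[2, 2], q37 * x3 - ex$Gamma[2])
  }

  # Omega + Omega^T = -2 diag(Gamma(x)) at random points
  pts <- probe_points(20, 3)
  for (p in seq_len(nrow(pts))) {
    Om <- flow_operator(ex, pts[p, ])
    diag_gamma <- ex$Gamma -
      vapply(1:3, function(i) sum(ex$q[[paste0(i, ".", i)]] *
                                    eval_basis(b, pts[p, ])), numeric(1))
    expect_equal(Om + t(Om), -2 * diag(diag_gamma), tolerance = 1e-12)
  }
})

test_that("correction term is the analytic row divergence of Omega", {
  b2 <- monomial_basis(2, 2)
  # constant Omega -> Lambda = 0
  q_const <- replace(numeric(6), 1, 3)
  pr <- helmholtz_params(b2, numeric(6), list("1.2" = q_const), c(1, 1))
  expect_equal(correction_term(pr, c(0.3, -2)), c(0, 0))

  # Q12 = x1 x2 -> Lambda = (x1, -x2) by hand differentiation
  q_cross <- replace(numeric(6), 5, 1)
  pr2 <- helmholtz_params(b2, numeric(6), list("1.2" = q_cross), c(1, 1))
  for (x in list(c(1, 2), c(-3, 0.5))) {
    expect_equal(correction_term(pr2, x), c(x[1], -x[2]))
  }

  # fitted system: Lambda matches finite-difference row divergence of Omega
  lp <- make_fixture("lorenz-laplace")$params
  pts <- probe_points(5, 3)
  for (p in seq_len(nrow(pts))) {
    x <- pts[p, ]
    lam_fd <- vapply(1:3, function(i) {
      sum(vapply(1:3, function(j) {
        e <- numeric(3); e[j] <- 1e-6
        (flow_operator(lp, x + e)[i, j] - flow_operator(lp, x - e)[i, j]) / 2e-6
      }, numeric(1)))
    }, numeric(1))
    expect_lt(max(abs(correction_term(lp, x) - lam_fd)), 1e-8)
  }
})

test_that("model flow and its Jacobian are mutually consistent", {
  b <- monomial_basis(3, 2)
  # zero potential, constant Omega -> zero flow
  pr <- helmholtz_params(b, numeric(10),
                         list("1.2" = replace(numeric(10), 1, 2)), c(1, 1, 1))
  expect_equal(model_flow(pr, c(1, -4, 2))$f, c(0, 0, 0))

  # quadratic potential, constant Omega: f linear with J = Omega H
  h <- numeric(10); h[3] <- 2; h[6] <- 1; h[10] <- 0.5; h[5] <- -0.3
  pr2 <- helmholtz_params(b, h, list("1.2" = replace(numeric(10), 1, 2)),
                          c(1, 1, 1))
  H <- potential_eval(pr2, c(0, 0, 0))$hessian
  Om <- flow_operator(pr2, c(0, 0, 0))
  for (x in list(c(1, 2, 3), c(-2, 0, 1))) {
    mf <- model_flow(pr2, x)
    expect_equal(mf$f, drop(Om %*% H %*% x), tolerance = 1e-12)
    expect_equal(mf$J, Om %*% H, tolerance = 1e-12)
  }

  # analytic Jacobian matches finite differences for a fitted system
  lp <- make_fixture("lorenz-laplace")$params
  pts <- probe_points(10, 3)
  for (p in seq_len(nrow(pts))) {
    x <- pts[p, ]
    mf <- model_flow(lp, x)
    Jfd <- fd_jacobian(function(z) model_flow(lp, z)$f, x)
    expect_lt(max(abs(mf$J - Jfd)), 1e-5)
  }
})

test_that("exact Lorenz decomposition reproduces the flow and relations", {
  sigma <- 10; rho <- 32; beta <- 8 / 3
  ex <- exact_lorenz_decomposition(sigma, rho, beta)
  fs <- lorenz(sigma, rho, beta)
  pts <- probe_points(100, 3, -20, 20, seed = 3)
  worst <- max(apply(pts, 1L, function(x)
    max(abs(model_flow(ex, x)$f - fs$flow(x)))))
  expect_lt(worst, 1e-10)

  # printed parameter relations
  expect_equal(-ex$h[5] * ex$q[["1.2"]][1], sigma)
  expect_equal(-ex$h[7] * ex$q[["3.3"]][7], beta)
  expect_equal(-ex$h[5] * ex$Gamma[2], rho)
  expect_equal(ex$h[5] * ex$Gamma[2], -rho)  # h5*Gamma2 = -rho

  # potential support: exactly h5 and h7
  expect_equal(which(abs(ex$h) > 1e-12), c(5L, 7L))

  # the Hessian is indefinite: no proper density
  ness <- gaussian_from_potential(ex)
  expect_false(ness$proper)
  expect_equal(ness$H, matrix(c(0, ex$h[5], 0, ex$h[5], 0, 0, 0, 0, 0), 3, 3))

  # alternative gauges still reproduce the flow exactly
  ex2 <- exact_lorenz_decomposition(sigma, rho, beta, gauge = c(h5 = 2, h7 = -0.5))
  worst2 <- max(apply(pts[1:20, ], 1L, function(x)
    max(abs(model_flow(ex2, x)$f - fs$flow(x)))))
  expect_lt(worst2, 1e-10)
  expect_error(exact_lorenz_decomposition(gauge = c(h5 = 0, h7 = 1)), "nonzero")
})

test_that("closed-form solenoidal solve satisfies its constraint", {
  # pure gradient flow: J = -Gamma -> Q = 0
  expect_equal(solve_solenoidal_linear(-diag(3), diag(3)), matrix(0, 3, 3))

  # random stable J: constraint residual and Hessian symmetry
  set.seed(5)
  for (rep in 1:5) {
    A <- matrix(stats::rnorm(9), 3)
    J <- A - 4 * diag(3)     # comfortably stable
    Gamma <- diag(c(1, 1, 1))
    Q <- solve_solenoidal_linear(J, Gamma)
    expect_equal(Q, -t(Q), tolerance = 1e-10)
    res <- J %*% Q + Q %*% t(J) - (Gamma %*% t(J) - J %*% Gamma)
    expect_lt(max(abs(res)), 1e-10)
    H <- solve(Q - Gamma, J)
    expect_lt(max(abs(H - t(H))), 1e-8)
  }

  # eigenvalue pair summing to zero -> named degeneracy
  Jsing <- diag(c(1, -1, 2))
  expect_error(solve_solenoidal_linear(Jsing, diag(3)), "singular")
})

test_that("kernel potential is positive semidefinite with exact gradients", {
  # K = I, m = 0: quadratic bowl
  b1 <- monomial_basis(2, 1)
  kI <- list("1.1" = c(1, 0, 0), "2.2" = c(1, 0, 0))
  kp <- kernel_potential(c(0, 0), kI, b1)
  ev <- kernel_potential_eval(kp, c(3, -4))
  expect_equal(ev$value, 0.5 * 25)
  expect_equal(ev$gradient, c(3, -4))

  # state-dependent K: KtK PSD at random points, gradient matches FD,
  # and the potential contains quartic terms in the state
  ks <- list("1.1" = c(1, 0.2, 0), "1.2" = c(0.1, 0, 0.3), "2.2" = c(1, 0, -0.1))
  kp2 <- kernel_potential(c(0.5, -1), ks, b1)
  pts <- probe_points(100, 2, -5, 5, seed = 9)
  for (p in seq_len(20)) {
    x <- pts[p, ]
    ev2 <- kernel_potential_eval(kp2, x)
    expect_gte(min(eigen(ev2$KtK, symmetric = TRUE, only.values = TRUE)$values),
               -1e-12)
    gfd <- fd_gradient(function(z) kernel_potential_eval(kp2, z)$value, x)
    expect_lt(max(abs(ev2$gradient - gfd)), 1e-5)
  }
  # quartic growth: value along a ray grows ~ t^4
  vals <- vapply(c(10, 20), function(t)
    kernel_potential_eval(kp2, c(t, t))$value, numeric(1))
  expect_gt(vals[2] / vals[1], 2^3.5)
})

test_that("fitting recovers exactly representable flows", {
  # Lorenz with free Gamma and free diagonal admits an exact solution
  fs <- lorenz(10, 32, 8 / 3)
  X <- sample_hypergrid(3, 4, 8, c(0, 0, 28))
  fit <- fit_helmholtz(fs, X, monomial_basis(3, 2), Gamma = "free",
                       fix_diagonal = FALSE)
  expect_lt(fit$fit$rms, 1e-6)

  # linear target flow: recovered (Q - Gamma) H equals J (closed-form oracle)
  J <- matrix(c(-1, 4, -4, -1), 2, 2)
  Xl <- sample_hypergrid(2, 5, 3, 0)
  lin_flow <- function(x) drop(J %*% x)
  fitl <- fit_helmholtz(lin_flow, Xl, monomial_basis(2, 2),
                        Gamma = c(1, 1), fix_diagonal = TRUE)
  expect_lt(fitl$fit$rms, 1e-8)
  H <- potential_eval(fitl, c(0, 0))$hessian
  Om <- flow_operator(fitl, c(0, 0))
  expect_equal(Om %*% H, J, tolerance = 1e-6)
  Qref <- solve_solenoidal_linear(J, diag(2))
  expect_equal(solenoidal_operator(fitl, c(0, 0)), Qref, tolerance = 1e-6)

  # sample grids that are too thin are refused
  Xthin <- cbind(rep(c(-1, 1), each = 4), rep(c(-1, 1), 4),
                 rep(c(-1, 1), 4))
  expect_error(fit_helmholtz(fs, Xthin, monomial_basis(3, 2), Gamma = "free"),
               "distinct sample coordinates")
})

test_that("refitting a fitted model's own flow is a fixed point", {
  fx <- make_fixture("ou-linear")
  pr <- fx$params
  X <- sample_hypergrid(2, 5, 3, 0)
  refit <- fit_helmholtz(function(x) model_flow(pr, x)$f, X, pr$basis,
                         Gamma = pr$Gamma, fix_diagonal = TRUE, init = pr)
  expect_lt(max(abs(refit$h - pr$h)), 1e-8)
  expect_lt(max(abs(refit$q[["1.2"]] - pr$q[["1.2"]])), 1e-8)
})

test_that("densities of proper parameter sets are stationary (Fokker-Planck)", {
  # the decisive check of the correction-term sign convention: for any
  # parameter set of this family with constant Gamma, p ~ exp(-I) must be a
  # stationary solution; the grid residual must shrink with refinement
  fx <- make_fixture("ou-linear")
  res_coarse <- fp_residual_grid(fx$params,
                                 list(seq(-4, 4, length.out = 21),
                                      seq(-4, 4, length.out = 21)))
  res_fine <- fp_residual_grid(fx$params,
                               list(seq(-4, 4, length.out = 41),
                                    seq(-4, 4, length.out = 41)))
  expect_lt(res_fine, res_coarse / 2)   # ~2nd order convergence
  expect_lt(res_fine, 5e-2)

  # a nonlinear (state-dependent Q) proper system: the fitted Lorenz Laplace
  lp <- make_fixture("lorenz-laplace")$params
  ness <- gaussian_from_potential(lp)
  axes <- lapply(1:3, function(i)
    seq(ness$mean[i] - 3 * sqrt(ness$Sigma[i, i]),
        ness$mean[i] + 3 * sqrt(ness$Sigma[i, i]), length.out = 17))
  axes_f <- lapply(1:3, function(i)
    seq(ness$mean[i] - 3 * sqrt(ness$Sigma[i, i]),
        ness$mean[i] + 3 * sqrt(ness$Sigma[i, i]), length.out = 33))
  r1 <- fp_residual_grid(lp, axes)
  r2 <- fp_residual_grid(lp, axes_f)
  expect_lt(r2, r1 / 2)
})

test_that("parameter sets with fixed diagonal and m = 2 imply a Gaussian", {
  lp <- make_fixture("lorenz-laplace")$params
  expect_true(all(vapply(1:3, function(i)
    is.null(lp$q[[paste0(i, ".", i)]]) ||
      all(lp$q[[paste0(i, ".", i)]] == 0), logical(1))))
  # quadratic potential: Hessian constant -> Gaussian steady state
  H1 <- potential_eval(lp, c(0, 0, 0))$hessian
  H2 <- potential_eval(lp, c(5, -3, 40))$hessian
  expect_equal(H1, H2)
  expect_true(gaussian_from_potential(lp)$proper)
})
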