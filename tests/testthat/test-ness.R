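test_that("Gaussian extraction from a quadratic potential", {
  b <- monomial_basis(3, 2)
  h <- numeric(10); h[c(3, 6, 10)] <- 1
  pr <- helmholtz_params(b, h, list(), c(1, 1, 1))
  ness <- gaussian_from_potential(pr)
  expect_true(ness$proper)
  expect_equal(ness$H, diag(3))
  expect_equal(ness$mean, c(0, 0, 0))
  expect_equal(ness$Sigma %*% ness$H, diag(3), tolerance = 1e-8)

  # exact Lorenz decomposition: improper, flagged not rejected
  ex <- make_fixture("lorenz-exact")$params
  expect_false(gaussian_from_potential(ex)$proper)

  # linear term shifts the mean: mean_i = -h_lin / h_sq on a diagonal H
  h2 <- h; h2[7] <- 1.5
  pr2 <- helmholtz_params(b, h2, list(), c(1, 1, 1))
  expect_equal(gaussian_from_potential(pr2)$mean, c(0, 0, -1.5))
})

test_that("sampled Gaussians behave like their generating process", {
  # white-noise series: precision close to identity
  S <- withr::with_seed(8, matrix(stats::rnorm(4000 * 3), 4000, 3))
  tr <- nessflow:::new_trajectory(seq(0, by = 0.1, length.out = 4000), S,
                                  0.1, "stochastic")
  ness <- gaussian_from_samples(tr)
  se <- 1 / sqrt(4000)
  expect_true(all(abs(ness$H - diag(3)) < 4 * se + 0.05))

  # degenerate input contract
  S2 <- matrix(c(1, 2, 2, 4), 2, 2)
  tr2 <- nessflow:::new_trajectory(c(0, 1), S2, 1, "stochastic")
  expect_error(gaussian_from_samples(tr2), "samples")

  # off-diagonal precision at the structural zeros shrinks with T
  lp <- make_fixture("lorenz-laplace")$params
  ens <- simulate_ensemble(lp, 1, x0 = gaussian_from_potential(lp)$mean,
                           dt = 1 / 64, T = 400, seed = 2)
  gshort <- gaussian_from_samples(ens[[1]], burn_in = 10)
  norm13 <- abs(gshort$H[1, 3]) / sqrt(gshort$H[1, 1] * gshort$H[3, 3])
  expect_lt(norm13, 0.1)
})

test_that("conditional Gaussians follow the Schur complement", {
  H <- matrix(c(2, 1, 1, 2), 2, 2)
  ness <- nessflow:::new_gaussian_ness(H)
  for (v in c(-1, 0.5, 2)) {
    cond <- conditional_gaussian(ness, given = 2L, values = v)
    expect_equal(cond$mean, -v / 2)
    expect_equal(drop(cond$Sigma), 1 / 2)
  }
  # empty conditioning set returns the marginal
  m <- conditional_gaussian(ness, integer(0), numeric(0))
  expect_equal(m$mean, ness$mean)
  expect_equal(m$Sigma, ness$Sigma)
  # improper retained block errors
  Hbad <- diag(c(1, -1))
  nb <- nessflow:::new_gaussian_ness(Hbad)
  expect_error(conditional_gaussian(nb, 1L, 0), "positive definite")
})

test_that("precision zeros encode conditional independence", {
  lp <- make_fixture("lorenz-laplace")$params
  ness <- gaussian_from_potential(lp)
  expect_true(is_conditionally_independent(ness, 1, 3))
  expect_true(is_conditionally_independent(ness, 2, 3))
  expect_false(is_conditionally_independent(ness, 1, 2))

  nd <- nessflow:::new_gaussian_ness(diag(c(1, 2, 3)))
  for (u in 1:2) for (v in (u + 1):3)
    expect_true(is_conditionally_independent(nd, u, v))

  # brute force agreement: zero H entry <=> zero conditional covariance
  cp <- make_fixture("coupled-laplace")$params
  nc <- gaussian_from_potential(cp)
  for (u in 1:5) for (v in (u + 1):6) {
    others <- setdiff(1:6, c(u, v))
    cond <- conditional_gaussian(nc, others, nc$mean[others])
    r <- cond$Sigma[1, 2] / sqrt(cond$Sigma[1, 1] * cond$Sigma[2, 2])
    expect_equal(is_conditionally_independent(nc, u, v), abs(r) < 1e-6)
  }

  # homologous internal/external states are conditionally independent in
  # the fitted coupled system (for this grid-sampled fit the potential
  # nearly factorises over the two subsystems, so their marginal
  # correlation is weak as well)
  expect_true(is_conditionally_independent(nc, 2, 5))
})

test_that("Markov boundaries and particular partitions are recovered", {
  lp <- make_fixture("lorenz-laplace")$params
  ness <- gaussian_from_potential(lp)
  expect_length(markov_boundary(ness, 3L), 0)
  expect_setequal(markov_boundary(ness, 1L), 2L)

  cp <- make_fixture("coupled-laplace")$params
  nc <- gaussian_from_potential(cp)
  expect_setequal(markov_boundary(nc, c(5L, 6L)), 4L)

  nd <- nessflow:::new_gaussian_ness(matrix(1, 4, 4) + diag(4))
  expect_setequal(markov_boundary(nd, 2L), c(1L, 3L, 4L))

  part <- particular_partition(nc, c(5L, 6L))
  expect_equal(part$a, 4L)
  expect_equal(part$s, 1L)
  expect_setequal(part$eta, c(2L, 3L))
  expect_setequal(part$b, c(1L, 4L))
  expect_setequal(part$pi, c(1L, 4L, 5L, 6L))
  # Eq-style zero blocks hold by construction (would error otherwise)
  d <- sqrt(diag(nc$H))
  expect_lt(max(abs(nc$H[part$mu, part$eta])) /
              min(outer(d[part$mu], d[part$eta])), 1e-5)

  # the third Lorenz state has no blanket: no partition of interest
  p3 <- particular_partition(ness, 3L)
  expect_length(p3$a, 0)
  expect_length(p3$s, 0)
  expect_setequal(p3$eta, c(1L, 2L))

  ndiag <- nessflow:::new_gaussian_ness(diag(3))
  pd <- particular_partition(ndiag, 1L)
  expect_length(pd$a, 0)
  expect_length(pd$s, 0)
})

test_that("sparse-coupling audit classifies pairs sensibly", {
  cp <- make_fixture("coupled-laplace")$params
  audit <- sparse_coupling_audit(cp)
  # every mutually uncoupled pair (zero Jacobian both ways) has zero H entry
  mutual <- audit[audit$J_zero & audit$J_zero_reverse, ]
  expect_true(all(mutual$H_zero))
  expect_true(all(mutual$class %in% c("conjecture-consistent", "edge-case")))

  # Lorenz Laplace: states 2 and 3 reciprocally coupled yet H23 = 0
  lp <- make_fixture("lorenz-laplace")$params
  a3 <- sparse_coupling_audit(lp)
  row23 <- a3[a3$u == 2 & a3$v == 3, ]
  expect_equal(row23$class, "coupled")
  expect_true(row23$independent_without_sparse_coupling)

  # linear gradient system f = -Hx (Q = 0): zero-J pairs are zero-H pairs
  b <- monomial_basis(3, 2)
  h <- numeric(10); h[c(3, 6, 10)] <- c(1, 2, 3); h[5] <- 0.5
  gr <- helmholtz_params(b, h, list(), c(1, 1, 1))
  ag <- sparse_coupling_audit(gr)
  expect_true(all(ag$H_zero[ag$J_zero & ag$J_zero_reverse]))
})

test_that("expected Jacobian eigenvalues and the Kaplan-Yorke formula", {
  # constant-J linear system: expectation equals the pointwise eigenvalues
  fx <- make_fixture("ou-linear")
  lam <- expected_jacobian_eigenvalues(fx$params, grid_points = 8)
  lam_ref <- sort(Re(eigen(fx$reference$J, only.values = TRUE)$values),
                  decreasing = TRUE)
  expect_equal(lam, lam_ref, tolerance = 1e-8)

  # grid refinement changes the estimate only slightly
  lp <- make_fixture("lorenz-laplace")$params
  l16 <- expected_jacobian_eigenvalues(lp, grid_points = 16)
  l32 <- expected_jacobian_eigenvalues(lp, grid_points = 32)
  expect_lt(max(abs(l16 - l32)), 0.005)

  # improper density refused
  expect_error(expected_jacobian_eigenvalues(make_fixture("lorenz-exact")$params),
               "improper")

  # Kaplan-Yorke arithmetic
  expect_equal(kaplan_yorke_dimension(c(0.0766, 0.0056, -0.1713)),
               2 + 0.0822 / 0.1713, tolerance = 1e-10)
  expect_equal(kaplan_yorke_dimension(c(-0.1, -0.5)), 0)
  expect_equal(kaplan_yorke_dimension(c(1, -2)), 1.5)
  expect_equal(kaplan_yorke_dimension(c(2, 1, -0.5)), 3)  # all sums >= 0
  expect_error(kaplan_yorke_dimension(c(-1, 2)), "sorted")
  # range property on random spectra
  for (k in 1:20) {
    lamr <- sort(withr::with_seed(k, stats::rnorm(4)), decreasing = TRUE)
    d <- kaplan_yorke_dimension(lamr)
    expect_gte(d, 0); expect_lte(d, 4)
  }
})

test_that("analytic Lorenz dimension follows the closed form", {
  expect_equal(round(lorenz_analytic_dimension(10, 32, 8 / 3), 2), 2.43)
  expect_equal(round(lorenz_analytic_dimension(10, 28, 8 / 3), 3), 2.401)
  # monotonically decreasing in beta
  ds <- vapply(c(1, 2, 4, 8), function(b) lorenz_analytic_dimension(10, 32, b),
               numeric(1))
  expect_true(all(diff(ds) < 0))
})

test_that("empirical partial correlations detect independence", {
  # independent white noise: all off-diagonals near zero
  trs <- lapply(1:4, function(s) {
    S <- withr::with_seed(s, matrix(stats::rnorm(2000 * 3), 2000, 3))
    nessflow:::new_trajectory(seq(0, by = 0.1, length.out = 2000), S, 0.1,
                              "stochastic")
  })
  pc <- empirical_partial_correlation(trs)
  P <- pc$partial[[1]]
  off <- P[upper.tri(P)]
  expect_true(all(abs(off) < 3 / sqrt(2000 * 4) * 3))
  # window handling
  pc2 <- empirical_partial_correlation(trs, window_lengths = c(100, 199))
  expect_length(pc2$partial, 2)
  expect_error(empirical_partial_correlation(trs, window_lengths = 1e6),
               "exceeds")
})
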