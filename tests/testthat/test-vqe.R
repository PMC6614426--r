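test_that("analytic gradients match central finite differences", {
  sys <- toy_system(3, seed = 41)
  set.seed(41)
  for (case in 1:12) {
    n <- sample(2:5, 1)
    k <- sample(pool_size(sys$pool), n)
    th <- rnorm(n, sd = 0.4)
    mats <- sys$pool_mats[k]
    an <- energy_and_analytic_gradient(mats, th, sys$H, sys$reference)
    fd <- vapply(seq_len(n), function(j) {
      e <- function(t) {
        t2 <- th; t2[j] <- t
        expectation(sys$H, prepare_state(mats, t2, sys$reference))
      }
      (e(th[j] + 1e-5) - e(th[j] - 1e-5)) / 2e-5
    }, numeric(1))
    expect_lt(max(abs(an$gradient - fd)), 1e-6)
    expect_equal(an$energy,
                 expectation(sys$H, prepare_state(mats, th, sys$reference)),
                 tolerance = 1e-12)
  }
})

test_that("gradients coincide with pool gradients where definitions overlap", {
  sys <- toy_system(3, seed = 43)
  mats <- sys$pool_mats[c(4, 16)]
  # all-zero parameters: ansatz gradient entries = pool gradient at reference
  an <- energy_and_analytic_gradient(mats, c(0, 0), sys$H, sys$reference)
  g0 <- pool_gradient(sys$H, sys$reference, mats)
  expect_equal(an$gradient, g0, tolerance = 1e-10)
  # one-element ansatz: the gradient is the commutator expectation at the
  # rotated state (last-applied operator derivative)
  th <- 0.37
  an1 <- energy_and_analytic_gradient(mats[1], th, sys$H, sys$reference)
  rot <- apply_exp(mats[[1]], th, sys$reference)
  g1 <- pool_gradient(sys$H, rot, mats[1])
  expect_equal(an1$gradient, g1, tolerance = 1e-10)
})

test_that("a single Givens rotation solves its 2x2 eigenproblem exactly", {
  sys <- h2_system("gsd")
  labels <- vapply(sys$pool$operators, `[[`, character(1), "label")
  k <- which(labels == "tau_{1 1b}^{2 2b}")
  A <- sys$pool_mats[[k]]
  # the generator couples the reference only to the doubly excited
  # determinant: restrict H to that 2-dimensional invariant subspace
  iref <- which(sys$reference == 1)
  idet <- which(as.vector(A %*% sys$reference) != 0)
  h2x2 <- as.matrix(sys$H[c(iref, idet), c(iref, idet)])
  e_exact <- min(eigen(h2x2, symmetric = TRUE)$values)
  res <- minimize_vqe(sys$H, list(A), 0, sys$reference)
  expect_equal(res$energy, e_exact, tolerance = 1e-8)
  # the optimal angle satisfies the closed-form arctan stationarity
  # condition tan(2 theta') = 2c / (a - b) of the 2x2 rotation
  a <- h2x2[1, 1]; b <- h2x2[2, 2]; c0 <- h2x2[1, 2]
  s <- A[idet, iref]
  expect_equal(tan(2 * s * res$parameters), 2 * c0 / (a - b), tolerance = 1e-6)
})

test_that("optimization is monotone under warm starts and idempotent at optima", {
  sys <- toy_system(3, seed = 47)
  k <- c(3, 12, 25)
  r1 <- minimize_vqe(sys$H, sys$pool_mats[k[1:2]], c(0, 0), sys$reference)
  # warm start with an appended zero parameter can never raise the energy
  r2 <- minimize_vqe(sys$H, sys$pool_mats[k], c(r1$parameters, 0), sys$reference)
  expect_lte(r2$energy, r1$energy + 1e-10)
  # restart at the optimum returns the same energy
  r3 <- minimize_vqe(sys$H, sys$pool_mats[k], r2$parameters, sys$reference)
  expect_equal(r3$energy, r2$energy, tolerance = 1e-9)
  expect_true(r3$converged)
  expect_error(minimize_vqe(sys$H, sys$pool_mats[k], c(0, NA, 0), sys$reference),
               "non-finite")
})

test_that("energy-plus-gradient costs at most 3x the energy-only sweep", {
  sys <- toy_system(3, seed = 53)
  k <- sample(pool_size(sys$pool), 6)
  th <- rnorm(6, sd = 0.3)
  mats <- sys$pool_mats[k]
  reset_exp_count()
  invisible(expectation(sys$H, prepare_state(mats, th, sys$reference)))
  n_energy <- exp_count()
  reset_exp_count()
  invisible(energy_and_analytic_gradient(mats, th, sys$H, sys$reference))
  n_both <- exp_count()
  expect_lte(n_both, 3 * n_energy + 2)
  expect_identical(n_energy, 6L)
})
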