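test_that("reference determinants occupy the requested bits", {
  v <- reference_state(4L, c(0L, 1L))
  expect_equal(which(v == 1), 4L)   # basis index 3, 1-based position 4
  expect_equal(sum(abs(v)), 1)
  expect_error(reference_state(4L, c(1L, 1L)), "duplicate")
  occ <- occupation_expectations(v, 0:15, 2L)
  expect_equal(occ$n_alpha + occ$n_beta, 2)
})

test_that("a single-excitation exponential is a Givens rotation", {
  # 2 qubits, 1 electron: generator a+_1 a_0 - a+_0 a_1 rotates |01> -> |10>
  tau <- fermion_add(fermion_term(c(1L, 0L), c(TRUE, FALSE)),
                     fermion_scale(fermion_term(c(0L, 1L), c(TRUE, FALSE)), -1))
  A <- to_matrix(jordan_wigner(tau, 2L))
  v0 <- reference_state(2L, 0L)
  for (theta in c(0.3, -1.2)) {
    v <- apply_exp(A, theta, v0)
    expect_equal(v[2], cos(theta), tolerance = 1e-12)
    expect_equal(abs(v[3]), abs(sin(theta)), tolerance = 1e-12)
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-12)
  }
  expect_identical(apply_exp(A, 0, v0), v0)
  # inverse rotation restores the state
  w <- apply_exp(A, -0.7, apply_exp(A, 0.7, v0))
  expect_lt(max(abs(w - v0)), 1e-12)
})

test_that("prepare_state composes oldest-first and preserves the sector", {
  sys <- toy_system(3, seed = 3)
  mats <- sys$pool_mats[c(2, 9, 17)]
  th <- c(0.4, -0.2, 0.15)
  expect_identical(prepare_state(list(), numeric(0), sys$reference), sys$reference)
  expect_equal(prepare_state(mats, c(0, 0, 0), sys$reference), sys$reference)
  one <- prepare_state(mats[1], th[1], sys$reference)
  expect_equal(one, apply_exp(mats[[1]], th[1], sys$reference))
  full <- prepare_state(mats, th, sys$reference)
  expect_equal(sqrt(sum(full^2)), 1, tolerance = 1e-10)
  occ <- occupation_expectations(full, sys$basis, sys$integrals$n_spatial)
  expect_equal(occ$n_alpha, sys$integrals$n_alpha, tolerance = 1e-10)
  expect_equal(occ$n_beta, sys$integrals$n_beta, tolerance = 1e-10)
  expect_error(prepare_state(mats, th[1:2], sys$reference), "length")
})

test_that("expectation values agree between matrix and per-term Pauli paths", {
  ints <- toy_integrals("random_twobody", 2, seed = 8)
  sys <- compile_system(ints, pool = "gsd", sector = FALSE)
  set.seed(2)
  v <- rnorm(length(sys$reference)); v <- v / sqrt(sum(v^2))
  e_mat <- expectation(sys$H, v)
  e_pauli <- expectation(sys$hamiltonian_q, v)
  expect_equal(e_mat, e_pauli, tolerance = 1e-12)
  expect_equal(expectation(Matrix::Diagonal(length(v)), v), 1, tolerance = 1e-12)
  # the ground eigenvector's expectation is the lowest eigenvalue
  sec <- compile_system(ints, pool = "none")
  f2 <- fci_ground(sec)
  expect_equal(expectation(sec$H, f2$vector), f2$energy, tolerance = 1e-10)
})

test_that("pool gradients equal finite differences of the appended parameter", {
  sys <- toy_system(3, seed = 19)
  th <- c(0.25, -0.4)
  mats <- sys$pool_mats[c(5, 11)]
  state <- prepare_state(mats, th, sys$reference)
  g <- pool_gradient(sys$H, state, sys$pool_mats)
  set.seed(19)
  for (k in sample(pool_size(sys$pool), 4)) {
    efun <- function(t) expectation(
      sys$H, apply_exp(sys$pool_mats[[k]], t, state))
    fd <- (efun(1e-5) - efun(-1e-5)) / 2e-5
    expect_equal(g[k], fd, tolerance = 1e-6)
  }
})

test_that("single-excitation gradients vanish at the canonical HF point", {
  sys <- h2_system("gsd")
  g <- pool_gradient(sys$H, sys$reference, sys$pool_mats)
  ranks <- vapply(sys$pool$operators, `[[`, character(1), "rank")
  occ_vir_single <- vapply(sys$pool$operators, function(o)
    o$rank == "single", logical(1))
  expect_lt(max(abs(g[occ_vir_single])), 1e-8)   # Brillouin condition
})

test_that("all pool gradients vanish in an exact eigenstate", {
  sys <- toy_system(3, seed = 23)
  fci <- fci_ground(sys)
  g <- pool_gradient(sys$H, fci$vector, sys$pool_mats)
  expect_lt(max(abs(g)), 1e-9)
})

test_that("prepared energies respect the variational bound", {
  sys <- toy_system(3, seed = 29)
  fci <- fci_ground(sys)
  set.seed(4)
  for (i in 1:10) {
    k <- sample(pool_size(sys$pool), 3)
    th <- rnorm(3, sd = 0.5)
    v <- prepare_state(sys$pool_mats[k], th, sys$reference)
    expect_gte(expectation(sys$H, v), fci$energy - 1e-10)
    expect_equal(sqrt(sum(v^2)), 1, tolerance = 1e-10)
  }
})
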