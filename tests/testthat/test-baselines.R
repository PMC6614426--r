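test_that("UCCSD is exact for two electrons and bounded by FCI elsewhere", {
  sys <- h2_system("none")
  fci <- fci_ground(sys)
  u <- uccsd_energy(sys)
  expect_equal(u$energy, fci$energy, tolerance = 1e-9)
  expect_identical(u$n_parameters, 3L)
  toy <- toy_system(3, seed = 83, pool = "none")
  ut <- uccsd_energy(toy)
  expect_gte(ut$energy, fci_ground(toy)$energy - 1e-9)
  expect_lte(ut$energy, toy$e_hf + 1e-12)
})

test_that("the quadrature gradient of the summed exponential matches finite differences", {
  sys <- toy_system(3, seed = 89, pool = "none")
  groups <- uccsd_parameter_groups(3, sys$integrals$n_alpha)
  gens <- lapply(groups, function(g)
    Reduce(fermion_add, lapply(g, function(m)
      fermion_scale(adaptvqe:::.exc_tau(m), m$sign))))
  mats <- lapply(gens, function(fs)
    to_matrix(jordan_wigner(fs, sys$n_qubits), sector = sys$basis))
  efun <- function(par) {
    Tm <- Reduce(`+`, Map(`*`, mats, par))
    expectation(sys$H, apply_exp(Tm, 1, sys$reference))
  }
  set.seed(89)
  th <- rnorm(length(mats), sd = 0.1)
  Tm <- Reduce(`+`, Map(`*`, mats, th))
  phi <- apply_exp(Tm, 1, sys$reference)
  hphi <- as.vector(sys$H %*% phi)
  gl <- adaptvqe:::.gauss_legendre01(16)
  g <- numeric(length(mats))
  for (q in seq_along(gl$nodes)) {
    lv <- apply_exp(Tm, -gl$nodes[q], hphi)
    rv <- apply_exp(Tm, 1 - gl$nodes[q], sys$reference)
    g <- g + gl$weights[q] * 2 *
      vapply(mats, function(A) sum(lv * as.vector(A %*% rv)), numeric(1))
  }
  fd <- vapply(seq_along(th), function(k) {
    t2 <- th; t2[k] <- th[k] + 1e-5; ep <- efun(t2)
    t2[k] <- th[k] - 1e-5; em <- efun(t2)
    (ep - em) / 2e-5
  }, numeric(1))
  expect_lt(max(abs(g - fd)), 1e-7)
})

test_that("a single-replica Trotter factorization recovers UCCSD on H2", {
  sys <- h2_system("none")
  pool <- build_sd_pool(2, 1)
  u <- uccsd_energy(sys)
  t1 <- trotter_ucc_energy(sys, pool, n_trotter = 1)
  expect_lt(abs(t1$energy - u$energy), 1e-6)
  # zero parameters reproduce the reference energy
  mats <- adaptvqe:::pool_matrices(pool, sys$n_qubits, sys$basis)
  e0 <- expectation(sys$H, prepare_state(mats, numeric(length(mats)), sys$reference))
  expect_equal(e0, sys$e_hf, tolerance = 1e-12)
})

test_that("independent replicas never raise the optimized energy", {
  sys <- toy_system(3, seed = 97, pool = "none")
  pool <- build_sd_pool(3, sys$integrals$n_alpha)
  e1 <- trotter_ucc_energy(sys, pool, n_trotter = 1)$energy
  e2 <- trotter_ucc_energy(sys, pool, n_trotter = 2)$energy
  expect_lte(e2, e1 + 1e-8)
  et <- trotter_ucc_energy(sys, pool, n_trotter = 2, replicas = "tied")$energy
  expect_gte(et, e2 - 1e-8)   # tied replicas are a subset of independent ones
})

test_that("fixed-order growth controls behave as specified", {
  ints <- toy_integrals("random_twobody", 4, seed = 101, n_alpha = 2)
  sys <- compile_system(ints, pool = "gsd")
  # lexical generalized order starts with an occupied-occupied move that
  # annihilates the HF determinant: the energy stays at E_HF until an
  # operator with support outside the occupied block arrives
  lex <- grow_fixed_order(sys, order = "lexical", n_steps = 2)
  expect_equal(lex$energy[1], sys$e_hf, tolerance = 1e-10)
  expect_lte(lex$energy[2], lex$energy[1] + 1e-10)
  # the first lexical operator moves within the occupied block
  first <- sys$pool$operators[[lex$pool_index[1]]]
  expect_true(all(c(first$occ %/% 2L, first$vir %/% 2L) < ints$n_alpha))
  # random orders are reproducible under a fixed seed
  r1 <- grow_fixed_order(sys, order = "random", seed = 5, n_steps = 4)
  r2 <- grow_fixed_order(sys, order = "random", seed = 5, n_steps = 4)
  expect_identical(r1, r2)
  r3 <- grow_fixed_order(sys, order = "random", seed = 6, n_steps = 4)
  expect_false(identical(r1$pool_index, r3$pool_index))
  # energies are non-increasing as operators are appended
  expect_true(all(diff(r1$energy) <= 1e-9))
})

test_that("adaptive selection dominates fixed-order growth at equal size", {
  ints <- toy_integrals("random_twobody", 4, seed = 103, n_alpha = 2)
  sys <- compile_system(ints, pool = "gsd")
  ad <- run_adapt(sys, adapt_config(epsilon = 1e-6, max_iterations = 6))
  n <- nrow(ad$ansatz)
  lex <- grow_fixed_order(sys, order = "lexical", n_steps = n)
  rnd <- grow_fixed_order(sys, order = "random", seed = 11, n_steps = n)
  expect_lte(ad$energies[n + 1], lex$energy[n] + 1e-9)
  expect_lte(ad$energies[n + 1], rnd$energy[n] + 1e-9)
})

test_that("gradient screening beats every control protocol on stretched BeH2", {
  ints <- read_fcidump(fixture_fcidump("beh2", 2.39))
  sys <- compile_system(ints, pool = "gsd")
  n <- 6L
  ad <- run_adapt(sys, adapt_config(epsilon = 1e-9, max_iterations = n))
  sd_pool <- build_sd_pool(ints$n_spatial, ints$n_alpha)
  curves <- list(
    lex_pqrs = grow_fixed_order(sys, order = "lexical", n_steps = n),
    lex_ijab = grow_fixed_order(sys, sd_pool, order = "lexical", n_steps = n),
    rnd_ijab_1 = grow_fixed_order(sys, sd_pool, order = "random", seed = 1,
                                  n_steps = n),
    rnd_pqrs_1 = grow_fixed_order(sys, order = "random", seed = 1,
                                  n_steps = n))
  for (cv in curves)
    expect_true(all(ad$energies[-1] <= cv$energy + 1e-9))
  # the generalized lexical order starts inside the occupied block and
  # stays at E_HF, while gradient screening recovers correlation at once
  expect_equal(curves$lex_pqrs$energy[1], sys$e_hf, tolerance = 1e-9)
  expect_lt(ad$energies[n + 1], sys$e_hf - 1e-3)
})
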