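test_that("number and hopping operators map to their textbook Pauli forms", {
  num <- jordan_wigner(fermion_term(c(0L, 0L), c(TRUE, FALSE)), 1L)
  expect_setequal(format_qubit_sum(num), c("0.5 I", "-0.5 Z0"))
  hop <- jordan_wigner(fermion_add(fermion_term(c(0L, 1L), c(TRUE, FALSE)),
                                   fermion_term(c(1L, 0L), c(TRUE, FALSE))), 2L)
  expect_setequal(format_qubit_sum(hop), c("0.5 X0 X1", "0.5 Y0 Y1"))
  M <- as.matrix(to_matrix(hop))
  expect_equal(M, oracle_fermion_matrix(
    fermion_add(fermion_term(c(0L, 1L), c(TRUE, FALSE)),
                fermion_term(c(1L, 0L), c(TRUE, FALSE))), 2), tolerance = 1e-13)
})

test_that("mapped matrices equal the brute-force ladder-matrix oracle", {
  for (seed in 1:8) {
    n <- 3 + seed %% 2
    fs <- oracle_random_fermion(n, n_terms = 5, seed = seed)
    M <- to_matrix(jordan_wigner(fs, n))
    M <- if (is(M, "sparseMatrix")) as.matrix(M) else Re(M)
    expect_lt(max(abs(M - oracle_fermion_matrix(fs, n))), 1e-11)
  }
})

test_that("the mapping is linear and preserves anticommutation", {
  n <- 4L
  A <- oracle_random_fermion(n, 3, seed = 21)
  B <- oracle_random_fermion(n, 3, seed = 22)
  lin <- jordan_wigner(fermion_add(fermion_scale(A, 0.3), fermion_scale(B, -1.7)), n)
  MA <- to_matrix(jordan_wigner(A, n)); MB <- to_matrix(jordan_wigner(B, n))
  expect_lt(max(abs(to_matrix(lin) - (0.3 * MA - 1.7 * MB))), 1e-12)
  # {a_i, a+_j} = delta_ij I
  for (i in 0:(n - 1)) for (j in 0:(n - 1)) {
    ai <- to_matrix(jordan_wigner(fermion_term(i, FALSE), n))
    adj <- to_matrix(jordan_wigner(fermion_term(j, TRUE), n))
    anti <- as.matrix(ai %*% adj + adj %*% ai)
    target <- if (i == j) diag(2^n) else matrix(0, 2^n, 2^n)
    expect_lt(max(Mod(anti - target)), 1e-12)
  }
})

test_that("simplify merges like strings and prunes small coefficients", {
  op <- qubit_sum(2L, x = c(1L, 1L, 0L), z = c(0L, 0L, 3L),
                  coef = c(1, 1, 1e-16), combine = FALSE)
  s <- simplify(op, tol = 1e-14)
  expect_equal(n_terms(s), 1L)
  expect_equal(format_qubit_sum(s), "2 X0")
  r <- qubit_sum(3L, x = c(5L, 2L), z = c(1L, 2L), coef = c(0.3, -2i))
  expect_lt(max(Mod(as.matrix(to_matrix(simplify(r, 0))) -
                    as.matrix(to_matrix(r)))), 1e-13)
})

test_that("matrix realization follows the bit-0-least-significant convention", {
  z0 <- qubit_sum(2L, x = 0L, z = 1L, coef = 1 + 0i)
  expect_equal(as.numeric(Matrix::diag(to_matrix(z0))), c(1, -1, 1, -1))
  fs <- oracle_random_fermion(3, 4, seed = 3)
  herm <- jordan_wigner(fermion_add(fs, fermion_dagger(fs)), 3L)
  M <- to_matrix(herm)
  M <- if (is(M, "sparseMatrix")) as.matrix(M) else M
  expect_lt(max(Mod(M - Conj(t(M)))), 1e-12)
})

test_that("plain-text serialization round-trips", {
  op <- jordan_wigner(oracle_random_fermion(4, 5, seed = 9), 4L)
  lines <- format_qubit_sum(op)
  back <- parse_qubit_sum(lines, 4L)
  expect_lt(max(Mod(as.matrix(to_matrix(back)) - as.matrix(to_matrix(op)))), 1e-11)
  expect_error(parse_qubit_sum("1.0 Q3", 4L), "unknown Pauli letter")
})

test_that("mapped Hamiltonians keep their symmetries as matrices", {
  sys <- toy_system(3, seed = 13, pool = "none")
  n_q <- sys$n_qubits
  H <- to_matrix(sys$hamiltonian_q)
  N <- to_matrix(jordan_wigner(number_operator(n_q), n_q))
  Sz <- to_matrix(jordan_wigner(sz_operator(n_q), n_q))
  expect_lt(max(abs(H %*% N - N %*% H)), 1e-10)
  expect_lt(max(abs(H %*% Sz - Sz %*% H)), 1e-10)
  expect_lt(max(abs(H - Matrix::t(H))), 1e-10)
})

test_that("the unimplemented tree-parity mapping is a guarded stub", {
  fs <- fermion_term(c(0L, 0L), c(TRUE, FALSE))
  expect_error(map_to_qubits(fs, 2L, mapping = "bravyi_kitaev"), "stub")
  expect_equal(n_terms(map_to_qubits(fs, 2L)), 2L)
})
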