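test_that("spin complement pairs excitations with their global spin flip", {
  # alpha single 1->3 (spatial, 1-based) pairs with its beta copy
  cmp <- spin_complement(occ = 0L, vir = 4L)
  expect_length(cmp, 2L)
  expect_identical(cmp[[2]]$occ, 1L)
  expect_identical(cmp[[2]]$vir, 5L)
  expect_equal(cmp[[2]]$sign, 1)
  # paired double 2a 2b -> 3a 3b is its own complement: returned once
  self <- spin_complement(occ = c(2L, 3L), vir = c(4L, 5L))
  expect_length(self, 1L)
  # complement of the complement is the original (involution)
  f <- cmp[[2]]
  back <- spin_complement(f$occ, f$vir)
  expect_identical(back[[2]]$occ, 0L)
  expect_identical(back[[2]]$vir, 4L)
  expect_error(spin_complement(occ = 0L, vir = 5L), "S_z")
})

test_that("the flipped member of a correlated single carries a -1 sign", {
  # occ = (2a, 2b) same-spatial pair, vir = (3a, 6b): flip inverts the
  # occupied pair's order, so the complement enters with sign -1
  cmp <- spin_complement(occ = c(2L, 3L), vir = c(4L, 11L))
  expect_length(cmp, 2L)
  expect_equal(cmp[[2]]$sign, -1)
  # both pairs same-spatial: two inversions cancel
  expect_equal(adaptvqe:::.exc_flip_sign(adaptvqe:::.exc(c(2L, 3L), c(10L, 11L))), 1)
  # no same-spatial pair: no inversion
  expect_equal(adaptvqe:::.exc_flip_sign(adaptvqe:::.exc(c(0L, 2L), c(4L, 6L))), 1)
})

test_that("amplitude counts for the LiH shape match the published accounting", {
  counts <- uccsd_parameter_count(6, 2)
  expect_identical(counts$raw, 92L)
  expect_identical(counts$grouped, 64L)
  sd <- build_sd_pool(6, 2)
  expect_identical(sd$raw_amplitudes, 92L)
  # full orbit merge (the pool grouping) gives fewer generators than the
  # published per-spin parameter accounting; verified against an
  # independent enumeration
  oc <- oracle_orbit_count(6, 2)
  expect_identical(oc$raw, 92L)
  expect_identical(pool_size(sd), oc$orbits)
})

test_that("spin-orbital amplitude counts match brute force on other shapes", {
  for (shape in list(c(4, 2), c(3, 1), c(5, 2))) {
    oc <- oracle_orbit_count(shape[1], shape[2])
    sd <- build_sd_pool(shape[1], shape[2])
    expect_identical(sd$raw_amplitudes, oc$raw)
    expect_identical(pool_size(sd), oc$orbits)
  }
  # minimal shape: one occupied, one virtual spatial orbital
  tiny <- build_sd_pool(2, 1)
  ranks <- vapply(tiny$operators, `[[`, character(1), "rank")
  expect_identical(sum(ranks == "single"), 1L)
  expect_identical(sum(ranks == "double"), 1L)
})

test_that("every generator is anti-Hermitian and conserves N and S_z", {
  n_spatial <- 3L
  n_q <- 2L * n_spatial
  N <- to_matrix(jordan_wigner(number_operator(n_q), n_q))
  Sz <- to_matrix(jordan_wigner(sz_operator(n_q), n_q))
  for (pool in list(build_sd_pool(3, 1), build_gsd_pool(3))) {
    for (op in pool$operators) {
      A <- to_matrix(jordan_wigner(op$generator, n_q))
      expect_true(check_anti_hermitian(A))
      expect_lt(max(abs(A %*% N - N %*% A)), 1e-12)
      expect_lt(max(abs(A %*% Sz - Sz %*% A)), 1e-12)
    }
  }
})

test_that("the generalized pool strictly contains the restricted pool", {
  sd <- build_sd_pool(4, 2)
  gsd <- build_gsd_pool(4)
  sd_keys <- vapply(sd$operators, `[[`, character(1), "key")
  gsd_keys <- vapply(gsd$operators, `[[`, character(1), "key")
  expect_true(all(sd_keys %in% gsd_keys))
  expect_gt(pool_size(gsd), pool_size(sd))
  # it includes the correlated-single generator selected for LiH (2 2b -> 3 6b)
  lih_gsd <- build_gsd_pool(6)
  labels <- vapply(lih_gsd$operators, `[[`, character(1), "label")
  expect_true("tau_{2 2b}^{3 6b}" %in% labels)
  # no duplicated generators after canonicalization
  expect_false(anyDuplicated(gsd_keys) > 0)
})

test_that("lexical order is deterministic with singles first", {
  pool <- build_gsd_pool(3)
  o1 <- lexical_order(pool)
  o2 <- lexical_order(pool)
  expect_identical(o1, o2)
  ranks <- vapply(pool$operators, `[[`, character(1), "rank")[o1]
  expect_true(all(diff(ranks == "single") <= 0))  # singles precede doubles
})

test_that("enumeration multiplicity marks same-spatial-pair doubles", {
  pool <- build_gsd_pool(3)
  for (op in pool$operators) {
    pp <- function(v) length(v) == 2 && bitwXor(v[1], 1L) == v[2]
    expect_identical(op$multiplicity,
                     if (pp(op$occ) || pp(op$vir)) 2L else 1L)
  }
})
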