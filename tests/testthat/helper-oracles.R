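# Independent brute-force oracles, deliberately built by a different route
# than the package (explicit Kronecker-product ladder matrices instead of the
# symplectic Pauli algebra).

# dense ladder matrix a_p^(dagger) on n qubits, qubit 0 least significant
oracle_ladder <- function(p, n, dagger = FALSE) {
  Zm <- matrix(c(1, 0, 0, -1), 2, 2)
  Am <- matrix(c(0, 1, 0, 0), 2, 2)        # |1><0| with basis (|0>, |1>)
  if (!dagger) Am <- t(Am)
  I2 <- diag(2)
  M <- matrix(1, 1, 1)
  for (q in 0:(n - 1)) {
    blk <- if (q < p) Zm else if (q == p) Am else I2
    M <- kronecker(blk, M)                  # higher qubits more significant
  }
  M
}

# dense matrix of a fermion_sum via explicit ladder products
oracle_fermion_matrix <- function(fs, n) {
  d <- 2^n
  M <- matrix(0, d, d)
  for (t in fs$terms) {
    P <- diag(d)
    for (k in seq_along(t$idx))
      P <- P %*% oracle_ladder(t$idx[k], n, t$dag[k])
    M <- M + Re(t$coef) * P
  }
  M
}

# random small fermionic operator sum (indices < n)
oracle_random_fermion <- function(n, n_terms = 4, seed = 1) {
  set.seed(seed)
  terms <- lapply(seq_len(n_terms), function(i) {
    k <- sample(1:2, 1) * 2L              # products of length 2 or 4
    list(idx = sample(0:(n - 1), k, replace = TRUE),
         dag = sample(c(TRUE, FALSE), k, replace = TRUE),
         coef = rnorm(1))
  })
  fermion_sum(terms, prune = 0)
}

# independent spin-flip orbit counter over raw HF-restricted amplitudes
# (text-key based, no shared code with the pool module internals)
oracle_orbit_count <- function(n_spatial, n_occ) {
  so_all <- 0:(2 * n_spatial - 1)
  occ <- so_all[(so_all %/% 2) < n_occ]
  vir <- setdiff(so_all, occ)
  spin <- function(i) i %% 2
  keys <- character(0)
  add <- function(o, v) keys <<- c(keys, paste(paste(sort(o), collapse = ","),
                                               paste(sort(v), collapse = ","),
                                               sep = "|"))
  for (i in occ) for (a in vir) if (spin(i) == spin(a)) add(i, a)
  oc <- combn(occ, 2, simplify = FALSE)
  vc <- combn(vir, 2, simplify = FALSE)
  szf <- function(x) sum(1 - 2 * spin(x))
  for (o in oc) for (v in vc) if (szf(o) == szf(v)) add(o, v)
  flip_key <- function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    f <- function(s) paste(sort(bitwXor(as.integer(strsplit(s, ",")[[1]]), 1L)),
                           collapse = ",")
    paste(f(parts[1]), f(parts[2]), sep = "|")
  }
  seen <- character(0); orbits <- 0L
  for (k in keys) {
    if (k %in% seen) next
    seen <- c(seen, k, flip_key(k))
    orbits <- orbits + 1L
  }
  list(raw = length(keys), orbits = orbits)
}

# small precompiled systems shared across tests (cached per session)
.test_cache <- new.env(parent = emptyenv())

h2_system <- function(pool = "gsd") {
  key <- paste0("h2_", pool)
  if (is.null(.test_cache[[key]])) {
    ints <- read_fcidump(fixture_fcidump("h2", 0.7414))
    .test_cache[[key]] <- compile_system(ints, pool = pool)
  }
  .test_cache[[key]]
}

toy_system <- function(n = 3, seed = 11, pool = "gsd", kind = "random_twobody",
                       n_alpha = NULL) {
  key <- sprintf("toy_%d_%d_%s_%s_%s", n, seed, pool, kind,
                 if (is.null(n_alpha)) "d" else n_alpha)
  if (is.null(.test_cache[[key]])) {
    ints <- toy_integrals(kind, n, seed = seed, n_alpha = n_alpha)
    .test_cache[[key]] <- compile_system(ints, pool = pool)
  }
  .test_cache[[key]]
}
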