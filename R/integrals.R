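#' Molecular integrals in the molecular-orbital basis
#'
#' Container for the classical input of the algorithm: one-body integrals
#' `h[p, q]` (Hartree), two-body integrals `g[p, q, r, s]` in chemists'
#' notation `(pq|rs)` with the full 8-fold permutational symmetry, a constant
#' core energy (nuclear repulsion plus any frozen contribution), and the
#' electron counts per spin.  Orbitals are assumed to be canonical restricted
#' Hartree-Fock MOs ordered by orbital energy, the FCIDUMP convention.
#'
#' @param h numeric `n x n` symmetric matrix of one-body integrals (Hartree).
#' @param g numeric `n x n x n x n` array, chemists' notation `(pq|rs)`.
#' @param e_core constant energy offset in Hartree.
#' @param n_alpha,n_beta electron counts per spin channel.
#' @param label free-text provenance (molecule, geometry, basis).
#' @return an object of class `molecular_integrals`.
#' @export
molecular_integrals <- function(h, g, e_core, n_alpha, n_beta, label = "") {
  h <- as.matrix(h)
  n <- nrow(h)
  stopifnot(ncol(h) == n, length(dim(g)) == 4L, all(dim(g) == n))
  if (n_alpha <= 0 && n_beta <= 0)
    stop("at least one electron required")
  if (n_alpha > n || n_beta > n)
    stop("electron count exceeds number of spatial orbitals")
  obj <- structure(
    list(n_spatial = n, n_alpha = as.integer(n_alpha),
         n_beta = as.integer(n_beta), e_core = as.numeric(e_core),
         h = h, g = g, label = label),
    class = "molecular_integrals")
  validate_integrals(obj)
  obj
}

#' @method print molecular_integrals
#' @export
print.molecular_integrals <- function(x, ...) {
  cat(sprintf("<molecular_integrals> %s\n", x$label))
  cat(sprintf("  %d spatial orbitals, %d alpha + %d beta electrons, e_core = %.8f\n",
              x$n_spatial, x$n_alpha, x$n_beta, x$e_core))
  invisible(x)
}

#' Validate permutational symmetry of an integral set
#'
#' Checks `h` symmetry and all 8 index permutations of `g` to `tol`.
#'
#' @param x a `molecular_integrals` object.
#' @param tol absolute tolerance.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_integrals <- function(x, tol = 1e-12) {
  stopifnot(inherits(x, "molecular_integrals"))
  if (max(abs(x$h - t(x$h))) > tol)
    stop("one-body integrals are not symmetric")
  g <- x$g
  perms <- list(c(2, 1, 3, 4), c(1, 2, 4, 3), c(2, 1, 4, 3),
                c(3, 4, 1, 2), c(4, 3, 1, 2), c(3, 4, 2, 1), c(4, 3, 2, 1))
  for (p in perms) {
    if (max(abs(g - aperm(g, p))) > tol)
      stop("two-body integrals violate 8-fold permutational symmetry (",
           paste(p, collapse = ""), ")")
  }
  invisible(x)
}

#' Synthetic integral generators for testing
#'
#' `random_twobody` draws `h` and `g` from a seeded normal distribution and
#' symmetrizes them to the full physical symmetry; `pairing` builds a
#' seniority-zero pairing model (diagonal one-body levels plus a constant
#' pair-hopping interaction), a classic minimal model of superconducting
#' correlation.  Deterministic for a fixed seed.
#'
#' @param kind one of `"random_twobody"`, `"pairing"`.
#' @param n_spatial number of spatial orbitals (small, <= 6 recommended).
#' @param seed integer seed.
#' @param n_alpha,n_beta electron counts (default half filling, rounded down).
#' @param scale standard deviation of the random entries.
#' @return a [molecular_integrals()] object.
#' @export
toy_integrals <- function(kind = c("random_twobody", "pairing"), n_spatial,
                          seed = 1L, n_alpha = NULL, n_beta = NULL,
                          scale = 0.5) {
  kind <- match.arg(kind)
  n <- as.integer(n_spatial)
  if (is.null(n_alpha)) n_alpha <- max(1L, n %/% 2L)
  if (is.null(n_beta)) n_beta <- n_alpha
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  if (kind == "random_twobody") {
    h <- matrix(rnorm(n * n, sd = scale), n, n)
    h <- (h + t(h)) / 2
    diag(h) <- diag(h) - seq_len(n)       # roughly ordered "orbital energies"
    g <- array(rnorm(n^4, sd = scale / 2), rep(n, 4))
    # symmetrize to the full 8-fold symmetry of real chemists' integrals
    perms <- list(c(1, 2, 3, 4), c(2, 1, 3, 4), c(1, 2, 4, 3), c(2, 1, 4, 3),
                  c(3, 4, 1, 2), c(4, 3, 1, 2), c(3, 4, 2, 1), c(4, 3, 2, 1))
    gs <- array(0, rep(n, 4))
    for (p in perms) gs <- gs + aperm(g, p)
    g <- gs / 8
    e_core <- rnorm(1)
  } else {
    h <- diag(seq_len(n) - (n + 1) / 2)   # evenly spaced levels
    g <- array(0, rep(n, 4))
    gpair <- -0.5 * scale                  # constant pair-hopping strength
    for (p in seq_len(n)) for (q in seq_len(n)) {
      # (pq|pq) plus its full 8-fold symmetry closure
      g[p, q, p, q] <- gpair; g[q, p, p, q] <- gpair
      g[p, q, q, p] <- gpair; g[q, p, q, p] <- gpair
    }
    e_core <- 0
  }
  molecular_integrals(h, g, e_core, n_alpha, n_beta,
                      label = sprintf("toy %s n=%d seed=%d", kind, n, seed))
}

#' Hartree-Fock reference occupation
#'
#' Marks the lowest `n_alpha` alpha and `n_beta` beta spin orbitals occupied,
#' assuming the MO-basis integrals are ordered by orbital energy (the FCIDUMP
#' convention).  Spin orbitals are indexed interleaved and 0-based: spin
#' orbital `2p` is spatial orbital `p` (0-based) with alpha spin, `2p + 1`
#' the same spatial orbital with beta spin.
#'
#' @param integrals a [molecular_integrals()] object.
#' @return sorted integer vector of occupied spin-orbital indices (0-based).
#' @export
hf_reference_occupation <- function(integrals) {
  n <- integrals$n_spatial
  if (integrals$n_alpha > n || integrals$n_beta > n)
    stop("electron count exceeds number of spatial orbitals")
  occ_a <- if (integrals$n_alpha > 0) 2L * (seq_len(integrals$n_alpha) - 1L) else integer(0)
  occ_b <- if (integrals$n_beta > 0) 2L * (seq_len(integrals$n_beta) - 1L) + 1L else integer(0)
  sort(c(occ_a, occ_b))
}

#' Closed-form restricted Hartree-Fock energy
#'
#' For a closed-shell determinant occupying the first `n_occ` spatial
#' orbitals: `E = e_core + sum_i 2 h_ii + sum_ij (2 (ii|jj) - (ij|ji))`.
#' Used as an independent oracle for `<HF|H|HF>`.
#'
#' @param integrals a [molecular_integrals()] object with `n_alpha == n_beta`.
#' @return RHF energy in Hartree.
#' @export
rhf_energy <- function(integrals) {
  stopifnot(integrals$n_alpha == integrals$n_beta)
  occ <- seq_len(integrals$n_alpha)
  e <- integrals$e_core + 2 * sum(diag(integrals$h)[occ])
  for (i in occ) for (j in occ)
    e <- e + 2 * integrals$g[i, i, j, j] - integrals$g[i, j, j, i]
  e
}
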