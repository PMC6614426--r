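#' Sums of products of fermionic ladder operators
#'
#' A `fermion_sum` is a list of terms, each a product of creation /
#' annihilation operators on spin orbitals with a numeric (possibly complex)
#' coefficient.  Spin orbitals are indexed 0-based and interleaved: spin
#' orbital `2p` is spatial orbital `p` with alpha spin, `2p + 1` beta spin.
#'
#' @param terms list of terms; each term is `list(idx, dag, coef)` with
#'   `idx` an integer vector of spin-orbital indices (applied right-to-left
#'   in the written order, i.e. `idx[1]` is the leftmost operator), `dag` a
#'   logical vector (`TRUE` = creation), and `coef` the coefficient.
#' @param prune terms with `|coef|` at or below this are dropped.
#' @return an object of class `fermion_sum`.
#' @export
fermion_sum <- function(terms = list(), prune = 1e-14) {
  keep <- vapply(terms, function(t) abs(t$coef) > prune, logical(1))
  structure(list(terms = terms[keep]), class = "fermion_sum")
}

#' @method print fermion_sum
#' @export
print.fermion_sum <- function(x, ...) {
  cat(sprintf("<fermion_sum> %d terms\n", length(x$terms)))
  for (t in utils::head(x$terms, 12)) {
    ops <- paste0("a", ifelse(t$dag, "+", "-"), "(", t$idx, ")", collapse = " ")
    cat(sprintf("  %+.6g  %s\n", Re(t$coef), ops))
  }
  if (length(x$terms) > 12) cat("  ...\n")
  invisible(x)
}

#' Add two fermionic sums (like terms are not combined; mapping simplifies)
#' @param a,b `fermion_sum` objects.
#' @return their sum.
#' @export
fermion_add <- function(a, b) fermion_sum(c(a$terms, b$terms), prune = 0)

#' Scale a fermionic sum by a constant
#' @param a a `fermion_sum`.
#' @param s scalar.
#' @return scaled sum.
#' @export
fermion_scale <- function(a, s) {
  fermion_sum(lapply(a$terms, function(t) { t$coef <- t$coef * s; t }), prune = 0)
}

#' Hermitian conjugate of a fermionic sum
#'
#' Reverses each operator product, swaps creation and annihilation, and
#' conjugates the coefficient.
#'
#' @param a a `fermion_sum`.
#' @return the adjoint sum.
#' @export
fermion_dagger <- function(a) {
  fermion_sum(lapply(a$terms, function(t) {
    list(idx = rev(t$idx), dag = rev(!t$dag), coef = Conj(t$coef))
  }), prune = 0)
}

#' Single fermionic product term
#' @param idx spin-orbital indices, leftmost operator first.
#' @param dag logical, `TRUE` for creation operators.
#' @param coef coefficient.
#' @return a `fermion_sum` with one term.
#' @export
fermion_term <- function(idx, dag, coef = 1) {
  fermion_sum(list(list(idx = as.integer(idx), dag = as.logical(dag),
                        coef = coef)), prune = 0)
}

#' Second-quantized molecular Hamiltonian from MO integrals
#'
#' Builds `H = e_core + sum_{pq,s} h[p,q] a+_{ps} a_{qs}
#' + 1/2 sum_{pqrs,s,s'} (pq|rs) a+_{ps} a+_{rs'} a_{ss'} a_{qs}`
#' over interleaved spin orbitals; Hermitian by construction since `h` is
#' symmetric and `g` has the full permutational symmetry.  The constant
#' `e_core` is carried as a zero-length operator product.
#'
#' @param integrals a [molecular_integrals()] object.
#' @param thresh integrals with `|value|` at or below this are skipped.
#' @return a `fermion_sum`.
#' @export
build_fermionic_hamiltonian <- function(integrals, thresh = 1e-14) {
  validate_integrals(integrals)
  n <- integrals$n_spatial
  terms <- vector("list", 4L * n^2 + 4L * n^4 + 1L)
  k <- 0L
  add <- function(idx, dag, coef) {
    k <<- k + 1L
    terms[[k]] <<- list(idx = idx, dag = dag, coef = coef)
  }
  if (abs(integrals$e_core) > 0)
    add(integer(0), logical(0), integrals$e_core)
  so <- function(p, spin) 2L * (p - 1L) + spin   # spin 0 = alpha, 1 = beta
  for (p in seq_len(n)) for (q in seq_len(n)) {
    v <- integrals$h[p, q]
    if (abs(v) <= thresh) next
    for (s in 0:1)
      add(c(so(p, s), so(q, s)), c(TRUE, FALSE), v)
  }
  for (p in seq_len(n)) for (q in seq_len(n))
    for (r in seq_len(n)) for (s in seq_len(n)) {
      v <- integrals$g[p, q, r, s]
      if (abs(v) <= thresh) next
      for (s1 in 0:1) for (s2 in 0:1) {
        # a+_{p s1} a+_{r s2} a_{s s2} a_{q s1}: zero if identical indices repeat
        i1 <- so(p, s1); i2 <- so(r, s2); i3 <- so(s, s2); i4 <- so(q, s1)
        if (i1 == i2 || i3 == i4) next
        add(c(i1, i2, i3, i4), c(TRUE, TRUE, FALSE, FALSE), 0.5 * v)
      }
    }
  fermion_sum(terms[seq_len(k)], prune = 0)
}

#' Total-particle-number operator as a fermionic sum
#' @param n_spin_orbitals number of spin orbitals.
#' @return a `fermion_sum` for `N = sum_p a+_p a_p`.
#' @export
number_operator <- function(n_spin_orbitals) {
  fermion_sum(lapply(seq_len(n_spin_orbitals) - 1L, function(p)
    list(idx = c(p, p), dag = c(TRUE, FALSE), coef = 1)), prune = 0)
}

#' Spin-projection operator S_z as a fermionic sum
#'
#' `S_z = (N_alpha - N_beta) / 2` with the interleaved spin-orbital
#' convention (even indices alpha).
#'
#' @param n_spin_orbitals number of spin orbitals (even).
#' @return a `fermion_sum`.
#' @export
sz_operator <- function(n_spin_orbitals) {
  fermion_sum(lapply(seq_len(n_spin_orbitals) - 1L, function(p)
    list(idx = c(p, p), dag = c(TRUE, FALSE),
         coef = if (p %% 2L == 0L) 0.5 else -0.5)), prune = 0)
}
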