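#' Reference determinant as a statevector
#'
#' Computational-basis state with bits set at the occupied spin orbitals.
#' With `sector` given, the state is expressed in that sector basis.
#'
#' @param n_qubits qubit count.
#' @param occupied distinct 0-based occupied qubit indices.
#' @param sector optional 0-based basis-index vector (from
#'   [sector_indices()]) to express the state in.
#' @return numeric unit vector.
#' @export
reference_state <- function(n_qubits, occupied, sector = NULL) {
  occupied <- as.integer(occupied)
  if (anyDuplicated(occupied)) stop("duplicate occupied indices")
  if (length(occupied) && max(occupied) >= n_qubits) stop("occupied index out of range")
  idx <- sum(bitwShiftL(1L, occupied))
  if (is.null(sector)) {
    v <- numeric(2^n_qubits)
    v[idx + 1L] <- 1
  } else {
    p <- match(idx, sector)
    if (is.na(p)) stop("reference determinant not contained in the sector")
    v <- numeric(length(sector))
    v[p] <- 1
  }
  v
}

#' Count of generator-exponential applications (instrumentation)
#'
#' [apply_exp()] increments a package-level counter; these helpers reset and
#' read it.  Used to verify that the analytic energy-plus-gradient sweep
#' costs at most three times the plain energy evaluation.
#'
#' @return `exp_count()` returns the current count.
#' @export
reset_exp_count <- function() {
  .pkg_env$exp_applications <- 0L
  invisible(NULL)
}

#' @rdname reset_exp_count
#' @export
exp_count <- function() .pkg_env$exp_applications

#' Act with a generator exponential on a statevector
#'
#' Computes `exp(theta * A) v` for an anti-Hermitian generator `A` by a
#' scaled Taylor series: the rotation is split into enough segments that
#' each partial series converges rapidly, and terms are accumulated until
#' they fall below `tol` relative to the running result.  Exact to near
#' machine precision; unitarity (norm preservation) follows.
#'
#' @param A square matrix (sparse `dgCMatrix` or dense, real or complex),
#'   anti-Hermitian.
#' @param theta real rotation parameter.
#' @param v statevector.
#' @param tol relative truncation tolerance of the series.
#' @return the rotated statevector.
#' @export
apply_exp <- function(A, theta, v, tol = 1e-13) {
  .pkg_env$exp_applications <- .pkg_env$exp_applications + 1L
  if (theta == 0) return(v)
  if (is(A, "dgCMatrix") && is.double(v) && !is.complex(v)) {
    return(exp_action_csc(A@p, A@i, A@x, theta, v, tol, 60L, .cached_norm(A)))
  }
  nrmA <- abs(theta) * .cached_norm(A)
  s <- max(1L, ceiling(nrmA / 1.0))
  h <- theta / s
  for (seg in seq_len(s)) {
    term <- v
    k <- 1
    repeat {
      term <- (h / k) * as.vector(A %*% term)
      v <- v + term
      if (sqrt(sum(Mod(term)^2)) <= tol * sqrt(sum(Mod(v)^2)) || k > 60) break
      k <- k + 1
    }
  }
  v
}

# infinity norm, cached on the matrix object when possible
.cached_norm <- function(A) {
  nrm <- attr(A, ".inf_norm")
  if (!is.null(nrm)) return(nrm)
  if (is(A, "sparseMatrix")) {
    max(Matrix::rowSums(abs(A)))
  } else {
    max(rowSums(Mod(A)))
  }
}

#' Attach a cached operator norm to a generator matrix
#' @param A matrix.
#' @return `A` with an `.inf_norm` attribute (speeds up [apply_exp()]).
#' @keywords internal
cache_norm <- function(A) {
  if (is(A, "sparseMatrix")) attr(A, ".inf_norm") <- max(Matrix::rowSums(abs(A)))
  else attr(A, ".inf_norm") <- max(rowSums(Mod(A)))
  A
}

#' Verify that a generator matrix is anti-Hermitian
#' @param A matrix.
#' @param tol absolute tolerance.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
check_anti_hermitian <- function(A, tol = 1e-12) {
  d <- if (is(A, "sparseMatrix")) max(abs(A + Matrix::t(A))) else max(Mod(A + Conj(t(A))))
  if (d > tol) stop("matrix is not anti-Hermitian (deviation ", format(d), ")")
  invisible(TRUE)
}

#' Prepare the trial state of a product-of-exponentials ansatz
#'
#' Applies `exp(theta_k A_k)` oldest-first, so the newest operator acts
#' last (leftmost in the operator product).
#'
#' @param mats list of generator matrices, element 1 applied first.
#' @param thetas numeric parameter vector, same length as `mats`.
#' @param reference reference statevector.
#' @return the prepared statevector.
#' @export
prepare_state <- function(mats, thetas, reference) {
  if (length(mats) != length(thetas))
    stop("parameter vector length (", length(thetas),
         ") does not match ansatz length (", length(mats), ")")
  v <- reference
  for (k in seq_along(mats)) v <- apply_exp(mats[[k]], thetas[k], v)
  v
}

#' Hamiltonian expectation value of a statevector
#'
#' Real part of `<psi|H|psi>`; the imaginary residue must be below
#' `imag_tol` (it is identically zero for real representations).
#'
#' @param H Hermitian matrix, or a `qubit_sum` (summed term by term, an
#'   independent evaluation path used for cross-checks).
#' @param state statevector (full space for the `qubit_sum` path).
#' @param imag_tol allowed imaginary residue.
#' @return real expectation value.
#' @export
expectation <- function(H, state, imag_tol = 1e-10) {
  if (inherits(H, "qubit_sum")) return(.expectation_pauli(H, state, imag_tol))
  if (nrow(H) != length(state)) stop("dimension mismatch")
  val <- sum(Conj(state) * as.vector(H %*% state))
  if (abs(Im(val)) > imag_tol) stop("expectation has imaginary residue ", Im(val))
  Re(val)
}

# term-by-term Pauli expectation: sum_i g_i <psi|P_i|psi>
.expectation_pauli <- function(op, state, imag_tol = 1e-10) {
  n <- op$n_qubits
  if (length(state) != 2^n) stop("term-by-term path needs a full-space state")
  js <- 0:(2^n - 1L)
  val <- 0 + 0i
  for (t in seq_along(op$x)) {
    tgt <- bitwXor(js, op$x[t])
    sgn <- 1 - 2 * (popcount(bitwAnd(js, op$z[t])) %% 2L)
    val <- val + op$coef[t] * sum(Conj(state[tgt + 1L]) * sgn * state)
  }
  if (abs(Im(val)) > imag_tol) stop("expectation has imaginary residue ", Im(val))
  Re(val)
}

#' Pool gradient: commutator expectations driving operator selection
#'
#' For each pool generator `A_k`, `g_k = <psi|[H, A_k]|psi>`, which equals
#' the derivative of the energy with respect to a new parameter appended on
#' the left of the ansatz at value zero.  With Hermitian `H` and
#' anti-Hermitian `A_k` this is `2 Re <H psi | A_k psi>`, so the whole sweep
#' costs one Hamiltonian application plus one generator application per pool
#' member.
#'
#' @param H Hermitian Hamiltonian matrix.
#' @param state normalized statevector.
#' @param pool_mats list of anti-Hermitian generator matrices.
#' @return numeric gradient vector over the pool.
#' @export
pool_gradient <- function(H, state, pool_mats) {
  hv <- as.vector(H %*% state)
  if (is.double(state) && !is.complex(state)) {
    return(vapply(pool_mats, function(A) {
      av <- if (is(A, "dgCMatrix")) spmv_csc(A@p, A@i, A@x, state)
            else as.vector(A %*% state)
      2 * Re(sum(Conj(hv) * av))
    }, numeric(1)))
  }
  vapply(pool_mats, function(A) {
    2 * Re(sum(Conj(hv) * as.vector(A %*% state)))
  }, numeric(1))
}

#' Alpha/beta occupation expectations of a statevector
#'
#' @param state statevector.
#' @param basis 0-based basis indices corresponding to the entries of
#'   `state` (full space: `0:(2^n - 1)`).
#' @param n_spatial number of spatial orbitals.
#' @return list with `n_alpha`, `n_beta` expectations.
#' @export
occupation_expectations <- function(state, basis, n_spatial) {
  amask <- sum(bitwShiftL(1L, 2L * (seq_len(n_spatial) - 1L)))
  bmask <- bitwShiftL(amask, 1L)
  w <- Mod(state)^2
  list(n_alpha = sum(w * popcount(bitwAnd(basis, amask))),
       n_beta = sum(w * popcount(bitwAnd(basis, bmask))))
}
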