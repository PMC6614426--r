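#' Weighted sums of Pauli strings on n qubits
#'
#' Internal representation is symplectic: each string is stored as
#' `coef * X^x Z^z`, where `x` and `z` are integer bit masks over qubits
#' (bit `b` set means an X, resp. Z, factor on qubit `b`) and `Y = i X Z`
#' per qubit.  This makes products and the Jordan-Wigner expansion cheap
#' integer arithmetic.  Qubit 0 is the least-significant bit of the
#' computational-basis index.
#'
#' @param n_qubits number of qubits (<= 24).
#' @param x,z integer bit-mask vectors (one entry per string).
#' @param coef complex coefficient vector.
#' @param combine merge equal `(x, z)` strings by summing coefficients.
#' @param tol drop strings with `|coef|` at or below `tol`.
#' @return an object of class `qubit_sum`.
#' @export
qubit_sum <- function(n_qubits, x = integer(0), z = integer(0),
                      coef = complex(0), combine = TRUE, tol = 0) {
  n_qubits <- as.integer(n_qubits)
  if (n_qubits > 24L) stop("resource guard: more than 24 qubits")
  stopifnot(length(x) == length(z), length(x) == length(coef))
  obj <- structure(list(n_qubits = n_qubits, x = as.integer(x),
                        z = as.integer(z), coef = as.complex(coef)),
                   class = "qubit_sum")
  if (combine) obj <- simplify(obj, tol = tol)
  obj
}

#' Merge like Pauli strings and drop negligible coefficients
#'
#' @param op a `qubit_sum`.
#' @param tol strings with `|coefficient| <= tol` are removed after merging.
#' @return a simplified `qubit_sum` with unique strings.
#' @export
simplify <- function(op, tol = 1e-12) {
  if (length(op$x) == 0) return(op)
  key <- as.numeric(op$x) * 16777216 + as.numeric(op$z)  # exact below 2^48
  u <- unique(key)
  grp <- match(key, u)
  re <- rowsum(Re(op$coef), grp, reorder = FALSE)
  im <- rowsum(Im(op$coef), grp, reorder = FALSE)
  first <- !duplicated(grp)
  xs <- op$x[first]; zs <- op$z[first]
  co <- complex(real = re[, 1], imaginary = im[, 1])
  keep <- Mod(co) > tol
  qubit_sum(op$n_qubits, xs[keep], zs[keep], co[keep], combine = FALSE)
}

#' Number of Pauli strings in a qubit operator sum
#' @param op a `qubit_sum`.
#' @return integer count.
#' @export
n_terms <- function(op) length(op$x)

#' @method print qubit_sum
#' @export
print.qubit_sum <- function(x, ...) {
  cat(sprintf("<qubit_sum> %d qubits, %d Pauli strings\n", x$n_qubits, n_terms(x)))
  txt <- format_qubit_sum(x)
  cat(paste0("  ", utils::head(txt, 10)), sep = "\n")
  if (length(txt) > 10) cat("  ...\n")
  invisible(x)
}

# letters + letter-basis coefficient of one stored string
.pauli_letters <- function(n_qubits, x, z, coef) {
  y <- bitwAnd(x, z)
  letter_coef <- coef * (-1i)^popcount(y)
  bits <- function(m) which(bitwAnd(m, bitwShiftL(1L, 0:(n_qubits - 1L))) != 0L) - 1L
  lab <- character(0)
  for (q in 0:(n_qubits - 1L)) {
    bx <- bitwAnd(bitwShiftR(x, q), 1L); bz <- bitwAnd(bitwShiftR(z, q), 1L)
    if (bx == 1L && bz == 1L) lab <- c(lab, paste0("Y", q))
    else if (bx == 1L) lab <- c(lab, paste0("X", q))
    else if (bz == 1L) lab <- c(lab, paste0("Z", q))
  }
  list(letters = if (length(lab)) paste(lab, collapse = " ") else "I",
       coef = letter_coef)
}

#' Serialize a qubit operator to a plain-text term list
#'
#' One line per Pauli string, e.g. `"0.5 X0 X1"`; purely real coefficients
#' are printed as plain numbers, otherwise as `re+imi`.  The inverse is
#' [parse_qubit_sum()].
#'
#' @param op a `qubit_sum`.
#' @param digits significant digits.
#' @return character vector of lines.
#' @export
format_qubit_sum <- function(op, digits = 15) {
  if (n_terms(op) == 0) return(character(0))
  vapply(seq_along(op$x), function(i) {
    pl <- .pauli_letters(op$n_qubits, op$x[i], op$z[i], op$coef[i])
    c0 <- pl$coef
    ctxt <- if (abs(Im(c0)) < 1e-14) format(Re(c0), digits = digits)
            else paste0(format(Re(c0), digits = digits),
                        if (Im(c0) < 0) "-" else "+",
                        format(abs(Im(c0)), digits = digits), "i")
    paste(ctxt, pl$letters)
  }, character(1))
}

#' Parse a plain-text Pauli term list
#'
#' @param lines character vector as produced by [format_qubit_sum()].
#' @param n_qubits qubit count of the target operator.
#' @return a `qubit_sum`.
#' @export
parse_qubit_sum <- function(lines, n_qubits) {
  xs <- zs <- integer(length(lines)); cs <- complex(length(lines))
  for (i in seq_along(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    cs[i] <- as.complex(parts[1])
    x <- z <- 0L; phase <- 1 + 0i
    for (p in parts[-1]) {
      if (p == "I") next
      q <- as.integer(substring(p, 2))
      bit <- bitwShiftL(1L, q)
      letter <- substring(p, 1, 1)
      if (letter == "X") x <- bitwOr(x, bit)
      else if (letter == "Z") z <- bitwOr(z, bit)
      else if (letter == "Y") { x <- bitwOr(x, bit); z <- bitwOr(z, bit); phase <- phase * 1i }
      else stop("unknown Pauli letter: ", letter)
    }
    xs[i] <- x; zs[i] <- z; cs[i] <- cs[i] * phase
  }
  qubit_sum(n_qubits, xs, zs, cs)
}

# ---------------------------------------------------------------- Jordan-Wigner

# symplectic strings of a single ladder operator (index 0-based):
#   a+_p = (X_p - iY_p)/2 (x) Z_{<p} = 1/2 X_p Z_{<p} + 1/2 X_p Z_p Z_{<p}
#   a_p  = (X_p + iY_p)/2 (x) Z_{<p} = 1/2 X_p Z_{<p} - 1/2 X_p Z_p Z_{<p}
.jw_ladder <- function(p, dagger) {
  zlt <- bitwShiftL(1L, p) - 1L
  xp <- bitwShiftL(1L, p)
  list(x = c(xp, xp), z = c(zlt, bitwOr(zlt, xp)),
       coef = c(0.5 + 0i, (if (dagger) 0.5 else -0.5) + 0i))
}

#' Jordan-Wigner transform of a fermionic operator sum
#'
#' Maps each ladder operator to its Pauli representation with the Z parity
#' string on all lower-index qubits (qubit index = spin-orbital index),
#' expands the products, and merges like strings.  The mapping is linear and
#' preserves the canonical anticommutation relations.
#'
#' @param op a [fermion_sum()].
#' @param n_qubits number of qubits; all spin-orbital indices must be below.
#' @param tol coefficient pruning tolerance for the merged result.
#' @return a `qubit_sum`.
#' @export
jordan_wigner <- function(op, n_qubits, tol = 1e-12) {
  n_qubits <- as.integer(n_qubits)
  nt <- length(op$terms)
  xs_all <- vector("list", nt); zs_all <- vector("list", nt); cs_all <- vector("list", nt)
  for (ti in seq_len(nt)) {
    t <- op$terms[[ti]]
    if (length(t$idx) > 0 && max(t$idx) >= n_qubits)
      stop("spin-orbital index ", max(t$idx), " outside 0..", n_qubits - 1L)
    x <- 0L; z <- 0L; c0 <- as.complex(t$coef)
    for (k in seq_along(t$idx)) {
      lad <- .jw_ladder(t$idx[k], t$dag[k])
      # multiply current strings (x, z, c0) by the two ladder strings:
      # (X^x1 Z^z1)(X^x2 Z^z2) = (-1)^{|z1 & x2|} X^{x1^x2} Z^{z1^z2}
      sgn1 <- 1 - 2 * (popcount(bitwAnd(z, lad$x[1])) %% 2L)
      sgn2 <- 1 - 2 * (popcount(bitwAnd(z, lad$x[2])) %% 2L)
      xn <- c(bitwXor(x, lad$x[1]), bitwXor(x, lad$x[2]))
      zn <- c(bitwXor(z, lad$z[1]), bitwXor(z, lad$z[2]))
      cn <- c(c0 * lad$coef[1] * sgn1, c0 * lad$coef[2] * sgn2)
      x <- xn; z <- zn; c0 <- cn
    }
    xs_all[[ti]] <- x; zs_all[[ti]] <- z; cs_all[[ti]] <- c0
  }
  qubit_sum(n_qubits, unlist(xs_all), unlist(zs_all),
            unlist(cs_all), combine = TRUE, tol = tol)
}

#' Fermion-to-qubit mapping dispatcher
#'
#' Only the Jordan-Wigner mapping is implemented; `"bravyi_kitaev"` is an
#' interface hook reserved for a future tree-parity encoding.
#'
#' @param op a [fermion_sum()].
#' @param n_qubits qubit count.
#' @param mapping mapping name.
#' @return a `qubit_sum`.
#' @export
map_to_qubits <- function(op, n_qubits,
                          mapping = c("jordan_wigner", "bravyi_kitaev")) {
  mapping <- match.arg(mapping)
  if (mapping == "bravyi_kitaev")
    stop("bravyi_kitaev mapping is an interface stub; use jordan_wigner")
  jordan_wigner(op, n_qubits)
}

# ------------------------------------------------------------------- matrices

#' Matrix realization of a qubit operator sum
#'
#' Builds the `2^n x 2^n` matrix (or its restriction to a basis-index
#' subset).  `(X^x Z^z)|j> = (-1)^{|j & z|} |j xor x>`, so strings sharing an
#' X mask share a sparsity pattern; entries are accumulated per X-mask group.
#' If every entry is real to `imag_tol` the result is a real sparse
#' `dgCMatrix`, otherwise a dense complex matrix (guarded to 12 qubits).
#'
#' @param op a `qubit_sum`.
#' @param sector optional 0-based computational-basis indices to restrict
#'   rows and columns to (e.g. a particle-number sector); default full space.
#' @param imag_tol tolerance for discarding imaginary parts.
#' @return a `Matrix::dgCMatrix` (real case) or a dense complex matrix.
#' @export
to_matrix <- function(op, sector = NULL, imag_tol = 1e-12) {
  n <- op$n_qubits
  if (n > 24L) stop("resource guard: more than 24 qubits")
  dim_full <- 2^n
  if (is.null(sector)) {
    js <- 0:(dim_full - 1L)
    pos <- seq_len(dim_full)          # pos[index + 1] = matrix column
  } else {
    js <- as.integer(sector)
    pos <- rep(NA_integer_, dim_full)
    pos[js + 1L] <- seq_along(js)
  }
  d <- length(js)
  ii <- list(); jj <- list(); vre <- list(); vim <- list(); nblk <- 0L
  for (xm in unique(op$x)) {
    sel <- which(op$x == xm)
    tgt <- bitwXor(js, xm)
    rows <- pos[tgt + 1L]
    ok <- which(!is.na(rows))
    if (length(ok) == 0) next
    vr <- numeric(length(ok)); vi <- numeric(length(ok))
    for (t in sel) {
      sgn <- 1 - 2 * (popcount(bitwAnd(js[ok], op$z[t])) %% 2L)
      vr <- vr + Re(op$coef[t]) * sgn
      vi <- vi + Im(op$coef[t]) * sgn
    }
    nblk <- nblk + 1L
    ii[[nblk]] <- rows[ok]; jj[[nblk]] <- ok; vre[[nblk]] <- vr; vim[[nblk]] <- vi
  }
  i <- unlist(ii); j <- unlist(jj)
  re <- unlist(vre); im <- unlist(vim)
  if (is.null(i)) i <- j <- integer(0)
  if (is.null(re)) re <- im <- numeric(0)
  if (length(im) == 0 || max(abs(im)) <= imag_tol) {
    Matrix::sparseMatrix(i = i, j = j, x = re, dims = c(d, d))
  } else {
    if (n > 12L) stop("resource guard: complex dense matrix beyond 12 qubits")
    m <- matrix(0 + 0i, d, d)
    m[cbind(i, j)] <- m[cbind(i, j)] + complex(real = re, imaginary = im)
    m
  }
}

#' Basis indices of a particle-number / spin sector
#'
#' Computational-basis indices (0-based) whose alpha (even qubit) and beta
#' (odd qubit) occupations match the requested electron counts.
#'
#' @param n_spatial number of spatial orbitals (qubits = 2 * n_spatial).
#' @param n_alpha,n_beta electron counts.
#' @return integer vector of basis indices, ascending.
#' @export
sector_indices <- function(n_spatial, n_alpha, n_beta) {
  n_q <- 2L * n_spatial
  amask <- sum(bitwShiftL(1L, 2L * (seq_len(n_spatial) - 1L)))
  bmask <- bitwShiftL(amask, 1L)
  js <- 0:(2^n_q - 1L)
  js[popcount(bitwAnd(js, amask)) == n_alpha &
     popcount(bitwAnd(js, bmask)) == n_beta]
}

#' Dimension of a particle-number / spin sector
#'
#' Equals `choose(n_spatial, n_alpha) * choose(n_spatial, n_beta)`.
#'
#' @inheritParams sector_indices
#' @return integer dimension.
#' @export
sector_dimension <- function(n_spatial, n_alpha, n_beta) {
  choose(n_spatial, n_alpha) * choose(n_spatial, n_beta)
}
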