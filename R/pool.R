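#' @section Excitations:
#' An excitation is a pair of disjoint-or-overlapping sets of spin orbitals
#' `occ -> vir` (0-based, interleaved spin convention).  The associated
#' cluster operator is `t = a+_{vir} ... a_{occ}` and the pool stores the
#' anti-Hermitian combination `tau = t - t^dagger` summed over the spin
#' complement (the same excitation with all spins flipped).
#' @name pool-internals
#' @keywords internal
NULL

# --- excitation primitives (internal) ---------------------------------------

.exc <- function(occ, vir) list(occ = sort(as.integer(occ)),
                                vir = sort(as.integer(vir)))

.exc_sz <- function(idx) sum(ifelse(idx %% 2L == 0L, 1L, -1L))  # twice Sz in halves

.exc_key <- function(e) paste(paste(e$occ, collapse = ","),
                              paste(e$vir, collapse = ","), sep = ">")

# flip all spins: alpha <-> beta of the same spatial orbital
.exc_flip <- function(e) .exc(bitwXor(e$occ, 1L), bitwXor(e$vir, 1L))

# fermionic sign picked up when re-sorting the index pairs of the flipped
# excitation: each pair that is the alpha+beta pair of one spatial orbital
# inverts its order under the flip and contributes a factor -1
.exc_flip_sign <- function(e) {
  pair_sign <- function(idx) {
    if (length(idx) < 2L) return(1)
    f <- bitwXor(idx, 1L)
    if (is.unsorted(f)) -1 else 1
  }
  pair_sign(e$occ) * pair_sign(e$vir)
}

# canonical direction: tau_{A->B} = -tau_{B->A}; pick the smaller key
.exc_canon <- function(e) {
  rev_e <- .exc(e$vir, e$occ)
  if (.exc_key(rev_e) < .exc_key(e)) rev_e else e
}

# t operator of an excitation as a fermion_sum term:
# double occ=(P,Q) vir=(R,S) (sorted):  a+_R a+_S a_Q a_P
.exc_t <- function(e) {
  fermion_term(c(e$vir, rev(e$occ)),
               c(rep(TRUE, length(e$vir)), rep(FALSE, length(e$occ))), 1)
}

.exc_tau <- function(e) fermion_add(.exc_t(e), fermion_scale(fermion_dagger(.exc_t(e)), -1))

.so_label <- function(idx) {
  paste0((idx %/% 2L) + 1L, ifelse(idx %% 2L == 1L, "b", ""))
}

.exc_label <- function(e) {
  sprintf("tau_{%s}^{%s}", paste(.so_label(e$occ), collapse = " "),
          paste(.so_label(e$vir), collapse = " "))
}

#' Spin complement of an excitation
#'
#' Returns the excitation together with its global spin flip (alpha and beta
#' exchanged on every index); a self-complementary excitation (one mapped to
#' itself by the flip, e.g. an alpha-beta pair out of one spatial orbital)
#' is returned once.  Each member carries the fermionic sign produced by
#' writing the flipped operator back in canonical index order (a -1 whenever
#' exactly one of the index pairs is a same-spatial-orbital alpha-beta
#' pair).  Errors if the excitation does not conserve S_z.
#'
#' @param occ,vir spin-orbital index vectors (0-based, interleaved spins).
#' @return list of one or two excitations, each `list(occ, vir, sign)`.
#' @export
spin_complement <- function(occ, vir) {
  e <- .exc(occ, vir)
  if (.exc_sz(e$occ) != .exc_sz(e$vir))
    stop("excitation does not conserve S_z")
  e$sign <- 1
  f <- .exc_flip(e)
  if (identical(.exc_key(f), .exc_key(e))) return(list(e))
  f$sign <- .exc_flip_sign(e)
  list(e, f)
}

# build one pool operator (orbit representative + complement members);
# the generator is normalized to unit fermionic coefficient norm when asked
.make_pool_op <- function(e, normalize = FALSE) {
  members <- spin_complement(e$occ, e$vir)
  gen <- Reduce(fermion_add, lapply(members, function(m)
    fermion_scale(.exc_tau(m), m$sign)))
  if (normalize) {
    nrm <- sqrt(sum(vapply(gen$terms, function(t) abs(t$coef)^2, numeric(1))))
    gen <- fermion_scale(gen, 1 / nrm)
  }
  same_spatial_pair <- function(v) length(v) == 2L && bitwXor(v[1], 1L) == v[2]
  structure(list(
    rank = if (length(e$occ) == 1L) "single" else "double",
    occ = e$occ, vir = e$vir, members = members,
    generator = gen, label = .exc_label(e), key = .exc_key(e),
    multiplicity = if (same_spatial_pair(e$occ) || same_spatial_pair(e$vir))
      2L else 1L),
    class = "pool_operator")
}

#' @method print pool_operator
#' @export
print.pool_operator <- function(x, ...) {
  cat(sprintf("<pool_operator> %s (%s, %d spin-complement member%s)\n",
              x$label, x$rank, length(x$members),
              if (length(x$members) > 1) "s" else ""))
  invisible(x)
}

# orbit-deduplicated pool from a list of excitations
.dedup_pool <- function(excs, normalize = FALSE) {
  ops <- list(); seen <- character(0)
  for (e in excs) {
    if (identical(e$occ, e$vir)) next              # tau identically zero
    ec <- .exc_canon(e)
    fc <- .exc_canon(.exc_flip(ec))
    orbit_key <- min(.exc_key(ec), .exc_key(fc))
    if (orbit_key %in% seen) next
    seen <- c(seen, orbit_key)
    rep_e <- if (.exc_key(ec) <= .exc_key(fc)) ec else fc
    ops[[length(ops) + 1L]] <- .make_pool_op(rep_e, normalize = normalize)
  }
  ops
}

# all Sz-conserving spin-orbital pairs drawn from a given index set
.sz_pairs <- function(idx_set) {
  if (length(idx_set) < 2) return(list())
  cmb <- combn(sort(idx_set), 2, simplify = FALSE)
  cmb
}

#' Enumerate raw S_z-conserving excitation amplitudes from the HF reference
#'
#' All unique occupied-to-virtual single and double spin-orbital excitations
#' that conserve S_z, without any spin-complement grouping.  For LiH in a
#' minimal basis (6 spatial orbitals, 2 occupied) this enumerates the 92
#' UCCSD amplitudes.
#'
#' @param n_spatial,n_occ_spatial spatial orbital counts (closed shell).
#' @return list of excitations `list(occ, vir)`.
#' @export
sd_excitations <- function(n_spatial, n_occ_spatial) {
  stopifnot(n_occ_spatial > 0, n_occ_spatial < n_spatial)
  occ_so <- 0:(2L * n_occ_spatial - 1L)
  vir_so <- (2L * n_occ_spatial):(2L * n_spatial - 1L)
  excs <- list()
  for (i in occ_so) for (a in vir_so)
    if (i %% 2L == a %% 2L)
      excs[[length(excs) + 1L]] <- .exc(i, a)
  for (op in .sz_pairs(occ_so)) for (vp in .sz_pairs(vir_so))
    if (.exc_sz(op) == .exc_sz(vp))
      excs[[length(excs) + 1L]] <- .exc(op, vp)
  excs
}

#' Restricted singles-and-doubles operator pool
#'
#' Unique spin-complemented, S_z-conserving, anti-Hermitized single and
#' double excitations from occupied to virtual spin orbitals, grouped into
#' orbits under the global spin flip (each orbit contributes one pool
#' operator whose generator sums both complement members).
#'
#' @param n_spatial,n_occ_spatial spatial orbital counts.
#' @param normalize scale each generator to unit fermionic coefficient norm
#'   (default FALSE, the convention of the published dissociation results);
#'   the variational parameter absorbs any scale, but normalization changes
#'   the gradient magnitudes the selection and epsilon stopping rule see.
#' @return an `operator_pool` (variant `"sd"`); the attribute
#'   `raw_amplitudes` records the ungrouped amplitude count.
#' @export
build_sd_pool <- function(n_spatial, n_occ_spatial, normalize = FALSE) {
  excs <- sd_excitations(n_spatial, n_occ_spatial)
  ops <- .dedup_pool(excs, normalize = normalize)
  structure(list(operators = ops, variant = "sd",
                 n_spatial = as.integer(n_spatial),
                 n_occ_spatial = as.integer(n_occ_spatial),
                 raw_amplitudes = length(excs)),
            class = "operator_pool")
}

#' Generalized singles-and-doubles operator pool
#'
#' Singles over all spatial orbital pairs and doubles over all unique
#' S_z-conserving spin-orbital pair combinations, with no occupied/virtual
#' restriction: the pool deliberately includes operators that annihilate the
#' HF determinant (occupied-to-occupied and virtual-to-virtual moves), which
#' acquire non-zero gradients only once the wavefunction is entangled.
#' Spin-complemented and orbit-deduplicated as in [build_sd_pool()].
#'
#' @param n_spatial spatial orbital count (>= 2).
#' @param normalize scale generators to unit fermionic coefficient norm.
#' @return an `operator_pool` (variant `"gsd"`).
#' @export
build_gsd_pool <- function(n_spatial, normalize = FALSE) {
  stopifnot(n_spatial >= 2)
  all_so <- 0:(2L * n_spatial - 1L)
  excs <- list()
  for (p in seq_len(n_spatial) - 1L) for (q in seq_len(n_spatial) - 1L) {
    if (p >= q) next
    excs[[length(excs) + 1L]] <- .exc(2L * p, 2L * q)       # alpha single p->q
    excs[[length(excs) + 1L]] <- .exc(2L * p + 1L, 2L * q + 1L)
  }
  pairs <- .sz_pairs(all_so)
  sz <- vapply(pairs, .exc_sz, integer(1))
  np <- length(pairs)
  for (i in seq_len(np)) for (j in seq_len(np)) {
    if (i >= j || sz[i] != sz[j]) next
    excs[[length(excs) + 1L]] <- .exc(pairs[[i]], pairs[[j]])
  }
  structure(list(operators = .dedup_pool(excs, normalize = normalize),
                 variant = "gsd",
                 n_spatial = as.integer(n_spatial),
                 n_occ_spatial = NA_integer_,
                 raw_amplitudes = length(excs)),
            class = "operator_pool")
}

#' @method print operator_pool
#' @export
print.operator_pool <- function(x, ...) {
  cat(sprintf("<operator_pool> variant %s, %d operators (%d spatial orbitals)\n",
              x$variant, length(x$operators), x$n_spatial))
  invisible(x)
}

#' Number of operators in a pool
#' @param pool an `operator_pool`.
#' @return integer count.
#' @export
pool_size <- function(pool) length(pool$operators)

#' Pool listing as a data frame
#'
#' One row per operator: label, rank, representative indices, number of
#' spin-complement members and fermionic terms.  Useful for citing selected
#' ansatz operators in the paper-style overbar notation (`b` suffix marks
#' beta spin in the labels).
#'
#' @param pool an `operator_pool`.
#' @return a `data.frame`.
#' @export
pool_table <- function(pool) {
  data.frame(
    index = seq_along(pool$operators),
    label = vapply(pool$operators, `[[`, character(1), "label"),
    rank = vapply(pool$operators, `[[`, character(1), "rank"),
    members = vapply(pool$operators, function(o) length(o$members), integer(1)),
    terms = vapply(pool$operators, function(o) length(o$generator$terms), integer(1)),
    stringsAsFactors = FALSE)
}

#' Deterministic lexical ordering of a pool
#'
#' Total order: singles before doubles, then ascending spatial index tuples
#' (occupied then virtual side of the representative), then the spin
#' pattern with alpha before beta.  Stable across runs and platforms.
#'
#' @param pool an `operator_pool`.
#' @return integer permutation of `seq_len(pool_size(pool))`.
#' @export
lexical_order <- function(pool) {
  keyf <- function(o) {
    spat <- c(o$occ %/% 2L, o$vir %/% 2L)
    spin <- c(o$occ %% 2L, o$vir %% 2L)
    sprintf("%d|%s|%s", as.integer(o$rank == "double"),
            paste(sprintf("%03d", spat), collapse = ""),
            paste(spin, collapse = ""))
  }
  order(vapply(pool$operators, keyf, character(1)))
}

#' UCCSD amplitude counts under the published parameter accounting
#'
#' `raw` counts every S_z-conserving occupied-to-virtual single and double
#' spin-orbital amplitude.  `grouped` ties each mixed-spin (alpha-beta)
#' double amplitude to its global spin-flip partner under one shared
#' parameter, while singles and same-spin doubles remain separate per-spin
#' parameters; this is the accounting that reduces LiH's 92 raw amplitudes
#' to 64.  (A full orbit merge, which additionally pairs the alpha/beta
#' singles and the alpha-alpha/beta-beta doubles and is what the operator
#' pools use, would give 50; see the methods vignette.)
#'
#' @param n_spatial,n_occ_spatial spatial orbital counts.
#' @return list with elements `raw` and `grouped`.
#' @export
uccsd_parameter_count <- function(n_spatial, n_occ_spatial) {
  groups <- uccsd_parameter_groups(n_spatial, n_occ_spatial)
  list(raw = sum(vapply(groups, length, integer(1))),
       grouped = length(groups))
}

#' Amplitude groups for the UCCSD parameterization
#'
#' Each group is a list of excitations sharing one variational parameter,
#' following the published accounting described in
#' [uccsd_parameter_count()].
#'
#' @param n_spatial,n_occ_spatial spatial orbital counts.
#' @return list of excitation groups.
#' @export
uccsd_parameter_groups <- function(n_spatial, n_occ_spatial) {
  excs <- sd_excitations(n_spatial, n_occ_spatial)
  is_mixed_double <- function(e)
    length(e$occ) == 2L && length(unique(e$occ %% 2L)) == 2L
  groups <- list(); seen <- character(0)
  for (e in excs) {
    k <- .exc_key(e)
    if (k %in% seen) next
    e$sign <- 1
    if (is_mixed_double(e)) {
      f <- .exc_flip(e)
      if (identical(.exc_key(f), k)) {
        groups[[length(groups) + 1L]] <- list(e)
      } else {
        f$sign <- .exc_flip_sign(e)    # fermionic reordering sign of the flip
        groups[[length(groups) + 1L]] <- list(e, f)
        seen <- c(seen, .exc_key(f))
      }
    } else {
      groups[[length(groups) + 1L]] <- list(e)
    }
    seen <- c(seen, k)
  }
  groups
}
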