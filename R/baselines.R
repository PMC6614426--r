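# Gauss-Legendre nodes/weights on [0, 1] via the Golub-Welsch eigenproblem.
.gauss_legendre01 <- function(m) {
  k <- seq_len(m - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, m, m)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  es <- eigen(J, symmetric = TRUE)
  nodes <- rev(es$values)
  weights <- rev(2 * es$vectors[1, ]^2)
  list(nodes = (nodes + 1) / 2, weights = weights / 2)
}

# sector matrices for the operators of a pool (or any list of fermion sums)
pool_matrices <- function(pool, n_qubits, basis) {
  lapply(pool$operators, function(op)
    cache_norm(to_matrix(jordan_wigner(op$generator, n_qubits), sector = basis)))
}

#' Un-Trotterized UCCSD ground-state energy
#'
#' Variational minimization of `<HF| exp(-T) H exp(T) |HF>` where
#' `T = sum_k theta_k G_k` is a single anti-Hermitian sum over the
#' spin-complement-grouped singles and doubles amplitudes
#' ([uccsd_parameter_groups()]); the exponential of the summed generator is
#' applied exactly (no Trotter factorization).  The parameter gradient is
#' evaluated analytically through the integral representation of the
#' exponential's directional derivative, discretized by Gauss-Legendre
#' quadrature (the integrand is entire, so the quadrature converges
#' geometrically; node count adapts to the generator norm).
#'
#' @param system a `vqe_system` (pool not required).
#' @param gtol projected-gradient stopping tolerance.
#' @param maxit optimizer iteration cap.
#' @param quad_nodes minimum quadrature node count.
#' @return list with `energy`, `parameters`, `n_parameters`, `groups`,
#'   `converged`.
#' @export
uccsd_energy <- function(system, gtol = 1e-8, maxit = 500L, quad_nodes = 16L) {
  ints <- system$integrals
  stopifnot(ints$n_alpha == ints$n_beta)
  groups <- uccsd_parameter_groups(ints$n_spatial, ints$n_alpha)
  gens <- lapply(groups, function(g)
    Reduce(fermion_add, lapply(g, function(m)
      fermion_scale(.exc_tau(m), if (is.null(m$sign)) 1 else m$sign))))
  mats <- lapply(gens, function(fs)
    to_matrix(jordan_wigner(fs, system$n_qubits), sector = system$basis))
  K <- length(mats)
  d <- length(system$reference)
  trip <- lapply(mats, function(m) Matrix::summary(m))
  i_all <- unlist(lapply(trip, `[[`, "i"))
  j_all <- unlist(lapply(trip, `[[`, "j"))
  x_all <- unlist(lapply(trip, `[[`, "x"))
  nnz <- vapply(trip, nrow, integer(1))
  assemble <- function(par) {
    Matrix::sparseMatrix(i = i_all, j = j_all,
                         x = x_all * rep(par, times = nnz), dims = c(d, d))
  }
  H <- system$H
  ref <- system$reference
  cache <- new.env(parent = emptyenv())
  best <- list(par = numeric(K), value = Inf)
  state_for <- function(par) {
    Tm <- assemble(par)
    phi <- apply_exp(Tm, 1, ref)
    list(Tm = Tm, phi = phi)
  }
  fn <- function(par) {
    st <- state_for(par)
    e <- expectation(H, st$phi)
    if (!is.finite(e)) stop("non-finite UCCSD energy at theta = (",
                            paste(format(par), collapse = ", "), ")")
    if (e < best$value) best <<- list(par = par, value = e)
    cache$par <- par; cache$st <- st
    e
  }
  gr <- function(par) {
    st <- if (identical(cache$par, par)) cache$st else state_for(par)
    hphi <- as.vector(H %*% st$phi)
    nrmT <- .cached_norm(st$Tm)
    m <- max(quad_nodes, ceiling(4 * nrmT))
    gl <- .gauss_legendre01(m)
    g <- numeric(K)
    for (q in seq_len(m)) {
      lv <- apply_exp(st$Tm, -gl$nodes[q], hphi)       # e^{sT}^T hphi
      rv <- apply_exp(st$Tm, 1 - gl$nodes[q], ref)     # e^{(1-s)T} ref
      g <- g + gl$weights[q] * 2 *
        vapply(mats, function(A) sum(lv * as.vector(A %*% rv)), numeric(1))
    }
    g
  }
  res <- optim(numeric(K), fn, gr, method = "L-BFGS-B",
               control = list(maxit = maxit, pgtol = gtol, factr = 10))
  final <- if (best$value < res$value) best$par else res$par
  e_final <- fn(final)
  list(energy = e_final, parameters = final, n_parameters = K,
       groups = groups, converged = res$convergence == 0L)
}

#' Trotterized generalized-UCC product ansatz energy
#'
#' Factorizes the summed cluster operator into a product of single-operator
#' exponentials — doubles applied first, then singles, in the deterministic
#' lexical order — repeated `n_trotter` times.  With post-factorization
#' variational optimization this is an ansatz in its own right rather than
#' an approximation; replicas carry independent parameters
#' (`replicas = "independent"`) or share one parameter per operator split
#' evenly across replicas (`"tied"`, the literal Trotter formula).
#'
#' @param system a `vqe_system`.
#' @param pool the operator pool to factorize (default: the system's pool).
#' @param n_trotter number of replicas (>= 1).
#' @param replicas parameter sharing mode.
#' @param gtol,maxit optimizer controls.
#' @return list with `energy`, `parameters`, `n_parameters`, `converged`.
#' @export
trotter_ucc_energy <- function(system, pool = NULL, n_trotter = 1L,
                               replicas = c("independent", "tied"),
                               gtol = 1e-8, maxit = 500L) {
  replicas <- match.arg(replicas)
  stopifnot(n_trotter >= 1L)
  if (is.null(pool)) pool <- system$pool
  mats1 <- if (!is.null(system$pool) && identical(pool, system$pool))
    system$pool_mats else pool_matrices(pool, system$n_qubits, system$basis)
  ord <- lexical_order(pool)
  ranks <- vapply(pool$operators, `[[`, character(1), "rank")[ord]
  ord <- c(ord[ranks == "double"], ord[ranks == "single"])  # doubles act first
  mats_rep <- rep(mats1[ord], n_trotter)
  n1 <- length(ord)
  if (replicas == "independent") {
    vqe <- minimize_vqe(system$H, mats_rep, numeric(length(mats_rep)),
                        system$reference, gtol = gtol, maxit = maxit)
    list(energy = vqe$energy, parameters = vqe$parameters,
         n_parameters = length(mats_rep), converged = vqe$converged)
  } else {
    expand <- function(par) rep(par / n_trotter, n_trotter)
    cache <- new.env(parent = emptyenv())
    best <- list(par = numeric(n1), value = Inf)
    fn <- function(par) {
      val <- energy_and_analytic_gradient(mats_rep, expand(par),
                                          system$H, system$reference)
      cache$par <- par; cache$val <- val
      if (val$energy < best$value) best <<- list(par = par, value = val$energy)
      val$energy
    }
    gr <- function(par) {
      val <- if (identical(cache$par, par)) cache$val
             else energy_and_analytic_gradient(mats_rep, expand(par),
                                               system$H, system$reference)
      rowSums(matrix(val$gradient, nrow = n1)) / n_trotter
    }
    res <- optim(numeric(n1), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, pgtol = gtol, factr = 10))
    final <- if (best$value < res$value) best$par else res$par
    list(energy = fn(final), parameters = final, n_parameters = n1,
         converged = res$convergence == 0L)
  }
}

#' Fixed-order ansatz-growth control protocols
#'
#' Grows the ansatz one operator at a time in a prescribed order with no
#' gradient screening, re-optimizing all parameters at every step: the
#' comparison curves for the adaptive selection.  Orders: `random` shuffles
#' the pool (sampling without replacement until the pool is exhausted, then
#' with replacement), `lexical` uses [lexical_order()].  Use an `sd` pool
#' for the HF-restricted (ijab) protocols and a `gsd` pool for the
#' unrestricted (pqrs) ones.
#'
#' @param system a `vqe_system`.
#' @param pool the pool to draw from (default: the system's pool).
#' @param order `"random"` or `"lexical"`.
#' @param seed integer seed for the random order.
#' @param n_steps number of growth steps.
#' @param gtol,maxit optimizer controls.
#' @return data frame with `step`, `pool_index`, `label`, `energy`.
#' @export
grow_fixed_order <- function(system, pool = NULL,
                             order = c("lexical", "random"), seed = 1L,
                             n_steps = 10L, gtol = 1e-8, maxit = 500L) {
  order <- match.arg(order)
  if (is.null(pool)) pool <- system$pool
  mats1 <- if (!is.null(system$pool) && identical(pool, system$pool))
    system$pool_mats else pool_matrices(pool, system$n_qubits, system$basis)
  np <- pool_size(pool)
  if (order == "lexical") {
    seq_idx <- rep(lexical_order(pool), length.out = max(n_steps, np))
  } else {
    old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({ if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()) })
    set.seed(seed)
    seq_idx <- sample.int(np, np)
    while (length(seq_idx) < n_steps)
      seq_idx <- c(seq_idx, sample.int(np, min(np, n_steps - length(seq_idx)),
                                       replace = TRUE))
  }
  seq_idx <- seq_idx[seq_len(n_steps)]
  labels <- vapply(pool$operators, `[[`, character(1), "label")
  thetas <- numeric(0)
  energies <- numeric(n_steps)
  for (s in seq_len(n_steps)) {
    mats <- mats1[seq_idx[seq_len(s)]]
    thetas <- c(thetas, 0)
    vqe <- minimize_vqe(system$H, mats, thetas, system$reference,
                        gtol = gtol, maxit = maxit)
    thetas <- vqe$parameters
    energies[s] <- vqe$energy
  }
  data.frame(step = seq_len(n_steps), pool_index = seq_idx,
             label = labels[seq_idx], energy = energies,
             stringsAsFactors = FALSE)
}
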