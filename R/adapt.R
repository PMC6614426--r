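#' Gradient-norm convergence threshold epsilon_m = 10^-m
#'
#' The conventional shorthand for reporting runs: a calculation converged to
#' a pool-gradient norm below 0.001 is denoted ADAPT(eps_3).
#'
#' @param m positive integer exponent.
#' @return `10^-m`.
#' @export
epsilon_from_m <- function(m) {
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != round(m))
    stop("m must be a positive integer (>= 1)")
  10^(-m)
}

#' Configuration of the adaptive ansatz-growth loop
#'
#' @param epsilon gradient-norm convergence threshold(s), Hartree.  A vector
#'   is allowed: the loop runs to the smallest value and the trace records
#'   when each looser threshold was crossed (see [adapt_at_threshold()]).
#' @param max_iterations cap on the number of added operators.
#' @param pool_variant `"gsd"` or `"sd"` (used when the system carries no pool).
#' @param norm `"l2"` (default) or `"max"` norm of the pool-gradient vector
#'   for the convergence test.
#' @param norm_multiplicity weight each operator's squared gradient in the
#'   L2 convergence norm by its enumeration multiplicity (doubles built from
#'   a same-spatial-orbital alpha-beta pair arise twice in an enumeration
#'   over spatial index quadruples and count twice); this convention
#'   reproduces the published dissociation-curve behavior of the loose
#'   thresholds.  Selection is unaffected.
#' @param gtol inner-loop VQE projected-gradient tolerance; kept well below
#'   the smallest supported epsilon so optimizer noise cannot pollute the
#'   pool-gradient convergence check.
#' @param operators_per_iteration reserved; only 1 is implemented.
#' @return an `adapt_config` list.
#' @export
adapt_config <- function(epsilon = 1e-2, max_iterations = 150L,
                         pool_variant = "gsd", norm = c("l2", "max"),
                         norm_multiplicity = TRUE,
                         gtol = 1e-8, operators_per_iteration = 1L) {
  stopifnot(all(epsilon > 0), max_iterations >= 1)
  if (operators_per_iteration != 1L)
    stop("multi-operator growth is reserved but not implemented")
  structure(list(epsilon = sort(as.numeric(epsilon), decreasing = TRUE),
                 max_iterations = as.integer(max_iterations),
                 pool_variant = pool_variant, norm = match.arg(norm),
                 norm_multiplicity = isTRUE(norm_multiplicity),
                 gtol = gtol, operators_per_iteration = 1L),
            class = "adapt_config")
}

#' Run the adaptive ansatz-growth VQE loop
#'
#' Iterates: prepare the current trial state; measure the commutator of the
#' Hamiltonian with every pool operator (the candidate-parameter gradients);
#' stop if the gradient-vector norm is below epsilon; otherwise append the
#' operator with the largest absolute gradient (ties broken toward the
#' lowest pool index) on the left end of the ansatz with a new parameter at
#' zero, and re-optimize all parameters warm-started from the previous
#' optimum.  Selecting an operator never removes it from the pool, so
#' operators can recur in the ansatz.
#'
#' @param system a `vqe_system` from [compile_system()] carrying a pool.
#' @param config an [adapt_config()].
#' @return an `adapt_result`: list with `ansatz` (data frame of selected
#'   operators and final parameters), `energy`, `vqe` (final inner-loop
#'   result), `trace` (per-iteration data frame: gradient norm before
#'   growth, selected operator, re-optimized energy), `termination`
#'   (`"converged"` or `"max_iterations"`), `energies` (E_HF first),
#'   `config`, and `final_gradient_norm` (independent recomputation at the
#'   returned state).
#' @export
run_adapt <- function(system, config = adapt_config()) {
  if (is.null(system$pool_mats)) stop("system was compiled without a pool")
  H <- system$H
  pool_mats <- system$pool_mats
  labels <- vapply(system$pool$operators, `[[`, character(1), "label")
  mult <- if (config$norm_multiplicity)
    vapply(system$pool$operators, `[[`, integer(1), "multiplicity")
  else rep(1L, length(pool_mats))
  eps_exit <- min(config$epsilon)
  sel <- integer(0)
  thetas <- numeric(0)
  energies <- system$e_hf
  vqe <- NULL
  it_rows <- list()
  termination <- "max_iterations"
  state <- system$reference
  for (it in seq_len(config$max_iterations + 1L)) {
    g <- pool_gradient(H, state, pool_mats)
    gnorm <- if (config$norm == "l2") sqrt(sum(mult * g^2)) else max(abs(g))
    if (gnorm < eps_exit) {
      termination <- "converged"
      it_rows[[it]] <- data.frame(
        iteration = it - 1L, grad_norm = gnorm, max_abs_grad = max(abs(g)),
        selected = NA_integer_, label = NA_character_,
        energy = energies[length(energies)],
        n_parameters = length(sel), stringsAsFactors = FALSE)
      break
    }
    if (it > config$max_iterations) break
    k <- which.max(abs(g))             # ties resolve to the lowest index
    sel <- c(sel, k)
    mats <- pool_mats[sel]
    thetas <- c(thetas, 0)
    vqe <- minimize_vqe(H, mats, thetas, system$reference, gtol = config$gtol)
    thetas <- vqe$parameters
    if (vqe$energy > energies[length(energies)] + 1e-10)
      warning("energy increased at iteration ", it, " (",
              format(vqe$energy - energies[length(energies)]), ")")
    energies <- c(energies, vqe$energy)
    state <- prepare_state(mats, thetas, system$reference)
    it_rows[[it]] <- data.frame(
      iteration = it, grad_norm = gnorm, max_abs_grad = max(abs(g)),
      selected = k, label = labels[k], energy = vqe$energy,
      n_parameters = length(sel), stringsAsFactors = FALSE)
  }
  trace <- do.call(rbind, it_rows)
  final_g <- pool_gradient(H, state, pool_mats)
  final_norm <- if (config$norm == "l2") sqrt(sum(mult * final_g^2))
                else max(abs(final_g))
  ansatz <- data.frame(position = seq_along(sel), pool_index = sel,
                       label = labels[sel], theta = thetas,
                       stringsAsFactors = FALSE)
  structure(list(ansatz = ansatz, energy = energies[length(energies)],
                 vqe = vqe, trace = trace, termination = termination,
                 energies = energies, config = config,
                 final_gradient_norm = final_norm),
            class = "adapt_result")
}

#' @method print adapt_result
#' @export
print.adapt_result <- function(x, ...) {
  cat(sprintf("<adapt_result> E = %.10f Hartree, %d operators, %s (|g| = %.2e)\n",
              x$energy, nrow(x$ansatz), x$termination, x$final_gradient_norm))
  if (nrow(x$ansatz) > 0)
    cat("  ansatz (first applied first):", paste(x$ansatz$label, collapse = " "), "\n")
  invisible(x)
}

#' Extract the state of a run at a looser convergence threshold
#'
#' A single run to a tight threshold contains every looser-threshold run as
#' a prefix: the loop is deterministic, so the ansatz that a run with
#' threshold `eps` would have returned is the prefix ending at the first
#' iteration whose measured gradient norm fell below `eps`.
#'
#' @param result an `adapt_result` whose run reached below `eps`.
#' @param eps threshold to extract.
#' @return list with `energy`, `n_parameters`, `converged` (whether the
#'   run's trace ever crossed `eps`).
#' @export
adapt_at_threshold <- function(result, eps) {
  tr <- result$trace
  hit <- which(tr$grad_norm < eps)
  if (length(hit) == 0) {
    return(list(energy = result$energy, n_parameters = nrow(result$ansatz),
                converged = FALSE))
  }
  i <- hit[1]
  list(energy = if (i == 1) result$energies[1] else tr$energy[i - 1L],
       n_parameters = if (i == 1) 0L else tr$n_parameters[i - 1L],
       converged = TRUE)
}

#' Flag false gradient troughs in an adaptive trace (diagnostic only)
#'
#' Marks stretches of `window` consecutive growth iterations over which
#' every energy improvement per added operator is below `tol` while the
#' measured pool-gradient norm stays at or above `eps`: the signature of a
#' plateau where a loose threshold would terminate the run early even
#' though correlation energy remains.  Purely diagnostic; never alters the
#' algorithm.
#'
#' @param result an `adapt_result`.
#' @param window number of consecutive iterations required (>= 2).
#' @param eps gradient threshold of interest (default: the run's exit value).
#' @param tol energy-improvement floor in Hartree.
#' @return integer vector of flagged starting iterations (possibly empty).
#' @export
detect_false_trough <- function(result, window = 2L, eps = NULL, tol = 1e-8) {
  stopifnot(window >= 2L)
  if (is.null(eps)) eps <- min(result$config$epsilon)
  tr <- result$trace[!is.na(result$trace$selected), , drop = FALSE]
  n <- nrow(tr)
  if (n < window) return(integer(0))
  improvement <- -diff(c(result$energies[1], tr$energy))
  flagged <- integer(0)
  for (s in seq_len(n - window + 1L)) {
    idx <- s:(s + window - 1L)
    if (all(improvement[idx] < tol) && all(tr$grad_norm[idx] >= eps))
      flagged <- c(flagged, s)
  }
  flagged
}
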