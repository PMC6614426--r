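#' Build atomic coordinates for the test molecules
#'
#' LiH: diatomic at separation `r`; BeH2: linear and symmetric with both
#' Be-H distances equal to `r`; H6: six collinear hydrogens with all
#' adjacent separations equal to `r` (the simultaneous-stretch coordinate).
#'
#' @param molecule `"lih"`, `"beh2"`, `"h6"`, or `"h2"`.
#' @param r bond length in Angstrom (> 0).
#' @return data frame with `element`, `x`, `y`, `z` (Angstrom).
#' @export
build_geometry <- function(molecule, r) {
  stopifnot(r > 0)
  switch(tolower(molecule),
    lih = data.frame(element = c("Li", "H"), x = 0, y = 0, z = c(0, r)),
    beh2 = data.frame(element = c("H", "Be", "H"), x = 0, y = 0,
                      z = c(-r, 0, r)),
    h6 = data.frame(element = rep("H", 6), x = 0, y = 0, z = r * (0:5)),
    h2 = data.frame(element = c("H", "H"), x = 0, y = 0, z = c(0, r)),
    stop("unknown molecule: ", molecule))
}

#' Potential-energy-surface scan over bond distances
#'
#' For each grid point, obtains integrals from the provider, computes the
#' requested method energies, and tabulates errors against sector-restricted
#' FCI in kcal/mol together with variational parameter counts.  The three
#' adaptive thresholds are extracted from a single run to the tightest
#' threshold (the loop is deterministic, so looser-threshold runs are
#' prefixes of it).
#'
#' @param molecule molecule name understood by the `provider`.
#' @param grid numeric vector of bond lengths in Angstrom.
#' @param methods subset of `"hf"`, `"uccsd"`, `"adapt"`, `"fci"`.
#' @param adapt_eps_m integer vector of threshold exponents `m`
#'   (`epsilon_m = 10^-m`); each produces an `adapt_eps<m>` column.
#' @param provider integral provider `(molecule, r) -> molecular_integrals`;
#'   defaults to the packaged FCIDUMP fixtures.
#' @param max_iterations adaptive-loop cap per grid point.
#' @param verbose print per-point progress to stderr.
#' @return a `pes_scan`: list with `rows` (data frame: one row per grid
#'   point with energies in Hartree, `err_*` columns in kcal/mol,
#'   `npar_*` parameter counts) and `summary` (per-method mean/max errors,
#'   see [summarize_table1()]), plus the grid and configuration.
#' @export
run_scan <- function(molecule, grid,
                     methods = c("hf", "uccsd", "adapt"),
                     adapt_eps_m = c(1L, 2L, 3L),
                     provider = fcidump_provider(),
                     max_iterations = 150L, verbose = TRUE) {
  stopifnot(length(grid) >= 1, all(grid > 0))
  methods <- match.arg(methods, c("hf", "uccsd", "adapt", "fci"),
                       several.ok = TRUE)
  rows <- list()
  for (r in grid) {
    ints <- tryCatch(provider(molecule, r), error = function(e) e)
    if (inherits(ints, "error")) {
      warning("no integrals for ", molecule, " at ", r, " Angstrom: ",
              conditionMessage(ints), "; point skipped")
      next
    }
    need_pool <- "adapt" %in% methods
    sys <- compile_system(ints, pool = if (need_pool) "gsd" else "none")
    fci <- fci_ground(sys)
    row <- list(molecule = molecule, r = r, e_fci = fci$energy,
                e_hf = sys$e_hf)
    if ("uccsd" %in% methods) {
      u <- uccsd_energy(sys)
      row$e_uccsd <- u$energy
      row$npar_uccsd <- u$n_parameters
    }
    if ("adapt" %in% methods) {
      eps <- 10^(-as.numeric(adapt_eps_m))
      cfg <- adapt_config(epsilon = eps, max_iterations = max_iterations)
      res <- run_adapt(sys, cfg)
      for (m in adapt_eps_m) {
        at <- adapt_at_threshold(res, 10^(-m))
        row[[paste0("e_adapt_eps", m)]] <- at$energy
        row[[paste0("npar_adapt_eps", m)]] <- at$n_parameters
        row[[paste0("conv_adapt_eps", m)]] <- at$converged
      }
    }
    if (verbose)
      message(sprintf("%s R=%.2f A: E_FCI=%.8f%s", molecule, r, fci$energy,
                      if (!is.null(row$e_uccsd))
                        sprintf(" E_UCCSD=%.8f", row$e_uccsd) else ""))
    rows[[length(rows) + 1L]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no grid point could be computed")
  tab <- do.call(rbind, rows)
  for (cn in grep("^e_", names(tab), value = TRUE)) {
    mname <- sub("^e_", "", cn)
    tab[[paste0("err_", mname)]] <-
      hartree_to_kcalmol(tab[[cn]] - tab$e_fci)
  }
  out <- structure(list(rows = tab, molecule = molecule, grid = grid,
                        methods = methods, adapt_eps_m = adapt_eps_m),
                   class = "pes_scan")
  out$summary <- summarize_table1(out)
  out
}

#' @method print pes_scan
#' @export
print.pes_scan <- function(x, ...) {
  cat(sprintf("<pes_scan> %s, %d points (%.2f..%.2f Angstrom)\n",
              x$molecule, nrow(x$rows), min(x$rows$r), max(x$rows$r)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Mean absolute errors across a PES scan
#'
#' The per-method average of `|E_method - E_FCI|` over the scan grid, in
#' kcal/mol, plus maxima and mean parameter counts.  Accepts a single scan
#' or a list of scans (one row each).
#'
#' @param scans a `pes_scan` or list of them.
#' @return data frame with one row per molecule and one column pair per
#'   method (`mean_*`, `max_*` in kcal/mol).
#' @export
summarize_table1 <- function(scans) {
  if (inherits(scans, "pes_scan")) scans <- list(scans)
  out <- lapply(scans, function(sc) {
    tab <- sc$rows
    res <- list(molecule = sc$molecule, n_points = nrow(tab))
    for (cn in grep("^err_", names(tab), value = TRUE)) {
      mname <- sub("^err_", "", cn)
      if (mname == "fci") next
      res[[paste0("mean_", mname)]] <- mean(abs(tab[[cn]]))
      res[[paste0("max_", mname)]] <- max(abs(tab[[cn]]))
    }
    npc <- grep("^npar_", names(tab), value = TRUE)
    for (cn in npc) res[[paste0("max_", cn)]] <- max(tab[[cn]])
    as.data.frame(res, stringsAsFactors = FALSE)
  })
  nm <- unique(unlist(lapply(out, names)))
  out <- lapply(out, function(d) { d[setdiff(nm, names(d))] <- NA; d[nm] })
  do.call(rbind, out)
}

#' Diagnose parameter-count discontinuities in an adaptive scan
#'
#' Along a dissociation curve the adaptive ansatz can change size abruptly,
#' producing visible jumps in the error curve.  This reports, for each
#' adaptive method, the grid intervals where the absolute error changes by
#' more than `factor` times the median step change, together with whether
#' the parameter count changed across the same interval.
#'
#' @param scan a `pes_scan` including adaptive methods.
#' @param factor jump detection multiplier.
#' @return data frame (possibly empty) with `method`, `r_from`, `r_to`,
#'   `err_jump`, `npar_change`.
#' @export
scan_discontinuities <- function(scan, factor = 10) {
  tab <- scan$rows[order(scan$rows$r), , drop = FALSE]
  out <- list()
  for (m in scan$adapt_eps_m) {
    err <- abs(tab[[paste0("err_adapt_eps", m)]])
    np <- tab[[paste0("npar_adapt_eps", m)]]
    if (is.null(err) || nrow(tab) < 3) next
    jumps <- abs(diff(err))
    med <- median(jumps)
    big <- which(jumps > factor * max(med, 1e-12))
    for (i in big)
      out[[length(out) + 1L]] <- data.frame(
        method = paste0("adapt_eps", m), r_from = tab$r[i], r_to = tab$r[i + 1],
        err_jump = jumps[i], npar_change = np[i + 1] - np[i])
  }
  if (length(out) == 0)
    return(data.frame(method = character(0), r_from = numeric(0),
                      r_to = numeric(0), err_jump = numeric(0),
                      npar_change = integer(0)))
  do.call(rbind, out)
}
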