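#' Read a Molpro-style FCIDUMP file
#'
#' Parses the namelist header (`&FCI NORB=..., NELEC=..., MS2=...` up to
#' `&END` or `/`), then integral lines `value i j k l` with 1-based indices:
#' four non-zero indices give a two-body entry `(ij|kl)` in chemists'
#' notation, `k = l = 0` a one-body entry `h[i, j]`, and the all-zero index
#' line the scalar core energy.  The 8-fold permutational symmetry is
#' completed from the non-redundant entries stored in the file.
#'
#' @param path path to an FCIDUMP file.
#' @return a [molecular_integrals()] object.
#' @export
read_fcidump <- function(path) {
  if (!file.exists(path)) stop("FCIDUMP file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr_end <- grep("(&END|/\\s*$)", lines, ignore.case = TRUE)[1]
  if (is.na(hdr_end)) {
    # single-line headers terminated implicitly: require &FCI on line 1
    if (!grepl("&FCI", lines[1], ignore.case = TRUE))
      stop("malformed FCIDUMP header: line 1 does not start a &FCI namelist")
    hdr_end <- 1L
  }
  header <- paste(lines[seq_len(hdr_end)], collapse = " ")
  get_field <- function(name) {
    m <- regmatches(header,
                    regexpr(paste0(name, "\\s*=\\s*-?[0-9]+"), header, ignore.case = TRUE))
    if (length(m) == 0)
      stop("malformed FCIDUMP header: missing ", name, " (header line 1)")
    as.integer(sub(".*=\\s*", "", m))
  }
  norb <- get_field("NORB")
  nelec <- get_field("NELEC")
  ms2 <- get_field("MS2")
  n_alpha <- (nelec + ms2) %/% 2L
  n_beta <- nelec - n_alpha

  body <- lines[-seq_len(hdr_end)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0) stop("FCIDUMP has no integral records")
  con <- textConnection(body)
  on.exit(close(con), add = TRUE)
  tab <- read.table(con, col.names = c("val", "i", "j", "k", "l"),
                    colClasses = c("numeric", rep("integer", 4)))
  if (any(tab$i > norb | tab$j > norb | tab$k > norb | tab$l > norb) ||
      any(tab$i < 0 | tab$j < 0 | tab$k < 0 | tab$l < 0))
    stop("FCIDUMP index out of range 0..", norb)

  h <- matrix(0, norb, norb)
  g <- array(0, rep(norb, 4))
  e_core <- 0
  two <- tab$i > 0L & tab$j > 0L & tab$k > 0L & tab$l > 0L
  one <- tab$i > 0L & tab$j > 0L & tab$k == 0L & tab$l == 0L
  zero <- tab$i == 0L & tab$j == 0L & tab$k == 0L & tab$l == 0L
  orbe <- tab$i > 0L & tab$j == 0L    # orbital-energy records: ignored
  if (any(!(two | one | zero | orbe)))
    stop("FCIDUMP record with unsupported index pattern")
  if (any(zero)) e_core <- tab$val[which(zero)[sum(zero)]]
  for (r in which(one)) {
    h[tab$i[r], tab$j[r]] <- tab$val[r]
    h[tab$j[r], tab$i[r]] <- tab$val[r]
  }
  for (r in which(two)) {
    p <- tab$i[r]; q <- tab$j[r]; s <- tab$k[r]; t <- tab$l[r]; v <- tab$val[r]
    g[p, q, s, t] <- v; g[q, p, s, t] <- v; g[p, q, t, s] <- v; g[q, p, t, s] <- v
    g[s, t, p, q] <- v; g[t, s, p, q] <- v; g[s, t, q, p] <- v; g[t, s, q, p] <- v
  }
  molecular_integrals(h, g, e_core, n_alpha, n_beta,
                      label = basename(path))
}

#' Write a Molpro-style FCIDUMP file
#'
#' Emits only the canonical non-redundant integrals (`p >= q`,
#' `(pq) >= (rs)` in compound-index order) with absolute value above
#' `thresh`, 1-based indices, and the core energy on the trailing all-zero
#' index line.  `read_fcidump(write_fcidump(x))` reproduces `x` to 1e-12.
#'
#' @param integrals a [molecular_integrals()] object.
#' @param path output file path.
#' @param thresh entries with `|value| <= thresh` are omitted.
#' @return `path`, invisibly.
#' @export
write_fcidump <- function(integrals, path, thresh = 1e-12) {
  validate_integrals(integrals)
  n <- integrals$n_spatial
  nelec <- integrals$n_alpha + integrals$n_beta
  ms2 <- integrals$n_alpha - integrals$n_beta
  out <- c(sprintf(" &FCI NORB=%d,NELEC=%d,MS2=%d,", n, nelec, ms2),
           paste0("  ORBSYM=", paste(rep("1,", n), collapse = "")),
           "  ISYM=1,", " &END")
  fmt <- function(v, i, j, k, l) sprintf("%23.16e %3d %3d %3d %3d", v, i, j, k, l)
  for (p in seq_len(n)) for (q in seq_len(p)) {
    pq <- p * (p - 1L) / 2L + q
    for (r in seq_len(p)) for (s in seq_len(r)) {
      if (r * (r - 1L) / 2L + s > pq) next
      v <- integrals$g[p, q, r, s]
      if (abs(v) > thresh) out <- c(out, fmt(v, p, q, r, s))
    }
  }
  for (p in seq_len(n)) for (q in seq_len(p)) {
    if (abs(integrals$h[p, q]) > thresh)
      out <- c(out, fmt(integrals$h[p, q], p, q, 0L, 0L))
  }
  out <- c(out, fmt(integrals$e_core, 0L, 0L, 0L, 0L))
  tryCatch(writeLines(out, path),
           error = function(e) stop("cannot write FCIDUMP to ", path, ": ",
                                    conditionMessage(e)))
  invisible(path)
}

#' Locate a shipped FCIDUMP fixture
#'
#' The package ships STO-3G canonical-RHF integrals for the test molecules,
#' generated at packaging time by a standalone integral code
#' (`tools/make_fixtures.py` in the source repository; provenance in
#' `inst/extdata/fcidump/README`).
#'
#' @param molecule one of `"h2"`, `"lih"`, `"beh2"`, `"h6"`.
#' @param r bond length in Angstrom (for `h6` and `beh2`, the common
#'   adjacent-atom separation).
#' @return path to the FCIDUMP file; error if the geometry is not shipped.
#' @export
fixture_fcidump <- function(molecule, r) {
  tag <- sub("0+$", "", sprintf("%.4f", r))
  tag <- sub("\\.$", "", tag)
  f <- system.file("extdata", "fcidump",
                   sprintf("%s_%s.fcidump", tolower(molecule), tag),
                   package = "adaptvqe")
  if (!nzchar(f))
    stop(sprintf("no shipped FCIDUMP for %s at %s Angstrom", molecule, tag))
  f
}

#' Integral provider backed by the shipped FCIDUMP fixtures
#'
#' The integral source is a pluggable hook: any function
#' `(molecule, r) -> molecular_integrals` can drive [run_scan()].  This
#' default provider reads the packaged STO-3G fixtures.
#'
#' @param dir optional directory of FCIDUMP files named
#'   `<molecule>_<r>.fcidump`; defaults to the packaged fixtures.
#' @return a function `(molecule, r)` returning [molecular_integrals()].
#' @export
fcidump_provider <- function(dir = NULL) {
  function(molecule, r) {
    if (is.null(dir)) {
      read_fcidump(fixture_fcidump(molecule, r))
    } else {
      tag <- sub("\\.$", "", sub("0+$", "", sprintf("%.4f", r)))
      read_fcidump(file.path(dir, sprintf("%s_%s.fcidump", tolower(molecule), tag)))
    }
  }
}
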