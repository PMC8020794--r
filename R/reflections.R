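#' Reflection data set
#'
#' Unique Miller indices with amplitudes, optional sigmas and phases —
#' the currency of all reciprocal-space stages.
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer matrix (n x 3) of Miller indices.
#' @param f Amplitudes, electrons, >= 0.
#' @param sigf Optional amplitude sigmas (electrons, >= 0).
#' @param phi Optional phases in degrees.
#' @param d_min Resolution limit in Angstrom (computed from `hkl` when
#'   missing).
#' @param label Free-text provenance label.
#' @return Object of class `reflection_set` with a data frame `data`
#'   (columns h, k, l, f, sigf, phi) plus `cell`, `d_min`, `label`.
#' @export
reflection_set <- function(cell, hkl, f, sigf = NULL, phi = NULL,
                           d_min = NULL, label = "reflections") {
  stopifnot(is_unit_cell(cell))
  hkl <- rbind(hkl)
  storage.mode(hkl) <- "integer"
  n <- nrow(hkl)
  if (length(f) != n) stop("f length does not match hkl rows")
  if (any(f < 0)) stop("amplitudes must be >= 0")
  if (!is.null(sigf) && any(sigf < 0, na.rm = TRUE))
    stop("sigmas must be >= 0")
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key))
    stop("duplicate Miller indices (upstream merge failure): ",
         key[duplicated(key)][1])
  d <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3], f = f,
                  sigf = if (is.null(sigf)) NA_real_ else sigf,
                  phi = if (is.null(phi)) NA_real_ else phi)
  structure(list(cell = cell, data = d,
                 d_min = d_min %||% min(hkl_d(cell, hkl)), label = label),
            class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("reflection_set '%s': %d reflections to %.2f A%s%s\n",
              x$label, nrow(x$data), x$d_min,
              if (all(is.na(x$data$sigf))) "" else ", with sigmas",
              if (all(is.na(x$data$phi))) "" else ", with phases"))
  invisible(x)
}

hkl_matrix <- function(rs) as.matrix(rs$data[, c("h", "k", "l")])

hkl_key <- function(d) paste(d$h, d$k, d$l)

#' Complex structure factors
#'
#' @param cell A [unit_cell()].
#' @param hkl Integer matrix (n x 3).
#' @param f Complex vector of structure factors (electrons).
#' @param d_min Resolution limit (Angstrom).
#' @param label Provenance label.
#' @return Object of class `complex_sf`.
#' @export
complex_sf <- function(cell, hkl, f, d_min = NULL, label = "calc") {
  hkl <- rbind(hkl)
  storage.mode(hkl) <- "integer"
  stopifnot(length(f) == nrow(hkl), is.complex(f))
  key <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  if (anyDuplicated(key)) stop("duplicate Miller indices")
  structure(list(cell = cell, hkl = hkl, f = f,
                 d_min = d_min %||% min(hkl_d(cell, hkl)), label = label),
            class = "complex_sf")
}

#' @export
print.complex_sf <- function(x, ...) {
  cat(sprintf("complex_sf '%s': %d reflections to %.2f A\n",
              x$label, nrow(x$hkl), x$d_min))
  invisible(x)
}

#' Convert complex structure factors to an amplitude/phase reflection set
#'
#' @param sf A [complex_sf()].
#' @return A [reflection_set()] with amplitudes `Mod(F)` and phases
#'   `Arg(F)` in degrees.
#' @export
as_reflection_set <- function(sf) {
  stopifnot(inherits(sf, "complex_sf"))
  reflection_set(sf$cell, sf$hkl, Mod(sf$f), phi = Arg(sf$f) * 180 / pi,
                 d_min = sf$d_min, label = sf$label)
}

#' Read/write reflection data
#'
#' The TSV dialect is a header line `h k l F SIGF [PHI]` followed by one
#' reflection per row; it round-trips losslessly and needs no external
#' tooling.  MTZ files are read and written through the gemmi library via
#' the system Python (columns F, SIGF and optionally PHI).
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"`, or `"mtz"`.
#' @param cell Cell to attach when the format does not carry one (TSV);
#'   defaults to a placeholder cubic cell of 1 Angstrom if omitted.
#' @param label Label for the returned set.
#' @return A [reflection_set()].
#' @export
read_reflections <- function(path, format = c("auto", "tsv", "mtz"),
                             cell = NULL, label = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "mtz") "mtz" else "tsv"
  label <- label %||% tools::file_path_sans_ext(basename(path))
  if (format == "mtz") return(read_mtz_gemmi(path, label))
  # optional cell comment line "# cell a b c alpha beta gamma" above the
  # header; a caller-supplied cell takes precedence
  first <- readLines(path, n = 1)
  has_cell_line <- grepl("^#\\s*cell", first)
  cl <- cell
  if (has_cell_line) {
    v <- as.numeric(strsplit(trimws(sub("^#\\s*cell", "", first)),
                             "[[:space:]]+")[[1]])
    if (is.null(cl) && length(v) == 6 && !anyNA(v))
      cl <- unit_cell(v[1], v[2], v[3], v[4], v[5], v[6])
  }
  if (is.null(cl))
    stop("reflection file ", path, " carries no cell; pass `cell`")
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           skip = as.integer(has_cell_line))
  names(tab) <- toupper(names(tab))
  need <- c("H", "K", "L", "F")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0)
    stop("reflection file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  reflection_set(cl, as.matrix(tab[, c("H", "K", "L")]), tab$F,
                 sigf = if ("SIGF" %in% names(tab)) tab$SIGF else NULL,
                 phi = if ("PHI" %in% names(tab)) tab$PHI else NULL,
                 label = label)
}

#' @rdname read_reflections
#' @param rs A [reflection_set()] to write.
#' @export
write_reflections <- function(rs, path, format = c("auto", "tsv", "mtz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "mtz") "mtz" else "tsv"
  if (format == "mtz") return(write_mtz_gemmi(rs, path))
  d <- rs$data
  cols <- c("h", "k", "l", "f")
  hdr <- c("H", "K", "L", "F")
  if (!all(is.na(d$sigf))) { cols <- c(cols, "sigf"); hdr <- c(hdr, "SIGF") }
  if (!all(is.na(d$phi)))  { cols <- c(cols, "phi");  hdr <- c(hdr, "PHI") }
  out <- d[, cols]
  names(out) <- hdr
  cl <- rs$cell
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# cell %.6f %.6f %.6f %.6f %.6f %.6f",
                     cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma), con)
  utils::write.table(format(out, digits = 10, scientific = FALSE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_mtz_gemmi <- function(path, label) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  script <- paste(
    "import sys, gemmi",
    "m = gemmi.read_mtz_file(sys.argv[1])",
    "cols = [c.label for c in m.columns]",
    "want = ['H','K','L','F'] + (['SIGF'] if 'SIGF' in cols else []) + (['PHI'] if 'PHI' in cols else [])",
    "missing = [c for c in ['H','K','L','F'] if c not in cols]",
    "assert not missing, 'missing column(s): ' + ','.join(missing)",
    "import numpy as np",
    "arr = np.column_stack([m.column_with_label(c).array for c in want])",
    "u = m.cell",
    "with open(sys.argv[2], 'w') as fh:",
    "    fh.write('# cell %.6f %.6f %.6f %.6f %.6f %.6f\\n' % (u.a,u.b,u.c,u.alpha,u.beta,u.gamma))",
    "    fh.write('\\t'.join(want) + '\\n')",
    "    for row in arr:",
    "        fh.write('\\t'.join(('%d' % round(v)) if i < 3 else repr(float(v)) for i, v in enumerate(row)) + '\\n')",
    sep = "\n")
  run_python(script, c(path, tmp), "MTZ read")
  rs <- read_reflections(tmp, format = "tsv", label = label)
  rs
}

write_mtz_gemmi <- function(rs, path) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  write_reflections(rs, tmp, format = "tsv")
  has_sig <- !all(is.na(rs$data$sigf))
  has_phi <- !all(is.na(rs$data$phi))
  script <- paste(
    "import sys, gemmi, numpy as np",
    "tsv = open(sys.argv[1]).read().splitlines()",
    "cellv = [float(x) for x in tsv[0].split()[2:8]]",
    "hdr = tsv[1].split('\\t')",
    "rows = np.array([[float(x) for x in ln.split('\\t')] for ln in tsv[2:]])",
    "m = gemmi.Mtz(with_base=True)",
    "m.cell = gemmi.UnitCell(*cellv)",
    "m.spacegroup = gemmi.SpaceGroup('P 1')",
    "m.add_column('F', 'F')",
    sprintf("%s", if (has_sig) "m.add_column('SIGF', 'Q')" else "pass"),
    sprintf("%s", if (has_phi) "m.add_column('PHI', 'P')" else "pass"),
    "m.set_data(rows)",
    "m.write_to_file(sys.argv[2])",
    sep = "\n")
  run_python(script, c(tmp, path), "MTZ write")
  invisible(path)
}

run_python <- function(script, args, what) {
  py <- Sys.which("python")
  if (!nzchar(py)) stop(what, " requires a system python with gemmi")
  res <- suppressWarnings(system2(py, c("-c", shQuote(script), args),
                                  stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0) stop(what, " failed: ", paste(res, collapse = "\n"))
  invisible(res)
}
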