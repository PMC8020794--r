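#' Atomic model container
#'
#' Bundles a coordinate set with its unit cell and symmetry operations.
#' Atoms are stored as a data frame with one row per atom; row indices act
#' as atom ids throughout the geometry and map-attribution functions.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resname`, `atom`
#'   (atom name), `element`, `altloc` (NA when absent), `x`, `y`, `z`
#'   (orthogonal Angstrom), `occ` (0..1), `b` (Angstrom^2, >= 0).
#' @param cell A [unit_cell()].
#' @param symops List of symmetry operations, each `list(R = 3x3, t = len-3)`
#'   acting on fractional coordinates.  Default: identity only (P1).
#' @param label Free-text label, e.g. `"dark"` or `"1ps"`.
#' @param spacegroup Space-group symbol (bookkeeping only; operations are
#'   what the structure-factor code uses).
#' @return Object of class `atomic_model`.
#' @export
atomic_model <- function(atoms, cell, symops = NULL, label = "model",
                         spacegroup = "P 1") {
  stopifnot(is.data.frame(atoms), is_unit_cell(cell))
  need <- c("chain", "resno", "resname", "atom", "element", "x", "y", "z",
            "occ", "b")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) stop("atoms lacks column(s): ", paste(miss, collapse = ", "))
  if (!"altloc" %in% names(atoms)) atoms$altloc <- NA_character_
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancies must lie in [0, 1]")
  if (any(atoms$b < 0)) stop("B-factors must be >= 0")
  key <- paste(atoms$chain, atoms$resno, atoms$atom,
               ifelse(is.na(atoms$altloc), "", atoms$altloc))
  if (anyDuplicated(key))
    stop("duplicate (chain, resno, atom, altloc): ", key[duplicated(key)][1])
  if (is.null(symops)) symops <- list(list(R = diag(3), t = c(0, 0, 0)))
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, cell = cell, symops = symops,
                 label = label, spacegroup = spacegroup),
            class = "atomic_model")
}

#' @export
print.atomic_model <- function(x, ...) {
  cat(sprintf("atomic_model '%s': %d atoms, %d chains, %d symmetry op(s), %s\n",
              x$label, nrow(x$atoms), length(unique(x$atoms$chain)),
              length(x$symops), x$spacegroup))
  print(x$cell)
  invisible(x)
}

n_atoms <- function(model) nrow(model$atoms)

# n x 3 matrix of orthogonal coordinates for atom ids (default all)
atom_xyz <- function(model, ids = seq_len(nrow(model$atoms))) {
  as.matrix(model$atoms[ids, c("x", "y", "z"), drop = FALSE])
}

guess_element <- function(atom_name, resname) {
  nm <- toupper(trimws(atom_name))
  if (nm %in% c("CL", "CL-")) return("CL")
  first <- substr(gsub("[0-9']", "", nm), 1, 1)
  if (first %in% c("C", "N", "O", "S", "P", "H")) first else first
}

parse_cryst1 <- function(lines) {
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0) return(NULL)
  f <- cl[1]
  cell <- unit_cell(as.numeric(substr(f, 7, 15)), as.numeric(substr(f, 16, 24)),
                    as.numeric(substr(f, 25, 33)), as.numeric(substr(f, 34, 40)),
                    as.numeric(substr(f, 41, 47)), as.numeric(substr(f, 48, 54)))
  sg <- trimws(substr(f, 56, 66))
  list(cell = cell, spacegroup = if (nzchar(sg)) sg else "P 1")
}

parse_cif_cell <- function(lines) {
  getv <- function(tag) {
    ln <- grep(paste0("^_cell[._]", tag), lines, value = TRUE)
    if (length(ln) == 0) return(NA_real_)
    as.numeric(strsplit(trimws(ln[1]), "[[:space:]]+")[[1]][2])
  }
  v <- c(getv("length_a"), getv("length_b"), getv("length_c"),
         getv("angle_alpha"), getv("angle_beta"), getv("angle_gamma"))
  if (anyNA(v)) return(NULL)
  sgl <- grep("_symmetry.space_group_name_H-M|_space_group.name_H-M",
              lines, value = TRUE)
  sg <- if (length(sgl) > 0)
    gsub("['\"]", "", sub("^\\S+\\s+", "", trimws(sgl[1]))) else "P 1"
  list(cell = unit_cell(v[1], v[2], v[3], v[4], v[5], v[6]), spacegroup = sg)
}

#' Read an atomic model from PDB or mmCIF
#'
#' Parses coordinates with bio3d and attaches the unit cell (CRYST1 /
#' `_cell` items), which downstream structure-factor and map operations
#' require.  All ATOM and HETATM records are retained, including waters
#' and ions.
#'
#' @param path Path to a `.pdb` or `.cif` file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"mmcif"`.
#' @param label Label stored on the model; default the file base name.
#' @return An [atomic_model()].
#' @export
read_model <- function(path, format = c("auto", "pdb", "mmcif"),
                       label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                    error = function(e) stop("PDB parse error in ", path, ": ",
                                             conditionMessage(e)))
    hdr <- parse_cryst1(lines)
  } else {
    pdb <- tryCatch(suppressWarnings(bio3d::read.cif(path, verbose = FALSE)),
                    error = function(e) stop("mmCIF parse error in ", path, ": ",
                                             conditionMessage(e)))
    hdr <- parse_cif_cell(lines)
  }
  if (is.null(hdr))
    stop("no unit cell found in ", path,
         " (CRYST1 / _cell records are required)")
  a <- pdb$atom
  el <- a$elesy
  if (is.null(el)) el <- rep(NA_character_, nrow(a))
  el <- toupper(trimws(el))
  fix <- which(is.na(el) | el == "")
  if (length(fix) > 0)
    el[fix] <- vapply(seq_along(fix), function(i)
      guess_element(a$elety[fix[i]], a$resid[fix[i]]), character(1))
  atoms <- data.frame(
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resno = a$resno, resname = a$resid, atom = a$elety, element = el,
    altloc = a$alt, x = a$x, y = a$y, z = a$z,
    occ = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    stringsAsFactors = FALSE)
  atomic_model(atoms, hdr$cell, label = label %||% tools::file_path_sans_ext(basename(path)),
               spacegroup = hdr$spacegroup)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an atomic model as PDB
#'
#' Emits CRYST1 plus fixed-column ATOM/HETATM records readable by standard
#' tools (and by [read_model()]).
#'
#' @param model An [atomic_model()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  cl <- model$cell
  lines <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s%4d",
                   cl$a, cl$b, cl$c, cl$alpha, cl$beta, cl$gamma,
                   model$spacegroup, 1L)
  a <- model$atoms
  het <- !(a$resname %in% c(bio3d::aa.table$aa3, "RLY"))
  nm <- ifelse(nchar(a$atom) < 4, paste0(" ", a$atom), a$atom)
  recs <- sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  ifelse(het, "HETATM", "ATOM"), seq_len(nrow(a)), nm,
                  ifelse(is.na(a$altloc), " ", a$altloc), a$resname, a$chain,
                  a$resno, a$x, a$y, a$z, a$occ, a$b, a$element)
  writeLines(c(lines, recs, "END"), path)
  invisible(path)
}
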