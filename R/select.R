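#' Select atoms by a text expression
#'
#' A small, deterministic selector language for addressing atoms.  An
#' expression is a set of clauses joined by `and`; each clause is a keyword
#' followed by a comma-separated value list:
#'
#' * `chain A` — chain identifiers
#' * `resno 5` / `resi 5-10,12` — residue numbers and ranges
#' * `resname RLY,HOH` — residue names
#' * `name C12,C13` — atom names
#' * `element CL` — element symbols
#' * `altloc A` — a specific alternate-location indicator
#' * `water` — water residues (HOH/WAT)
#' * `all` — every atom
#'
#' Unless an `altloc` clause is given, alternate conformers are reduced to
#' the highest-occupancy one per (chain, residue, atom name); ties keep the
#' alphabetically first altloc.  The result preserves atom (row) order, so
#' selections are order-stable.  An empty result is valid.
#'
#' @param model An [atomic_model()].
#' @param selector Selector string.
#' @return Integer vector of atom ids (row indices into `model$atoms`).
#' @examples
#' \dontrun{
#' select_atoms(dark, "resname RLY and name C12,C13,C14,C15")
#' select_atoms(dark, "element CL")
#' }
#' @export
select_atoms <- function(model, selector) {
  stopifnot(inherits(model, "atomic_model"))
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  sel <- trimws(selector)
  if (!nzchar(sel)) stop("empty selector")
  clauses <- trimws(strsplit(sel, "\\s+and\\s+")[[1]])
  saw_altloc <- FALSE
  for (cl in clauses) {
    toks <- strsplit(cl, "\\s+")[[1]]
    kw <- tolower(toks[1])
    val <- if (length(toks) > 1) paste(toks[-1], collapse = "") else ""
    vals <- toupper(strsplit(val, ",")[[1]])
    keep <- keep & switch(kw,
      all = rep(TRUE, nrow(a)),
      water = toupper(a$resname) %in% c("HOH", "WAT", "H2O"),
      chain = toupper(a$chain) %in% vals,
      resname = toupper(a$resname) %in% vals,
      name = toupper(a$atom) %in% vals,
      element = , elem = toupper(a$element) %in% vals,
      resno = , resi = a$resno %in% parse_resno(vals),
      altloc = { saw_altloc <- TRUE
                 toupper(ifelse(is.na(a$altloc), "", a$altloc)) %in% vals },
      stop("invalid selector clause: '", cl, "'")
    )
  }
  ids <- which(keep)
  if (!saw_altloc) ids <- drop_alt_conformers(a, ids)
  ids
}

parse_resno <- function(vals) {
  out <- integer(0)
  for (v in vals) {
    if (grepl("^-?[0-9]+--?[0-9]+$", v)) {
      m <- regmatches(v, regexec("^(-?[0-9]+)-(-?[0-9]+)$", v))[[1]]
      out <- c(out, as.integer(m[2]):as.integer(m[3]))
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else stop("invalid residue number or range: '", v, "'")
  }
  out
}

# keep, per (chain, resno, atom name), the highest-occupancy altloc
drop_alt_conformers <- function(atoms, ids) {
  if (length(ids) == 0) return(ids)
  sub <- atoms[ids, ]
  key <- paste(sub$chain, sub$resno, sub$atom)
  if (!anyDuplicated(key)) return(ids)
  ord <- order(key, -sub$occ, ifelse(is.na(sub$altloc), "", sub$altloc))
  first <- !duplicated(key[ord])
  sort(ids[ord][first])
}

# Resolve an atom reference to exactly one atom id.  Accepts an integer id
# or a selector string that matches a single atom.
resolve_atom <- function(model, ref) {
  if (is.numeric(ref) && length(ref) == 1) {
    id <- as.integer(ref)
    if (id < 1 || id > nrow(model$atoms)) stop("atom id out of range: ", ref)
    return(id)
  }
  ids <- select_atoms(model, ref)
  if (length(ids) != 1)
    stop("atom reference '", ref, "' matched ", length(ids),
         " atoms (need exactly 1)")
  ids
}

# a numeric vector of ids, one selector string, or a character vector of
# selector strings (union of their matches)
resolve_selection <- function(model, sel) {
  if (is.numeric(sel)) {
    ids <- as.integer(sel)
    if (any(ids < 1 | ids > nrow(model$atoms))) stop("atom id out of range")
    return(ids)
  }
  sort(unique(unlist(lapply(sel, function(s) select_atoms(model, s)))))
}
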