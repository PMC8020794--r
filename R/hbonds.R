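#' Identify and classify hydrogen bonds from heavy-atom geometry
#'
#' Donor-acceptor pairs are screened on distance and on the angle at the
#' donor between its bonded heavy-atom antecedent(s) and the acceptor
#' (hydrogen positions are not required).  Pairs meeting the strict
#' cutoffs are classified `stable`; pairs meeting the cutoffs widened by
#' the slop values but failing the strict ones are `relaxed`.  Cutoffs are
#' inclusive.  Donors are N and O atoms bearing at least one polar proton
#' in common residues (all N; hydroxyl/water O); acceptors are N, O, S and
#' halide ions (the chloride substrate of an anion pump counts as an
#' acceptor).  Donors with no resolvable antecedent (waters, ions) pass
#' the angle test by construction.
#'
#' @param model An [atomic_model()].
#' @param strict_dist Strict donor-acceptor distance cutoff, Angstrom
#'   (default 3.3).
#' @param strict_angle Strict antecedent-donor-acceptor angle cutoff,
#'   degrees (default 120).
#' @param dist_slop Added to `strict_dist` for the relaxed class
#'   (default 0.4).
#' @param angle_slop Subtracted from `strict_angle` for the relaxed class
#'   (default 20).
#' @param selection Optional selection restricting candidate atoms.
#' @return Data frame of class `hbond_table`: donor/acceptor ids and
#'   descriptions, distance (Angstrom), donor angle (degrees, NA when no
#'   antecedent), and `klass` in `{stable, relaxed}`.  Rows are ordered by
#'   donor id then acceptor id (deterministic).  Pairs that meet neither
#'   set of cutoffs are omitted.
#' @export
hydrogen_bonds <- function(model, strict_dist = 3.3, strict_angle = 120,
                           dist_slop = 0.4, angle_slop = 20,
                           selection = NULL) {
  a <- model$atoms
  ids <- if (is.null(selection)) seq_len(nrow(a)) else
    resolve_selection(model, selection)
  el <- toupper(a$element)
  is_water <- toupper(a$resname) %in% c("HOH", "WAT", "H2O")
  hydroxyl <- toupper(a$atom) %in% c("OG", "OG1", "OH", "OW", "O")
  donor <- ids[el[ids] == "N" | (el[ids] == "O" & (is_water[ids] | hydroxyl[ids]))]
  accept <- ids[el[ids] %in% c("N", "O", "S", "CL", "F", "BR", "I")]
  if (length(donor) == 0 || length(accept) == 0)
    return(empty_hbond_table())
  xyz <- atom_xyz(model)
  loose_dist <- strict_dist + dist_slop
  loose_angle <- strict_angle - angle_slop
  rows <- list()
  for (d in donor) {
    dv <- sweep(xyz[accept, , drop = FALSE], 2, xyz[d, ])
    dist <- sqrt(rowSums(dv^2))
    cand <- which(dist <= loose_dist & dist > 1.8 & accept != d)
    if (length(cand) == 0) next
    ante <- donor_antecedents(model, xyz, d)
    for (i in cand) {
      acc <- accept[i]
      ang <- donor_angle(xyz, d, acc, ante)
      eps <- 1e-9                      # cutoffs are inclusive
      ang_ok_strict <- is.na(ang) || ang >= strict_angle - eps
      ang_ok_loose <- is.na(ang) || ang >= loose_angle - eps
      klass <- if (dist[i] <= strict_dist + eps && ang_ok_strict) "stable"
               else if (ang_ok_loose) "relaxed" else NA_character_
      if (is.na(klass)) next
      rows[[length(rows) + 1]] <- data.frame(
        donor = d, acceptor = acc,
        donor_desc = atom_key(model, d), acceptor_desc = atom_key(model, acc),
        distance = dist[i], angle = ang, klass = klass,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty_hbond_table())
  out <- do.call(rbind, rows)
  # a pair where both partners can donate would appear twice; keep one
  # row per atom pair, preferring the better-classified direction
  pair <- paste(pmin(out$donor, out$acceptor),
                pmax(out$donor, out$acceptor))
  out <- out[order(pair, out$klass != "stable", out$donor), ]
  out <- out[!duplicated(paste(pmin(out$donor, out$acceptor),
                               pmax(out$donor, out$acceptor))), ]
  out <- out[order(out$donor, out$acceptor), ]
  rownames(out) <- NULL
  class(out) <- c("hbond_table", class(out))
  out
}

empty_hbond_table <- function() {
  out <- data.frame(donor = integer(0), acceptor = integer(0),
                    donor_desc = character(0), acceptor_desc = character(0),
                    distance = numeric(0), angle = numeric(0),
                    klass = character(0), stringsAsFactors = FALSE)
  class(out) <- c("hbond_table", class(out))
  out
}

# heavy atoms covalently bonded to the donor (same residue, < 1.8 A)
donor_antecedents <- function(model, xyz, d) {
  a <- model$atoms
  same <- which(a$chain == a$chain[d] & a$resno == a$resno[d])
  same <- setdiff(same, d)
  if (length(same) == 0) return(integer(0))
  dv <- sweep(xyz[same, , drop = FALSE], 2, xyz[d, ])
  same[sqrt(rowSums(dv^2)) < 1.8]
}

# widest antecedent-donor-acceptor angle; NA when no antecedent
donor_angle <- function(xyz, d, acc, ante) {
  if (length(ante) == 0) return(NA_real_)
  va <- xyz[acc, ] - xyz[d, ]
  angs <- vapply(ante, function(x) {
    vx <- xyz[x, ] - xyz[d, ]
    ct <- sum(vx * va) / sqrt(sum(vx^2) * sum(va^2))
    acos(max(-1, min(1, ct))) * 180 / pi
  }, numeric(1))
  max(angs)
}
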