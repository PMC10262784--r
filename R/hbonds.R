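# Geometric hydrogen-bond detection between atom selections.
# Chemistry table (N/O heavy atoms only, no pKa logic):
.donor_atoms <- list(
  backbone = "N",
  SER = "OG", THR = "OG1", TYR = "OH", LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
  TRP = "NE1", ASN = "ND2", GLN = "NE2")
.acceptor_atoms <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH", HIS = c("ND1", "NE2"))

.side_chain_role <- function(at, table) {
  if (nrow(at) == 0) return(logical(0))
  mapply(function(rn, an) an %in% (table[[rn]] %||% character()),
         at$residue_name, at$atom_name, USE.NAMES = FALSE)
}
.is_donor <- function(at) {
  (at$atom_name == "N" & at$residue_name != "PRO") |
    .side_chain_role(at, .donor_atoms)
}
.is_acceptor <- function(at) {
  at$atom_name %in% .acceptor_atoms$backbone |
    .side_chain_role(at, .acceptor_atoms)
}

#' Hydrogen-bond criteria
#'
#' Defaults: donor-acceptor distance <= 3.5 A and, when a hydrogen is
#' attached to the donor, D-H...A deviation from linearity <= 30 degrees.
#' On heavy-atom-only structures the distance criterion alone applies.
#'
#' @param max_da_distance maximum donor-acceptor heavy-atom distance (A)
#' @param max_dha_angle_dev maximum deviation of D-H...A from 180 (degrees)
#' @return an `hbond_criteria` list
#' @export
hbond_criteria <- function(max_da_distance = 3.5, max_dha_angle_dev = 30) {
  if (max_da_distance <= 0) stop("max_da_distance must be > 0")
  if (max_dha_angle_dev < 0 || max_dha_angle_dev > 180)
    stop("max_dha_angle_dev must be in [0, 180]")
  structure(list(max_da_distance = max_da_distance,
                 max_dha_angle_dev = max_dha_angle_dev),
            class = "hbond_criteria")
}

# hydrogens covalently attached to a donor: same residue, within 1.2 A
.attached_h <- function(at, xyz, donor_idx) {
  hs <- which(at$element == "H" &
                at$chain_id == at$chain_id[donor_idx] &
                at$residue_index == at$residue_index[donor_idx])
  if (!length(hs)) return(integer())
  d <- sqrt(rowSums((xyz[hs, , drop = FALSE] -
                       matrix(xyz[donor_idx, ], length(hs), 3,
                              byrow = TRUE))^2))
  hs[d <= 1.2]
}

#' Detect hydrogen bonds in one frame
#'
#' Reports donor-acceptor pairs satisfying the geometric criteria: distance
#' `<= max_da_distance`, and (when the donor carries a hydrogen) at least
#' one D-H...A geometry within `max_dha_angle_dev` of linear.  Donors are
#' N/O heavy atoms from the documented chemistry table inside the donor
#' selection; acceptors likewise.  Pairs within one residue are skipped.
#' Output is ordered by (donor serial, acceptor serial).
#'
#' @param frame an [md_structure]
#' @param donors,acceptors `md_selection`s or selection strings
#' @param criteria an [hbond_criteria]
#' @return data.frame with donor/acceptor identifiers, `distance` (A) and
#'   `angle_dev` (degrees; NA in heavy-atom-only mode)
#' @export
detect_hbonds <- function(frame, donors, acceptors,
                          criteria = hbond_criteria()) {
  stopifnot(inherits(frame, "md_structure"),
            inherits(criteria, "hbond_criteria"))
  if (is.character(donors)) donors <- resolve_selection(frame, donors)
  if (is.character(acceptors)) acceptors <- resolve_selection(frame, acceptors)
  at <- frame$atoms; xyz <- frame$xyz
  di <- donors$indices[.is_donor(at[donors$indices, , drop = FALSE])]
  ai <- acceptors$indices[.is_acceptor(at[acceptors$indices, , drop = FALSE])]
  rows <- list()
  for (d in di) {
    if (!length(ai)) break
    dv <- sqrt(rowSums((xyz[ai, , drop = FALSE] -
                          matrix(xyz[d, ], length(ai), 3, byrow = TRUE))^2))
    cand <- ai[dv <= criteria$max_da_distance]
    cand <- cand[!(at$chain_id[cand] == at$chain_id[d] &
                     at$residue_index[cand] == at$residue_index[d])]
    if (!length(cand)) next
    hs <- .attached_h(at, xyz, d)
    for (a in cand) {
      dist <- .norm(xyz[a, ] - xyz[d, ])
      dev <- NA_real_
      if (length(hs)) {
        devs <- vapply(hs, function(h)
          180 - .bond_angle(xyz[d, ], xyz[h, ], xyz[a, ]), numeric(1))
        dev <- min(devs)
        if (dev > criteria$max_dha_angle_dev) next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        donor_serial = at$serial[d], donor_chain = at$chain_id[d],
        donor_residue = at$residue_index[d], donor_atom = at$atom_name[d],
        acceptor_serial = at$serial[a], acceptor_chain = at$chain_id[a],
        acceptor_residue = at$residue_index[a],
        acceptor_atom = at$atom_name[a],
        distance = dist, angle_dev = dev, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor_serial = integer(), donor_chain = character(),
               donor_residue = integer(), donor_atom = character(),
               acceptor_serial = integer(), acceptor_chain = character(),
               acceptor_residue = integer(), acceptor_atom = character(),
               distance = numeric(), angle_dev = numeric(),
               stringsAsFactors = FALSE)
  out[order(out$donor_serial, out$acceptor_serial), , drop = FALSE]
}

#' Per-frame hydrogen-bond counts between two selections
#'
#' Counts, for every frame, bonds with the donor in `sel_A` and acceptor in
#' `sel_B` plus bonds in the opposite direction (e.g. a kinase insertion
#' loop against the bound substrate).
#'
#' @param traj an [md_trajectory]
#' @param sel_A,sel_B `md_selection`s or selection strings
#' @param criteria an [hbond_criteria]
#' @return integer vector of per-frame bond counts
#' @export
hbond_count_series <- function(traj, sel_A, sel_B,
                               criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "md_trajectory"))
  if (is.character(sel_A)) sel_A <- resolve_selection(traj$topology, sel_A)
  if (is.character(sel_B)) sel_B <- resolve_selection(traj$topology, sel_B)
  vapply(seq_len(n_frames(traj)), function(f) {
    fr <- get_frame(traj, f)
    nrow(detect_hbonds(fr, sel_A, sel_B, criteria)) +
      nrow(detect_hbonds(fr, sel_B, sel_A, criteria))
  }, numeric(1))
}
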