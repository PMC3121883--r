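# Geometric detection of polar contacts (hydrogen bonds, salt bridges) and
# per-pair occupancy over a trajectory.  Criteria are plain literature
# defaults, all exposed as parameters:
#   hbond:      donor-acceptor heavy-atom distance <= 3.5 A and, when the
#               donor hydrogen is present, donor-H-acceptor angle >= 120 deg
#               (distance-only fallback is flagged when H is absent);
#   saltbridge: minimum distance between opposing charged-group heavy atoms
#               <= 4.0 A (Arg/Lys/His+ N vs Asp/Glu/pSer/C-terminal O-).
# Phosphoserine is accepted under residue names SEP or PSE with its
# phosphate oxygens as anionic atoms.

#' Default contact criteria
#'
#' @param d_hbond donor-acceptor heavy-atom cutoff, Angstrom.
#' @param angle_hbond minimum donor-H-acceptor angle, degrees.
#' @param d_saltbridge charged-group heavy-atom cutoff, Angstrom.
#' @return A named list of criteria.
#' @export
contact_params <- function(d_hbond = 3.5, angle_hbond = 120,
                           d_saltbridge = 4.0) {
  list(d_hbond = d_hbond, angle_hbond = angle_hbond,
       d_saltbridge = d_saltbridge)
}

# side-chain donor / acceptor / charged-atom tables by residue name
.polar_tables <- local({
  donors <- list(
    ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"),
    ASN = "ND2", GLN = "NE2", SER = "OG", THR = "OG1", TYR = "OH",
    TRP = "NE1", CYS = "SG", SEP = "OG", PSE = "OG")
  acceptors <- list(
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
    GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
    HIS = c("ND1", "NE2"), MET = "SD",
    SEP = c("O1P", "O2P", "O3P", "OP1", "OP2", "OP3"),
    PSE = c("O1P", "O2P", "O3P", "OP1", "OP2", "OP3"))
  cations <- list(
    ARG = c("NE", "NH1", "NH2"), LYS = "NZ", HIS = c("ND1", "NE2"))
  anions <- list(
    ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
    SEP = c("O1P", "O2P", "O3P", "OP1", "OP2", "OP3"),
    PSE = c("O1P", "O2P", "O3P", "OP1", "OP2", "OP3"))
  list(donors = donors, acceptors = acceptors,
       cations = cations, anions = anions)
})

polar_atoms <- function(topology, table) {
  rows <- lapply(seq_len(nrow(topology)), function(i) {
    res <- topology$residue_name[i]
    nm <- topology$name[i]
    hit <- !is.null(table[[res]]) && nm %in% table[[res]]
    # backbone N donates, backbone O (and OXT) accepts, in any residue
    if (identical(table, .polar_tables$donors) && nm == "N") hit <- TRUE
    if (identical(table, .polar_tables$acceptors) && nm %in% c("O", "OXT"))
      hit <- TRUE
    # C-terminal carboxylate (O, OXT) is anionic
    if (identical(table, .polar_tables$anions) && nm == "OXT") hit <- TRUE
    if (hit) i else NULL
  })
  unlist(rows)
}

residue_key <- function(topology, i) {
  sprintf("%s/%s%d", topology$chain_id[i], topology$residue_name[i],
          topology$residue_id[i])
}

#' Detect hydrogen bonds and salt bridges over a trajectory
#'
#' Per-frame geometric detection plus per-pair occupancy fractions.
#' Pairs within the same residue are skipped.  When donor hydrogens are
#' absent from the topology, hydrogen bonds fall back to the distance
#' criterion alone and are flagged (`angle_checked = FALSE`).  Residues with
#' no entry in the charged-group tables are silently outside the salt-bridge
#' search (a warning lists unknown residue names once).
#'
#' @param traj a [trajectory()].
#' @param params criteria from [contact_params()].
#' @param kinds subset of `c("hbond", "saltbridge")`.
#' @return A list with `records` (one row per contact per frame: kind,
#'   donor/cation and acceptor/anion atom identifiers, distance, angle,
#'   frame) and `occupancy` (one row per residue pair and kind with the
#'   fraction of frames in which the contact is present).
#' @export
detect_contacts <- function(traj, params = contact_params(),
                            kinds = c("hbond", "saltbridge")) {
  stopifnot(inherits(traj, "pepmd_trajectory"))
  top <- traj$topology
  nf <- n_frames(traj)
  tabs <- .polar_tables
  known <- unique(c(names(tabs$donors), names(tabs$acceptors),
                    names(tabs$cations), names(tabs$anions),
                    "GLY", "ALA", "VAL", "LEU", "ILE", "PRO", "PHE"))
  unk <- setdiff(unique(top$residue_name), known)
  if (length(unk))
    warning("residues outside the polar tables skipped for side-chain ",
            "contacts: ", paste(unk, collapse = ", "), call. = FALSE)

  has_h <- any(top$element == "H")
  recs <- list()
  for (f in seq_len(nf)) {
    xyz <- traj_frame(traj, f)
    if ("hbond" %in% kinds) {
      don <- polar_atoms(top, tabs$donors)
      acc <- polar_atoms(top, tabs$acceptors)
      for (d in don) for (a in acc) {
        if (top$residue_id[d] == top$residue_id[a] &&
            top$chain_id[d] == top$chain_id[a]) next
        dist <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
        if (dist > params$d_hbond) next
        ang <- NA_real_; ok <- TRUE
        if (has_h) {
          h <- donor_hydrogen(top, xyz, d)
          if (!is.na(h)) {
            ang <- angle_deg(xyz[d, ], xyz[h, ], xyz[a, ])
            ok <- ang >= params$angle_hbond
          }
        }
        if (ok)
          recs[[length(recs) + 1]] <- data.frame(
            kind = "hbond", from = residue_key(top, d),
            from_atom = top$name[d], to = residue_key(top, a),
            to_atom = top$name[a], distance = dist, angle = ang,
            angle_checked = has_h && !is.na(ang), frame = f,
            stringsAsFactors = FALSE)
      }
    }
    if ("saltbridge" %in% kinds) {
      cat_i <- polar_atoms(top, tabs$cations)
      ani_i <- polar_atoms(top, tabs$anions)
      for (ci in cat_i) for (ai in ani_i) {
        if (top$residue_id[ci] == top$residue_id[ai] &&
            top$chain_id[ci] == top$chain_id[ai]) next
        dist <- sqrt(sum((xyz[ci, ] - xyz[ai, ])^2))
        if (dist <= params$d_saltbridge)
          recs[[length(recs) + 1]] <- data.frame(
            kind = "saltbridge", from = residue_key(top, ci),
            from_atom = top$name[ci], to = residue_key(top, ai),
            to_atom = top$name[ai], distance = dist, angle = NA_real_,
            angle_checked = NA, frame = f, stringsAsFactors = FALSE)
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(kind = character(), from = character(),
               from_atom = character(), to = character(),
               to_atom = character(), distance = numeric(),
               angle = numeric(), angle_checked = logical(),
               frame = integer(), stringsAsFactors = FALSE)
  occupancy <- if (nrow(records)) {
    # a residue pair counts once per frame regardless of how many atom
    # pairs satisfy the criterion
    u <- unique(records[, c("kind", "from", "to", "frame")])
    agg <- aggregate(frame ~ kind + from + to, data = u, FUN = length)
    names(agg)[names(agg) == "frame"] <- "n_frames_present"
    agg$occupancy <- agg$n_frames_present / nf
    agg[order(-agg$occupancy), ]
  } else {
    data.frame(kind = character(), from = character(), to = character(),
               n_frames_present = integer(), occupancy = numeric())
  }
  list(records = records, occupancy = occupancy)
}

donor_hydrogen <- function(topology, xyz, d, max_dh = 1.3) {
  h_idx <- which(topology$element == "H" &
                 topology$residue_id == topology$residue_id[d] &
                 topology$chain_id == topology$chain_id[d])
  if (!length(h_idx)) return(NA_integer_)
  dists <- sqrt(rowSums((xyz[h_idx, , drop = FALSE] -
                         matrix(xyz[d, ], length(h_idx), 3, byrow = TRUE))^2))
  cand <- h_idx[dists <= max_dh]
  if (!length(cand)) return(NA_integer_)
  cand[which.min(dists[dists <= max_dh])]
}

angle_deg <- function(a, b, c) {
  v1 <- a - b; v2 <- c - b
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}
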