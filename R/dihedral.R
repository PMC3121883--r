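# Inter-domain orientation dihedral: the signed torsion through the two
# domain mass centers and the two hinge atoms at the dimer interface
# (MC1 - hinge1 - hinge2 - MC2).

#' Signed dihedral angle through four points
#'
#' IUPAC convention: right-handed, cis = 0 degrees, range (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 numeric vectors (Angstrom).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-12 || sqrt(sum(b2^2)) < 1e-12 ||
      sqrt(sum(b3^2)) < 1e-12)
    stop("zero-length bond vector in dihedral", call. = FALSE)
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Inter-domain orientation dihedral of a two-domain structure
#'
#' Computes the mass-weighted centers MC1, MC2 of the two domain selections
#' and returns the signed dihedral over (MC1, hinge1, hinge2, MC2).  Used to
#' follow the relative orientation of two domains joined at a hinge (for a
#' domain-swapped PDZ dimer: the Calpha atoms of the interface residue in
#' each protomer serve as hinges).
#'
#' @param frame `n_atoms x 3` coordinate matrix.
#' @param topology the matching topology (for selection resolution and
#'   masses).
#' @param dom1_sel,dom2_sel selections (or indices) defining the two
#'   domains.
#' @param hinge1,hinge2 single atom indices, or selections resolving to one
#'   atom each.
#' @return Signed dihedral in degrees, range (-180, 180].
#' @export
interdomain_dihedral <- function(frame, topology, dom1_sel, dom2_sel,
                                 hinge1, hinge2) {
  i1 <- resolve_selection(dom1_sel, topology)
  i2 <- resolve_selection(dom2_sel, topology)
  h1 <- resolve_selection(hinge1, topology)
  h2 <- resolve_selection(hinge2, topology)
  if (length(h1) != 1 || length(h2) != 1)
    stop("hinge selections must resolve to exactly one atom", call. = FALSE)
  w1 <- topology$mass[i1]; w2 <- topology$mass[i2]
  mc1 <- colSums(frame[i1, , drop = FALSE] * w1) / sum(w1)
  mc2 <- colSums(frame[i2, , drop = FALSE] * w2) / sum(w2)
  dihedral_angle(mc1, frame[h1, ], frame[h2, ], mc2)
}

#' Inter-domain dihedral time series over a trajectory
#'
#' @inheritParams interdomain_dihedral
#' @param traj a [trajectory()].
#' @return A `data.frame` with columns `frame`, `time_ps`, `dihedral_deg`.
#' @export
interdomain_dihedral_series <- function(traj, dom1_sel, dom2_sel,
                                        hinge1, hinge2) {
  stopifnot(inherits(traj, "pepmd_trajectory"))
  vals <- vapply(seq_len(n_frames(traj)), function(f)
    interdomain_dihedral(traj_frame(traj, f), traj$topology,
                         dom1_sel, dom2_sel, hinge1, hinge2),
    numeric(1))
  data.frame(frame = seq_len(n_frames(traj)), time_ps = traj$times,
             dihedral_deg = vals)
}
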