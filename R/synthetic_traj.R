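# Ground-truth synthetic trajectories: a peptide interconverting among a
# small set of distinct bound conformations (Markov labels + isotropic
# Gaussian positional noise), and rigid two-domain geometries with an
# exactly known inter-domain dihedral.

#' Idealized multi-conformation peptide references
#'
#' Builds `n_states` reference conformations of one peptide chain over an
#' identical topology.  The backbone (N, CA, C per residue) follows simple
#' parametric motifs (extended, hairpin, L-shape, V-shape); by construction
#' the last `n_anchor` residues are identical across states (the bound
#' C-terminal anchor), while the upstream part diverges by several
#' Angstrom, so that a fit on the C-terminal anchor followed by a
#' whole-backbone RMSD separates the states cleanly.
#'
#' @param n_states number of conformational states (1..4).
#' @param n_residues residues in the peptide (default 9).
#' @param chain_id chain identifier (default "P").
#' @param n_anchor C-terminal residues shared across states (default 3).
#' @return A list with `topology` and `frames` (list of `n_atoms x 3`
#'   matrices, one per state).
#' @export
reference_conformations <- function(n_states, n_residues = 9,
                                    chain_id = "P", n_anchor = 3) {
  stopifnot(n_states >= 1, n_states <= 4, n_residues > n_anchor)
  resnames <- rep(c("ALA", "GLY", "SER", "LEU", "ASP", "ARG", "GLU",
                    "VAL", "THR", "ASN", "ILE", "LYS"),
                  length.out = n_residues)
  top <- atom_topology(
    name = rep(c("N", "CA", "C"), n_residues),
    residue_name = rep(resnames, each = 3),
    residue_id = rep(seq_len(n_residues), each = 3),
    chain_id = rep(chain_id, 3 * n_residues))

  # CA trace generators; the chain runs N->C, the last n_anchor residues
  # form the C-terminal anchor placed identically in all motifs.  The
  # anchor zig-zags in three dimensions so that a least-squares fit on it
  # is rotationally well conditioned, and the free part of every motif
  # follows a compact circular arc (short lever arms keep fit-noise
  # amplification of the whole-backbone RMSD small).
  spacing <- 3.8
  anchor_ca <- t(vapply(seq_len(n_anchor), function(k)
    c((k - 1) * 3.0, 2.5 * (-1)^(k - 1), (k - 1) * 2.5), numeric(3)))
  motif_ca <- function(state, nfree) {
    arc_r <- max(nfree * spacing / (2 * pi), spacing / 2)
    p0 <- c(-3.5, 1.0, -1.0)           # ~3.8 A before the first anchor CA
    u <- c(-1, 0, 0)                   # initial chain direction
    v <- switch(state,                 # arc-plane normal offset per motif
                c(0, 1, 0),            # hairpin: curls up over the anchor
                c(0, -1, 0),           # L-shape: curls below
                c(0, 0, 1),            # extended-arc: gentle out-of-plane
                c(0, 0, -1))           # V-shape: opposite out-of-plane
    t(vapply(seq_len(nfree), function(k) {
      theta <- (nfree - k + 1) * spacing / arc_r
      p0 + arc_r * sin(theta) * u + arc_r * (1 - cos(theta)) * v
    }, numeric(3)))
  }
  frames <- lapply(seq_len(n_states), function(s) {
    nfree <- n_residues - n_anchor
    ca <- rbind(motif_ca(s, nfree), anchor_ca)
    # decorate each CA with N and C at fixed offsets along the local chain
    # direction; crude, but geometrically valid for fitting and RMSD
    xyz <- matrix(NA_real_, 3 * n_residues, 3)
    for (r in seq_len(n_residues)) {
      dirv <- if (r < n_residues) ca[r + 1, ] - ca[r, ] else ca[r, ] - ca[r - 1, ]
      dirv <- dirv / sqrt(sum(dirv^2))
      perp <- cross3(dirv, c(0, 0, 1))
      if (sqrt(sum(perp^2)) < 1e-6) perp <- cross3(dirv, c(0, 1, 0))
      perp <- perp / sqrt(sum(perp^2))
      xyz[3 * r - 2, ] <- ca[r, ] - 1.46 * dirv + 0.8 * perp   # N
      xyz[3 * r - 1, ] <- ca[r, ]                              # CA
      xyz[3 * r, ]     <- ca[r, ] + 1.52 * dirv - 0.8 * perp   # C
    }
    xyz
  })
  list(topology = top, frames = frames)
}

#' Specification for a multi-state synthetic trajectory
#'
#' @param reference_frames list of `n_atoms x 3` matrices, one per state,
#'   over a common topology.
#' @param topology the shared topology.
#' @param stationary_populations state probabilities summing to 1.
#' @param transition_matrix row-stochastic matrix whose stationary vector is
#'   `stationary_populations`; default: every row equals the stationary
#'   vector (independent labels), which trivially satisfies the
#'   stationarity requirement and makes binomial sampling theory exact.
#' @param noise_sigma isotropic per-coordinate Gaussian displacement sd,
#'   Angstrom.
#' @param n_frames frames to generate.
#' @param dt frame spacing, ps.
#' @param seed integer RNG seed.
#' @return A `pepmd_multistate_spec` (validated).
#' @export
multistate_spec <- function(reference_frames, topology,
                            stationary_populations,
                            transition_matrix = NULL,
                            noise_sigma = 0.3, n_frames = 1000, dt = 1,
                            seed = 1L) {
  k <- length(reference_frames)
  stopifnot(k >= 1, length(stationary_populations) == k,
            abs(sum(stationary_populations) - 1) < 1e-9,
            all(stationary_populations > 0),
            noise_sigma >= 0, n_frames >= 1, dt > 0)
  if (is.null(transition_matrix))
    transition_matrix <- matrix(stationary_populations, k, k, byrow = TRUE)
  if (!is.matrix(transition_matrix) || any(dim(transition_matrix) != k) ||
      any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-12))
    stop("transition_matrix must be row-stochastic over the states",
         call. = FALSE)
  statdev <- max(abs(as.numeric(stationary_populations %*% transition_matrix) -
                     stationary_populations))
  if (statdev > 1e-9)
    stop("stationary_populations is not the stationary vector of ",
         "transition_matrix (deviation ", format(statdev), ")",
         call. = FALSE)
  if (k > 1 && noise_sigma > 0) {
    # separability: inter-state backbone RMSD must exceed 3 * noise_sigma
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      r <- rmsd(reference_frames[[i]], reference_frames[[j]], fit = TRUE)
      if (r <= 3 * noise_sigma)
        stop(sprintf(
          "states %d and %d are not separable: RMSD %.3f A <= 3 * sigma",
          i, j, r), call. = FALSE)
    }
  }
  structure(list(reference_frames = reference_frames, topology = topology,
                 stationary_populations = stationary_populations,
                 transition_matrix = transition_matrix,
                 noise_sigma = noise_sigma, n_frames = as.integer(n_frames),
                 dt = dt, seed = as.integer(seed)),
            class = "pepmd_multistate_spec")
}

#' Generate a multi-state synthetic trajectory
#'
#' Frame t is `reference_frames[[s_t]]` plus i.i.d. Gaussian noise per
#' coordinate, where `s_t` is a Markov chain driven by the transition
#' matrix, started from a draw of the stationary distribution.  Fully
#' reproducible from the spec seed.
#'
#' @param spec a [multistate_spec()].
#' @return A list: `trajectory` (a [trajectory()]) and `labels` (integer
#'   state index per frame, the ground truth for recovery scoring).
#' @export
generate_multistate_trajectory <- function(spec) {
  stopifnot(inherits(spec, "pepmd_multistate_spec"))
  k <- length(spec$reference_frames)
  na <- nrow(spec$topology)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  labels <- integer(spec$n_frames)
  labels[1] <- sample.int(k, 1, prob = spec$stationary_populations)
  if (spec$n_frames > 1)
    for (t in 2:spec$n_frames)
      labels[t] <- sample.int(k, 1, prob = spec$transition_matrix[labels[t - 1], ])
  coords <- array(NA_real_, c(na, 3L, spec$n_frames))
  for (t in seq_len(spec$n_frames))
    coords[, , t] <- spec$reference_frames[[labels[t]]] +
      matrix(rnorm(3 * na, 0, spec$noise_sigma), na, 3)
  list(trajectory = trajectory(spec$topology, coords, dt = spec$dt),
       labels = labels)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Rigid two-domain fixture with an exact inter-domain dihedral
#'
#' Constructs two point-mass "domains" hinged at two central atoms such that
#' the dihedral through (MC1, hinge1, hinge2, MC2) equals `dihedral_deg`
#' exactly: the hinge axis lies along z, domain 1's mass center sits at
#' `(arm_length, 0, 0)` off hinge 1, and domain 2's mass center is rotated
#' by the requested angle about the axis off hinge 2.
#'
#' @param dihedral_deg target signed dihedral, degrees.
#' @param arm_length distance from each hinge to its domain center,
#'   Angstrom.
#' @return A list: `frame` (coordinate matrix), `topology`, and index
#'   vectors `dom1`, `dom2`, `hinge1`, `hinge2`.
#' @export
generate_two_domain_frame <- function(dihedral_deg, arm_length = 10) {
  stopifnot(arm_length > 0)
  th <- dihedral_deg * pi / 180
  h1 <- c(0, 0, 0); h2 <- c(0, 0, 5)
  # two atoms per domain, placed symmetrically so the mass center is exact
  d1a <- c(arm_length, 0.5, 0); d1b <- c(arm_length, -0.5, 0)
  # for the dihedral sign convention used here (IUPAC, right-handed about
  # b2 = h2 - h1), a positive angle rotates domain 2 by +th about +z
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
  d2a <- as.numeric(rot %*% c(arm_length, 0.5, 0)) + c(0, 0, 5)
  d2b <- as.numeric(rot %*% c(arm_length, -0.5, 0)) + c(0, 0, 5)
  frame <- rbind(d1a, d1b, h1, h2, d2a, d2b)
  rownames(frame) <- NULL
  top <- atom_topology(
    name = c("CA", "CB", "CA", "CA", "CA", "CB"),
    residue_name = rep("GLY", 6),
    residue_id = 1:6,
    chain_id = c("A", "A", "A", "B", "B", "B"))
  list(frame = frame, topology = top, dom1 = 1:2, dom2 = 5:6,
       hinge1 = 3L, hinge2 = 4L)
}
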