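#' @useDynLib pepmd, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats acf aggregate pbeta rnorm sd var
#' @importFrom utils read.csv write.csv
NULL

# Boltzmann constant / molar gas constant in kcal/(mol K).  A single value is
# used package-wide so per-molecule and per-mole forms cannot diverge.
KB_KCAL <- 1.987204e-3

#' Molar gas constant in kcal/(mol K)
#'
#' Returns the value of R (equivalently k_B in molar units) used throughout
#' the package: 1.987204e-3 kcal/(mol K).
#'
#' @return A numeric scalar.
#' @export
kb_kcal <- function() KB_KCAL

#' Construct an atom topology table
#'
#' A topology is a plain `data.frame` with one row per atom, ordered as the
#' coordinates are.  Columns: `name` (PDB atom name), `residue_name`
#' (3-letter code), `residue_id` (author numbering, integer), `chain_id`
#' (single character), `element` (symbol), `mass` (atomic mass units).
#'
#' @param name character vector of atom names (e.g. `"CA"`).
#' @param residue_name character vector of 3-letter residue codes.
#' @param residue_id integer vector of residue numbers.
#' @param chain_id character vector of single-character chain identifiers.
#' @param element optional element symbols; guessed from the first letter of
#'   the atom name when missing.
#' @param mass optional atomic masses in amu; looked up from `element` when
#'   missing.
#'
#' @return A `data.frame` of class `pepmd_topology`.
#' @export
atom_topology <- function(name, residue_name, residue_id, chain_id,
                          element = NULL, mass = NULL) {
  n <- length(name)
  stopifnot(length(residue_name) == n, length(residue_id) == n,
            length(chain_id) == n)
  if (is.null(element)) element <- guess_element(name)
  if (is.null(mass)) mass <- element_mass(element)
  if (any(!is.finite(mass)) || any(mass <= 0))
    stop("atom masses must be positive and finite", call. = FALSE)
  top <- data.frame(name = as.character(name),
                    residue_name = as.character(residue_name),
                    residue_id = as.integer(residue_id),
                    chain_id = as.character(chain_id),
                    element = as.character(element),
                    mass = as.numeric(mass),
                    stringsAsFactors = FALSE)
  key <- paste(top$chain_id, top$residue_id, top$name)
  if (anyDuplicated(key))
    stop("duplicate (chain_id, residue_id, name) in topology: ",
         key[duplicated(key)][1], call. = FALSE)
  class(top) <- c("pepmd_topology", "data.frame")
  top
}

guess_element <- function(name) {
  # PDB convention: columns 13-14 carry the element for standard names;
  # after whitespace stripping the element is the leading alphabetic part
  # minus greek-position suffixes.  A first-character lookup covers the
  # biomolecular elements used here (C, N, O, S, P, H).
  first <- toupper(substr(gsub("[^A-Za-z].*$", "", name), 1, 1))
  ifelse(first %in% c("C", "N", "O", "S", "P", "H"), first, "C")
}

element_mass <- function(element) {
  m <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
         P = 30.974, S = 32.06, NA. = 22.990, CL = 35.45)
  out <- m[toupper(element)]
  out[is.na(out)] <- 12.011
  unname(out)
}

#' Construct a trajectory
#'
#' A trajectory couples a topology to a time-ordered stack of coordinate
#' frames.  Coordinates are in Angstrom, times in picoseconds.
#'
#' @param topology a topology `data.frame` (see [atom_topology()]).
#' @param coords either a 3-D array `[n_atoms, 3, n_frames]` or a list of
#'   `n_atoms x 3` matrices.
#' @param dt time step between stored frames in ps (default 1).
#' @param times optional explicit frame times in ps; defaults to
#'   `(0:(n_frames-1)) * dt`.
#'
#' @return An object of class `pepmd_trajectory` with elements `topology`,
#'   `coords` (3-D array), `times`, `dt`.
#' @export
trajectory <- function(topology, coords, dt = 1, times = NULL) {
  if (is.list(coords) && !is.array(coords)) {
    nf <- length(coords)
    na <- nrow(coords[[1]])
    arr <- array(NA_real_, c(na, 3L, nf))
    for (i in seq_len(nf)) {
      if (!identical(dim(coords[[i]]), c(na, 3L)) &&
          !identical(dim(coords[[i]]), as.integer(c(na, 3))))
        stop("frame ", i, " has inconsistent dimensions", call. = FALSE)
      arr[, , i] <- coords[[i]]
    }
    coords <- arr
  }
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  if (dim(coords)[1] != nrow(topology))
    stop("coordinate count (", dim(coords)[1],
         ") does not match topology atom count (", nrow(topology), ")",
         call. = FALSE)
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in trajectory", call. = FALSE)
  nf <- dim(coords)[3]
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt
  if (nf > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (nf > 1 && any(abs(diff(times) - dt) > 1e-6))
    stop("frame times inconsistent with dt beyond 1e-6 ps", call. = FALSE)
  structure(list(topology = topology, coords = coords,
                 times = times, dt = dt),
            class = "pepmd_trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `pepmd_trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Extract one frame as a coordinate matrix
#' @param traj a `pepmd_trajectory`.
#' @param i frame index (1-based).
#' @return An `n_atoms x 3` numeric matrix.
#' @export
traj_frame <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  traj$coords[, , i, drop = TRUE]
}

#' @export
print.pepmd_trajectory <- function(x, ...) {
  cat(sprintf("pepmd trajectory: %d atoms, %d frames, dt = %g ps\n",
              nrow(x$topology), n_frames(x), x$dt))
  invisible(x)
}
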