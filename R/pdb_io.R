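# Multi-model PDB input/output.  Parsing and writing of the fixed-width
# record layout is delegated to bio3d; a light pre-scan of the file supplies
# the structural diagnostics (per-line parse errors, per-MODEL atom counts)
# that the contract here requires.

#' Read a (multi-model) PDB file as a trajectory
#'
#' MODEL records map to frames in file order; a file without MODEL records
#' yields a single-frame trajectory.  The atom order must be identical
#' across models.  Only the first alternate location of each atom is kept
#' (a warning reports dropped altlocs).
#'
#' @param path path to a PDB file.
#' @param format input format; only `"pdb"` is native.
#' @param dt frame spacing in ps assigned to the frames (default 1).
#'
#' @return A [trajectory()].
#' @export
read_structure <- function(path, format = "pdb", dt = 1) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom))
    stop("no ATOM/HETATM records in ", path, call. = FALSE)
  bad <- which(is_atom & nchar(lines) < 54)
  if (length(bad))
    stop("malformed ATOM record at line ", bad[1], " of ", path,
         call. = FALSE)
  # coordinates must parse as numbers in their fixed columns
  for (ln in which(is_atom)) {
    xyz <- c(substr(lines[ln], 31, 38), substr(lines[ln], 39, 46),
             substr(lines[ln], 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz))))
      stop("malformed coordinate field at line ", ln, " of ", path,
           call. = FALSE)
  }
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 1) {
    ends <- which(rec == "ENDMDL")
    if (length(ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records in ", path, call. = FALSE)
    counts <- mapply(function(a, b) sum(is_atom[a:b]), model_starts, ends)
    if (length(unique(counts)) != 1)
      stop("inconsistent atom count across models in ", path, ": ",
           paste(counts, collapse = ", "), call. = FALSE)
  }

  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  # keep first altloc only
  if (!is.null(at$alt) && any(!is.na(at$alt) & at$alt != "")) {
    keep_alt <- is.na(at$alt) | at$alt == "" |
      at$alt == sort(unique(at$alt[!is.na(at$alt) & at$alt != ""]))[1]
    if (!all(keep_alt)) {
      warning(sum(!keep_alt), " alternate-location atoms dropped",
              call. = FALSE)
      at <- at[keep_alt, , drop = FALSE]
      pdb$xyz <- pdb$xyz[, bio3d::atom2xyz(which(keep_alt)), drop = FALSE]
    }
  }
  chain <- at$chain
  chain[is.na(chain) | chain == ""] <- " "
  top <- atom_topology(name = at$elety, residue_name = at$resid,
                       residue_id = at$resno, chain_id = chain)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  na <- nrow(top)
  coords <- array(NA_real_, c(na, 3L, nf))
  for (f in seq_len(nf))
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  trajectory(top, coords, dt = dt)
}

#' Write a trajectory as a (multi-model) PDB file
#'
#' One MODEL/ENDMDL block per frame; a single-frame trajectory is written
#' without MODEL records.  Coordinates are emitted at PDB precision
#' (3 decimals, 1e-3 Angstrom).
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @param format output format; only `"pdb"`.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(traj, path, format = "pdb") {
  format <- match.arg(format, "pdb")
  stopifnot(inherits(traj, "pepmd_trajectory"))
  if (n_frames(traj) < 1) stop("empty trajectory", call. = FALSE)
  ok <- tryCatch({
    top <- traj$topology
    nf <- n_frames(traj)
    xyz <- t(apply(traj$coords, 3, function(m) as.numeric(t(m))))
    if (nf == 1) xyz <- matrix(xyz, nrow = 1)
    chain <- top$chain_id
    chain[chain == " "] <- ""
    bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", nrow(top)),
                     resno = top$residue_id, resid = top$residue_name,
                     eleno = seq_len(nrow(top)), elety = top$name,
                     chain = chain, elesy = top$element)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write PDB to ", path, ": ", conditionMessage(ok),
         call. = FALSE)
  invisible(path)
}
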