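# Declarative atom selections and the C-terminal position-label map used to
# name peptide residues (position 0 = C-terminal residue, -1 the next one
# toward the N terminus, ...).

#' Construct an atom selection
#'
#' A declarative subset of atoms: any combination of chain identifiers,
#' residue ids and atom names.  `NULL` means "no restriction".  The
#' conventional peptide backbone here is atom names N, CA, C (mainchain
#' heavy atoms without the carbonyl O); pass
#' `atom_names = c("N","CA","C","O")` to include it.
#'
#' @param chain_ids optional character vector of chain ids.
#' @param residue_ids optional integer vector of residue numbers.
#' @param atom_names optional character vector of atom names.
#' @return An object of class `pepmd_selection`.
#' @export
atom_selection <- function(chain_ids = NULL, residue_ids = NULL,
                           atom_names = NULL) {
  structure(list(chain_ids = chain_ids,
                 residue_ids = if (is.null(residue_ids)) NULL
                               else as.integer(residue_ids),
                 atom_names = atom_names),
            class = "pepmd_selection")
}

#' Backbone atom-name selection
#' @param chain_ids optional chain restriction.
#' @param residue_ids optional residue restriction.
#' @param include_o include the carbonyl O (default FALSE).
#' @return A `pepmd_selection` over N, CA, C (and O if requested).
#' @export
backbone_selection <- function(chain_ids = NULL, residue_ids = NULL,
                               include_o = FALSE) {
  atom_selection(chain_ids, residue_ids,
                 if (include_o) c("N", "CA", "C", "O") else c("N", "CA", "C"))
}

#' Resolve a selection against a topology
#'
#' @param sel a `pepmd_selection`, or an integer index vector (returned
#'   unchanged after bounds checking).
#' @param topology a topology `data.frame`.
#' @return An ordered integer vector of atom indices (topology order).
#'   Resolution is a pure function of `(sel, topology)`; an empty result is
#'   an error naming the unmatched criteria.
#' @export
resolve_selection <- function(sel, topology) {
  stopifnot(nrow(topology) > 0)
  if (is.numeric(sel)) {
    idx <- as.integer(sel)
    if (any(idx < 1) || any(idx > nrow(topology)))
      stop("selection index out of range", call. = FALSE)
    return(idx)
  }
  stopifnot(inherits(sel, "pepmd_selection"))
  keep <- rep(TRUE, nrow(topology))
  if (!is.null(sel$chain_ids)) keep <- keep & topology$chain_id %in% sel$chain_ids
  if (!is.null(sel$residue_ids)) keep <- keep & topology$residue_id %in% sel$residue_ids
  if (!is.null(sel$atom_names)) keep <- keep & topology$name %in% sel$atom_names
  idx <- which(keep)
  if (!length(idx)) {
    crit <- c(
      if (!is.null(sel$chain_ids) && !any(topology$chain_id %in% sel$chain_ids))
        paste0("chain_ids {", paste(sel$chain_ids, collapse = ","), "}"),
      if (!is.null(sel$residue_ids) && !any(topology$residue_id %in% sel$residue_ids))
        paste0("residue_ids {", paste(sel$residue_ids, collapse = ","), "}"),
      if (!is.null(sel$atom_names) && !any(topology$name %in% sel$atom_names))
        paste0("atom_names {", paste(sel$atom_names, collapse = ","), "}"))
    if (!length(crit)) crit <- "combination of criteria"
    stop("selection matches no atoms; unmatched: ",
         paste(crit, collapse = "; "), call. = FALSE)
  }
  idx
}

#' Map C-terminal position labels to residues of a peptide chain
#'
#' Peptide residues are labelled by their distance from the C terminus:
#' position 0 is the last residue of the chain, -1 the one before it, and
#' so on (e.g. Ile(0) ... Ala(-11) for a 12-residue peptide).
#'
#' @param topology a topology `data.frame`.
#' @param chain_id the peptide chain.
#' @return A `data.frame` with columns `position`, `chain_id`, `residue_id`,
#'   `residue_name`, ordered from position 0 downward.
#' @export
peptide_position_map <- function(topology, chain_id) {
  rows <- topology[topology$chain_id == chain_id, , drop = FALSE]
  if (!nrow(rows)) stop("no atoms in chain ", chain_id, call. = FALSE)
  resno <- unique(rows$residue_id)          # topology order
  n <- length(resno)
  resname <- vapply(resno, function(r)
    rows$residue_name[match(r, rows$residue_id)], character(1))
  data.frame(position = 0:(-(n - 1)),
             chain_id = chain_id,
             residue_id = rev(resno),
             residue_name = rev(resname),
             stringsAsFactors = FALSE)
}

#' Selection for C-terminal peptide positions
#'
#' Convenience wrapper: the residues at the given C-terminal position labels
#' of one chain, optionally restricted to a set of atom names.
#'
#' @param topology a topology `data.frame`.
#' @param chain_id the peptide chain.
#' @param positions position labels (0 = C terminus), e.g. `c(0, -1, -2)`.
#' @param atom_names optional atom-name restriction (e.g. backbone
#'   `c("N","CA","C")`).
#' @return A `pepmd_selection`.
#' @export
position_selection <- function(topology, chain_id, positions,
                               atom_names = NULL) {
  pmap <- peptide_position_map(topology, chain_id)
  miss <- setdiff(positions, pmap$position)
  if (length(miss))
    stop("positions not present in chain ", chain_id, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  atom_selection(chain_ids = chain_id,
                 residue_ids = pmap$residue_id[match(positions, pmap$position)],
                 atom_names = atom_names)
}
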