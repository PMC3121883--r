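# Least-squares rigid superposition (Kabsch), RMSD with the two-selection
# fit/measure scheme, and RMSF about the iterated mean structure.

#' Optimal rigid superposition of two frames (Kabsch)
#'
#' Finds the proper rotation R and translation t minimising the RMSD between
#' `R %*% mobile + t` and `reference` over the fit selection.  Reflections
#' are excluded (det(R) = +1).
#'
#' @param mobile,reference `n_atoms x 3` coordinate matrices sharing one
#'   topology/atom order.
#' @param fit_sel selection (or integer indices) of atoms used for the fit;
#'   `NULL` fits on all atoms.
#' @param topology required when `fit_sel` is a declarative selection.
#' @return A list of class `pepmd_superposition`: `rotation` (3x3, applied
#'   to row vectors as `x %*% t(R)`), `translation` (length-3, Angstrom),
#'   `fit_rmsd` (Angstrom over the fit atoms).
#' @export
kabsch_fit <- function(mobile, reference, fit_sel = NULL, topology = NULL) {
  idx <- fit_indices(fit_sel, topology, nrow(mobile))
  if (length(idx) < 3)
    stop("need at least 3 fit atoms", call. = FALSE)
  P <- mobile[idx, , drop = FALSE]     # mobile fit atoms
  Q <- reference[idx, , drop = FALSE]
  if (collinear(P) || collinear(Q))
    stop("fit atoms are collinear; superposition underdetermined",
         call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)               # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- as.numeric(cq - R %*% cp)
  fitted <- sweep(Pc %*% t(R), 2, cq, "+")
  structure(list(rotation = R, translation = tr,
                 fit_rmsd = sqrt(mean(rowSums((fitted - Q)^2)))),
            class = "pepmd_superposition")
}

fit_indices <- function(sel, topology, n) {
  if (is.null(sel)) return(seq_len(n))
  if (is.numeric(sel)) return(resolve_selection(sel,
    if (is.null(topology)) data.frame(dummy = seq_len(n)) else topology))
  if (is.null(topology))
    stop("a topology is required to resolve a declarative selection",
         call. = FALSE)
  resolve_selection(sel, topology)
}

collinear <- function(X, tol = 1e-9) {
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc, nu = 0, nv = 0)$d
  sv[2] <= tol * max(sv[1], 1)
}

#' Apply a superposition to coordinates
#' @param coords `n x 3` matrix.
#' @param fit a `pepmd_superposition`.
#' @return Transformed `n x 3` matrix.
#' @export
apply_fit <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2, fit$translation, "+")
}

#' RMSD between two frames over a selection
#'
#' Implements the two-selection scheme: fitting and measuring may use
#' different atom sets.  If `prefit` is given it is applied to `a` (no
#' refitting); if `fit = TRUE` a Kabsch fit of `a` onto `b` over `fit_sel`
#' is performed first; with `fit = FALSE` and no `prefit` the raw deviation
#' is measured.
#'
#' @param a,b `n_atoms x 3` coordinate matrices with identical atom order.
#' @param sel selection (or indices) over which the deviation is measured;
#'   `NULL` = all atoms.
#' @param prefit optional `pepmd_superposition` applied to `a`.
#' @param fit logical: perform a fresh fit of `a` onto `b` (ignored when
#'   `prefit` is supplied).
#' @param fit_sel selection used for the fresh fit (defaults to `sel`).
#' @param topology required for declarative selections.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(a, b, sel = NULL, prefit = NULL, fit = FALSE,
                 fit_sel = NULL, topology = NULL) {
  if (!identical(dim(a), dim(b)))
    stop("frames have different dimensions", call. = FALSE)
  idx <- fit_indices(sel, topology, nrow(a))
  if (!is.null(prefit)) {
    a <- apply_fit(a, prefit)
  } else if (isTRUE(fit)) {
    a <- apply_fit(a, kabsch_fit(a, b, fit_sel = if (is.null(fit_sel)) sel
                                 else fit_sel, topology = topology))
  }
  sqrt(mean(rowSums((a[idx, , drop = FALSE] - b[idx, , drop = FALSE])^2)))
}

#' Per-atom RMSF about the mean structure
#'
#' Each frame is Kabsch-fit over `fit_sel`; the reference is the mean
#' structure, obtained by one fit-average-refit iteration starting from the
#' raw time-averaged coordinates (an order-invariant initial reference).
#' RMSF_i = sqrt(mean over frames of |r_i - <r_i>|^2), reported over
#' `measure_sel`.
#'
#' @param traj a [trajectory()] with at least 2 frames.
#' @param fit_sel selection used for superposition; `NULL` = all atoms.
#' @param measure_sel selection of atoms to report; `NULL` = all atoms.
#' @param fit logical; `FALSE` skips superposition entirely (useful when
#'   frames are already in a common frame of reference).
#' @return A `data.frame` with one row per measured atom: topology columns
#'   plus `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, fit_sel = NULL, measure_sel = NULL, fit = TRUE) {
  stopifnot(inherits(traj, "pepmd_trajectory"))
  nf <- n_frames(traj)
  if (nf < 2)
    stop("RMSF needs at least 2 frames", call. = FALSE)
  top <- traj$topology
  coords <- traj$coords
  if (isTRUE(fit)) {
    fidx <- fit_indices(fit_sel, top, nrow(top))
    aligned <- coords
    ref <- apply(coords, c(1, 2), mean)
    for (pass in 1:2) {
      for (f in seq_len(nf))
        aligned[, , f] <- apply_fit(coords[, , f],
                                    kabsch_fit(coords[, , f], ref, fidx))
      ref <- apply(aligned, c(1, 2), mean)
    }
    coords <- aligned
  }
  mean_xyz <- apply(coords, c(1, 2), mean)
  dev2 <- apply(coords, 3, function(m) rowSums((m - mean_xyz)^2))
  rmsf_all <- sqrt(rowMeans(dev2))
  midx <- fit_indices(measure_sel, top, nrow(top))
  out <- top[midx, c("name", "residue_name", "residue_id", "chain_id")]
  out$rmsf <- rmsf_all[midx]
  rownames(out) <- NULL
  out
}
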