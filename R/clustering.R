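# Ensemble clustering stage: pool peptide conformations from several
# trajectories/binding sites with stride subsampling, build the pairwise
# two-selection RMSD matrix, run GROMOS (Daura) greedy clustering at a
# distance cutoff, and count inter-cluster transitions along each source
# series.

#' Pool peptide conformations from trajectories with stride subsampling
#'
#' For each trajectory and each site selection, extracts the selected atoms
#' from frames 1, 1+stride, 1+2*stride, ...; the pooled conformations carry
#' full provenance (trajectory id, site id, source frame, source time).
#' All site selections must resolve to the same atom template (atom names
#' and within-chain residue ordinals) so conformations are comparable.
#'
#' @param trajs list of [trajectory()] objects.
#' @param site_selections list (one element per trajectory) of lists of
#'   selections, one per binding site.  A single selection is promoted to a
#'   one-site list; a single list is recycled across trajectories.
#' @param stride keep every `stride`-th frame (default 1).
#' @return An object of class `pepmd_pool`: `coords` (array
#'   `[n_sel_atoms, 3, n_conf]`), `template` (topology rows of the first
#'   site), `provenance` (data.frame: traj, site, frame, time_ps),
#'   `dt_effective` (ps between consecutive pooled frames of one site).
#' @export
pool_and_subsample <- function(trajs, site_selections, stride = 1) {
  stopifnot(stride >= 1)
  if (inherits(trajs, "pepmd_trajectory")) trajs <- list(trajs)
  if (inherits(site_selections, "pepmd_selection") ||
      is.numeric(site_selections))
    site_selections <- list(list(site_selections))
  if (length(site_selections) && !is.list(site_selections[[1]]))
    site_selections <- list(site_selections)
  if (length(site_selections) == 1 && length(trajs) > 1)
    site_selections <- rep(site_selections, length(trajs))
  stopifnot(length(site_selections) == length(trajs))

  template <- NULL
  chunks <- list(); prov <- list()
  for (ti in seq_along(trajs)) {
    traj <- trajs[[ti]]
    keep <- seq(1, n_frames(traj), by = stride)
    for (si in seq_along(site_selections[[ti]])) {
      idx <- resolve_selection(site_selections[[ti]][[si]], traj$topology)
      tmpl <- traj$topology[idx, c("name", "residue_name")]
      ord <- match(traj$topology$residue_id[idx],
                   unique(traj$topology$residue_id[idx]))
      tmpl$residue_ordinal <- ord
      rownames(tmpl) <- NULL
      if (is.null(template)) {
        template <- tmpl
        template_top <- traj$topology[idx, , drop = FALSE]
      } else if (!identical(tmpl$name, template$name) ||
                 !identical(tmpl$residue_ordinal, template$residue_ordinal)) {
        stop("site (traj ", ti, ", site ", si, ") does not match the ",
             "pooled atom template", call. = FALSE)
      }
      chunks[[length(chunks) + 1]] <- traj$coords[idx, , keep, drop = FALSE]
      prov[[length(prov) + 1]] <- data.frame(
        traj = ti, site = si, frame = keep, time_ps = traj$times[keep])
    }
  }
  coords <- array(NA_real_, c(nrow(template), 3L,
                              sum(vapply(chunks, function(x) dim(x)[3],
                                         numeric(1)))))
  at <- 0L
  for (ch in chunks) {
    nf <- dim(ch)[3]
    coords[, , at + seq_len(nf)] <- ch
    at <- at + nf
  }
  provenance <- do.call(rbind, prov)
  rownames(provenance) <- NULL
  structure(list(coords = coords, template = template,
                 template_topology = template_top,
                 provenance = provenance,
                 dt_effective = stride * trajs[[1]]$dt),
            class = "pepmd_pool")
}

#' @export
print.pepmd_pool <- function(x, ...) {
  cat(sprintf("pepmd pool: %d conformations x %d atoms (dt_eff = %g ps)\n",
              dim(x$coords)[3], dim(x$coords)[1], x$dt_effective))
  invisible(x)
}

#' Pairwise two-selection RMSD matrix over pooled conformations
#'
#' Entry (i, j) is the RMSD over `rmsd_sel` after a Kabsch fit of
#' conformation j onto i over `fit_sel`.  The fitted RMSD is symmetric in
#' (i, j) up to floating-point noise, so the matrix is computed on the
#' upper triangle and mirrored.  Selections are resolved against the pool's
#' atom template.
#'
#' @param pool a `pepmd_pool` (or a bare `[n_atoms, 3, n_conf]` array).
#' @param fit_sel selection/indices for the superposition (e.g. backbone of
#'   C-terminal positions 0, -1, -2); `NULL` = all pooled atoms.
#' @param rmsd_sel selection/indices over which the deviation is measured
#'   (e.g. the whole peptide backbone); `NULL` = all pooled atoms.
#' @return An object of class `pepmd_rmsd_matrix`: `values` (symmetric
#'   matrix, Angstrom), `fit_idx`, `rmsd_idx`, and the pool `provenance`.
#' @export
build_rmsd_matrix <- function(pool, fit_sel = NULL, rmsd_sel = NULL) {
  if (is.array(pool) && length(dim(pool)) == 3) {
    pool <- structure(list(coords = pool, template_topology = NULL,
                           provenance = NULL, dt_effective = NA_real_),
                      class = "pepmd_pool")
  }
  stopifnot(inherits(pool, "pepmd_pool"))
  na <- dim(pool$coords)[1]
  top <- pool$template_topology
  fit_idx <- fit_indices(fit_sel, top, na)
  rmsd_idx <- fit_indices(rmsd_sel, top, na)
  if (length(fit_idx) < 3)
    stop("need at least 3 fit atoms", call. = FALSE)
  vals <- pairwise_rmsd_cpp(pool$coords, fit_idx - 1L, rmsd_idx - 1L)
  structure(list(values = vals, fit_idx = fit_idx, rmsd_idx = rmsd_idx,
                 provenance = pool$provenance,
                 dt_effective = pool$dt_effective),
            class = "pepmd_rmsd_matrix")
}

#' GROMOS (Daura) greedy clustering of an RMSD matrix
#'
#' Iteratively: count each unassigned conformation's unassigned neighbors
#' within `cutoff`; the conformation with the most neighbors becomes a
#' cluster center; it and its neighbors form a cluster and leave the pool;
#' repeat until none remain.  Singleton clusters are allowed.  Equal
#' neighbor counts are broken toward the lowest conformation index, making
#' the partition deterministic.  Clusters are renumbered by decreasing size
#' (size ties broken by center index).
#'
#' @param mat a `pepmd_rmsd_matrix`, or a plain symmetric numeric matrix of
#'   distances.
#' @param cutoff neighbor distance cutoff, Angstrom (the study-standard
#'   choice for peptide backbone ensembles is 1.5).
#' @return An object of class `pepmd_clusters`: `labels` (1-based cluster
#'   id per conformation, decreasing size order), `centers` (representative
#'   conformation index per cluster), `sizes`, `percentages`, `cutoff`,
#'   plus the matrix provenance when available.
#' @export
gromos_cluster <- function(mat, cutoff = 1.5) {
  stopifnot(cutoff > 0)
  prov <- NULL; dt_eff <- NA_real_
  if (inherits(mat, "pepmd_rmsd_matrix")) {
    prov <- mat$provenance; dt_eff <- mat$dt_effective
    mat <- mat$values
  }
  stopifnot(is.matrix(mat), nrow(mat) == ncol(mat))
  if (max(abs(mat - t(mat))) > 1e-9)
    stop("distance matrix is not symmetric", call. = FALSE)
  n <- nrow(mat)
  adj <- mat <= cutoff
  diag(adj) <- FALSE

  labels <- integer(n)
  centers <- integer(0)
  remaining <- rep(TRUE, n)
  cl <- 0L
  while (any(remaining)) {
    cl <- cl + 1L
    idx <- which(remaining)
    counts <- if (length(idx) == 1) 0L else
      colSums(adj[idx, idx, drop = FALSE])
    center <- idx[which.max(counts)]      # which.max takes the first max
    members <- unique(c(center, idx[adj[idx, center]]))
    labels[members] <- cl
    centers[cl] <- center
    remaining[members] <- FALSE
  }
  sizes <- tabulate(labels, nbins = cl)
  ord <- order(-sizes, centers)
  relabel <- integer(cl); relabel[ord] <- seq_len(cl)
  labels <- relabel[labels]
  centers <- centers[ord]
  sizes <- sizes[ord]
  structure(list(labels = labels, centers = centers, sizes = sizes,
                 percentages = 100 * sizes / n, cutoff = cutoff,
                 n = n, provenance = prov, dt_effective = dt_eff),
            class = "pepmd_clusters")
}

#' @export
print.pepmd_clusters <- function(x, ...) {
  cat(sprintf("GROMOS clustering: %d conformations, %d clusters (cutoff %g A)\n",
              x$n, length(x$sizes), x$cutoff))
  k <- min(length(x$sizes), 6)
  cat(sprintf("  largest: %s\n",
              paste(sprintf("%.1f%%", x$percentages[seq_len(k)]),
                    collapse = ", ")))
  invisible(x)
}

#' Inter-cluster transition statistics
#'
#' A transition is a change of cluster label between consecutive frames of
#' the same trajectory+site series; transitions are never counted across
#' pooling boundaries.  The rate is transitions per unit elapsed time.
#'
#' @param clusters a `pepmd_clusters` carrying provenance, or an integer
#'   label vector (then `provenance` is required).
#' @param provenance data.frame with columns `traj`, `site`, `frame`
#'   aligned with the labels (taken from the cluster object when omitted).
#' @param dt_effective ps between consecutive pooled frames of one series
#'   (taken from the cluster object when omitted).
#' @return A list: `n_transitions`, `total_time_ps`, `rate_per_ps`,
#'   `mean_interval_ps` (NA when no transitions), `pair_counts`
#'   (data.frame from, to, count).
#' @export
transition_stats <- function(clusters, provenance = NULL,
                             dt_effective = NULL) {
  if (inherits(clusters, "pepmd_clusters")) {
    labels <- clusters$labels
    if (is.null(provenance)) provenance <- clusters$provenance
    if (is.null(dt_effective)) dt_effective <- clusters$dt_effective
  } else labels <- as.integer(clusters)
  if (is.null(provenance))
    stop("transition counting requires per-conformation provenance",
         call. = FALSE)
  if (is.null(dt_effective) || is.na(dt_effective))
    stop("dt_effective is required", call. = FALSE)
  stopifnot(nrow(provenance) == length(labels))

  series_id <- paste(provenance$traj, provenance$site, sep = "/")
  n_trans <- 0L; total_steps <- 0L
  pairs <- list()
  for (sid in unique(series_id)) {
    rows <- which(series_id == sid)
    rows <- rows[order(provenance$frame[rows])]
    lab <- labels[rows]
    if (length(lab) < 2) next
    changed <- which(lab[-1] != lab[-length(lab)])
    n_trans <- n_trans + length(changed)
    total_steps <- total_steps + length(lab) - 1L
    if (length(changed))
      pairs[[length(pairs) + 1]] <- data.frame(
        from = lab[changed], to = lab[changed + 1])
  }
  pair_counts <- if (length(pairs)) {
    p <- do.call(rbind, pairs)
    agg <- aggregate(rep(1, nrow(p)), by = list(from = p$from, to = p$to),
                     FUN = sum)
    names(agg)[3] <- "count"
    agg[order(-agg$count), ]
  } else data.frame(from = integer(), to = integer(), count = integer())
  total_time <- total_steps * dt_effective
  list(n_transitions = n_trans, total_time_ps = total_time,
       rate_per_ps = if (total_time > 0) n_trans / total_time else NA_real_,
       mean_interval_ps = if (n_trans > 0) total_time / n_trans else NA_real_,
       pair_counts = pair_counts)
}
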