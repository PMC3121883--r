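# Track composition: the ensemble track (trajectory -> metrics ->
# clustering -> transitions) and the energetics track (window directories
# -> per-leg accumulation -> thermodynamic cycle -> optional Kd
# comparison).  Every output set is written next to a serialized copy of
# the configuration and its hash for provenance.

#' Build a run configuration
#'
#' All fields have documented defaults except the input paths.
#'
#' @param track one of `"ensemble"`, `"energetics"`.
#' @param traj_paths character vector of (multi-model) PDB trajectory
#'   paths (ensemble track).
#' @param peptide_chains chain id(s) of the bound peptide, one entry per
#'   binding site (recycled across trajectories).
#' @param stride frame-picking stride (default 4).
#' @param cutoff clustering cutoff in Angstrom (default 1.5).
#' @param fit_positions C-terminal position labels used for the fit
#'   (default `c(0, -1, -2)`).
#' @param bound_dir,free_dir window directories for the energetics track
#'   (see [read_fep_windows()]); `free_dir` optional.
#' @param kd_wt,kd_mut optional dissociation constants (molar) for the
#'   experimental comparison block.
#' @param temperature K (default 300).
#' @param dt trajectory frame spacing in ps (default 1).
#' @param seed integer seed recorded for provenance (default 1).
#' @param out_prefix output path prefix; `NULL` disables file output.
#' @return A `pepmd_config` list.
#' @export
run_config <- function(track = c("ensemble", "energetics"),
                       traj_paths = NULL, peptide_chains = "P",
                       stride = 4, cutoff = 1.5,
                       fit_positions = c(0, -1, -2),
                       bound_dir = NULL, free_dir = NULL,
                       kd_wt = NULL, kd_mut = NULL,
                       temperature = 300, dt = 1, seed = 1L,
                       out_prefix = NULL) {
  cfg <- list(track = match.arg(track), traj_paths = traj_paths,
              peptide_chains = peptide_chains, stride = stride,
              cutoff = cutoff, fit_positions = fit_positions,
              bound_dir = bound_dir, free_dir = free_dir,
              kd_wt = kd_wt, kd_mut = kd_mut,
              temperature = temperature, dt = dt, seed = as.integer(seed),
              out_prefix = out_prefix)
  class(cfg) <- "pepmd_config"
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  cfg$out_prefix <- NULL            # output location must not change the hash
  yaml::write_yaml(cfg[order(names(cfg))], tmp)
  unname(tools::md5sum(tmp))
}

write_outputs <- function(prefix, cfg, files) {
  if (is.null(prefix)) return(invisible(NULL))
  dir.create(dirname(prefix), showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), paste0(prefix, "_config.yaml"))
  for (nm in names(files)) files[[nm]]()
  invisible(NULL)
}

#' Run the ensemble analysis track
#'
#' Loads the trajectories, pools the peptide conformations from every
#' binding site with the configured stride, builds the two-selection RMSD
#' matrix (fit on the backbone of C-terminal positions 0/-1/-2, deviation
#' over the whole peptide backbone), clusters with the GROMOS rule at the
#' configured cutoff, and computes transition statistics, per-residue
#' Calpha RMSF of the peptide, and polar contacts.
#'
#' @param cfg a [run_config()] with `track = "ensemble"`; `traj_paths` may
#'   be pre-loaded `pepmd_trajectory` objects instead of paths.
#' @return A list: `summary` (cluster sizes/percentages/centers, transition
#'   stats, config hash), `clusters`, `rmsd_matrix`, `rmsf`, `contacts`.
#'   When `out_prefix` is set, writes `_summary.json`, `_labels.csv`,
#'   `_matrix.csv`, `_rmsf.csv`, `_config.yaml` and representative
#'   structures `_rep<k>.pdb`.
#' @export
run_ensemble_track <- function(cfg) {
  stopifnot(inherits(cfg, "pepmd_config"), cfg$track == "ensemble")
  trajs <- lapply(cfg$traj_paths, function(p)
    if (inherits(p, "pepmd_trajectory")) p else read_structure(p, dt = cfg$dt))
  if (inherits(cfg$traj_paths, "pepmd_trajectory"))
    trajs <- list(cfg$traj_paths)

  site_sels <- lapply(trajs, function(tr)
    lapply(cfg$peptide_chains, function(ch)
      backbone_selection(chain_ids = ch)))
  pool <- pool_and_subsample(trajs, site_sels, stride = cfg$stride)

  top <- pool$template_topology
  chain0 <- top$chain_id[1]
  fit_sel <- position_selection(top, chain0, cfg$fit_positions,
                                atom_names = c("N", "CA", "C"))
  mat <- build_rmsd_matrix(pool, fit_sel = fit_sel, rmsd_sel = NULL)
  clusters <- gromos_cluster(mat, cutoff = cfg$cutoff)
  trans <- if (dim(pool$coords)[3] >= 2)
    transition_stats(clusters) else NULL

  rmsf_tab <- NULL; contacts <- NULL
  if (n_frames(trajs[[1]]) >= 2) {
    rmsf_tab <- rmsf(trajs[[1]],
                     fit_sel = NULL,
                     measure_sel = atom_selection(
                       chain_ids = cfg$peptide_chains[1],
                       atom_names = "CA"))
    contacts <- detect_contacts(trajs[[1]])
  }

  hash <- config_hash(cfg)
  summary <- list(
    package = paste0("pepmd ", as.character(utils::packageVersion("pepmd"))),
    config_hash = hash,
    n_conformations = clusters$n,
    n_clusters = length(clusters$sizes),
    cluster_sizes = clusters$sizes,
    cluster_percentages = round(clusters$percentages, 1),
    cluster_centers = clusters$centers,
    cutoff_angstrom = cfg$cutoff,
    transitions = if (is.null(trans)) NULL else trans[
      c("n_transitions", "total_time_ps", "rate_per_ps",
        "mean_interval_ps")])

  if (!is.null(cfg$out_prefix)) {
    pre <- cfg$out_prefix
    write_outputs(pre, cfg, list(
      summary = function() jsonlite::write_json(
        summary, paste0(pre, "_summary.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE),
      labels = function() {
        lab <- cbind(clusters$provenance,
                     data.frame(cluster = clusters$labels))
        write.csv(lab, paste0(pre, "_labels.csv"), row.names = FALSE)
      },
      matrix = function() write.csv(mat$values, paste0(pre, "_matrix.csv"),
                                    row.names = FALSE),
      rmsf = function() if (!is.null(rmsf_tab))
        write.csv(rmsf_tab, paste0(pre, "_rmsf.csv"), row.names = FALSE),
      reps = function() {
        for (k in seq_len(min(4, length(clusters$centers)))) {
          rep_xyz <- pool$coords[, , clusters$centers[k], drop = FALSE]
          write_structure(trajectory(top, rep_xyz, dt = 1),
                          paste0(pre, sprintf("_rep%d.pdb", k)))
        }
      }))
  }
  list(summary = summary, clusters = clusters, rmsd_matrix = mat,
       pool = pool, rmsf = rmsf_tab, contacts = contacts,
       transitions = trans)
}

#' Run the energetics analysis track
#'
#' Accumulates each leg's windows (validating the lambda tiling); with two
#' legs, closes the thermodynamic cycle; with Kd values supplied, adds the
#' experimental `R T log(Kd ratio)` comparison block.
#'
#' @param cfg a [run_config()] with `track = "energetics"`; `bound_dir`
#'   (and optionally `free_dir`) may be directories or pre-loaded lists of
#'   [fep_window()].
#' @return A list: `bound`, `free` (`pepmd_fep_result` or NULL), `cycle`,
#'   `kd_comparison`, `summary`.  When `out_prefix` is set, writes
#'   `_fep.json` and `_config.yaml`.
#' @export
run_energetics_track <- function(cfg) {
  stopifnot(inherits(cfg, "pepmd_config"), cfg$track == "energetics")
  load_leg <- function(x) {
    if (is.null(x)) return(NULL)
    wins <- if (is.character(x)) read_fep_windows(x) else x
    accumulate(wins)
  }
  bound <- load_leg(cfg$bound_dir)
  if (is.null(bound)) stop("bound_dir is required", call. = FALSE)
  free <- load_leg(cfg$free_dir)
  cyc <- if (!is.null(free)) cycle_ddg(bound, free) else NULL
  kd <- if (!is.null(cfg$kd_wt) && !is.null(cfg$kd_mut))
    list(kd_wt_molar = cfg$kd_wt, kd_mut_molar = cfg$kd_mut,
         ddg_kcal_per_mol = ddg_from_kd(cfg$kd_wt, cfg$kd_mut,
                                        cfg$temperature)) else NULL
  summary <- list(
    package = paste0("pepmd ", as.character(utils::packageVersion("pepmd"))),
    config_hash = config_hash(cfg),
    bound = list(dg = bound$dg, sigma = bound$sigma,
                 n_windows = nrow(bound$windows)),
    free = if (is.null(free)) NULL else
      list(dg = free$dg, sigma = free$sigma, n_windows = nrow(free$windows)),
    cycle = if (is.null(cyc)) NULL else
      list(ddg = cyc$ddg, sigma = cyc$sigma),
    kd_comparison = kd)
  if (!is.null(cfg$out_prefix)) {
    pre <- cfg$out_prefix
    write_outputs(pre, cfg, list(
      fep = function() jsonlite::write_json(
        summary, paste0(pre, "_fep.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)))
  }
  list(bound = bound, free = free, cycle = cyc, kd_comparison = kd,
       summary = summary)
}
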