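# Pipeline orchestration: config-driven stage commands with reproducible,
# fully provenanced outputs.  Each command is a pure function of
# (inputs, config, seed); a thin command-line launcher ships in
# inst/cli/occluder.R.

#' Read a run configuration
#'
#' @param path YAML config file.  Recognized keys depend on the stage; see
#'   [cmd_build_template()], [cmd_diagnose()], [cmd_hydrate()].
#' @return a `run_config` (named list).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- "run_config"
  cfg
}

.ensure_outdir <- function(config) {
  out <- config$out_dir
  if (is.null(out)) stop("config needs out_dir")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  # full config serialized into the output directory (provenance)
  yaml::write_yaml(unclass(config), file.path(out, "run_config.yaml"))
  out
}

.load_roles <- function(config) {
  if (is.null(config$role_map)) default_role_map()
  else read_role_map(config$role_map)
}

#' Build a chimeric template from a config
#'
#' Config keys: `target` (PDB path), `donor` (PDB path), `segment_map`
#' (YAML path), optional `role_map`, `out_dir`, `full_sequence` (optional,
#' enables PIR emission), `restraints` (optional generic_tsv path to
#' validate and re-emit alongside the template).
#'
#' Writes `chimera.pdb` (+ YAML sidecar), `segment_fits.csv`,
#' `report.json` (segment RMSDs and junction bond lengths), and optionally
#' `alignment.pir`.
#'
#' @param config a `run_config` or list.
#' @return the `chimera_record`, invisibly.
#' @export
cmd_build_template <- function(config) {
  out <- .ensure_outdir(config)
  for (key in c("target", "donor", "segment_map")) {
    if (is.null(config[[key]])) stop("config needs ", key)
    if (!file.exists(config[[key]]))
      stop("config ", key, ": file not found: ", config[[key]])
  }
  target <- read_structure(config$target)
  donor <- read_structure(config$donor)
  if (is.list(target) && !inherits(target, "structure3d")) target <- target[[1]]
  if (is.list(donor) && !inherits(donor, "structure3d")) donor <- donor[[1]]
  roles <- .load_roles(config)
  segments <- read_segment_map(config$segment_map)
  chim <- build_template(target, donor, segments, roles)
  write_chimera(chim, file.path(out, "chimera.pdb"))

  fits <- segment_fit_table(target, donor, list(default = segments), roles)
  utils::write.csv(fits[, c("candidate", "n_segments", "total_residues",
                            "combined_rmsd")],
                   file.path(out, "segment_fits.csv"), row.names = FALSE)
  jb <- junction_bond_lengths(chim)
  report <- list(
    segments = lapply(names(chim$transforms), function(nm)
      list(label = nm, backbone_rmsd = chim$transforms[[nm]]$rmsd)),
    donor_hash_rmsd = chim$donor_hash_transform$rmsd,
    junction_bonds = if (nrow(jb)) jb else NULL,
    n_repositioned = sum(chim$provenance == "repositioned_target"))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (!is.null(config$full_sequence)) {
    pir <- emit_pir_alignment(chim, config$full_sequence,
                              offset = config$offset %||% 0)
    writeLines(pir, file.path(out, "alignment.pir"))
  }
  invisible(chim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trajectory diagnostics from a config
#'
#' Config keys: `trajectories` (one or more multi-model PDB paths,
#' replicas), optional `reference` (PDB path; defaults to frame 1 of the
#' first replica), optional `role_map`, `out_dir`, `stride` (default 1),
#' `dt` (ns per frame, default 0.02), `gate_roles` (default
#' `c("EC_gate_salt", "EC_gate_lid")` as pairs plus `IC_gate_pairs`),
#' `chi_residues` (resid vector), `tilt_helices` (role names),
#' `rmsd_exclusions` (role names, default termini + EL2), `bin_width`
#' (A, default 0.1).
#'
#' Writes one CSV per metric plus pooled normalized histograms; with
#' several replicas, aggregate files with mean and standard error.
#'
#' @param config a `run_config` or list.
#' @return list of computed objects, invisibly.
#' @export
cmd_diagnose <- function(config) {
  out <- .ensure_outdir(config)
  paths <- config$trajectories
  if (is.null(paths)) stop("config needs trajectories")
  for (p in paths) if (!file.exists(p)) stop("trajectory not found: ", p)
  stride <- config$stride %||% 1
  trajs <- lapply(paths, read_trajectory, dt = config$dt %||% 0.02)
  roles <- .load_roles(config)
  reference <- if (!is.null(config$reference)) {
    r <- read_structure(config$reference)
    if (is.list(r) && !inherits(r, "structure3d")) r[[1]] else r
  } else get_frame(trajs[[1]], 1)
  results <- list()

  # gate distance series (EC salt bridge + lid as pairs, IC network pairs)
  pairs <- list()
  for (role in config$gate_roles %||% c("EC_gate_salt", "EC_gate_lid")) {
    rr <- role_residues(roles, role)
    if (nrow(rr) == 2) pairs[[role]] <- rr$resid
  }
  ic <- tryCatch(role_pairs(roles, "IC_gate_pairs"), error = function(e) NULL)
  pairs <- c(pairs, ic)
  # drop pairs whose residues are absent from the trajectory topology
  have <- unique(trajs[[1]]$topology$atoms$resid)
  resolvable <- vapply(pairs, function(p) all(p %in% have), logical(1))
  if (any(!resolvable))
    warning("dropping gate pair(s) not present in the topology: ",
            paste(vapply(pairs[!resolvable], paste, "", collapse = "-"),
                  collapse = ", "))
  pairs <- pairs[resolvable]
  if (length(pairs)) {
    per_rep <- lapply(trajs, pair_series, pairs = pairs, stride = stride)
    for (ri in seq_along(per_rep))
      write_series_csv(per_rep[[ri]],
                       file.path(out, sprintf("gates_rep%d.csv", ri)))
    if (length(trajs) > 1) {
      for (pi in seq_along(per_rep[[1]])) {
        agg <- aggregate_replicas(lapply(per_rep, `[[`, pi))
        utils::write.csv(agg, file.path(out, sprintf(
          "gates_aggregate_%s.csv", per_rep[[1]][[pi]]$label)),
          row.names = FALSE)
      }
    }
    pooled <- lapply(seq_along(per_rep[[1]]), function(pi)
      normalized_histogram(lapply(per_rep, `[[`, pi),
                           config$bin_width %||% 0.1))
    hist_df <- do.call(rbind, lapply(seq_along(pooled), function(pi)
      data.frame(label = per_rep[[1]][[pi]]$label, mid = pooled[[pi]]$mids,
                 density = pooled[[pi]]$density, unit = pooled[[pi]]$unit)))
    utils::write.csv(hist_df, file.path(out, "gate_histograms.csv"),
                     row.names = FALSE)
    results$gates <- per_rep
  } else warning("no gate pairs resolved; gate CSV not written")

  # chi1 series
  if (!is.null(config$chi_residues)) {
    chi_df <- do.call(rbind, lapply(seq_along(trajs), function(ri) {
      tr <- trajs[[ri]]
      do.call(rbind, lapply(config$chi_residues, function(r) {
        vals <- vapply(seq_len(n_frames(tr)), function(f)
          chi1(get_frame(tr, f), r), numeric(1))
        data.frame(replica = ri, resid = r, time_ns = tr$times, chi1 = vals)
      }))
    }))
    utils::write.csv(chi_df, file.path(out, "chi1.csv"), row.names = FALSE)
    results$chi1 <- chi_df
  }

  # helix tilts vs reference
  if (!is.null(config$tilt_helices)) {
    tilt_df <- do.call(rbind, lapply(seq_along(trajs), function(ri) {
      tr <- trajs[[ri]]
      do.call(rbind, lapply(config$tilt_helices, function(h) {
        vals <- vapply(seq_len(n_frames(tr)), function(f)
          helix_tilt(get_frame(tr, f), reference, h, roles), numeric(1))
        data.frame(replica = ri, helix = h, time_ns = tr$times, tilt = vals)
      }))
    }))
    utils::write.csv(tilt_df, file.path(out, "tilts.csv"), row.names = FALSE)
    results$tilts <- tilt_df
  }

  # backbone RMSD series (termini and EL2 excluded by default)
  excl <- config$rmsd_exclusions %||% c("termini_ranges", "EL2_range")
  rms <- lapply(trajs, function(tr)
    rmsd_series(tr, reference, fit_expr = "protein and backbone",
                exclusions = excl, roles = roles, unit = "nm"))
  write_series_csv(rms, file.path(out, "rmsd_backbone_nm.csv"))
  results$rmsd <- rms
  invisible(results)
}

#' Hydration analysis from a config
#'
#' Config keys: `trajectories` (multi-model PDB paths), optional
#' `role_map`, `out_dir`, `ligand_expr` (enables the occupancy grid),
#' `grid_radius` (default 20), `grid_spacing` (default 2), `bin_width`
#' (waters, default 1).
#'
#' Writes per-frame compartment counts per replica, pooled normalized
#' count distributions, and (if a ligand is given) an OpenDX occupancy
#' grid per replica.
#'
#' @param config a `run_config` or list.
#' @return list of computed objects, invisibly.
#' @export
cmd_hydrate <- function(config) {
  out <- .ensure_outdir(config)
  paths <- config$trajectories
  if (is.null(paths)) stop("config needs trajectories")
  trajs <- lapply(paths, read_trajectory, dt = config$dt %||% 0.02)
  roles <- .load_roles(config)
  spec <- build_compartments(get_frame(trajs[[1]], 1), roles,
                             strict = !isTRUE(config$lenient_box))
  counts <- lapply(seq_along(trajs), function(ri) {
    cs <- water_count_series(trajs[[ri]], spec)
    utils::write.csv(cs, file.path(out, sprintf("water_counts_rep%d.csv", ri)),
                     row.names = FALSE)
    cs
  })
  pooled <- do.call(rbind, counts)
  bw <- config$bin_width %||% 1
  hist_df <- do.call(rbind, lapply(c("n_ec", "n_site", "n_ic"), function(cmp) {
    h <- normalized_histogram(pooled[[cmp]], bw)
    data.frame(compartment = cmp, mid = h$mids, density = h$density)
  }))
  utils::write.csv(hist_df, file.path(out, "water_count_distributions.csv"),
                   row.names = FALSE)
  grids <- NULL
  if (!is.null(config$ligand_expr)) {
    grids <- lapply(seq_along(trajs), function(ri) {
      g <- occupancy_map(trajs[[ri]], config$ligand_expr,
                         radius = config$grid_radius %||% 20,
                         spacing = config$grid_spacing %||% 2)
      write_dx(g, file.path(out, sprintf("occupancy_rep%d.dx", ri)))
      g
    })
  }
  invisible(list(spec = spec, counts = counts, grids = grids))
}

#' Cluster docking poses from a config
#'
#' Config keys: `poses` (multi-model PDB of refined complexes),
#' `ligand_expr`, `site_expr`, optional `scores` (CSV, row i = pose i),
#' `out_dir`.  Writes cluster assignments, the Kelley penalty table and
#' per-pose fingerprints.
#'
#' @param config a `run_config` or list.
#' @return the [cluster_poses()] result, invisibly.
#' @export
cmd_cluster_poses <- function(config) {
  out <- .ensure_outdir(config)
  frames <- read_structure(config$poses, format = "multi_model_pdb")
  if (inherits(frames, "structure3d")) frames <- list(frames)
  scores <- if (!is.null(config$scores)) utils::read.csv(config$scores)
  ps <- pose_set_from_structures(frames, config$ligand_expr, config$site_expr,
                                 scores = scores)
  cl <- cluster_poses(ps)
  utils::write.csv(data.frame(pose = seq_along(cl$labels),
                              cluster = cl$labels),
                   file.path(out, "clusters.csv"), row.names = FALSE)
  utils::write.csv(attr(kelley_select(cl$tree), "penalty"),
                   file.path(out, "kelley_penalty.csv"), row.names = FALSE)
  fps <- do.call(rbind, lapply(seq_along(frames), function(i) {
    fp <- fingerprints(ps[[i]], frames[[i]])
    fp$pose <- i
    fp
  }))
  utils::write.csv(fps, file.path(out, "fingerprints.csv"), row.names = FALSE)
  invisible(cl)
}

#' Model QC from a config
#'
#' Config keys: `models` (PDB paths), optional `scores` (CSV with
#' `model_id` plus score columns), `out_dir`.  Writes a per-model QC table
#' (Ramachandran summary, clash count) as CSV and JSON.
#'
#' @param config a `run_config` or list.
#' @return the QC data.frame, invisibly.
#' @export
cmd_qc <- function(config) {
  out <- .ensure_outdir(config)
  rows <- lapply(config$models, function(p) {
    s <- read_structure(p)
    if (is.list(s) && !inherits(s, "structure3d")) s <- s[[1]]
    ra <- ramachandran(s)
    cl <- clash_report(s)
    data.frame(model = basename(p),
               pct_favored = ra$summary[["favored"]],
               pct_allowed = ra$summary[["allowed"]],
               pct_disallowed = ra$summary[["disallowed"]],
               n_clashes = nrow(cl))
  })
  qc <- do.call(rbind, rows)
  utils::write.csv(qc, file.path(out, "qc.csv"), row.names = FALSE)
  jsonlite::write_json(qc, file.path(out, "qc.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(qc)
}

#' Emit the toy fixture set from a config
#'
#' Config keys: `out_dir`, optional `seed` (default 1).  Writes the
#' two-state toy transporter (open/occluded PDB + role map + segment map +
#' ground-truth ledger YAML), a hydration frame, and a toy trajectory.
#'
#' @param config a `run_config` or list.
#' @return invisible NULL.
#' @export
cmd_make_fixtures <- function(config) {
  out <- .ensure_outdir(config)
  seed <- config$seed %||% 1L
  toy <- toy_transporter(seed = seed)
  write_structure(toy$open, file.path(out, "toy_open.pdb"))
  write_structure(toy$occluded, file.path(out, "toy_occluded.pdb"))
  yaml::write_yaml(list(roles = unclass(toy$roles)),
                   file.path(out, "toy_roles.yaml"))
  yaml::write_yaml(list(segments = lapply(toy$segments, function(s)
    list(label = s$label, target = paste(range(s$target_resids), collapse = "-"),
         donor = paste(range(s$donor_resids), collapse = "-")))),
    file.path(out, "toy_segments.yaml"))
  led <- toy$ledger
  led$segment_transforms <- lapply(led$segment_transforms, function(t_)
    list(angle = t_$angle, axis = as.numeric(t_$axis),
         origin = as.numeric(t_$origin)))
  led$global_transform <- NULL
  yaml::write_yaml(led, file.path(out, "toy_ledger.yaml"))

  spec <- build_compartments(toy$open, toy$roles, strict = FALSE)
  hf <- hydration_frame(spec, seed = seed)
  write_structure(hf$frame, file.path(out, "hydration_frame.pdb"))
  yaml::write_yaml(hf$ledger, file.path(out, "hydration_ledger.yaml"))

  tt <- toy_trajectory(seed = seed)
  write_trajectory(tt$traj, file.path(out, "toy_traj.pdb"))
  yaml::write_yaml(tt$ledger[c("gate_distances", "chi_schedule", "noise_sd")],
                   file.path(out, "trajectory_ledger.yaml"))
  invisible(NULL)
}
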