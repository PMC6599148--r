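# Pathway hydration: residue-anchored compartment box (extracellular
# vestibule / orthosteric site / intracellular vestibule), per-frame water
# counts, and frame-averaged occupancy grids.

#' Build the compartment box from anchor residues
#'
#' The interior box is 20 x 15 x 25 Angstrom, split along z (the membrane
#' normal; the structure must already be membrane-aligned) into a 9 A
#' extracellular vestibule, a 7 A orthosteric-site band and a 9 A
#' intracellular vestibule.  The site band is centered between the CA z of
#' the extracellular anchors (Y176/F335 by default role) and the
#' cytoplasmic anchor (F341), padded to exactly 7 A; x,y are centered on
#' the geometric center of the site anchors.
#'
#' @param structure a membrane-aligned `structure3d`.
#' @param roles a `role_map` providing `site_anchors_ec` and
#'   `site_anchor_cyt`.
#' @param strict if TRUE (default), an anchor span exceeding the 7 A site
#'   band is an error; otherwise a warning.
#' @return a `compartment_spec`.
#' @export
build_compartments <- function(structure, roles, strict = TRUE) {
  ec <- resolve_role(structure, roles, "site_anchors_ec", atoms = "CA")
  cy <- resolve_role(structure, roles, "site_anchor_cyt", atoms = "CA")
  ec_xyz <- coords(structure, ec)
  cy_xyz <- coords(structure, cy)
  z_ec <- mean(ec_xyz[, 3]); z_cy <- mean(cy_xyz[, 3])
  span <- abs(z_ec - z_cy)
  if (span > 7) {
    msg <- sprintf("site anchor z-span %.2f A exceeds the 7 A site band", span)
    if (strict) stop(msg) else warning(msg)
  }
  center_z <- (z_ec + z_cy) / 2
  ec_dir <- if (z_ec >= z_cy) 1 else -1
  site <- c(center_z - 3.5, center_z + 3.5)
  ecb <- if (ec_dir > 0) c(site[2], site[2] + 9) else c(site[1] - 9, site[1])
  icb <- if (ec_dir > 0) c(site[1] - 9, site[1]) else c(site[2], site[2] + 9)
  anchors_xy <- rbind(ec_xyz, cy_xyz)
  out <- list(center_xy = colMeans(anchors_xy[, 1:2, drop = FALSE]),
              x_half = 10, y_half = 7.5,
              z_site = site, z_ec = ecb, z_ic = icb, ec_dir = ec_dir,
              anchors = list(ec = ec_xyz, cyt = cy_xyz))
  class(out) <- "compartment_spec"
  out
}

#' @export
print.compartment_spec <- function(x, ...) {
  cat(sprintf(paste0("<compartment_spec> box 20 x 15 x 25 A at xy = ",
                     "(%.1f, %.1f); z bands EC [%.1f, %.1f] / site ",
                     "[%.1f, %.1f] / IC [%.1f, %.1f]\n"),
              x$center_xy[1], x$center_xy[2], x$z_ec[1], x$z_ec[2],
              x$z_site[1], x$z_site[2], x$z_ic[1], x$z_ic[2]))
  invisible(x)
}

.water_O_indices <- function(structure) {
  at <- structure$atoms
  which(at$resname %in% .water_resnames & toupper(at$element) == "O")
}

# band membership with the documented tie rule: intervals are (lo, hi], so
# a water exactly on a shared boundary belongs to the lower-z compartment
.in_band <- function(z, band) z > band[1] & z <= band[2]

#' Count waters per compartment in one frame
#'
#' Waters are located by their O atom (single point).  Each water falls in
#' exactly one compartment or outside; a water exactly on a z boundary is
#' assigned to the lower-z compartment.
#'
#' @param frame a `structure3d`.
#' @param spec a `compartment_spec`.
#' @return named integer vector `(n_ec, n_site, n_ic)` with attribute
#'   `n_outside`; no waters gives zeros.
#' @export
water_counts <- function(frame, spec) {
  idx <- .water_O_indices(frame)
  if (!length(idx)) {
    out <- c(n_ec = 0L, n_site = 0L, n_ic = 0L)
    attr(out, "n_outside") <- 0L
    return(out)
  }
  xyz <- coords(frame, idx)
  in_xy <- abs(xyz[, 1] - spec$center_xy[1]) <= spec$x_half &
    abs(xyz[, 2] - spec$center_xy[2]) <= spec$y_half
  z <- xyz[, 3]
  ec <- in_xy & .in_band(z, spec$z_ec)
  site <- in_xy & .in_band(z, spec$z_site)
  ic <- in_xy & .in_band(z, spec$z_ic)
  out <- c(n_ec = sum(ec), n_site = sum(site), n_ic = sum(ic))
  attr(out, "n_outside") <- length(idx) - sum(out)
  out
}

#' Per-frame compartment water counts for a trajectory
#' @param traj a `trajectory`.
#' @param spec a `compartment_spec`.
#' @return data.frame with `time_ns`, `n_ec`, `n_site`, `n_ic`, `n_outside`.
#' @export
water_count_series <- function(traj, spec) {
  rows <- lapply(seq_len(n_frames(traj)), function(i) {
    wc <- water_counts(get_frame(traj, i), spec)
    data.frame(time_ns = traj$times[i], n_ec = wc["n_ec"],
               n_site = wc["n_site"], n_ic = wc["n_ic"],
               n_outside = attr(wc, "n_outside"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Frame-averaged water occupancy grid around a ligand
#'
#' Every frame is Kabsch-fitted to the first frame on all protein backbone
#' atoms; water O atoms within `radius` of any ligand atom are binned on a
#' regular grid; each voxel value is the fraction of frames in which it is
#' occupied by at least one water.
#'
#' @param traj a `trajectory`.
#' @param ligand_expr selection expression for the ligand (must be
#'   non-empty in the topology; it is an error if empty).
#' @param radius inclusion radius around the ligand in Angstrom
#'   (default 20).
#' @param spacing grid spacing in Angstrom (default 2).
#' @return an `occupancy_grid`: list with `origin`, `spacing`, `dims`,
#'   `values` (3-d array in [0, 1]), `n_frames`.
#' @export
occupancy_map <- function(traj, ligand_expr, radius = 20, spacing = 2) {
  top <- traj$topology
  lig <- select_atoms(top, ligand_expr)
  if (!length(lig)) stop("ligand selection empty in frame 1")
  bb <- select_atoms(top, "protein and backbone")
  if (!length(bb)) stop("no protein backbone atoms to align on")
  wat <- .water_O_indices(top)
  ref_bb <- coords(get_frame(traj, 1), bb)
  lig0 <- coords(get_frame(traj, 1), lig)
  origin <- apply(lig0, 2, min) - radius - spacing
  upper <- apply(lig0, 2, max) + radius + spacing
  dims <- pmax(1L, as.integer(ceiling((upper - origin) / spacing)))
  acc <- array(0L, dims)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    fr <- get_frame(traj, f)
    if (!length(select_atoms(fr, ligand_expr)))
      stop("ligand missing in frame ", f)
    tr <- kabsch_fit(coords(fr, bb), ref_bb)
    fr <- apply_transform(fr, tr)
    ligf <- coords(fr, lig)
    if (!length(wat)) next
    wxyz <- coords(fr, wat)
    near <- vapply(seq_len(nrow(wxyz)), function(i) {
      d2 <- (ligf[, 1] - wxyz[i, 1])^2 + (ligf[, 2] - wxyz[i, 2])^2 +
        (ligf[, 3] - wxyz[i, 3])^2
      any(d2 <= radius^2)
    }, logical(1))
    if (!any(near)) next
    vox <- floor(sweep(wxyz[near, , drop = FALSE], 2, origin) / spacing) + 1
    ok <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
      vox[, 2] >= 1 & vox[, 2] <= dims[2] &
      vox[, 3] >= 1 & vox[, 3] <= dims[3]
    vox <- unique(vox[ok, , drop = FALSE])
    if (nrow(vox)) acc[vox] <- acc[vox] + 1L
  }
  out <- list(origin = origin, spacing = spacing, dims = dims,
              values = acc / nf, n_frames = nf)
  class(out) <- "occupancy_grid"
  out
}

#' Write an occupancy grid in OpenDX text format
#'
#' The grid is written as a regular-positions scalar field readable by
#' common molecular viewers.
#'
#' @param grid an `occupancy_grid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path) {
  d <- grid$dims
  n <- prod(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# water occupancy grid (fraction of frames occupied)",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.4f %.4f %.4f", grid$origin[1], grid$origin[2],
            grid$origin[3]),
    sprintf("delta %.4f 0 0", grid$spacing),
    sprintf("delta 0 %.4f 0", grid$spacing),
    sprintf("delta 0 0 %.4f", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n)
  ), con)
  # DX order: z fastest
  vals <- as.numeric(aperm(grid$values, c(1, 2, 3))[
    cbind(rep(seq_len(d[1]), each = d[2] * d[3]),
          rep(rep(seq_len(d[2]), each = d[3]), times = d[1]),
          rep(seq_len(d[3]), times = d[1] * d[2]))])
  rows <- split(vals, ceiling(seq_along(vals) / 3))
  writeLines(vapply(rows, function(r) paste(sprintf("%.6f", r), collapse = " "),
                    character(1)), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}
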