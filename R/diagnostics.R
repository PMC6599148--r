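# Conformational-state diagnostics: trajectory container, gate-distance
# series, chi1 rotamers, hash-superposed helix tilts, RMSD series and
# normalized distributions.

#' Construct a trajectory
#'
#' Frames share one topology (the atom table of the first frame); only
#' coordinates vary.  Times are in nanoseconds and must be strictly
#' increasing.
#'
#' @param structures list of `structure3d` with identical atom counts.
#' @param times numeric vector of frame times (ns); defaults to 0, 1, 2, ...
#' @return a `trajectory`: list with `topology`, `coords`
#'   (frames x atoms x 3 array), `times`.
#' @export
trajectory <- function(structures, times = NULL) {
  n <- length(structures)
  if (!n) stop("no frames")
  na <- nrow(structures[[1]]$atoms)
  if (is.null(times)) times <- seq_len(n) - 1
  if (length(times) != n) stop("times length != frame count")
  if (n > 1 && any(diff(times) <= 0)) stop("times must be strictly increasing")
  coords_arr <- array(NA_real_, c(n, na, 3))
  for (i in seq_len(n)) {
    if (nrow(structures[[i]]$atoms) != na)
      stop("frame ", i, ": atom count differs (", nrow(structures[[i]]$atoms),
           " vs ", na, ")")
    coords_arr[i, , ] <- coords(structures[[i]])
  }
  out <- list(topology = structures[[1]], coords = coords_arr,
              times = as.numeric(times))
  class(out) <- "trajectory"
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d frames x %d atoms, t = %g..%g ns\n",
              n_frames(x), dim(x$coords)[2], min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Extract one frame as a structure
#' @param traj a `trajectory`.
#' @param i frame index.
#' @return a `structure3d`.
#' @export
get_frame <- function(traj, i) {
  s <- traj$topology
  s <- set_coords(s, traj$coords[i, , ])
  s$model_id <- as.integer(i)
  s
}

#' Read a trajectory from a multi-model PDB
#' @param path file path.
#' @param dt frame spacing in ns (default 0.02, i.e. one frame per 20 ps).
#' @param t0 time of the first frame (ns).
#' @return a `trajectory`.
#' @export
read_trajectory <- function(path, dt = 0.02, t0 = 0) {
  frames <- read_structure(path, format = "multi_model_pdb")
  if (inherits(frames, "structure3d")) frames <- list(frames)
  trajectory(frames, times = t0 + dt * (seq_along(frames) - 1))
}

#' Write a trajectory as a multi-model PDB
#' @param traj a `trajectory`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  frames <- lapply(seq_len(n_frames(traj)), get_frame, traj = traj)
  write_structure(frames, path)
}

# ---------------------------------------------------------------------------
# Distances

#' Minimum distance between two selections
#'
#' Minimum over all cross pairs; heavy atoms only by default (crystal
#' reference states lack hydrogens, so gate metrics are heavy-atom metrics).
#'
#' @param frame a `structure3d`.
#' @param selA,selB non-empty `atom_selection`s.
#' @param heavy_only drop hydrogens first (default TRUE).
#' @return distance in Angstrom.
#' @export
min_distance <- function(frame, selA, selB, heavy_only = TRUE) {
  if (!length(selA) || !length(selB)) stop("empty selection")
  ia <- as.integer(selA); ib <- as.integer(selB)
  if (heavy_only) {
    el <- toupper(frame$atoms$element)
    ia <- ia[el[ia] != "H"]; ib <- ib[el[ib] != "H"]
    if (!length(ia) || !length(ib)) stop("selection empty after removing H")
  }
  A <- coords(frame, ia); B <- coords(frame, ib)
  best <- Inf
  for (i in seq_len(nrow(A))) {
    d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 + (B[, 3] - A[i, 3])^2
    best <- min(best, min(d2))
  }
  sqrt(best)
}

.distance_series <- function(label, times, values, unit = "A") {
  out <- list(label = label, times = as.numeric(times),
              values = as.numeric(values), unit = unit)
  if (any(out$values < 0)) stop("negative distances in series")
  class(out) <- "distance_series"
  out
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %s: %d points, %.2f-%.2f %s\n", x$label,
              length(x$values), min(x$values), max(x$values), x$unit))
  invisible(x)
}

#' Convert a distance series between Angstrom and nm
#' @param series a `distance_series`.
#' @param unit `"A"` or `"nm"`.
#' @return converted series (explicit unit field; never silent).
#' @export
convert_unit <- function(series, unit = c("A", "nm")) {
  unit <- match.arg(unit)
  if (series$unit == unit) return(series)
  f <- if (unit == "nm") 0.1 else 10
  series$values <- series$values * f
  series$unit <- unit
  series
}

#' Per-frame minimum-distance series for residue pairs
#'
#' The gate metric: for each residue pair, the per-frame minimum
#' heavy-atom distance between the two residues.
#'
#' @param traj a `trajectory`.
#' @param pairs list of 2-element residue-ID vectors (e.g. from
#'   [role_pairs()]), or a single vector.
#' @param stride keep every `stride`-th frame (default 1).
#' @param chain chain ID.
#' @return list of `distance_series`, labelled like `"R104-E493"`.
#' @export
pair_series <- function(traj, pairs, stride = 1, chain = "A") {
  if (!is.list(pairs)) pairs <- list(pairs)
  top <- traj$topology
  at <- top$atoms
  keep <- seq(1, n_frames(traj), by = stride)
  lapply(pairs, function(pr) {
    sa <- which(at$chain == chain & at$resid == pr[1] &
                  toupper(at$element) != "H")
    sb <- which(at$chain == chain & at$resid == pr[2] &
                  toupper(at$element) != "H")
    if (!length(sa) || !length(sb))
      stop("pair ", pr[1], "-", pr[2], " not resolvable in topology")
    lab <- paste0(.res_label(at$resname[sa[1]], pr[1]), "-",
                  .res_label(at$resname[sb[1]], pr[2]))
    vals <- vapply(keep, function(f) {
      A <- traj$coords[f, sa, , drop = FALSE]; dim(A) <- c(length(sa), 3)
      B <- traj$coords[f, sb, , drop = FALSE]; dim(B) <- c(length(sb), 3)
      best <- Inf
      for (i in seq_len(nrow(A))) {
        d2 <- (B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 + (B[, 3] - A[i, 3])^2
        best <- min(best, min(d2))
      }
      sqrt(best)
    }, numeric(1))
    .distance_series(lab, traj$times[keep], vals)
  })
}

#' Aggregate replicate series: mean and standard error at matched times
#'
#' @param series_list list of `distance_series` with identical time grids
#'   (one per replica).
#' @return data.frame with `time`, `mean`, `se`.
#' @export
aggregate_replicas <- function(series_list) {
  t0 <- series_list[[1]]$times
  for (s in series_list)
    if (!isTRUE(all.equal(s$times, t0))) stop("replica time grids differ")
  vals <- sapply(series_list, `[[`, "values")
  if (is.null(dim(vals))) vals <- matrix(vals, ncol = length(series_list))
  m <- rowMeans(vals)
  se <- apply(vals, 1, stats::sd) / sqrt(ncol(vals))
  data.frame(time = t0, mean = m, se = se)
}

# ---------------------------------------------------------------------------
# Helix tilt

.helix_axis <- function(structure, sel, method = c("helix", "principal")) {
  method <- match.arg(method)
  xyz <- coords(structure, sel)
  n <- nrow(xyz)
  if (n < 6) stop("helix axis unstable: fewer than 6 CA atoms")
  ax <- NULL
  if (method == "helix") {
    # geometric helix-axis estimator: second-difference vectors of the CA
    # trace point radially inward, so their successive cross products all
    # point along the axis (exact for an ideal helix, where the raw
    # principal axis of a finite CA cloud carries an end-effect tilt)
    D <- diff(xyz, differences = 2)
    cr <- t(vapply(seq_len(nrow(D) - 1), function(i) .cross3(D[i, ], D[i + 1, ]),
                   numeric(3)))
    m <- colMeans(cr)
    if (sqrt(sum(m^2)) > 1e-8) ax <- .unit(m)
  }
  if (is.null(ax)) {
    cc <- sweep(xyz, 2, colMeans(xyz))
    ax <- svd(cc)$v[, 1]
  }
  # orient N -> C (first to last residue)
  if (sum(ax * (xyz[n, ] - xyz[1, ])) < 0) ax <- -ax
  unname(ax)
}

#' Hash-superposed helix tilt angle
#'
#' The frame is superposed onto the reference using the hash-domain
#' backbone; the helix axis is the dominant principal axis of the helix CA
#' coordinates, oriented N-terminal to C-terminal; the tilt is the angle
#' between the frame and reference axes, folded into [0, 90] degrees.
#'
#' @param frame,reference `structure3d` objects containing the hash and
#'   helix roles.
#' @param helix_role role name (e.g. `"TM1b"`, `"TM6a"`).
#' @param roles a `role_map`, or `list(mobile = ..., reference = ...)`.
#' @param axis_method `"helix"` (geometric helix-axis estimator, exact on
#'   ideal helices) or `"principal"` (raw dominant principal axis);
#'   provided as a sensitivity diagnostic for the axis convention.
#' @return tilt angle in degrees.
#' @export
helix_tilt <- function(frame, reference, helix_role, roles,
                       axis_method = c("helix", "principal")) {
  axis_method <- match.arg(axis_method)
  rf <- if (!is.null(roles$mobile)) roles$mobile else roles
  rr <- if (!is.null(roles$reference)) roles$reference else roles
  tr <- hash_superpose(frame, reference, list(mobile = rf, reference = rr))
  frame_h <- apply_transform(frame, tr)
  a1 <- .helix_axis(frame_h, resolve_role(frame_h, rf, helix_role, atoms = "CA"),
                    method = axis_method)
  a2 <- .helix_axis(reference, resolve_role(reference, rr, helix_role,
                                            atoms = "CA"),
                    method = axis_method)
  ang <- acos(pmin(1, pmax(-1, sum(a1 * a2)))) * 180 / pi
  if (ang > 90) ang <- 180 - ang
  ang
}

# ---------------------------------------------------------------------------
# RMSD series

#' Per-frame fitted RMSD series
#'
#' Each frame is Kabsch-fitted to the reference on `fit_expr` (after
#' removing any `exclusions` roles) and the RMSD is reported over
#' `report_expr` without refitting.  With the default
#' `report_expr = fit_expr` this is the usual backbone RMSD; with
#' `fit_expr` = protein backbone and `report_expr` = ligand heavy atoms it
#' is the in-site ligand RMSD.
#'
#' @param traj a `trajectory`.
#' @param reference a `structure3d` with the same atom table.
#' @param fit_expr selection expression for the fit.
#' @param report_expr selection expression for the reported RMSD
#'   (default: same as `fit_expr`).
#' @param exclusions character vector of role names to exclude (e.g.
#'   termini and the large extracellular loop EL2).
#' @param roles a `role_map` (needed only when `exclusions` given).
#' @param unit `"A"` or `"nm"`.
#' @return a `distance_series`.
#' @export
rmsd_series <- function(traj, reference, fit_expr = "backbone",
                        report_expr = NULL, exclusions = NULL, roles = NULL,
                        unit = "A") {
  sel_fit <- as.integer(select_atoms(reference, fit_expr))
  sel_rep <- if (is.null(report_expr)) sel_fit
             else as.integer(select_atoms(reference, report_expr))
  if (!is.null(exclusions)) {
    if (is.null(roles)) stop("exclusions need a role map")
    drop <- unlist(lapply(exclusions, function(nm) {
      res <- role_residues(roles, nm)
      which(paste(reference$atoms$chain, reference$atoms$resid) %in%
              paste(res$chain, res$resid))
    }))
    sel_fit <- setdiff(sel_fit, drop)
    sel_rep <- setdiff(sel_rep, drop)
  }
  if (!length(sel_fit) || !length(sel_rep))
    stop("empty selection after exclusions")
  ref_fit <- coords(reference, sel_fit)
  ref_rep <- coords(reference, sel_rep)
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    ff <- traj$coords[f, sel_fit, , drop = FALSE]; dim(ff) <- c(length(sel_fit), 3)
    fr <- traj$coords[f, sel_rep, , drop = FALSE]; dim(fr) <- c(length(sel_rep), 3)
    tr <- kabsch_fit(ff, ref_fit)
    rmsd_nofit(apply_transform(fr, tr), ref_rep)
  }, numeric(1))
  s <- .distance_series(paste0("rmsd[", fit_expr, "]"), traj$times, vals)
  convert_unit(s, unit)
}

# ---------------------------------------------------------------------------
# Histograms

#' Normalized histogram of one or more series
#'
#' Pools the values of all inputs (replicas pooled over combined time) and
#' bins them at `bin_width`; the result is a density: sum(density) x
#' bin_width = 1.
#'
#' @param series a `distance_series`, a list of them, or a numeric vector.
#' @param bin_width bin width (> 0), in the series unit.
#' @return a `normalized_histogram`: list with `edges`, `mids`, `density`,
#'   `unit`, `n`.
#' @export
normalized_histogram <- function(series, bin_width) {
  if (bin_width <= 0) stop("bin width must be > 0")
  unit <- "A"
  if (inherits(series, "distance_series")) {
    unit <- series$unit; vals <- series$values
  } else if (is.list(series)) {
    units <- vapply(series, `[[`, "", "unit")
    if (length(unique(units)) > 1) stop("cannot pool series with mixed units")
    unit <- units[1]
    vals <- unlist(lapply(series, `[[`, "values"))
  } else vals <- as.numeric(series)
  if (!length(vals)) stop("no values to bin")
  lo <- floor(min(vals) / bin_width) * bin_width
  hi <- ceiling(max(vals) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  edges <- seq(lo, hi, by = bin_width)
  counts <- tabulate(pmin(findInterval(vals, edges, rightmost.closed = TRUE),
                          length(edges) - 1), nbins = length(edges) - 1)
  density <- counts / (sum(counts) * bin_width)
  out <- list(edges = edges, mids = edges[-1] - bin_width / 2,
              density = density, unit = unit, n = length(vals))
  class(out) <- "normalized_histogram"
  out
}

#' Write distance series to CSV
#' @param series a `distance_series` or list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "distance_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(label = s$label, time_ns = s$times, value = s$values,
               unit = s$unit)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
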