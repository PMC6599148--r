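# Synthetic fixtures: ideal helices, two-state toy transporters with
# planted segment rotations, hydration frames with planted water counts,
# and toy trajectories with planted distance/dihedral time courses.
# Fixtures are poly-ALA (plus a PHE-like branch where chi tests need a CG):
# non-physical side-chain chemistry, geometrically exact.

# Cylindrical offsets of backbone atoms relative to the CA helix of an
# ideal alpha-helix (radius A, phase deg relative to CA of the same
# residue, z offset A along the axis).  Derived once from a
# (-57, -47) internal-coordinate helix.
.helix_offsets <- list(
  N  = c(r = 1.548, dphase = 26.9, dz = -0.919),
  CA = c(r = 2.271, dphase = 0.0, dz = 0.0),
  C  = c(r = 1.663, dphase = -26.8, dz = 1.069),
  O  = c(r = 1.917, dphase = -20.4, dz = 2.257),
  CB = c(r = 3.391, dphase = 17.0, dz = 0.644)
)

#' Ideal poly-ALA alpha helix
#'
#' Backbone + CB on an ideal helical lattice (every atom type on its own
#' coaxial helix).  After construction the structure is rotated so the
#' dominant principal axis of its CA atoms is exactly +z (N- to
#' C-terminal).
#'
#' @param n_res number of residues (>= 4).
#' @param rise rise per residue in Angstrom (default 1.5).
#' @param twist twist per residue in degrees (default 100).
#' @param chain chain ID.
#' @param resid_start first residue number.
#' @param center xyz position of the helix centroid (default origin).
#' @return a `structure3d`.
#' @export
ideal_helix <- function(n_res, rise = 1.5, twist = 100, chain = "A",
                        resid_start = 1L, center = c(0, 0, 0)) {
  if (n_res < 4) stop("need at least 4 residues for a helix")
  rows <- list()
  for (i in seq_len(n_res)) {
    for (nm in names(.helix_offsets)) {
      o <- .helix_offsets[[nm]]
      # right-handed alpha helix: phase decreases as z increases in this frame
      th <- (-(i - 1) * twist + o[["dphase"]]) * pi / 180
      rows[[length(rows) + 1]] <- data.frame(
        name = nm, resname = "ALA", chain = chain,
        resid = resid_start + i - 1L,
        x = o[["r"]] * cos(th), y = o[["r"]] * sin(th),
        z = (i - 1) * rise + o[["dz"]],
        element = substr(nm, 1, 1), het = FALSE, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  df$serial <- seq_len(nrow(df))
  s <- structure3d(df, source = sprintf("ideal_helix(n=%d)", n_res))
  # lattice axis is +z by construction (and so is the helix axis computed
  # by the package's estimator, which is exact on ideal helices)
  ca <- which(s$atoms$name == "CA")
  xyz <- coords(s)
  shift <- center - colMeans(xyz[ca, , drop = FALSE])
  set_coords(s, sweep(xyz, 2, shift, `+`))
}

# append a PHE-like residue (N, CA, CB, CG, CD1, CD2) with a given chi1 to
# an atom table, at an arbitrary location
.phe_branch <- function(chain, resid, chi = 60, origin = c(0, 0, 0)) {
  N <- origin
  CA <- origin + c(1.458, 0, 0)
  CB <- .place_atom(origin + c(0, 1, 0), N, CA, 1.53, 110.5, 0)
  CG <- .place_atom(N, CA, CB, 1.52, 114, chi)
  CD1 <- .place_atom(CA, CB, CG, 1.39, 120, 90)
  CD2 <- .place_atom(CA, CB, CG, 1.39, 120, -90)
  xyz <- rbind(N, CA, CB, CG, CD1, CD2)
  data.frame(name = c("N", "CA", "CB", "CG", "CD1", "CD2"), resname = "PHE",
             chain = chain, resid = resid, x = xyz[, 1], y = xyz[, 2],
             z = xyz[, 3], element = c("N", "C", "C", "C", "C", "C"),
             het = FALSE, stringsAsFactors = FALSE)
}

#' Two-state toy transporter with planted segment rotations
#'
#' Builds a minimal LeuT-fold caricature: eight 20-residue helices on a
#' ring, four of them the quasi-static hash (TM3/TM4/TM8/TM9), with the
#' extracellular halves of the TM1 and TM6 analogs (TM1b, TM6a) as mobile
#' bundle segments.  The occluded state equals the open state with those
#' segments rotated by planted angles about axes perpendicular to the helix
#' axes; the hash is identical between states.  An optional planted global
#' rigid transform is applied to the occluded state afterwards.  Every
#' planted quantity is recorded in the returned ground-truth ledger.
#'
#' @param tilt_angles named numeric: planted rotation in degrees per
#'   segment (default `c(TM1b = 17, TM6a = 8)`, mirroring the tilt regime
#'   of the outward-occluded transition).
#' @param global_rotation,global_translation optional planted global motion
#'   of the occluded state: rotation angle (degrees, about `global_axis`
#'   through the origin) and translation 3-vector.
#' @param global_axis axis for the global rotation.
#' @param seed integer seed (fixtures are deterministic given the seed).
#' @return list with `open`, `occluded` (`structure3d`), `roles`
#'   (`role_map`), `segments` (`segment_map`) and `ledger`.
#' @export
toy_transporter <- function(tilt_angles = c(TM1b = 17, TM6a = 8),
                            global_rotation = 0, global_axis = c(0, 0, 1),
                            global_translation = c(0, 0, 0), seed = 1L) {
  set.seed(seed)
  n <- 20L
  helices <- list(TM1 = 1L, TM2 = 21L, TM3 = 41L, TM4 = 61L, TM6 = 81L,
                  TM7 = 101L, TM8 = 121L, TM9 = 141L)
  ring_r <- 12
  parts <- list()
  for (k in seq_along(helices)) {
    th <- (k - 1) * 2 * pi / length(helices)
    parts[[k]] <- ideal_helix(n, resid_start = helices[[k]],
                              center = c(ring_r * cos(th), ring_r * sin(th), 0))
  }
  atoms <- do.call(rbind, lapply(parts, function(p) p$atoms))
  atoms$serial <- seq_len(nrow(atoms))
  open <- structure3d(atoms, source = "toy_transporter(open)")

  seg_ranges <- list(TM1b = 11:20, TM6a = 91:100)
  occluded <- open
  seg_ledger <- list()
  for (nm in names(tilt_angles)) {
    rng <- seg_ranges[[nm]]
    if (is.null(rng)) stop("unknown segment '", nm, "' (use TM1b / TM6a)")
    idx <- which(occluded$atoms$resid %in% rng)
    ca <- which(occluded$atoms$resid %in% rng & occluded$atoms$name == "CA")
    base <- coords(occluded)[ca[1], ]
    # rotation axis perpendicular to the helix axis (z): radial direction
    axis <- .unit(c(base[1], base[2], 0))
    ang <- tilt_angles[[nm]]
    xyz <- coords(occluded, idx)
    occluded <- set_coords(occluded, .rotate_about_line(xyz, axis, ang, base),
                           idx)
    seg_ledger[[nm]] <- list(angle = ang, axis = axis, origin = base)
  }
  gl <- NULL
  if (abs(global_rotation) > 0 || any(global_translation != 0)) {
    R <- rotation_about_axis(global_axis, global_rotation)
    tr <- list(rotation = R, translation = as.numeric(global_translation),
               rmsd = 0)
    class(tr) <- "rigid_transform"
    occluded <- apply_transform(occluded, tr)
    gl <- tr
  }
  occluded$source <- "toy_transporter(occluded)"

  roles <- list(
    TM1a = list(chain = "A", resid = "1-10"),
    TM1b = list(chain = "A", resid = "11-20"),
    TM2 = list(chain = "A", resid = "21-40"),
    TM3 = list(chain = "A", resid = "41-60"),
    TM4 = list(chain = "A", resid = "61-80"),
    TM5 = list(chain = "A", resid = "21-40"),    # alias: toy has 8 helices
    TM6a = list(chain = "A", resid = "91-100"),
    TM6b = list(chain = "A", resid = "81-90"),
    TM7 = list(chain = "A", resid = "101-120"),
    TM8 = list(chain = "A", resid = "121-140"),
    TM9 = list(chain = "A", resid = "141-160"),
    TM10 = list(chain = "A", resid = "101-120"), # alias
    TM11 = list(chain = "A", resid = "121-140"), # alias
    TM12 = list(chain = "A", resid = "141-160"), # alias
    hash = list(union = c("TM3", "TM4", "TM8", "TM9")),
    EC_gate_salt = list(chain = "A", resid = c(15, 110)),
    EC_gate_lid = list(chain = "A", resid = c(50, 95)),
    IC_gate_pairs = list(chain = "A", pairs = list(c(5, 125), c(6, 126))),
    amine_partners = list(chain = "A", resid = c(12, 13, 95, 96)),
    site_anchors_ec = list(chain = "A", resid = c(52, 92)),
    site_anchor_cyt = list(chain = "A", resid = 88),
    ec_vestibule_limit = list(chain = "A", resid = c(15, 110)),
    ic_vestibule_limit = list(chain = "A", resid = c(3, 25)),
    EL2_range = list(chain = "A", resid = "41-44"),
    termini_ranges = list(chain = "A", resid = c("1-2", "159-160"))
  )
  class(roles) <- "role_map"

  segments <- segment_map(list(
    list(label = "TM1b", target = "11-20", donor = "11-20"),
    list(label = "TM6a", target = "91-100", donor = "91-100")))

  list(open = open, occluded = occluded, roles = roles, segments = segments,
       ledger = list(seed = seed, segment_transforms = seg_ledger,
                     global_transform = gl))
}

#' Hydration frame with planted per-compartment water counts
#'
#' Places waters uniformly at random (seeded) strictly inside each
#' requested compartment band (0.2 A margin from every boundary) and, for
#' the `n_outside` waters, strictly outside the box.
#'
#' @param spec a `compartment_spec`.
#' @param counts integer vector `c(ec, site, ic)` of waters per band.
#' @param n_outside waters placed outside the box.
#' @param seed integer seed.
#' @return list with `frame` (`structure3d` of water O atoms) and `ledger`
#'   (planted truth).
#' @export
hydration_frame <- function(spec, counts = c(3, 2, 4), n_outside = 5,
                            seed = 1L) {
  if (any(counts < 0) || n_outside < 0) stop("counts must be >= 0")
  set.seed(seed)
  m <- 0.2
  bands <- list(ec = spec$z_ec, site = spec$z_site, ic = spec$z_ic)
  place_in <- function(k, band) {
    if (band[2] - band[1] <= 2 * m) stop("zero-volume band")
    cbind(stats::runif(k, spec$center_xy[1] - spec$x_half + m,
                       spec$center_xy[1] + spec$x_half - m),
          stats::runif(k, spec$center_xy[2] - spec$y_half + m,
                       spec$center_xy[2] + spec$y_half - m),
          stats::runif(k, band[1] + m, band[2] - m))
  }
  xyz <- do.call(rbind, lapply(seq_along(bands), function(i)
    if (counts[i] > 0) place_in(counts[i], bands[[i]]) else NULL))
  if (n_outside > 0) {
    # outside in x, beyond the box wall
    side <- sample(c(-1, 1), n_outside, replace = TRUE)
    allz <- range(unlist(bands))
    xyz <- rbind(xyz, cbind(
      spec$center_xy[1] + side * stats::runif(n_outside, spec$x_half + 1,
                                              spec$x_half + 8),
      stats::runif(n_outside, spec$center_xy[2] - spec$y_half,
                   spec$center_xy[2] + spec$y_half),
      stats::runif(n_outside, allz[1], allz[2])))
  }
  if (is.null(xyz)) xyz <- matrix(numeric(), ncol = 3)
  k <- nrow(xyz)
  df <- data.frame(serial = seq_len(k), name = "O", resname = "HOH",
                   chain = "W", resid = seq_len(k),
                   x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                   element = "O", het = TRUE, stringsAsFactors = FALSE)
  frame <- structure3d(df, source = "hydration_frame")
  list(frame = frame,
       ledger = list(seed = seed, counts = stats::setNames(
         as.integer(counts), c("n_ec", "n_site", "n_ic")),
         n_outside = as.integer(n_outside)))
}

#' Toy trajectory with planted distance and dihedral time courses
#'
#' Frames contain: a 20-residue helix backdrop (resid 201-220) for RMSD
#' fitting; a gate pair realized as two single-atom pseudo-residues
#' (resid 1 and 2) separated along x by the planted distance; and a
#' PHE-like branch (resid 3) whose chi1 follows the planted schedule.
#' Planted values are realized exactly before noise; optional isotropic
#' Gaussian coordinate noise (sd in Angstrom) is added to every atom.
#'
#' @param gate_distances numeric vector: planted gate distance per frame (A).
#' @param chi_schedule numeric vector: planted chi1 per frame (degrees),
#'   same length as `gate_distances`.
#' @param noise_sd isotropic Gaussian noise sd per coordinate (A);
#'   default 0.
#' @param dt frame spacing in ns (default 0.02).
#' @param seed integer seed.
#' @return list with `traj` (`trajectory`) and `ledger`.
#' @export
toy_trajectory <- function(gate_distances = c(3, 8, 3, 8, 3),
                           chi_schedule = rep(60, length(gate_distances)),
                           noise_sd = 0, dt = 0.02, seed = 1L) {
  nf <- length(gate_distances)
  if (length(chi_schedule) != nf)
    stop("schedule lengths differ: ", nf, " vs ", length(chi_schedule))
  set.seed(seed)
  backdrop <- ideal_helix(20, resid_start = 201L, center = c(30, 0, 0))
  frames <- lapply(seq_len(nf), function(f) {
    g1 <- data.frame(name = "CA", resname = "GTA", chain = "A", resid = 1L,
                     x = 0, y = -15, z = 0, element = "C", het = TRUE,
                     stringsAsFactors = FALSE)
    g2 <- g1; g2$resid <- 2L; g2$x <- gate_distances[f]
    phe <- .phe_branch("A", 3L, chi = chi_schedule[f], origin = c(-15, 10, 0))
    at <- rbind(g1, g2, phe[, names(g1)], backdrop$atoms[, names(g1)])
    at$serial <- seq_len(nrow(at))
    s <- structure3d(at, model_id = f, source = "toy_trajectory")
    if (noise_sd > 0) {
      xyz <- coords(s)
      s <- set_coords(s, xyz + matrix(stats::rnorm(length(xyz), 0, noise_sd),
                                      ncol = 3))
    }
    s
  })
  traj <- trajectory(frames, times = dt * (seq_len(nf) - 1))
  list(traj = traj,
       ledger = list(seed = seed, gate_pair = c(1L, 2L),
                     gate_distances = gate_distances, chi_resid = 3L,
                     chi_schedule = chi_schedule, noise_sd = noise_sd))
}
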