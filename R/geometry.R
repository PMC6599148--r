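# Low-level geometry: vectors, dihedrals, internal-coordinate atom
# placement, rotations about arbitrary axes, side-chain chi handling.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize near-zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Signed dihedral angle of four points
#'
#' Standard right-handed convention; result in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 3-vectors (Angstrom).
#' @return angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- .cross3(b1, b2)
  n2 <- .cross3(b2, b3)
  m1 <- .cross3(n1, .unit(b2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# Place atom D bonded to C with bond length, angle B-C-D (deg) and
# dihedral A-B-C-D (deg).  Sign convention matches dihedral_angle(), i.e.
# dihedral_angle(A, B, C, D) returns `torsion`.
.place_atom <- function(a, b, c, bond, angle, torsion) {
  angle <- angle * pi / 180
  torsion <- -torsion * pi / 180  # sign flip: local frame is left-handed
  bc <- .unit(c - b)
  n <- .unit(.cross3(b - a, bc))
  m <- .cross3(n, bc)
  d2 <- bond * c(-cos(angle), sin(angle) * cos(torsion), sin(angle) * sin(torsion))
  as.numeric(c + cbind(bc, m, n) %*% d2)
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis 3-vector (normalized internally).
#' @param angle rotation angle in degrees (right-handed).
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- .unit(axis)
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# rotate points about a line through `origin` along `axis`
.rotate_about_line <- function(xyz, axis, angle, origin) {
  R <- rotation_about_axis(axis, angle)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
}

# ---------------------------------------------------------------------------
# Side-chain chi definitions (heavy-atom convention).  For each residue type
# and chi index: the four defining atoms; atoms listed after the bond atoms
# rotate rigidly when the chi is set.

.chi_defs <- list(
  ARG = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "NE"), c("CG", "CD", "NE", "CZ")),
  ASN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  ASP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "OD1")),
  CYS = list(c("N", "CA", "CB", "SG")),
  GLN = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  GLU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "OE1")),
  HIS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "ND1")),
  ILE = list(c("N", "CA", "CB", "CG1"), c("CA", "CB", "CG1", "CD1")),
  LEU = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  LYS = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD"),
             c("CB", "CG", "CD", "CE"), c("CG", "CD", "CE", "NZ")),
  MET = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "SD"),
             c("CB", "CG", "SD", "CE")),
  PHE = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  PRO = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD")),
  SER = list(c("N", "CA", "CB", "OG")),
  THR = list(c("N", "CA", "CB", "OG1")),
  TRP = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  TYR = list(c("N", "CA", "CB", "CG"), c("CA", "CB", "CG", "CD1")),
  VAL = list(c("N", "CA", "CB", "CG1"))
)

# side-chain atom names per residue, in "distance from CA" order, used to
# decide which atoms are distal to a rotated chi bond
.sidechain_atoms <- list(
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

.chi_def_for <- function(resname, chi_index) {
  defs <- .chi_defs[[toupper(resname)]]
  if (is.null(defs) || chi_index > length(defs)) return(NULL)
  defs[[chi_index]]
}

# atoms distal to the chi_index bond (rotate rigidly on set_chi).  The bond
# axis is def[2]-def[3]; everything in the side chain beyond def[3] moves,
# including def[4].
.chi_distal_atoms <- function(resname, chi_index) {
  def <- .chi_def_for(resname, chi_index)
  sc <- .sidechain_atoms[[toupper(resname)]]
  if (is.null(def) || is.null(sc)) return(NULL)
  pivot <- match(def[3], sc)
  if (is.na(pivot)) return(NULL)
  sc[(pivot + 1):length(sc)][seq_len(max(0, length(sc) - pivot))]
}

.residue_atom_xyz <- function(structure, chain, resid, name) {
  at <- structure$atoms
  i <- which(at$chain == chain & at$resid == resid & at$name == name)
  if (!length(i)) return(NULL)
  as.numeric(at[i[1], c("x", "y", "z")])
}

#' Measure a side-chain chi dihedral
#'
#' Heavy-atom convention (chi1 = N-CA-CB-CG for PHE/TYR/TRP, N-CA-CB-OG for
#' SER, ...).  Residues without the defining atoms (GLY, ALA, truncated side
#' chains) are reported as unevaluable (`NA`) rather than guessed.
#'
#' @param structure a `structure3d`.
#' @param resid residue number (author numbering).
#' @param chain chain ID.
#' @param chi_index which chi (default 1).
#' @param branch `"principal"` reports in (-180, 180]; `"unwrapped_minus"`
#'   reports angles in (-360, 0] (the other branch of the same dihedral),
#'   for comparison with circular means near the branch cut.
#' @return angle in degrees, or `NA` with attribute `reason` if unevaluable.
#' @export
chi1 <- function(structure, resid, chain = "A", chi_index = 1,
                 branch = c("principal", "unwrapped_minus")) {
  branch <- match.arg(branch)
  at <- structure$atoms
  row <- at[at$chain == chain & at$resid == resid, , drop = FALSE]
  if (!nrow(row)) stop("residue ", chain, ":", resid, " not in structure")
  resname <- row$resname[1]
  def <- .chi_def_for(resname, chi_index)
  if (is.null(def)) {
    out <- NA_real_
    attr(out, "reason") <- paste0("no chi", chi_index, " defined for ", resname)
    return(out)
  }
  pts <- lapply(def, function(nm) .residue_atom_xyz(structure, chain, resid, nm))
  if (any(vapply(pts, is.null, logical(1)))) {
    out <- NA_real_
    attr(out, "reason") <- paste0("missing atom(s): ",
      paste(def[vapply(pts, is.null, logical(1))], collapse = ", "))
    return(out)
  }
  ang <- dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
  if (branch == "unwrapped_minus" && ang > 0) ang <- ang - 360
  ang
}

#' Set a side-chain chi dihedral to an absolute value
#'
#' Atoms distal to the rotated bond move rigidly about it so the named chi
#' equals `angle`; bond lengths and angles are untouched.  Setting is
#' absolute: setting twice is equivalent to the last set.
#'
#' @param structure a `structure3d`.
#' @param resid residue number.
#' @param angle target angle in degrees, in (-180, 180].
#' @param chain chain ID.
#' @param chi_index which chi (default 1).
#' @return modified `structure3d`.
#' @export
set_chi <- function(structure, resid, angle, chain = "A", chi_index = 1) {
  if (angle <= -180 || angle > 180) stop("angle must be in (-180, 180]")
  at <- structure$atoms
  row <- at[at$chain == chain & at$resid == resid, , drop = FALSE]
  if (!nrow(row)) stop("residue ", chain, ":", resid, " not in structure")
  resname <- row$resname[1]
  def <- .chi_def_for(resname, chi_index)
  if (is.null(def)) stop("no chi", chi_index, " defined for ", resname)
  cur <- chi1(structure, resid, chain, chi_index)
  if (is.na(cur)) stop("chi", chi_index, " unevaluable for ", resname, resid,
                       ": ", attr(cur, "reason"))
  b <- .residue_atom_xyz(structure, chain, resid, def[2])
  c_ <- .residue_atom_xyz(structure, chain, resid, def[3])
  distal <- c(def[4], .chi_distal_atoms(resname, chi_index))
  idx <- which(at$chain == chain & at$resid == resid & at$name %in% distal)
  if (!length(idx)) stop("no distal atoms to rotate for ", resname, resid)
  delta <- angle - cur
  xyz <- coords(structure, idx)
  # a right-handed rotation about the b->c axis decreases the dihedral
  newxyz <- .rotate_about_line(xyz, c_ - b, -delta, c_)
  set_coords(structure, newxyz, idx)
}

#' Backbone phi/psi dihedrals
#'
#' Chain breaks (consecutive CA-CA > 4.5 Angstrom) split the dihedral chain;
#' residues at termini or breaks have `NA` phi or psi.
#'
#' @param structure a `structure3d`.
#' @param chain chain ID, or `NULL` for all chains.
#' @return data.frame with `chain`, `resid`, `resname`, `phi`, `psi`.
#' @export
phi_psi <- function(structure, chain = NULL) {
  at <- structure$atoms
  at <- at[!at$het & at$name %in% c("N", "CA", "C"), , drop = FALSE]
  if (!is.null(chain)) at <- at[at$chain %in% chain, , drop = FALSE]
  out <- list()
  for (ch in unique(at$chain)) {
    a <- at[at$chain == ch, , drop = FALSE]
    resids <- unique(a$resid)
    if (length(resids) < 3) next
    get <- function(r, nm) {
      i <- which(a$resid == r & a$name == nm)
      if (length(i)) as.numeric(a[i[1], c("x", "y", "z")]) else NULL
    }
    linked <- function(r1, r2) {
      ca1 <- get(r1, "CA"); ca2 <- get(r2, "CA")
      !is.null(ca1) && !is.null(ca2) && sqrt(sum((ca2 - ca1)^2)) <= 4.5
    }
    n <- length(resids)
    phi <- psi <- rep(NA_real_, n)
    for (k in seq_len(n)) {
      r <- resids[k]
      Np <- get(r, "N"); CAp <- get(r, "CA"); Cp <- get(r, "C")
      if (is.null(Np) || is.null(CAp) || is.null(Cp)) next
      if (k > 1 && linked(resids[k - 1], r)) {
        Cm <- get(resids[k - 1], "C")
        if (!is.null(Cm)) phi[k] <- dihedral_angle(Cm, Np, CAp, Cp)
      }
      if (k < n && linked(r, resids[k + 1])) {
        Nn <- get(resids[k + 1], "N")
        if (!is.null(Nn)) psi[k] <- dihedral_angle(Np, CAp, Cp, Nn)
      }
    }
    resname <- vapply(resids, function(r) a$resname[a$resid == r][1], character(1))
    out[[ch]] <- data.frame(chain = ch, resid = resids, resname = resname,
                            phi = phi, psi = psi, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chain = character(), resid = integer(),
                      resname = character(), phi = numeric(), psi = numeric()))
  do.call(rbind, c(out, make.row.names = FALSE))
}
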