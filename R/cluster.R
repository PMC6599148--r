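# Docking-pose clustering: no-fit RMSD distance matrix, average-linkage
# agglomeration, Kelley-penalty cluster-number selection, and interaction
# fingerprints for cluster characterization.

#' Construct a pose set
#'
#' @param poses list of poses, each a list with `ligand` (heavy-atom
#'   coordinate matrix with atom-name rownames), `site` (binding-site
#'   backbone coordinate matrix) and optional named `scores`.
#' @return a `pose_set`.  All poses must share atom names and counts.
#' @export
pose_set <- function(poses) {
  if (length(poses) < 1) stop("empty pose list")
  ref_lig <- rownames(poses[[1]]$ligand)
  nsite <- nrow(poses[[1]]$site)
  for (i in seq_along(poses)) {
    p <- poses[[i]]
    if (!identical(rownames(p$ligand), ref_lig))
      stop("pose ", i, ": ligand atom names differ from pose 1")
    if (nrow(p$site) != nsite)
      stop("pose ", i, ": site atom count differs from pose 1")
  }
  class(poses) <- "pose_set"
  poses
}

#' Build a pose set from structures
#'
#' @param structures list of `structure3d` (e.g. from a multi-model PDB),
#'   each containing the ligand and the refined binding site.
#' @param ligand_expr selection expression for the ligand (heavy atoms
#'   taken automatically).
#' @param site_expr selection expression for the binding-site backbone,
#'   e.g. `"resid 95 96 98 ... and backbone"`.
#' @param scores optional data.frame of per-pose scores (row i = pose i).
#' @return a `pose_set`.
#' @export
pose_set_from_structures <- function(structures, ligand_expr, site_expr,
                                     scores = NULL) {
  poses <- lapply(seq_along(structures), function(i) {
    s <- structures[[i]]
    lig <- select_atoms(s, paste0("(", ligand_expr, ") and heavy"))
    site <- select_atoms(s, site_expr)
    if (!length(lig)) stop("pose ", i, ": ligand selection empty")
    if (!length(site)) stop("pose ", i, ": site selection empty")
    lm <- coords(s, lig)
    rownames(lm) <- s$atoms$name[as.integer(lig)]
    list(ligand = lm, site = coords(s, site),
         scores = if (!is.null(scores)) as.list(scores[i, , drop = FALSE]))
  })
  pose_set(poses)
}

.pose_coords <- function(pose) rbind(pose$ligand, pose$site)

#' Pairwise no-fit RMSD matrix over a pose set
#'
#' Entry (i, j) is the RMSD, without superposition, over the concatenated
#' ligand heavy atoms and binding-site backbone atoms.
#'
#' @param poses a `pose_set` with >= 2 poses.
#' @return symmetric matrix in Angstrom with zero diagonal.
#' @export
pose_distance_matrix <- function(poses) {
  n <- length(poses)
  if (n < 2) stop("need at least 2 poses")
  xyz <- lapply(poses, .pose_coords)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- rmsd_nofit(xyz[[i]], xyz[[j]])
  }
  m
}

#' Average-linkage (UPGMA) agglomeration of a distance matrix
#'
#' Unweighted average inter-cluster distance, via [stats::hclust()].  The
#' merge history, heights and the input matrix are kept so the Kelley
#' penalty can be evaluated at every level.
#'
#' @param dmat symmetric distance matrix, zero diagonal, no NaN.
#' @return a `cluster_tree`: list with `hclust`, `merge`, `height`, `n`,
#'   `dmat`.
#' @export
average_linkage <- function(dmat) {
  dmat <- as.matrix(dmat)
  if (any(!is.finite(dmat))) stop("non-finite values in distance matrix")
  if (max(abs(dmat - t(dmat))) > 1e-9) stop("distance matrix not symmetric")
  if (any(abs(diag(dmat)) > 1e-12)) stop("distance matrix diagonal not zero")
  hc <- stats::hclust(stats::as.dist(dmat), method = "average")
  out <- list(hclust = hc, merge = hc$merge, height = hc$height,
              n = nrow(dmat), dmat = dmat)
  class(out) <- "cluster_tree"
  out
}

#' Cluster memberships at a level
#' @param tree a `cluster_tree`.
#' @param k number of clusters.
#' @return integer vector of cluster labels.
#' @export
cut_clusters <- function(tree, k) as.integer(stats::cutree(tree$hclust, k))

#' Kelley penalty and cluster-number selection
#'
#' For each level k in 2..N-1, the average spread is the mean over clusters
#' of size >= 2 of the mean pairwise intra-cluster distance (singletons
#' contribute nothing, the standard treatment).  Spreads are min-max
#' normalized across levels onto [1, N-2]; the penalty is
#' K(k) = normalized spread + k, and k* is its argmin (ties broken toward
#' smaller k).  This is the published Kelley-Gardner-Sutcliffe scheme.
#'
#' @param tree a `cluster_tree` from [average_linkage()] (N >= 4).
#' @return integer k*, with attribute `penalty`: data.frame of k, spread,
#'   normalized spread and K(k).
#' @export
kelley_select <- function(tree) {
  n <- tree$n
  if (n < 4) stop("Kelley selection needs at least 4 poses")
  ks <- 2:(n - 1)
  spread <- vapply(ks, function(k) {
    lab <- cut_clusters(tree, k)
    sp <- vapply(unique(lab), function(cl) {
      i <- which(lab == cl)
      if (length(i) < 2) return(NA_real_)
      sub <- tree$dmat[i, i]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    sp <- sp[!is.na(sp)]
    if (!length(sp)) NA_real_ else mean(sp)
  }, numeric(1))
  ok <- !is.na(spread)
  if (!any(ok)) stop("degenerate tree: all clusters are singletons at every level")
  rng <- range(spread[ok])
  norm <- rep(NA_real_, length(ks))
  if (diff(rng) < 1e-12) norm[ok] <- 1
  else norm[ok] <- (spread[ok] - rng[1]) / diff(rng) * (n - 3) + 1
  K <- norm + ks
  kstar <- ks[which.min(K)]  # which.min takes the first (smallest k) on ties
  pen <- data.frame(k = ks, spread = spread, normalized = norm, K = K)
  attr(kstar, "penalty") <- pen
  kstar
}

# ---------------------------------------------------------------------------
# Interaction fingerprints

#' Default serotonin interaction-fingerprint definitions
#'
#' The four classic orthosteric-site criteria for serotonin in SLC6
#' monoamine transporters: a salt bridge between the cationic amine and the
#' D98 carboxylate; the C6 ring atom close to A173; an H-bond between the
#' 5-hydroxyl and T439; and the indole nitrogen pointing toward F341.
#' Ligand atom names vary with preparation; override them to match yours.
#'
#' @param amine,c6,hydroxyl_O,indole_N ligand atom names.
#' @return list of fingerprint definitions for [fingerprints()].
#' @export
serotonin_fingerprint_defs <- function(amine = "N10", c6 = "C6",
                                       hydroxyl_O = "O1", indole_N = "N1") {
  list(
    list(name = "D98_ionic", ligand_atom = amine, resid = 98,
         protein_atoms = c("OD1", "OD2"), cutoff = 4.0),
    list(name = "A173_proximal", ligand_atom = c6, resid = 173,
         protein_atoms = NULL, cutoff = 4.5),
    list(name = "T439_hbond", ligand_atom = hydroxyl_O, resid = 439,
         protein_atoms = c("OG1"), cutoff = 3.5),
    list(name = "F341_indoleN", ligand_atom = indole_N, resid = 341,
         protein_atoms = NULL, cutoff = 4.5)
  )
}

#' Evaluate interaction fingerprints for a pose
#'
#' Each definition is a heavy-atom distance criterion between one named
#' ligand atom and a residue (specific atoms, or any heavy atom when
#' `protein_atoms` is NULL).  Distances are always reported alongside the
#' bits; an unresolvable atom makes that bit unevaluable (`NA`).
#'
#' @param pose a pose (list with `ligand` matrix, atom-name rownames) or a
#'   bare coordinate matrix with rownames.
#' @param protein a `structure3d`.
#' @param defs list of definitions (see [serotonin_fingerprint_defs()]).
#' @param chain protein chain (default "A").
#' @return data.frame with `name`, `distance`, `bit`.
#' @export
fingerprints <- function(pose, protein, defs = serotonin_fingerprint_defs(),
                         chain = "A") {
  lig <- if (is.list(pose) && !is.null(pose$ligand)) pose$ligand else pose
  at <- protein$atoms
  rows <- lapply(defs, function(d) {
    la <- match(d$ligand_atom, rownames(lig))
    if (is.na(la))
      return(data.frame(name = d$name, distance = NA_real_, bit = NA))
    sel <- at$chain == chain & at$resid == d$resid &
      toupper(at$element) != "H" & !at$het
    if (!is.null(d$protein_atoms)) sel <- sel & at$name %in% d$protein_atoms
    idx <- which(sel)
    if (!length(idx))
      return(data.frame(name = d$name, distance = NA_real_, bit = NA))
    pxyz <- as.matrix(at[idx, c("x", "y", "z")])
    dmin <- sqrt(min(rowSums(sweep(pxyz, 2, lig[la, ])^2)))
    data.frame(name = d$name, distance = dmin, bit = dmin <= d$cutoff)
  })
  do.call(rbind, rows)
}

#' Cluster assignment summary for a pose set
#'
#' Convenience wrapper: distance matrix, average linkage, Kelley selection
#' and per-cluster sizes in one call.
#'
#' @param poses a `pose_set`.
#' @return list with `tree`, `k`, `labels`, `sizes`.
#' @export
cluster_poses <- function(poses) {
  dmat <- pose_distance_matrix(poses)
  tree <- average_linkage(dmat)
  k <- kelley_select(tree)
  labels <- cut_clusters(tree, k)
  list(tree = tree, k = as.integer(k), labels = labels,
       sizes = sort(table(labels), decreasing = TRUE))
}
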