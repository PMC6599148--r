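# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# dihedral via in-plane projection (independent of the package's
# atan2(cross, dot) formula)
oracle_dihedral <- function(p1, p2, p3, p4) {
  u <- function(v) v / sqrt(sum(v^2))
  b2 <- u(p3 - p2)
  v1 <- (p1 - p2) - sum((p1 - p2) * b2) * b2
  v2 <- (p4 - p3) - sum((p4 - p3) * b2) * b2
  ang <- acos(max(-1, min(1, sum(u(v1) * u(v2))))) * 180 / pi
  s <- det(cbind(v1, b2, v2))
  if (s < 0) -ang else ang
}

# random proper rotation matrix
rand_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# brute-force minimum RMSD over rotations (Euler-angle parameterization,
# numeric optimization from several starts)
oracle_min_rmsd <- function(mobile, target) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(target, 2, colMeans(target))
  rotmat <- function(p) {
    cx <- cos(p[1]); sx <- sin(p[1]); cy <- cos(p[2]); sy <- sin(p[2])
    cz <- cos(p[3]); sz <- sin(p[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
    Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Rz %*% Ry %*% Rx
  }
  f <- function(p) sqrt(mean(rowSums((A %*% t(rotmat(p)) - B)^2)))
  best <- Inf
  for (start in list(c(0, 0, 0), c(1, 1, 1), c(-2, 0.5, 2), c(3, -1, 0.3))) {
    o <- stats::optim(start, f, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  best
}

# naive UPGMA: quadratic agglomeration by explicit averaging over members;
# returns merge heights and the partition at every level (n, n-1, ..., 1)
naive_upgma <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  partitions <- list()
  heights <- numeric(0)
  part_vec <- function(cl) {
    v <- integer(n)
    for (i in seq_along(cl)) v[cl[[i]]] <- i
    v
  }
  partitions[[1]] <- part_vec(clusters)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(Inf, 0, 0)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      avg <- mean(d[clusters[[i]], clusters[[j]]])
      if (avg < best[1] - 1e-12) best <- c(avg, i, j)
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    heights <- c(heights, best[1])
    partitions[[length(partitions) + 1]] <- part_vec(clusters)
  }
  list(heights = heights, partitions = rev(partitions))  # partitions[[k]] = k clusters
}

# Kelley penalty recomputed from scratch for a given set of partitions
oracle_kelley <- function(d, partitions) {
  n <- nrow(d)
  ks <- 2:(n - 1)
  spread <- sapply(ks, function(k) {
    lab <- partitions[[k]]
    per <- c()
    for (cl in unique(lab)) {
      idx <- which(lab == cl)
      if (length(idx) < 2) next
      sub <- d[idx, idx]
      per <- c(per, mean(sub[upper.tri(sub)]))
    }
    if (!length(per)) NA_real_ else mean(per)
  })
  ok <- !is.na(spread)
  rng <- range(spread[ok])
  norm <- rep(NA_real_, length(ks))
  norm[ok] <- if (diff(rng) < 1e-12) 1 else
    (spread[ok] - rng[1]) / diff(rng) * (n - 3) + 1
  K <- norm + ks
  list(k = ks, K = K, kstar = ks[which.min(K)])
}

# tiny peptide-like fixture: residues with full backbone, arbitrary coords
make_two_residue_fixture <- function() {
  df <- data.frame(
    name = rep(c("N", "CA", "C", "O"), 2),
    resname = rep(c("PHE", "GLY"), each = 4),
    chain = "A",
    resid = rep(c(335L, 336L), each = 4),
    x = c(0, 1.4, 2.4, 3.1, 3.8, 5.2, 6.2, 6.9),
    y = c(0, 0.5, 1.5, 2.2, 1.2, 1.6, 2.6, 3.3),
    z = 0,
    element = rep(c("N", "C", "C", "O"), 2),
    het = FALSE, stringsAsFactors = FALSE)
  structure3d(df)
}

# simple pose builder for clustering tests
make_pose <- function(center, jitter = 0, nlig = 3, nsite = 2) {
  lig <- matrix(rep(center, each = nlig), nlig, 3) +
    matrix(seq_len(nlig * 3), nlig, 3) * 0.01 +
    matrix(rnorm(nlig * 3, 0, jitter), nlig, 3)
  rownames(lig) <- paste0("L", seq_len(nlig))
  list(ligand = lig, site = matrix(0, nsite, 3))
}
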