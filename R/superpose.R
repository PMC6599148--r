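# Rigid-body least-squares superposition (Kabsch), hash-domain alignment,
# and segment-fit evaluation for chimeric template construction.

#' Kabsch least-squares superposition
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' transformed mobile coordinates against the target.
#'
#' @param mobile,target n x 3 coordinate matrices, n >= 3, paired row-wise.
#' @return a `rigid_transform`: list with `rotation` (3x3, det +1),
#'   `translation` (3-vector) and `rmsd` (Angstrom).  The transform maps
#'   mobile coordinates as `x %*% t(rotation) + translation`.
#' @export
kabsch_fit <- function(mobile, target) {
  mobile <- unname(as.matrix(mobile)); target <- unname(as.matrix(target))
  if (!all(dim(mobile) == dim(target)))
    stop("coordinate sets differ in size: ", nrow(mobile), " vs ", nrow(target))
  if (nrow(mobile) < 3) stop("need at least 3 points for a rigid fit")
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  trans <- ct - as.numeric(R %*% cm)
  moved <- sweep(A %*% t(R), 2, ct, `+`)
  rmsd <- sqrt(mean(rowSums((moved - target)^2)))
  out <- list(rotation = R, translation = trans, rmsd = rmsd)
  class(out) <- "rigid_transform"
  out
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.2f deg, |t| = %.3f A, rmsd %.4f A\n",
              ang, sqrt(sum(x$translation^2)), x$rmsd))
  invisible(x)
}

#' Apply a rigid transform
#'
#' @param x n x 3 matrix or `structure3d`.
#' @param transform a `rigid_transform`.
#' @param sel optional atom selection (structures only): transform only
#'   those atoms.
#' @return transformed object of the same type.
#' @export
apply_transform <- function(x, transform, sel = NULL) {
  f <- function(m) sweep(m %*% t(transform$rotation), 2,
                         transform$translation, `+`)
  if (inherits(x, "structure3d")) {
    idx <- if (is.null(sel)) seq_len(nrow(x$atoms)) else as.integer(sel)
    set_coords(x, f(coords(x, idx)), idx)
  } else f(as.matrix(x))
}

#' Invert a rigid transform
#' @param transform a `rigid_transform`.
#' @return the inverse `rigid_transform` (rmsd carried over unchanged).
#' @export
invert_transform <- function(transform) {
  Rt <- t(transform$rotation)
  out <- list(rotation = Rt, translation = -as.numeric(Rt %*% transform$translation),
              rmsd = transform$rmsd)
  class(out) <- "rigid_transform"
  out
}

#' RMSD without superposition
#'
#' Root-mean-square of paired distances as-is; no fitting.  This is the
#' pose-to-pose metric used for docking-pose clustering.
#'
#' @param A,B n x 3 coordinate matrices, n >= 1.
#' @return RMSD in Angstrom.
#' @export
rmsd_nofit <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!all(dim(A) == dim(B)))
    stop("coordinate sets differ in size: ", nrow(A), " vs ", nrow(B))
  sqrt(mean(rowSums((A - B)^2)))
}

# pair backbone atoms of a role positionally between two structures:
# i-th residue of the role in `a` maps to i-th residue in `b`
.paired_role_backbone <- function(a, b, roles_a, roles_b, role) {
  sel_a <- resolve_role(a, roles_a, role, atoms = "backbone")
  sel_b <- resolve_role(b, roles_b, role, atoms = "backbone")
  ta <- a$atoms[as.integer(sel_a), ]
  tb <- b$atoms[as.integer(sel_b), ]
  ra <- unique(ta[, c("chain", "resid")])
  rb <- unique(tb[, c("chain", "resid")])
  n <- min(nrow(ra), nrow(rb))
  if (nrow(ra) != nrow(rb))
    warning("role '", role, "': residue counts differ (", nrow(ra), " vs ",
            nrow(rb), "); pairing the first ", n)
  keep <- function(tab, res, k) {
    key <- paste(tab$chain, tab$resid)
    tab[key %in% paste(res$chain, res$resid)[seq_len(k)], , drop = FALSE]
  }
  ta <- keep(ta, ra, n); tb <- keep(tb, rb, n)
  # align per-residue on shared backbone atom names, in N CA C O order
  outa <- list(); outb <- list()
  for (i in seq_len(n)) {
    ai <- ta[ta$chain == ra$chain[i] & ta$resid == ra$resid[i], , drop = FALSE]
    bi <- tb[tb$chain == rb$chain[i] & tb$resid == rb$resid[i], , drop = FALSE]
    nm <- intersect(.backbone_names, intersect(ai$name, bi$name))
    outa[[i]] <- ai[match(nm, ai$name), c("x", "y", "z")]
    outb[[i]] <- bi[match(nm, bi$name), c("x", "y", "z")]
  }
  list(a = as.matrix(do.call(rbind, outa)), b = as.matrix(do.call(rbind, outb)))
}

#' Superpose on the hash domain
#'
#' Computes the Kabsch fit of the mobile structure's hash-region backbone
#' (TM3 + TM4 + TM8 + TM9) onto the reference's.  The transform is returned,
#' not applied; apply it with [apply_transform()].
#'
#' @param mobile,reference `structure3d` objects containing the hash roles.
#' @param roles a `role_map` for both structures, or a list
#'   `list(mobile = ..., reference = ...)` when numbering differs.
#' @return a `rigid_transform`.
#' @export
hash_superpose <- function(mobile, reference, roles) {
  rm_ <- if (!is.null(roles$mobile)) roles$mobile else roles
  rr <- if (!is.null(roles$reference)) roles$reference else roles
  pr <- .paired_role_backbone(mobile, reference, rm_, rr, "hash")
  kabsch_fit(pr$a, pr$b)
}

# ---------------------------------------------------------------------------
# Segment maps

#' Read a segment map
#'
#' A segment map pairs target residue ranges with donor residue ranges for
#' rigid repositioning.  YAML format:
#' ```
#' segments:
#'   - {label: TM1b, target: "99-117", donor: "25-43",
#'      target_chain: A, donor_chain: A}
#' ```
#'
#' @param path YAML file path.
#' @return a `segment_map`: list of segment entries.
#' @export
read_segment_map <- function(path) {
  sm <- yaml::read_yaml(path)
  if (!is.null(sm$segments)) sm <- sm$segments
  segment_map(sm)
}

#' Construct a segment map from a list of segment entries
#' @param segments list of lists with `label`, `target`, `donor` (resid range
#'   strings or vectors) and optional `target_chain`, `donor_chain`.
#' @return a `segment_map`.
#' @export
segment_map <- function(segments) {
  segs <- lapply(segments, function(s) {
    s$target_chain <- if (is.null(s$target_chain)) "A" else s$target_chain
    s$donor_chain <- if (is.null(s$donor_chain)) "A" else s$donor_chain
    s$target_resids <- .parse_resid_values(as.character(unlist(s$target)))
    s$donor_resids <- .parse_resid_values(as.character(unlist(s$donor)))
    s
  })
  labs <- vapply(segs, function(s) as.character(s$label), character(1))
  if (anyDuplicated(labs)) stop("duplicate segment labels")
  tall <- unlist(lapply(segs, `[[`, "target_resids"))
  dall <- unlist(lapply(segs, `[[`, "donor_resids"))
  if (anyDuplicated(tall)) stop("overlapping target ranges in segment map")
  if (anyDuplicated(dall)) stop("overlapping donor ranges in segment map")
  class(segs) <- "segment_map"
  segs
}

.segment_backbone_pair <- function(target, donor, seg) {
  at <- target$atoms; ad <- donor$atoms
  get <- function(tab, chain, resids) {
    x <- tab[tab$chain == chain & tab$resid %in% resids &
               tab$name %in% .backbone_names & !tab$het, , drop = FALSE]
    x[order(match(x$resid, resids), match(x$name, .backbone_names)), ,
      drop = FALSE]
  }
  tt <- get(at, seg$target_chain, seg$target_resids)
  dd <- get(ad, seg$donor_chain, seg$donor_resids)
  rt <- unique(tt$resid); rd <- unique(dd$resid)
  n <- min(length(rt), length(rd))
  if (n < 1) return(NULL)
  outa <- list(); outb <- list(); idx <- list()
  for (i in seq_len(n)) {
    ai <- tt[tt$resid == rt[i], , drop = FALSE]
    bi <- dd[dd$resid == rd[i], , drop = FALSE]
    nm <- intersect(.backbone_names, intersect(ai$name, bi$name))
    if (!length(nm)) next
    outa[[length(outa) + 1]] <- ai[match(nm, ai$name), c("x", "y", "z")]
    outb[[length(outb) + 1]] <- bi[match(nm, bi$name), c("x", "y", "z")]
  }
  if (!length(outa)) return(NULL)
  list(target = as.matrix(do.call(rbind, outa)),
       donor = as.matrix(do.call(rbind, outb)),
       n_res = n)
}

#' Evaluate candidate segment maps against a donor structure
#'
#' Both structures are first superposed on the hash domain (donor moved onto
#' target frame internally).  For each candidate, every target segment is
#' Kabsch-fitted (backbone atoms) to its donor segment; the combined RMSD is
#' the atom-count-weighted RMS over segments.  The table is sorted by
#' descending total residues then ascending combined RMSD — i.e. the best
#' fit is the smallest RMSD for the largest combination of fragments.
#'
#' @param target,donor `structure3d` objects.
#' @param candidates list of `segment_map` objects (named or not).
#' @param roles a `role_map`, or `list(target = ..., donor = ...)`.
#' @return data.frame with one row per candidate: `candidate`, `n_segments`,
#'   `total_residues`, `combined_rmsd`, plus a `per_segment` list column of
#'   per-segment RMSDs; unevaluable candidates carry `NA` and sort last.
#' @export
segment_fit_table <- function(target, donor, candidates, roles) {
  rt <- if (!is.null(roles$target)) roles$target else roles
  rd <- if (!is.null(roles$donor)) roles$donor else roles
  tr <- hash_superpose(donor, target, list(mobile = rd, reference = rt))
  donor_h <- apply_transform(donor, tr)
  nms <- names(candidates)
  if (is.null(nms)) nms <- paste0("candidate_", seq_along(candidates))
  rows <- lapply(seq_along(candidates), function(ci) {
    cand <- candidates[[ci]]
    per <- numeric(0); wts <- numeric(0); nres <- 0L; ok <- TRUE
    for (seg in cand) {
      pr <- .segment_backbone_pair(target, donor_h, seg)
      if (is.null(pr)) { ok <- FALSE; break }
      fit <- kabsch_fit(pr$target, pr$donor)
      per <- c(per, stats::setNames(fit$rmsd, seg$label))
      wts <- c(wts, nrow(pr$target))
      nres <- nres + pr$n_res
    }
    if (!ok || !length(per))
      return(data.frame(candidate = nms[ci], n_segments = length(cand),
                        total_residues = NA_integer_,
                        combined_rmsd = NA_real_))
    comb <- sqrt(sum(wts * per^2) / sum(wts))
    df <- data.frame(candidate = nms[ci], n_segments = length(cand),
                     total_residues = nres, combined_rmsd = comb)
    df$per_segment <- list(per)
    df
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$per_segment)) r$per_segment <- list(NULL)
    r
  }))
  ord <- order(-ifelse(is.na(out$total_residues), -Inf, out$total_residues),
               ifelse(is.na(out$combined_rmsd), Inf, out$combined_rmsd))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
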