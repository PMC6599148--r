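# Model quality control: Ramachandran classification, steric clashes,
# ion-site coordination checks, and the ordered score-filter cascade.

# Ramachandran regions as unions of (phi, psi) rectangles, in the standard
# 4-class scheme (general / GLY / PRO / pre-PRO).  These are coarse,
# documented approximations of the usual contour art: the filtering logic,
# not the exact contours, is what the cascade exercises, so per-model
# percentages are comparable with — but not bit-identical to — contour-based
# programs.
.rama_boxes <- local({
  gen_fav <- list(c(-160, -20, -80, -5),    # alpha
                  c(-180, -45, 90, 180),    # beta
                  c(-180, -45, -180, -150)) # beta tail (wraps to +180)
  list(
    general = list(favored = gen_fav,
                   extra_allowed = list(c(20, 100, -20, 90))),  # L-alpha
    GLY = list(favored = c(gen_fav,
                           list(c(20, 160, 5, 80),      # mirrored alpha
                                c(45, 180, -180, -90))),
               extra_allowed = list(c(-180, 180, 150, 180))),
    PRO = list(favored = list(c(-110, -40, -75, 10),
                              c(-110, -40, 110, 180)),
               extra_allowed = list()),
    prePro = list(favored = gen_fav,
                  extra_allowed = list(c(20, 100, -20, 90)))
  )
})

.in_boxes <- function(phi, psi, boxes, pad = 0) {
  for (b in boxes) {
    if (phi >= b[1] - pad && phi <= b[2] + pad &&
        psi >= b[3] - pad && psi <= b[4] + pad) return(TRUE)
  }
  FALSE
}

.rama_class <- function(phi, psi, resname, next_resname = NA) {
  cls <- if (toupper(resname) == "GLY") "GLY"
         else if (toupper(resname) == "PRO") "PRO"
         else if (!is.na(next_resname) && toupper(next_resname) == "PRO") "prePro"
         else "general"
  reg <- .rama_boxes[[cls]]
  if (.in_boxes(phi, psi, reg$favored)) return("favored")
  if (.in_boxes(phi, psi, reg$favored, pad = 20) ||
      .in_boxes(phi, psi, reg$extra_allowed)) return("allowed")
  "disallowed"
}

#' Ramachandran classification
#'
#' Computes backbone phi/psi for every residue and classifies each
#' evaluable residue (both dihedrals defined; termini and chain breaks are
#' skipped) as favored / allowed / disallowed against a shipped
#' rectangle-union region table in the standard four-class scheme
#' (general, GLY, PRO, pre-PRO).
#'
#' @param structure a `structure3d`.
#' @return list with `residues` (per-residue phi, psi, class) and `summary`
#'   (percent favored / allowed / disallowed over evaluable residues;
#'   sums to 100).
#' @export
ramachandran <- function(structure) {
  pp <- phi_psi(structure)
  if (nrow(pp) < 3) stop("need at least 3 consecutive residues")
  pp$class <- NA_character_
  for (i in seq_len(nrow(pp))) {
    if (is.na(pp$phi[i]) || is.na(pp$psi[i])) next
    nxt <- if (i < nrow(pp) && pp$chain[i + 1] == pp$chain[i] &&
               pp$resid[i + 1] == pp$resid[i] + 1) pp$resname[i + 1] else NA
    pp$class[i] <- .rama_class(pp$phi[i], pp$psi[i], pp$resname[i], nxt)
  }
  ev <- pp$class[!is.na(pp$class)]
  n <- length(ev)
  summary <- c(favored = 100 * sum(ev == "favored") / n,
               allowed = 100 * sum(ev == "allowed") / n,
               disallowed = 100 * sum(ev == "disallowed") / n)
  list(residues = pp, summary = summary)
}

# ---------------------------------------------------------------------------
# Clashes

.vdw_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, "NA" = 2.27, K = 2.75,
                MG = 1.73, ZN = 1.39, FE = 1.50, SE = 1.90)
.cov_radii <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
                F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20)

.neighbor_pairs <- function(xyz, cutoff) {
  # grid-hash candidate pairs with distance <= cutoff
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(), ncol = 2))
  cell <- pmax(cutoff, 1)
  key <- floor(sweep(xyz, 2, apply(xyz, 2, min)) / cell)
  id <- key[, 1] + 4096 * key[, 2] + 4096^2 * key[, 3]
  split_idx <- split(seq_len(n), id)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- list()
  keys <- unique(key, MARGIN = 1)
  lookup <- new.env(hash = TRUE)
  for (nm in names(split_idx)) assign(nm, split_idx[[nm]], envir = lookup)
  for (k in seq_len(nrow(keys))) {
    base <- keys[k, ]
    a <- get(as.character(base[1] + 4096 * base[2] + 4096^2 * base[3]),
             envir = lookup)
    for (o in seq_len(nrow(offs))) {
      nb <- base + offs[o, ]
      nm <- as.character(nb[1] + 4096 * nb[2] + 4096^2 * nb[3])
      if (!exists(nm, envir = lookup, inherits = FALSE)) next
      b <- get(nm, envir = lookup)
      cand <- expand.grid(i = a, j = b)
      cand <- cand[cand$i < cand$j, , drop = FALSE]
      if (!nrow(cand)) next
      d2 <- rowSums((xyz[cand$i, , drop = FALSE] -
                       xyz[cand$j, , drop = FALSE])^2)
      keep <- d2 <= cutoff^2
      if (any(keep)) out[[length(out) + 1]] <-
          cbind(cand$i[keep], cand$j[keep])
    }
  }
  if (!length(out)) return(matrix(integer(), ncol = 2))
  unique(do.call(rbind, out))
}

#' Steric clash report
#'
#' Non-bonded heavy-atom pairs whose van der Waals overlap
#' (r_i + r_j - d) meets the cutoff.  Bonded 1-2 and 1-3 pairs are
#' excluded; bonds are inferred from covalent radii (d < 1.3 (rc_i + rc_j)),
#' which also covers inter-residue peptide bonds and ion coordination.
#' Unknown elements get a 1.7 Angstrom fallback radius with a warning.
#'
#' @param structure a `structure3d`.
#' @param overlap_cutoff minimum overlap in Angstrom to report (default 0.4).
#' @return data.frame with atom pair descriptors, `distance` and `overlap`,
#'   sorted by decreasing overlap.
#' @export
clash_report <- function(structure, overlap_cutoff = 0.4) {
  at <- structure$atoms
  heavy <- which(toupper(at$element) != "H")
  a <- at[heavy, , drop = FALSE]
  el <- toupper(a$element)
  unknown <- !(el %in% names(.vdw_radii))
  if (any(unknown)) {
    warning("unknown element(s) ", paste(unique(el[unknown]), collapse = ", "),
            "; using 1.7 A van der Waals radius")
  }
  rv <- ifelse(unknown, 1.7, .vdw_radii[el])
  rc <- ifelse(el %in% names(.cov_radii), .cov_radii[el], 0.8)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  pairs <- .neighbor_pairs(xyz, max(rv) * 2)
  if (!nrow(pairs)) return(.empty_clash_df())
  d <- sqrt(rowSums((xyz[pairs[, 1], , drop = FALSE] -
                       xyz[pairs[, 2], , drop = FALSE])^2))
  bonded <- d < 1.3 * (rc[pairs[, 1]] + rc[pairs[, 2]])
  # 1-3 exclusion: adjacency via bonded pairs
  adj <- split(c(pairs[bonded, 2], pairs[bonded, 1]),
               c(pairs[bonded, 1], pairs[bonded, 2]))
  one_three <- vapply(seq_len(nrow(pairs)), function(k) {
    ni <- adj[[as.character(pairs[k, 1])]]
    if (is.null(ni)) return(FALSE)
    nj <- adj[[as.character(pairs[k, 2])]]
    if (is.null(nj)) return(FALSE)
    length(intersect(ni, nj)) > 0
  }, logical(1))
  overlap <- rv[pairs[, 1]] + rv[pairs[, 2]] - d
  keep <- !bonded & !one_three & overlap >= overlap_cutoff
  if (!any(keep)) return(.empty_clash_df())
  k1 <- pairs[keep, 1]; k2 <- pairs[keep, 2]
  lab <- function(i) paste0(a$chain[i], ":", a$resname[i], a$resid[i], ":",
                            a$name[i])
  out <- data.frame(atom_a = lab(k1), atom_b = lab(k2),
                    distance = d[keep], overlap = overlap[keep],
                    stringsAsFactors = FALSE)
  out[order(-out$overlap), , drop = FALSE]
}

.empty_clash_df <- function() {
  data.frame(atom_a = character(), atom_b = character(),
             distance = numeric(), overlap = numeric())
}

# ---------------------------------------------------------------------------
# Ion-site coordination

#' Check ion coordination distances against reference values
#'
#' @param structure a `structure3d`.
#' @param site_spec data.frame with columns `ion`, `atom` (atom references
#'   `"chain:resid:name"`), `ref_distance`, `tolerance` (Angstrom).
#' @return data.frame with measured distance, deviation and `pass`; a
#'   missing ion yields `pass = FALSE` with a `reason`.  An empty spec is a
#'   vacuous pass (zero rows).
#' @export
ion_site_check <- function(structure, site_spec) {
  if (!nrow(site_spec))
    return(data.frame(ion = character(), atom = character(),
                      ref_distance = numeric(), measured = numeric(),
                      deviation = numeric(), pass = logical(),
                      reason = character()))
  rows <- lapply(seq_len(nrow(site_spec)), function(i) {
    sp <- site_spec[i, ]
    ii <- tryCatch(.atom_ref_index(structure, sp$ion), error = function(e) NA)
    ij <- tryCatch(.atom_ref_index(structure, sp$atom), error = function(e) NA)
    if (is.na(ii) || is.na(ij)) {
      return(data.frame(ion = sp$ion, atom = sp$atom,
                        ref_distance = sp$ref_distance, measured = NA_real_,
                        deviation = NA_real_, pass = FALSE,
                        reason = if (is.na(ii)) "ion atom missing"
                                 else "coordinating atom missing"))
    }
    d <- sqrt(sum((coords(structure)[ii, ] - coords(structure)[ij, ])^2))
    dev <- d - sp$ref_distance
    data.frame(ion = sp$ion, atom = sp$atom, ref_distance = sp$ref_distance,
               measured = d, deviation = dev,
               pass = abs(dev) <= sp$tolerance, reason = "")
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# Score-filter cascade

#' Filter rules for model selection cascades
#'
#' `top_n` keeps the n best models by a score (direction = "min" for
#' builder-style objective scores, "max" for quality scores).
#' `within_sd_of_best` keeps models whose score is within k sample standard
#' deviations of the best score, the sd being taken over the set entering
#' the rule.  `exclude_if` drops models for which the predicate (an
#' expression in the score columns) is TRUE.
#'
#' @param score score column name.
#' @param n number of models to keep.
#' @param k multiple of the standard deviation (default 1).
#' @param direction `"min"` or `"max"`: which end is best.
#' @param predicate an expression (unquoted) evaluated in the score table.
#' @return a filter rule object for [filter_models()].
#' @name filter_rules
NULL

#' @rdname filter_rules
#' @export
top_n <- function(score, n, direction = c("min", "max")) {
  structure(list(type = "top_n", score = score, n = n,
                 direction = match.arg(direction)), class = "filter_rule")
}

#' @rdname filter_rules
#' @export
within_sd_of_best <- function(score, k = 1, direction = c("max", "min")) {
  structure(list(type = "within_sd_of_best", score = score, k = k,
                 direction = match.arg(direction)), class = "filter_rule")
}

#' @rdname filter_rules
#' @export
exclude_if <- function(predicate) {
  structure(list(type = "exclude_if", predicate = substitute(predicate)),
            class = "filter_rule")
}

#' Apply an ordered score-filter cascade
#'
#' Rules are applied in order; the audit trail records the surviving set
#' size and, for `within_sd_of_best`, the numeric threshold used.  Output
#' model order is input order (order-stable subset).
#'
#' @param scores data.frame with a `model_id` column plus score columns.
#' @param rules list of rules built with [top_n()], [within_sd_of_best()],
#'   [exclude_if()].
#' @return list with `selected` (model IDs), `scores` (subset table), and
#'   `audit` (one row per rule).
#' @export
filter_models <- function(scores, rules) {
  if (is.null(scores$model_id)) stop("score table needs a model_id column")
  cur <- scores
  audit <- list()
  for (r in rules) {
    n0 <- nrow(cur)
    thr <- NA_real_
    if (r$type %in% c("top_n", "within_sd_of_best")) {
      if (is.null(cur[[r$score]]))
        stop("rule references absent score column '", r$score, "'")
    }
    cur <- switch(r$type,
      top_n = {
        v <- cur[[r$score]]
        ord <- if (r$direction == "min") order(v) else order(-v)
        keep <- sort(ord[seq_len(min(r$n, nrow(cur)))])
        cur[keep, , drop = FALSE]
      },
      within_sd_of_best = {
        v <- cur[[r$score]]
        s <- stats::sd(v)
        thr <- if (r$direction == "max") max(v) - r$k * s else min(v) + r$k * s
        if (r$direction == "max") cur[v >= thr, , drop = FALSE]
        else cur[v <= thr, , drop = FALSE]
      },
      exclude_if = {
        drop <- eval(r$predicate, cur, parent.frame())
        if (!is.logical(drop)) stop("exclude_if predicate must be logical")
        cur[!drop %in% TRUE, , drop = FALSE]
      },
      stop("unknown rule type: ", r$type))
    audit[[length(audit) + 1]] <- data.frame(
      rule = r$type,
      detail = if (r$type == "exclude_if") deparse(r$predicate)
               else r$score,
      threshold = thr, n_before = n0, n_after = nrow(cur))
  }
  list(selected = cur$model_id, scores = cur, audit = do.call(rbind, audit))
}
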