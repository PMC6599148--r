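# Chimeric template assembly: rigid repositioning of bundle segments onto a
# donor conformation, PIR alignment emission, ion transfer, restraint lists.

#' Build a two-template chimeric modeling template
#'
#' The donor is superposed onto the target using the hash-domain backbone.
#' Each target segment (typically TM1b, TM6a and the extracellular halves of
#' TM2/TM7 plus their loops) is then Kabsch-fitted by its backbone atoms
#' onto the corresponding donor segment and all of its atoms — side chains
#' included — are moved rigidly by that transform.  Every other target atom
#' is left bit-identical.  The result is a template for comparative
#' modeling, not a finished model: junction geometry is reported, not
#' repaired.
#'
#' @param target `structure3d` providing all coordinates (e.g. the
#'   outward-open experimental structure).
#' @param donor `structure3d` defining the new segment positions (e.g. an
#'   outward-occluded homolog).
#' @param segments a `segment_map` pairing target and donor residue ranges.
#' @param roles a `role_map`, or `list(target = ..., donor = ...)`.
#' @return a `chimera_record`: list with `structure` (the chimera),
#'   `provenance` (per-atom, `"unchanged_target"` or
#'   `"repositioned_target"`), `segment_map`, `transforms` (per segment,
#'   each with its backbone rmsd to the donor), and `donor_hash_transform`.
#' @export
build_template <- function(target, donor, segments, roles) {
  rt <- if (!is.null(roles$target)) roles$target else roles
  rd <- if (!is.null(roles$donor)) roles$donor else roles
  htr <- hash_superpose(donor, target, list(mobile = rd, reference = rt))
  donor_h <- apply_transform(donor, htr)

  chim <- target
  prov <- rep("unchanged_target", nrow(target$atoms))
  transforms <- list()
  for (seg in segments) {
    pr <- .segment_backbone_pair(target, donor_h, seg)
    if (is.null(pr))
      stop("segment '", seg$label, "' has no pairable backbone atoms")
    fit <- kabsch_fit(pr$target, pr$donor)
    idx <- which(chim$atoms$chain == seg$target_chain &
                   chim$atoms$resid %in% seg$target_resids)
    if (!length(idx)) stop("segment '", seg$label, "' matches no target atoms")
    chim <- set_coords(chim, apply_transform(coords(target, idx), fit), idx)
    prov[idx] <- "repositioned_target"
    transforms[[as.character(seg$label)]] <- fit
  }
  out <- list(structure = chim, provenance = prov, segment_map = segments,
              transforms = transforms, donor_hash_transform = htr)
  class(out) <- "chimera_record"
  out
}

#' @export
print.chimera_record <- function(x, ...) {
  n <- sum(x$provenance == "repositioned_target")
  cat(sprintf("<chimera_record> %d atoms (%d repositioned in %d segments)\n",
              nrow(x$structure$atoms), n, length(x$transforms)))
  for (nm in names(x$transforms))
    cat(sprintf("  segment %-8s backbone rmsd to donor: %.4f A\n", nm,
                x$transforms[[nm]]$rmsd))
  invisible(x)
}

#' Peptide-bond lengths across segment junctions
#'
#' Reports the C(i)-N(i+1) distance at every boundary between an unchanged
#' and a repositioned residue, as a geometric sanity check on the template
#' (downstream modeling is expected to regularize these).
#'
#' @param chimera a `chimera_record`.
#' @return data.frame with `chain`, `resid_c`, `resid_n`, `length`.
#' @export
junction_bond_lengths <- function(chimera) {
  at <- chimera$structure$atoms
  rp <- unique(at[chimera$provenance == "repositioned_target",
                  c("chain", "resid")])
  res_prov <- paste(rp$chain, rp$resid)
  out <- list()
  for (ch in unique(at$chain)) {
    a <- at[at$chain == ch & !at$het, ]
    resids <- sort(unique(a$resid))
    for (i in seq_len(length(resids) - 1)) {
      r1 <- resids[i]; r2 <- resids[i + 1]
      if (r2 != r1 + 1) next
      p1 <- paste(ch, r1) %in% res_prov
      p2 <- paste(ch, r2) %in% res_prov
      if (p1 == p2) next
      Cx <- a[a$resid == r1 & a$name == "C", c("x", "y", "z")]
      Nx <- a[a$resid == r2 & a$name == "N", c("x", "y", "z")]
      if (!nrow(Cx) || !nrow(Nx)) next
      out[[length(out) + 1]] <- data.frame(
        chain = ch, resid_c = r1, resid_n = r2,
        length = sqrt(sum((as.numeric(Cx[1, ]) - as.numeric(Nx[1, ]))^2)))
    }
  }
  if (!length(out)) return(data.frame(chain = character(), resid_c = integer(),
                                      resid_n = integer(), length = numeric()))
  do.call(rbind, out)
}

#' Write a chimera as PDB plus sidecar metadata
#'
#' Provenance is encoded in the B-factor column (0 = unchanged,
#' 1 = repositioned); segment transforms and RMSDs go to a YAML sidecar.
#'
#' @param chimera a `chimera_record`.
#' @param path PDB output path; sidecar written to `<path>.yaml`.
#' @return `path`, invisibly.
#' @export
write_chimera <- function(chimera, path) {
  s <- chimera$structure
  s$atoms$b <- as.numeric(chimera$provenance == "repositioned_target")
  write_structure(s, path)
  meta <- list(
    segments = lapply(seq_along(chimera$segment_map), function(i) {
      seg <- chimera$segment_map[[i]]
      tr <- chimera$transforms[[as.character(seg$label)]]
      list(label = seg$label,
           target = paste(range(seg$target_resids), collapse = "-"),
           donor = paste(range(seg$donor_resids), collapse = "-"),
           backbone_rmsd = tr$rmsd,
           rotation = as.numeric(tr$rotation),
           translation = as.numeric(tr$translation))
    }),
    donor_hash_rmsd = chimera$donor_hash_transform$rmsd)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

# ---------------------------------------------------------------------------
# PIR alignment

#' Emit a PIR alignment for template-based modeling
#'
#' Writes a two-entry PIR alignment: the chimera as the structure template
#' (gaps at positions its residues do not cover) and the full target
#' sequence.  Chimera residue `i` maps to position `i - offset` of
#' `full_sequence` (author numbering, 1-based).
#'
#' @param chimera a `chimera_record` or `structure3d`.
#' @param full_sequence one-letter target sequence string.
#' @param template_id,target_id entry identifiers.
#' @param offset author resid of position 1 minus one (default 0).
#' @param width wrap column (default 60).
#' @return character vector of PIR lines.
#' @export
emit_pir_alignment <- function(chimera, full_sequence, template_id = "chimera",
                               target_id = "target", offset = 0, width = 60) {
  s <- if (inherits(chimera, "chimera_record")) chimera$structure else chimera
  at <- s$atoms[!s$atoms$het, ]
  res <- unique(at[, c("chain", "resid", "resname")])
  n <- nchar(full_sequence)
  tmpl <- rep("-", n)
  for (i in seq_len(nrow(res))) {
    pos <- res$resid[i] - offset
    if (pos < 1 || pos > n)
      stop("residue ", res$resname[i], res$resid[i],
           " maps outside the full sequence (position ", pos, ")")
    one <- .aa1[toupper(res$resname[i])]
    if (is.na(one)) one <- "X"
    tmpl[pos] <- one
  }
  wrap <- function(x) {
    starts <- seq(1, nchar(x), by = width)
    vapply(starts, function(i) substr(x, i, min(i + width - 1, nchar(x))),
           character(1))
  }
  first <- min(res$resid); last <- max(res$resid); ch <- res$chain[1]
  c(paste0(">P1;", template_id),
    sprintf("structureX:%s:%d:%s:%d:%s::::", template_id, first, ch, last, ch),
    wrap(paste0(paste(tmpl, collapse = ""), "*")),
    "",
    paste0(">P1;", target_id),
    sprintf("sequence:%s::::::::", target_id),
    wrap(paste0(full_sequence, "*")))
}

#' Parse a PIR alignment
#' @param lines character vector (or file path) of PIR text.
#' @return named list of sequences (gaps kept, terminator stripped).
#' @export
read_pir <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  out <- list(); id <- NULL; buf <- character()
  flush <- function() {
    if (!is.null(id)) {
      seq <- gsub("\\*$", "", paste(buf[-1], collapse = ""))
      out[[id]] <<- seq
    }
  }
  for (ln in lines) {
    if (startsWith(ln, ">P1;")) {
      flush(); id <- sub("^>P1;", "", ln); buf <- character()
    } else if (nzchar(trimws(ln)) && !is.null(id)) {
      buf <- c(buf, trimws(ln))
    }
  }
  flush()
  out
}

# ---------------------------------------------------------------------------
# Ion transfer

#' Transfer ions (or tagged waters) between structures by local site fit
#'
#' For each ion, the coordination site is taken as all residues with heavy
#' atoms within `site_cutoff` of the ion in the source; the source site
#' backbone is Kabsch-fitted onto the same-numbered residues in the
#' destination, and the ion is copied under that transform.
#'
#' @param source `structure3d` containing the ions.
#' @param dest `structure3d` to receive them.
#' @param ion_ids character vector of selection expressions, each resolving
#'   to one ion (or one water) in the source, e.g.
#'   `"resname NA and resid 601"`.
#' @param site_cutoff site radius in Angstrom (default 4.5).
#' @return `dest` with the transferred atoms appended.
#' @export
transfer_ions <- function(source, dest, ion_ids, site_cutoff = 4.5) {
  for (expr in ion_ids) {
    sel <- select_atoms(source, expr)
    if (!length(sel)) stop("ion selection matches nothing: '", expr, "'")
    site <- residues_within(source, sel, site_cutoff)
    if (!nrow(site)) stop("no site residues within ", site_cutoff,
                          " A of '", expr, "'")
    bb <- function(s, res) {
      a <- s$atoms
      x <- a[paste(a$chain, a$resid) %in% paste(res$chain, res$resid) &
               a$name %in% .backbone_names & !a$het, , drop = FALSE]
      x[order(x$chain, x$resid, match(x$name, .backbone_names)), , drop = FALSE]
    }
    sb <- bb(source, site); db <- bb(dest, site)
    key <- intersect(paste(sb$chain, sb$resid, sb$name),
                     paste(db$chain, db$resid, db$name))
    if (length(key) < 3)
      stop("site residues for '", expr, "' absent in destination (",
           length(key), " shared backbone atoms)")
    sb <- sb[match(key, paste(sb$chain, sb$resid, sb$name)), ]
    db <- db[match(key, paste(db$chain, db$resid, db$name)), ]
    fit <- kabsch_fit(as.matrix(sb[, c("x", "y", "z")]),
                      as.matrix(db[, c("x", "y", "z")]))
    ion_atoms <- source$atoms[as.integer(sel), , drop = FALSE]
    ion_atoms[, c("x", "y", "z")] <-
      apply_transform(as.matrix(ion_atoms[, c("x", "y", "z")]), fit)
    ion_atoms$serial <- max(dest$atoms$serial) + seq_len(nrow(ion_atoms))
    dest$atoms <- rbind(dest$atoms, ion_atoms)
  }
  dest
}

# ---------------------------------------------------------------------------
# Restraints

#' Construct a distance-restraint list
#'
#' @param atom_a,atom_b atom references `"chain:resid:name"`.
#' @param distance target distances in Angstrom (> 0).
#' @param k force constants in kcal/mol/A^2 (> 0).  Conventional defaults:
#'   10 for minimization sets, 200 for equilibration sets.
#' @return a `restraint_list` data.frame.
#' @export
restraint_list <- function(atom_a, atom_b, distance, k = 10) {
  df <- data.frame(atom_a = as.character(atom_a), atom_b = as.character(atom_b),
                   distance = as.numeric(distance), k = as.numeric(k),
                   stringsAsFactors = FALSE)
  if (nrow(df) && any(df$distance <= 0)) stop("restraint distances must be > 0")
  if (nrow(df) && any(df$k <= 0)) stop("force constants must be > 0")
  class(df) <- c("restraint_list", "data.frame")
  df
}

.atom_ref_index <- function(structure, ref) {
  p <- strsplit(ref, ":", fixed = TRUE)[[1]]
  if (length(p) != 3) stop("bad atom reference '", ref, "' (chain:resid:name)")
  at <- structure$atoms
  i <- which(at$chain == p[1] & at$resid == as.integer(p[2]) & at$name == p[3])
  if (!length(i)) stop("atom reference '", ref, "' not found in structure")
  i[1]
}

#' Emit a restraint list as text
#'
#' @param restraints a `restraint_list`.
#' @param structure companion `structure3d`; every referenced atom must
#'   exist in it (dangling references are an error).
#' @param dialect `"generic_tsv"` (self-describing, round-trippable) or
#'   `"plumed_style"` (DISTANCE/RESTRAINT pairs; AT in nm, KAPPA converted
#'   to kJ/mol/nm^2).
#' @return character vector of lines.
#' @export
emit_restraints <- function(restraints, structure,
                            dialect = c("generic_tsv", "plumed_style")) {
  dialect <- match.arg(dialect)
  ia <- vapply(restraints$atom_a, .atom_ref_index, numeric(1),
               structure = structure)
  ib <- vapply(restraints$atom_b, .atom_ref_index, numeric(1),
               structure = structure)
  if (dialect == "generic_tsv") {
    c("atom_a\tatom_b\tdistance_A\tk_kcal_mol_A2",
      if (nrow(restraints))
        sprintf("%s\t%s\t%g\t%g", restraints$atom_a, restraints$atom_b,
                restraints$distance, restraints$k))
  } else {
    # kcal/mol/A^2 -> kJ/mol/nm^2: x 4.184 x 100
    out <- character()
    for (i in seq_len(nrow(restraints))) {
      out <- c(out,
        sprintf("d%d: DISTANCE ATOMS=%d,%d", i,
                structure$atoms$serial[ia[i]], structure$atoms$serial[ib[i]]),
        sprintf("RESTRAINT ARG=d%d AT=%.4f KAPPA=%.1f", i,
                restraints$distance[i] / 10, restraints$k[i] * 418.4))
    }
    out
  }
}

#' Parse a generic_tsv restraint file
#' @param lines character vector of lines (or a file path).
#' @return a `restraint_list`.
#' @export
read_restraints <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[1], "atom_a"))
    stop("not a generic_tsv restraint file")
  if (length(lines) == 1) return(restraint_list(character(), character(),
                                                numeric(), numeric()))
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  restraint_list(vapply(parts, `[`, "", 1), vapply(parts, `[`, "", 2),
                 as.numeric(vapply(parts, `[`, "", 3)),
                 as.numeric(vapply(parts, `[`, "", 4)))
}
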