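# Atom table column order, fixed for round-trip stability
.atom_cols <- c("serial", "name", "altloc", "resname", "chain", "resid",
                "x", "y", "z", "occ", "b", "element", "het")

.backbone_names <- c("N", "CA", "C", "O")
.water_resnames <- c("HOH", "TIP3", "WAT", "SOL", "TIP", "SPC")

# one-letter codes, used for residue labels like "Y176"
.aa1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", HSD = "H", HSE = "H", ILE = "I",
          LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P", SER = "S",
          THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Construct a molecular structure object
#'
#' A `structure3d` is the package's coordinate container: an ordered atom
#' table (one row per atom, author residue numbering preserved exactly as in
#' the source file) plus a model identifier and a provenance string.
#'
#' @param atoms data.frame with columns `serial`, `name`, `altloc`,
#'   `resname`, `chain`, `resid`, `x`, `y`, `z`, `occ`, `b`, `element`,
#'   `het`.  Missing optional columns are filled with defaults.
#' @param model_id integer model number (1 for single-model files).
#' @param source provenance string (file path or generator tag).
#' @return object of class `structure3d`.
#' @export
structure3d <- function(atoms, model_id = 1L, source = "in-memory") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  defaults <- list(serial = seq_len(nrow(atoms)), altloc = "", occ = 1,
                   b = 0, element = NA_character_, het = FALSE, chain = "A")
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- rep_len(defaults[[nm]], nrow(atoms))
  }
  need <- setdiff(.atom_cols, names(atoms))
  if (length(need)) stop("atom table lacks columns: ", paste(need, collapse = ", "))
  atoms <- atoms[, .atom_cols]
  atoms$resid <- as.integer(atoms$resid)
  atoms$serial <- as.integer(atoms$serial)
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) stop("non-finite coordinates at atom row(s) ",
                     paste(utils::head(which(bad), 5), collapse = ", "))
  if (any(is.na(atoms$element)))
    atoms$element[is.na(atoms$element)] <- .guess_element(
      atoms$name[is.na(atoms$element)], atoms$resname[is.na(atoms$element)])
  out <- list(atoms = atoms, model_id = as.integer(model_id), source = source)
  class(out) <- "structure3d"
  out
}

#' @export
print.structure3d <- function(x, ...) {
  cat(sprintf("<structure3d> %d atoms, %d residues, chains %s, model %d [%s]\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resid")])),
              paste(unique(x$atoms$chain), collapse = ","),
              x$model_id, x$source))
  invisible(x)
}

#' Coordinates of a structure (optionally restricted to a selection)
#'
#' @param structure a `structure3d`.
#' @param sel optional `atom_selection` or integer indices.
#' @return numeric matrix, n x 3, columns x/y/z in Angstrom.
#' @export
coords <- function(structure, sel = NULL) {
  a <- structure$atoms
  if (!is.null(sel)) a <- a[as.integer(sel), , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

#' Replace coordinates of a structure
#' @param structure a `structure3d`.
#' @param xyz n x 3 matrix (all atoms) or matching a selection.
#' @param sel optional selection the rows of `xyz` refer to.
#' @return modified `structure3d`.
#' @export
set_coords <- function(structure, xyz, sel = NULL) {
  idx <- if (is.null(sel)) seq_len(nrow(structure$atoms)) else as.integer(sel)
  stopifnot(nrow(xyz) == length(idx))
  structure$atoms[idx, c("x", "y", "z")] <- xyz
  structure
}

.guess_element <- function(name, resname) {
  two <- c("NA", "CL", "MG", "ZN", "FE", "BR", "MN", "CU", "K")
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  el <- substr(nm, 1, 1)
  ion <- toupper(resname) %in% c("NA", "CL", "K", "MG", "ZN", "SOD", "CLA",
                                 "POT", "MN", "FE", "CU", "BR")
  el[ion & nm %in% two] <- nm[ion & nm %in% two]
  el[ion & toupper(resname) == "SOD"] <- "NA"
  el[ion & toupper(resname) == "CLA"] <- "CL"
  el[ion & toupper(resname) == "POT"] <- "K"
  el
}

# ---------------------------------------------------------------------------
# PDB fixed-column I/O

.parse_pdb_atom <- function(line, lineno) {
  # PDB v3 fixed columns
  f <- function(a, b) substr(line, a, b)
  serial <- suppressWarnings(as.integer(trimws(f(7, 11))))
  x <- suppressWarnings(as.numeric(trimws(f(31, 38))))
  y <- suppressWarnings(as.numeric(trimws(f(39, 46))))
  z <- suppressWarnings(as.numeric(trimws(f(47, 54))))
  resid <- suppressWarnings(as.integer(trimws(f(23, 26))))
  if (anyNA(c(x, y, z, resid)))
    stop("unparseable ATOM/HETATM record at line ", lineno, ": ", trimws(line))
  occ <- suppressWarnings(as.numeric(trimws(f(55, 60)))); if (is.na(occ)) occ <- 1
  b <- suppressWarnings(as.numeric(trimws(f(61, 66)))); if (is.na(b)) b <- 0
  el <- trimws(f(77, 78))
  list(serial = serial, name = trimws(f(13, 16)), altloc = trimws(f(17, 17)),
       resname = trimws(f(18, 20)), chain = trimws(f(22, 22)), resid = resid,
       x = x, y = y, z = z, occ = occ, b = b,
       element = if (nzchar(el)) toupper(el) else NA_character_,
       het = startsWith(line, "HETATM"))
}

.apply_altloc_policy <- function(atoms) {
  # keep highest-occupancy altloc per (chain, resid, name); ties -> first
  # alphabetically; blank altloc always kept
  multi <- nzchar(atoms$altloc)
  if (!any(multi)) return(atoms)
  key <- paste(atoms$chain, atoms$resid, atoms$name, sep = "|")
  drop <- logical(nrow(atoms))
  for (k in unique(key[multi])) {
    i <- which(key == k & multi)
    if (length(i) < 2) next
    ord <- order(-atoms$occ[i], atoms$altloc[i])
    drop[i[-ord[1]]] <- TRUE
  }
  if (any(drop)) {
    dropped <- unique(paste0(atoms$resname[drop], atoms$resid[drop], ":",
                             atoms$altloc[drop]))
    message("altloc policy: discarded ", sum(drop), " atom(s) [",
            paste(utils::head(dropped, 8), collapse = ", "),
            if (length(dropped) > 8) ", ..." else "", "]")
  }
  atoms[!drop, , drop = FALSE]
}

#' Read a coordinate file
#'
#' Reads PDB (fixed-column), multi-model PDB, or mmCIF.  All ATOM and HETATM
#' records are retained; author residue numbers are preserved exactly; for
#' alternate locations the highest-occupancy altloc is kept (ties broken
#' alphabetically) and discards are reported via `message()`.
#'
#' @param path file path.
#' @param format one of `"auto"`, `"pdb"`, `"mmcif"`, `"multi_model_pdb"`.
#'   `"auto"` dispatches on the file extension and on MODEL records.
#' @return a `structure3d`, or a list of them for multi-model files.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif",
                                            "multi_model_pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  if (format == "mmcif") return(.read_mmcif(path))

  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path)
  models <- list()
  cur <- list()
  cur_id <- 1L
  seen_model <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, "MODEL")) {
      seen_model <- TRUE
      cur_id <- suppressWarnings(as.integer(trimws(substr(ln, 11, 14))))
      if (is.na(cur_id)) cur_id <- length(models) + 1L
      cur <- list()
    } else if (startsWith(ln, "ENDMDL")) {
      models[[length(models) + 1L]] <- list(id = cur_id, atoms = cur)
      cur <- list()
    } else if (startsWith(ln, "ATOM") || startsWith(ln, "HETATM")) {
      cur[[length(cur) + 1L]] <- .parse_pdb_atom(ln, i)
    }
  }
  if (length(cur)) models[[length(models) + 1L]] <- list(id = cur_id, atoms = cur)
  models <- Filter(function(m) length(m$atoms) > 0, models)
  if (!length(models)) stop("no ATOM/HETATM records in ", path)

  build <- function(m) {
    df <- do.call(rbind, lapply(m$atoms, function(a)
      as.data.frame(a, stringsAsFactors = FALSE)))
    df <- .apply_altloc_policy(df)
    structure3d(df, model_id = m$id, source = path)
  }
  out <- lapply(models, build)
  if (format == "multi_model_pdb" || (seen_model && length(out) > 1)) out
  else out[[1]]
}

.read_mmcif <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("mmCIF reading requires the 'bio3d' package")
  cif <- bio3d::read.cif(path)
  at <- cif$atom
  df <- data.frame(serial = at$eleno, name = at$elety, altloc = ifelse(
                     is.na(at$alt), "", at$alt),
                   resname = at$resid, chain = at$chain, resid = at$resno,
                   x = at$x, y = at$y, z = at$z,
                   occ = ifelse(is.na(at$o), 1, at$o),
                   b = ifelse(is.na(at$b), 0, at$b),
                   element = toupper(at$elesy),
                   het = at$type == "HETATM", stringsAsFactors = FALSE)
  df <- .apply_altloc_policy(df)
  structure3d(df, source = path)
}

.format_pdb_atom <- function(a) {
  name <- a$name
  # atom-name column convention: 1-3 char names start at col 14
  name <- if (nchar(name) < 4 && nchar(a$element) == 1) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (a$het) "HETATM" else "ATOM", a$serial %% 100000, name,
          substr(a$altloc, 1, 1), a$resname, a$chain, a$resid,
          a$x, a$y, a$z, a$occ, a$b, a$element)
}

#' Write a structure (or list of structures) as PDB
#'
#' A list is written as a multi-model PDB with MODEL/ENDMDL records.
#' Coordinates are written at the PDB field precision (1e-3 Angstrom).
#'
#' @param structure a `structure3d` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  one <- function(s) vapply(seq_len(nrow(s$atoms)), function(i)
    .format_pdb_atom(as.list(s$atoms[i, ])), character(1))
  if (inherits(structure, "structure3d")) {
    writeLines(c(one(structure), "END"), path)
  } else {
    out <- character()
    for (s in structure)
      out <- c(out, sprintf("MODEL     %4d", s$model_id), one(s), "ENDMDL")
    writeLines(c(out, "END"), path)
  }
  invisible(path)
}
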