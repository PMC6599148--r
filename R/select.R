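# Atom selection mini-language and residue role maps.
#
# Grammar (whitespace-tokenized):
#   expr      := orterm
#   orterm    := andterm ("or" andterm)*
#   andterm   := unary ("and" unary)*
#   unary     := ["not"] factor
#   factor    := "(" expr ")" | primitive
#   primitive := "chain" v+ | "resid" v+ | "resname" v+ | "name" v+
#              | "backbone" | "heavy" | "water" | "hetero" | "protein" | "all"
# resid values may be single numbers or ranges "10-20" / "10:20".

.sel_keywords <- c("chain", "resid", "resname", "name", "backbone", "heavy",
                   "water", "hetero", "protein", "all", "and", "or", "not",
                   "(", ")")

.tokenize_sel <- function(expr) {
  expr <- gsub("\\(", " ( ", expr)
  expr <- gsub("\\)", " ) ", expr)
  toks <- strsplit(trimws(expr), "\\s+")[[1]]
  if (!length(toks)) stop("empty selection expression")
  toks
}

.parse_resid_values <- function(vals) {
  out <- integer()
  for (v in vals) {
    if (grepl("^-?[0-9]+[-:][0-9]+$", v)) {
      sep <- if (grepl(":", v)) ":" else "-"
      parts <- strsplit(v, sep, fixed = TRUE)[[1]]
      out <- c(out, seq(as.integer(parts[1]), as.integer(parts[2])))
    } else if (grepl("^-?[0-9]+$", v)) {
      out <- c(out, as.integer(v))
    } else stop("bad resid value in selection: '", v, "'")
  }
  out
}

.sel_eval <- function(toks, atoms) {
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  take_values <- function() {
    vals <- character()
    while (!is.na(peek()) && !(peek() %in% .sel_keywords)) vals <- c(vals, advance())
    if (!length(vals)) stop("selection keyword needs at least one value")
    vals
  }
  primitive <- function() {
    kw <- advance()
    switch(kw,
      chain   = atoms$chain %in% take_values(),
      resname = atoms$resname %in% toupper(take_values()),
      name    = atoms$name %in% toupper(take_values()),
      resid   = atoms$resid %in% .parse_resid_values(take_values()),
      backbone = atoms$name %in% .backbone_names & !atoms$het,
      heavy   = toupper(atoms$element) != "H",
      water   = atoms$resname %in% .water_resnames,
      hetero  = atoms$het,
      protein = !atoms$het & !(atoms$resname %in% .water_resnames),
      all     = rep(TRUE, nrow(atoms)),
      stop("unknown selection keyword: '", kw, "'")
    )
  }
  factor_ <- function() {
    if (identical(peek(), "(")) {
      advance()
      v <- orterm()
      if (!identical(peek(), ")")) stop("unbalanced parentheses in selection")
      advance()
      v
    } else primitive()
  }
  unary <- function() {
    if (identical(peek(), "not")) { advance(); !factor_() } else factor_()
  }
  andterm <- function() {
    v <- unary()
    while (identical(peek(), "and")) { advance(); v <- v & unary() }
    v
  }
  orterm <- function() {
    v <- andterm()
    while (identical(peek(), "or")) { advance(); v <- v | andterm() }
    v
  }
  v <- orterm()
  if (pos <= length(toks)) stop("trailing tokens in selection: ",
                                paste(toks[pos:length(toks)], collapse = " "))
  v
}

#' Select atoms by expression
#'
#' Deterministic, order-preserving atom selection.  Supported keywords:
#' `chain`, `resid` (values or ranges `10-20`), `resname`, `name`,
#' `backbone` (N, CA, C, O), `heavy` (element != H), `water`, `hetero`,
#' `protein`, `all`, combined with `and`, `or`, `not` and parentheses.
#' A selection matching zero atoms is returned empty, not an error.
#'
#' @param structure a `structure3d`.
#' @param expr selection expression string.
#' @return an `atom_selection`: integer indices into the atom table with the
#'   producing expression attached.
#' @export
select_atoms <- function(structure, expr) {
  mask <- .sel_eval(.tokenize_sel(expr), structure$atoms)
  out <- which(mask)
  attr(out, "expr") <- expr
  class(out) <- "atom_selection"
  out
}

#' @export
print.atom_selection <- function(x, ...) {
  cat(sprintf("<atom_selection> %d atoms from '%s'\n", length(x),
              attr(x, "expr")))
  invisible(x)
}

#' @export
as.integer.atom_selection <- function(x, ...) { attributes(x) <- NULL; x }

.res_key <- function(atoms) paste(atoms$chain, atoms$resid, sep = "|")

.res_label <- function(resname, resid) {
  one <- .aa1[toupper(resname)]
  ifelse(is.na(one), paste0(resname, resid), paste0(one, resid))
}

#' Residues with any heavy atom within a cutoff of a reference selection
#'
#' A residue is included iff any of its heavy (non-hydrogen) atoms lies
#' within `cutoff` Angstrom of any atom in `ref`.  Residues contributing
#' atoms to `ref` itself are excluded.
#'
#' @param structure a `structure3d`.
#' @param ref an `atom_selection` (non-empty).
#' @param cutoff distance cutoff in Angstrom (> 0).
#' @return data.frame with `chain`, `resid`, `resname` and a one-letter
#'   `label` (e.g. `"Y176"`), sorted by chain then residue number.
#' @export
residues_within <- function(structure, ref, cutoff) {
  if (!length(ref)) stop("reference selection is empty")
  if (cutoff <= 0) stop("cutoff must be > 0")
  at <- structure$atoms
  refxyz <- coords(structure, ref)
  key <- .res_key(at)
  ref_res <- unique(key[as.integer(ref)])
  heavy <- toupper(at$element) != "H" & !(key %in% ref_res)
  idx <- which(heavy)
  if (!length(idx)) return(data.frame(chain = character(), resid = integer(),
                                      resname = character(), label = character()))
  xyz <- coords(structure, idx)
  # min distance of each candidate atom to any ref atom
  cut2 <- cutoff^2
  hit <- vapply(seq_len(nrow(xyz)), function(i) {
    d2 <- (refxyz[, 1] - xyz[i, 1])^2 + (refxyz[, 2] - xyz[i, 2])^2 +
      (refxyz[, 3] - xyz[i, 3])^2
    any(d2 <= cut2)
  }, logical(1))
  sel <- idx[hit]
  res <- unique(at[sel, c("chain", "resid", "resname")])
  res <- res[order(res$chain, res$resid), , drop = FALSE]
  rownames(res) <- NULL
  res$label <- .res_label(res$resname, res$resid)
  res
}

# ---------------------------------------------------------------------------
# Role maps

.required_roles <- c("TM1a", "TM1b", "TM2", "TM3", "TM4", "TM5", "TM6a",
                     "TM6b", "TM7", "TM8", "TM9", "TM10", "TM11", "TM12",
                     "hash", "EC_gate_salt", "EC_gate_lid", "IC_gate_pairs",
                     "amine_partners", "site_anchors_ec", "site_anchor_cyt",
                     "ec_vestibule_limit", "ic_vestibule_limit", "EL2_range",
                     "termini_ranges")

#' Read a residue role map
#'
#' A role map binds named structural roles (TM helices, the hash domain,
#' gate pairs, binding-site anchors) to residue IDs or ranges in author
#' numbering.  YAML entries take the forms
#' `role: {chain: A, resid: "88-96"}`, `role: {chain: A, resid: [104, 493]}`,
#' `role: {union: [TM3, TM4, TM8, TM9]}` or, for pair lists,
#' `role: {chain: A, pairs: [[79, 452], [82, 350]]}`.
#'
#' @param path YAML file path.
#' @return a `role_map` (named list).
#' @export
read_role_map <- function(path) {
  rm <- yaml::read_yaml(path)
  if (!is.null(rm$roles)) rm <- rm$roles
  class(rm) <- "role_map"
  validate_role_map(rm)
  rm
}

#' The packaged default hSERT role map
#'
#' TM boundaries are derived from topology annotation of the human serotonin
#' transporter (UniProt P31645), not from any single structure; edit the YAML
#' for other constructs.  Gate, anchor and vestibule-limit residues follow
#' the standard hSERT numbering (R104/E493 salt bridge, Y176/F335 lid,
#' R79-D452 / W82-Y350 / Y350-E444 / E444-R462 intracellular network).
#'
#' @return a `role_map`.
#' @export
default_role_map <- function() {
  read_role_map(system.file("extdata", "hsert_roles.yaml",
                            package = "occludeR", mustWork = TRUE))
}

.role_resids <- function(roles, name, depth = 0) {
  if (depth > 5) stop("role union nesting too deep at '", name, "'")
  entry <- roles[[name]]
  if (is.null(entry)) stop("role '", name, "' not present in role map")
  if (!is.null(entry$union)) {
    parts <- lapply(entry$union, .role_resids, roles = roles, depth = depth + 1)
    return(do.call(rbind, parts))
  }
  chain <- if (is.null(entry$chain)) "A" else entry$chain
  if (!is.null(entry$pairs)) {
    ids <- unique(unlist(entry$pairs))
    return(data.frame(chain = chain, resid = as.integer(ids)))
  }
  vals <- entry$resid
  if (is.null(vals)) stop("role '", name, "' has neither resid, pairs nor union")
  ids <- .parse_resid_values(as.character(unlist(vals)))
  data.frame(chain = chain, resid = ids)
}

#' Residue IDs bound to a role
#' @param roles a `role_map`.
#' @param name role name.
#' @return data.frame with `chain`, `resid` (duplicates removed, order kept).
#' @export
role_residues <- function(roles, name) {
  df <- .role_resids(roles, name)
  unique(df)
}

#' Gate pairs bound to a pair-list role
#' @param roles a `role_map`.
#' @param name role name holding `pairs`.
#' @return list of 2-element integer vectors.
#' @export
role_pairs <- function(roles, name) {
  entry <- roles[[name]]
  if (is.null(entry) || is.null(entry$pairs))
    stop("role '", name, "' does not define residue pairs")
  lapply(entry$pairs, as.integer)
}

#' Resolve a role to an atom selection
#'
#' @param structure a `structure3d`.
#' @param roles a `role_map`.
#' @param name role name.
#' @param atoms optional restriction: `"all"`, `"backbone"`, `"CA"`, `"heavy"`.
#' @return an `atom_selection`.  Errors if the role resolves to zero residues
#'   present in the structure.
#' @export
resolve_role <- function(structure, roles, name, atoms = "all") {
  res <- role_residues(roles, name)
  at <- structure$atoms
  mask <- paste(at$chain, at$resid) %in% paste(res$chain, res$resid)
  mask <- mask & switch(atoms,
    all = TRUE,
    backbone = at$name %in% .backbone_names,
    CA = at$name == "CA",
    heavy = toupper(at$element) != "H",
    stop("unknown atom restriction: ", atoms))
  out <- which(mask)
  if (!length(out)) stop("role '", name, "' matches no atoms in structure")
  attr(out, "expr") <- sprintf("role:%s[%s]", name, atoms)
  class(out) <- "atom_selection"
  out
}

#' Validate a role map
#'
#' Checks that all required role names are present and that `hash` equals
#' the union of TM3, TM4, TM8 and TM9.
#'
#' @param roles a `role_map`.
#' @param structure optional `structure3d`; if given, additionally checks
#'   that every role resolves to at least one residue present in it.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_role_map <- function(roles, structure = NULL) {
  missing <- setdiff(.required_roles, names(roles))
  if (length(missing))
    stop("role map lacks required roles: ", paste(missing, collapse = ", "))
  hash <- role_residues(roles, "hash")
  un <- unique(do.call(rbind, lapply(c("TM3", "TM4", "TM8", "TM9"),
                                     role_residues, roles = roles)))
  if (!setequal(paste(hash$chain, hash$resid), paste(un$chain, un$resid)))
    stop("role map invariant violated: hash != TM3 + TM4 + TM8 + TM9")
  if (!is.null(structure)) {
    at <- structure$atoms
    have <- paste(at$chain, at$resid)
    for (nm in names(roles)) {
      res <- tryCatch(role_residues(roles, nm), error = function(e) NULL)
      if (is.null(res)) next
      if (!any(paste(res$chain, res$resid) %in% have))
        stop("role '", nm, "' resolves to no residue present in the structure")
    }
  }
  invisible(TRUE)
}
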