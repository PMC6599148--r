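# Access to deposited reference coordinates (wwPDB entries and published
# simulation end-states).  Printed-value validation runs against these
# depositions; nothing in the package bundles or fabricates them.

#' Locate or fetch a deposited PDB entry
#'
#' Looks for `<id>.pdb` in `cache_dir` (default: the `occludeR.depositions`
#' option, else `depositions/` under the working directory); if absent,
#' attempts to download it from the wwPDB (https://files.rcsb.org) into the
#' cache.  Offline and with an empty cache this is an error.
#'
#' @param id 4-character PDB ID (e.g. `"5I71"`).
#' @param cache_dir directory for cached depositions.
#' @return path to the PDB file.
#' @export
fetch_pdb <- function(id, cache_dir = getOption("occludeR.depositions",
                                                "depositions")) {
  id <- toupper(id)
  dest <- file.path(cache_dir, paste0(id, ".pdb"))
  if (file.exists(dest)) return(dest)
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", id)
  ok <- tryCatch({
    utils::download.file(url, dest, quiet = TRUE, mode = "wb")
    file.exists(dest) && file.size(dest) > 0
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) {
    unlink(dest)
    stop("PDB entry ", id, " is not cached in '", cache_dir,
         "' and could not be downloaded from the wwPDB ",
         "(offline?). Place ", id, ".pdb there to proceed.")
  }
  dest
}

#' Locate deposited simulation end-state frames
#'
#' The outward-occluded simulation end states are published as a Zenodo
#' deposition (DOI 10.5281/zenodo.3241982).  This helper only locates
#' already-downloaded frames: any file matching `pattern` under `dir`.
#'
#' @param dir directory holding the deposition contents.
#' @param pattern filename regex (default: occluded final-frame PDBs).
#' @return character vector of paths (error if none).
#' @export
final_frame_paths <- function(dir = getOption("occludeR.depositions",
                                              "depositions"),
                              pattern = "occluded.*final.*\\.(pdb|gro)$") {
  if (!dir.exists(dir))
    stop("deposition directory '", dir, "' does not exist; download the ",
         "simulation end states (DOI 10.5281/zenodo.3241982) into it")
  hits <- list.files(dir, pattern = pattern, recursive = TRUE,
                     full.names = TRUE, ignore.case = TRUE)
  if (!length(hits))
    stop("no final-frame files matching '", pattern, "' under '", dir, "'")
  hits
}
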