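#' Chromophore ligand configuration
#'
#' Describes which ligand component codes are treated as chromophores, which
#' atom is the anchor (the bilin "C10", the central methine carbon between
#' pyrrole rings B and C, used for all inter-bilin distances), and which heavy
#' atoms span the conjugated system for geometric dipole-axis estimation.
#'
#' Atom naming varies between chemical-component dictionaries, so none of
#' these names are hard-coded elsewhere: the shipped default anchor name is
#' `"C10"` and can be overridden per deposition (some phycocyanobilin
#' dictionaries name the central methine carbon differently, e.g. `"CHC"`).
#'
#' @param codes Character vector of ligand component codes to extract
#'   (default `"CYC"`, the phycocyanobilin component code).
#' @param anchor_atom Name of the anchor atom within each ligand.
#' @param ring_atoms Optional character vector of heavy-atom names defining
#'   the conjugated axis for [estimate_dipole_axis()]. `NULL` means all heavy
#'   atoms of the ligand.
#' @param reference_atom Atom whose direction from the anchor fixes the sign
#'   of geometric dipole axes (see [estimate_dipole_axis()]). Defaults to the
#'   last entry of `ring_atoms` when available.
#' @return An object of class `ligand_config`.
#' @examples
#' ligand_config()
#' ligand_config(codes = "CYC", anchor_atom = "CHC")
#' @export
ligand_config <- function(codes = "CYC", anchor_atom = "C10",
                          ring_atoms = NULL, reference_atom = NULL) {
  stopifnot(is.character(codes), length(codes) >= 1L,
            is.character(anchor_atom), length(anchor_atom) == 1L)
  if (!is.null(ring_atoms)) stopifnot(is.character(ring_atoms))
  if (is.null(reference_atom) && length(ring_atoms) >= 1L) {
    reference_atom <- ring_atoms[length(ring_atoms)]
  }
  structure(
    list(codes = toupper(codes), anchor_atom = anchor_atom,
         ring_atoms = ring_atoms, reference_atom = reference_atom),
    class = "ligand_config"
  )
}

#' Read a ligand configuration from a key-value text file
#'
#' The file holds `key = value` (or `key: value`) lines; recognised keys are
#' `codes`, `anchor_atom`, `ring_atoms` and `reference_atom`, with
#' comma-separated lists for the multi-valued keys. Blank lines and lines
#' starting with `#` are ignored.
#'
#' @param path Path to the configuration file.
#' @return A [ligand_config()] object.
#' @export
read_ligand_config <- function(path) {
  if (!file.exists(path)) abort(paste0("ligand config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  sep <- regexpr("[=:]", lines)
  if (any(sep < 0)) {
    abort(paste0("unparseable ligand config line(s): ",
                 paste(lines[sep < 0], collapse = "; ")))
  }
  keys <- trimws(substr(lines, 1L, sep - 1L))
  vals <- trimws(substr(lines, sep + 1L, nchar(lines)))
  split_list <- function(x) trimws(strsplit(x, ",")[[1]])
  get <- function(key, default = NULL) {
    if (key %in% keys) vals[match(key, keys)] else default
  }
  codes <- get("codes")
  if (is.null(codes)) abort("ligand config must name at least one component code")
  ring <- get("ring_atoms")
  ligand_config(
    codes = split_list(codes),
    anchor_atom = get("anchor_atom", "C10"),
    ring_atoms = if (!is.null(ring)) split_list(ring),
    reference_atom = get("reference_atom")
  )
}

#' @export
print.ligand_config <- function(x, ...) {
  cat("<ligand_config>\n")
  cat("  codes:        ", paste(x$codes, collapse = ", "), "\n")
  cat("  anchor_atom:  ", x$anchor_atom, "\n")
  cat("  ring_atoms:   ",
      if (is.null(x$ring_atoms)) "(all heavy atoms)"
      else paste(x$ring_atoms, collapse = ", "), "\n")
  cat("  reference:    ", x$reference_atom %||% "(none)", "\n")
  invisible(x)
}
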