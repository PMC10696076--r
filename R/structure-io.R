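#' Read a coordinate model and extract its bilin chromophores
#'
#' Parses a PDB (fixed-column) or mmCIF coordinate file, locates every ligand
#' instance whose component code matches the [ligand_config()], and returns a
#' `pbs_model` holding one chromophore site per ligand. The anchor of each
#' site is the configured anchor atom (the bilin C10 by default); all heavy
#' atoms of the ligand are retained for dipole-axis estimation.
#'
#' Only the first model block is used (a warning record is attached when more
#' exist). Alternate locations are collapsed by keeping the highest-occupancy
#' conformer, ties broken by alphabetical alt-loc id. Hydrogens are ignored.
#' A ligand lacking the anchor atom is reported in the model's warning table,
#' not silently dropped; its anchor coordinates are `NA` and distance
#' operations on it raise an error naming the site.
#'
#' @param path Path to a `.pdb`/`.ent` or `.cif`/`.mmcif` file.
#' @param config A [ligand_config()]; defaults to phycocyanobilin (`CYC`)
#'   anchored at `C10`.
#' @param format `"auto"` (by extension), `"pdb"` or `"mmcif"`.
#' @return A `pbs_model`: a list with tibbles `chromophores` (one row per
#'   site: `site_id`, `ligand_code`, `chain_id`, `resno`, `x`, `y`, `z`,
#'   `subunit_role`, `group_label`, `dx`, `dy`, `dz`, `dipole_source`),
#'   `atoms` (ligand heavy atoms), `label_map`, a character vector `chains`
#'   of every chain id in the file, and a `warnings` tibble.
#' @seealso [apply_label_map()], [estimate_dipoles()], [build_graph()]
#' @examples
#' asm <- make_assembly(synthetic_params(n_hexamers = 2, packing = "rod"))
#' dir <- tempfile(); paths <- write_fixture(asm, dir)
#' model <- read_structure(paths$structure)
#' nrow(chromophores(model))
#' @export
read_structure <- function(path, config = ligand_config(),
                           format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!inherits(config, "ligand_config")) abort("`config` must be a ligand_config")
  if (!file.exists(path)) abort(paste0("coordinate file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) "mmcif" else "pdb"
  }
  atoms <- switch(format,
    pdb   = parse_pdb_atoms(path),
    mmcif = parse_mmcif_atoms(path)
  )
  warnings <- tibble(site_id = character(), message = character())

  n_models <- max(length(unique(atoms$model_number)),
                  attr(atoms, "n_model_blocks") %||% 1L)
  if (n_models > 1L) {
    warnings <- add_model_warning(
      warnings, NA_character_,
      paste0(n_models, " model blocks present; using the first"))
    atoms <- dplyr::filter(atoms, .data$model_number == min(.data$model_number))
  }

  all_chains <- unique(atoms$chain_id)
  lig <- dplyr::filter(atoms, toupper(.data$residue_name) %in% config$codes)
  lig <- drop_hydrogens(lig)
  lig <- collapse_alt_locs(lig)

  if (nrow(lig) == 0L) {
    warn(paste0("no chromophore ligands (", paste(config$codes, collapse = ", "),
                ") found in ", path),
         class = "pbsnet_empty_model")
    return(new_pbs_model(path, empty_chromophores(), lig, all_chains, warnings))
  }

  lig <- dplyr::mutate(
    lig,
    site_id = paste(toupper(.data$residue_name), .data$chain_id,
                    .data$residue_seq, sep = "_"))

  sites <- lig |>
    dplyr::group_by(.data$site_id, .data$residue_name, .data$chain_id,
                    .data$residue_seq) |>
    dplyr::summarise(
      has_anchor = any(.data$atom_name == config$anchor_atom),
      x = .data$x[match(config$anchor_atom, .data$atom_name)],
      y = .data$y[match(config$anchor_atom, .data$atom_name)],
      z = .data$z[match(config$anchor_atom, .data$atom_name)],
      .groups = "drop") |>
    dplyr::transmute(
      site_id = .data$site_id,
      ligand_code = toupper(.data$residue_name),
      chain_id = .data$chain_id,
      resno = .data$residue_seq,
      x = .data$x, y = .data$y, z = .data$z,
      subunit_role = "unknown",
      group_label = NA_character_,
      dx = NA_real_, dy = NA_real_, dz = NA_real_,
      dipole_source = NA_character_,
      has_anchor = .data$has_anchor) |>
    dplyr::arrange(.data$chain_id, .data$resno, .data$site_id)

  missing <- sites$site_id[!sites$has_anchor]
  for (sid in missing) {
    warnings <- add_model_warning(
      warnings, sid, paste0("anchor atom '", config$anchor_atom, "' absent"))
  }
  sites$has_anchor <- NULL

  new_pbs_model(path, sites, lig, all_chains, warnings, config = config)
}

empty_chromophores <- function() {
  tibble(site_id = character(), ligand_code = character(),
         chain_id = character(), resno = integer(),
         x = double(), y = double(), z = double(),
         subunit_role = character(), group_label = character(),
         dx = double(), dy = double(), dz = double(),
         dipole_source = character())
}

add_model_warning <- function(warnings, site_id, message) {
  dplyr::bind_rows(warnings, tibble(site_id = site_id, message = message))
}

new_pbs_model <- function(path, chromophores, atoms, chains, warnings,
                          label_map = NULL, config = NULL) {
  structure(
    list(
      source_path = path,
      chromophores = chromophores,
      atoms = atoms,
      chains = chains,
      label_map = label_map %||% tibble(group_label = character(),
                                        chain_id = character()),
      warnings = warnings,
      config = config %||% ligand_config()),
    class = "pbs_model")
}

drop_hydrogens <- function(atoms) {
  el <- toupper(trimws(atoms$element))
  is_h <- el %in% c("H", "D") |
    (!nzchar(el) & grepl("^[0-9]*H", toupper(atoms$atom_name)))
  atoms[!is_h, , drop = FALSE]
}

# Highest occupancy wins; ties broken by alphabetical alt-loc id.
collapse_alt_locs <- function(atoms) {
  atoms |>
    dplyr::group_by(.data$chain_id, .data$residue_seq, .data$residue_name,
                    .data$atom_name) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$alt_loc,
                   .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
}

parse_pdb_atoms <- function(path) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse PDB file ", path, ": ",
                                     conditionMessage(e))))
  a <- pdb$atom
  tibble(
    atom_name = trimws(a$elety),
    element = trimws(a$elesy %||% ""),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    alt_loc = ifelse(is.na(a$alt) | a$alt == "", "", trimws(a$alt)),
    residue_name = trimws(a$resid),
    residue_seq = as.integer(a$resno),
    chain_id = ifelse(is.na(a$chain), "", trimws(a$chain)),
    model_number = rep(1L, nrow(a)),
    record_type = trimws(a$type)) |>
    add_multimodel_count(path)
}

# bio3d reads only the first frame; note additional MODEL blocks by a cheap
# line scan so read_structure() can attach the warning record.
add_multimodel_count <- function(atoms, path) {
  n <- sum(startsWith(readLines(path, warn = FALSE), "MODEL "))
  if (n > 1L) attr(atoms, "n_model_blocks") <- n
  atoms
}

parse_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- which(trimws(lines) == "loop_")
  header <- NULL
  data_start <- NA_integer_
  for (ls in loop_starts) {
    i <- ls + 1L
    tags <- character()
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      tags <- c(tags, trimws(lines[i]))
      i <- i + 1L
    }
    if (length(tags) && all(startsWith(tags, "_atom_site."))) {
      header <- sub("^_atom_site\\.", "", tags)
      data_start <- i
      break
    }
  }
  if (is.null(header)) {
    abort(paste0("failed to parse mmCIF file ", path,
                 ": no _atom_site loop found"))
  }
  rows <- character()
  i <- data_start
  while (i <= length(lines)) {
    l <- trimws(lines[i])
    if (!nzchar(l) || startsWith(l, "#") || startsWith(l, "_") ||
        l == "loop_" || startsWith(l, "data_")) break
    rows <- c(rows, lines[i])
    i <- i + 1L
  }
  tokens <- scan(text = paste(rows, collapse = "\n"), what = character(),
                 quote = "'\"", quiet = TRUE)
  if (length(tokens) %% length(header) != 0L) {
    abort(paste0("failed to parse mmCIF file ", path,
                 ": atom_site row near line ", data_start,
                 " does not match ", length(header), " columns"))
  }
  m <- matrix(tokens, ncol = length(header), byrow = TRUE)
  colnames(m) <- header
  col <- function(nm, default = NA_character_) {
    if (nm %in% header) m[, nm] else rep(default, nrow(m))
  }
  alt <- col("label_alt_id", ".")
  tibble(
    atom_name = col("auth_atom_id", NA) %|NA|% col("label_atom_id"),
    element = col("type_symbol", ""),
    x = as.numeric(col("Cartn_x")),
    y = as.numeric(col("Cartn_y")),
    z = as.numeric(col("Cartn_z")),
    occupancy = suppressWarnings(as.numeric(col("occupancy", "1"))) %|NA|% 1,
    alt_loc = ifelse(alt %in% c(".", "?"), "", alt),
    residue_name = col("auth_comp_id", NA) %|NA|% col("label_comp_id"),
    residue_seq = as.integer(suppressWarnings(as.numeric(
      col("auth_seq_id", NA) %|NA|% col("label_seq_id")))),
    chain_id = col("auth_asym_id", NA) %|NA|% col("label_asym_id"),
    model_number = as.integer(suppressWarnings(as.numeric(
      col("pdbx_PDB_model_num", "1")))) %|NA|% 1L,
    record_type = col("group_PDB", "HETATM"))
}

`%|NA|%` <- function(a, b) ifelse(is.na(a), b, a)

#' Attach group labels from a mapping file
#'
#' Assigns assembly nomenclature labels (hexamer names such as `Rt1'`, core
#' cylinders `A`...`D'`) to chromophore sites by chain id. Labeling never
#' changes coordinates or site counts.
#'
#' @param model A `pbs_model` from [read_structure()].
#' @param mapping A tab-separated file with two columns (`group_label`,
#'   `chain_id`, no header required) or a data frame with those columns.
#' @return The model with `group_label` filled for sites whose chain appears
#'   in the map; unmapped chains keep an empty label.
#' @export
apply_label_map <- function(model, mapping) {
  stopifnot(inherits(model, "pbs_model"))
  map <- if (is.character(mapping)) read_label_map(mapping) else {
    out <- as_tibble(mapping)
    if (!all(c("group_label", "chain_id") %in% names(out))) {
      abort("label map must have columns group_label and chain_id")
    }
    out[, c("group_label", "chain_id")]
  }
  if (nrow(map) == 0L) return(model)
  if (anyDuplicated(map)) {
    abort("label map contains duplicate (group_label, chain_id) rows")
  }
  dup_chain <- unique(map$chain_id[duplicated(map$chain_id)])
  if (length(dup_chain)) {
    abort(paste0("chain(s) mapped to more than one group label: ",
                 paste(dup_chain, collapse = ", ")))
  }
  missing <- setdiff(map$chain_id, model$chains)
  if (length(missing)) {
    abort(paste0("label map references chain(s) absent from the model: ",
                 paste(missing, collapse = ", ")))
  }
  idx <- match(model$chromophores$chain_id, map$chain_id)
  hit <- !is.na(idx)
  model$chromophores$group_label[hit] <- map$group_label[idx[hit]]
  model$label_map <- map
  model
}

#' Read a label map (TSV: group_label, chain_id)
#' @param path Path to the tab-separated mapping file.
#' @return A tibble with columns `group_label`, `chain_id`.
#' @export
read_label_map <- function(path) {
  if (!file.exists(path)) abort(paste0("label map file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (length(lines) == 0L) {
    return(tibble(group_label = character(), chain_id = character()))
  }
  if (identical(tolower(strsplit(lines[1], "\t")[[1]][1]), "group_label")) {
    lines <- lines[-1]
  }
  if (length(lines) == 0L) {
    return(tibble(group_label = character(), chain_id = character()))
  }
  parts <- strsplit(lines, "\t")
  if (any(lengths(parts) < 2L)) {
    abort(paste0("label map lines must be 'group_label<TAB>chain_id'; bad: ",
                 paste(lines[lengths(parts) < 2L], collapse = "; ")))
  }
  tibble(group_label = trimws(vapply(parts, `[[`, "", 1L)),
         chain_id = trimws(vapply(parts, `[[`, "", 2L)))
}

#' Extract the chromophore site table from a model
#' @param model A `pbs_model`.
#' @return A tibble of chromophore sites (see [read_structure()]).
#' @export
chromophores <- function(model) {
  stopifnot(inherits(model, "pbs_model"))
  model$chromophores
}

#' Site ids belonging to a group label
#' @param model A labeled `pbs_model`.
#' @param label A group label present in the model.
#' @return Character vector of site ids.
#' @export
sites_in_group <- function(model, label) {
  sites <- chromophores(model)
  ids <- sites$site_id[!is.na(sites$group_label) & sites$group_label == label]
  if (length(ids) == 0L) {
    abort(paste0("no chromophores carry group label '", label, "'"))
  }
  ids
}

#' Write the chromophore table as TSV
#' @param model A `pbs_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chromophore_table <- function(model, path) {
  tab <- chromophores(model)[, c("site_id", "ligand_code", "chain_id",
                                 "group_label", "x", "y", "z")]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.pbs_model <- function(x, ...) {
  cat("<pbs_model> ", x$source_path, "\n", sep = "")
  cat("  chromophores: ", nrow(x$chromophores),
      " (", sum(!is.na(x$chromophores$group_label)), " labeled)\n", sep = "")
  cat("  chains: ", length(x$chains), "\n", sep = "")
  if (nrow(x$warnings)) {
    cat("  warnings: ", nrow(x$warnings), "\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.pbs_model <- function(x, ...) chromophores(x)

#' @export
glance.pbs_model <- function(x, ...) {
  tibble(
    n_chromophores = nrow(x$chromophores),
    n_chains = length(x$chains),
    n_labeled = sum(!is.na(x$chromophores$group_label)),
    n_with_dipole = sum(!is.na(x$chromophores$dx)),
    n_warnings = nrow(x$warnings),
    source_path = x$source_path)
}
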