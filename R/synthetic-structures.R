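#' Parameters for a synthetic hexamer assembly
#'
#' Describes a toy assembly of toroidal (alpha beta)6 hexamers carrying point
#' chromophores with known dipole vectors, packed either as a coaxially
#' stacked rod or a laterally staggered chain. Every geometric quantity of
#' the result is analytically known, so the generator serves as ground truth
#' for the analysis modules.
#'
#' Within a hexamer, the six protomers sit at 60-degree azimuths on a toroid
#' of radius `toroid_radius`; each protomer carries one alpha chromophore on
#' the outer rim and `chromophores_per_protomer - 1` beta chromophores inset
#' by 8 Angstrom per level and rotated by 20 degrees per level (all in the
#' hexamer plane). Rod packing translates successive hexamers along the
#' toroid axis by `axial_spacing` (optionally rotating by `stagger_angle`);
#' chain packing translates them by `lateral_offset` so that exactly one
#' azimuthal sector forms the closest inter-hexamer contact.
#'
#' @param n_hexamers Number of hexamers (>= 1).
#' @param packing `"chain"` or `"rod"`.
#' @param toroid_radius Radius of the alpha-chromophore ring, Angstrom.
#' @param axial_spacing Rod packing: hexamer-to-hexamer translation along the
#'   axis, Angstrom. With zero stagger this is exactly the minimal
#'   inter-hexamer anchor distance.
#' @param lateral_offset Chain packing: 3-vector translation between
#'   successive hexamer centers, Angstrom. The default
#'   `c(2 * toroid_radius + 37, 0, 0)` makes the single closest junction
#'   contact exactly 37 Angstrom — the inner-chain bilin step of the
#'   paddle-shaped phycobilisome chain.
#' @param stagger_angle Rotation (degrees) applied cumulatively to successive
#'   hexamers.
#' @param chromophores_per_protomer Chromophores per protomer (default 3,
#'   phycocyanin-like: 1 alpha + 2 beta).
#' @param dipole_mode Direction of the true site dipoles: `"tangent"` (to
#'   the toroid circle), `"radial"`, or `"axial"`.
#' @param jitter_sd Gaussian positional noise (Angstrom) added to anchors;
#'   default 0 (exact geometry).
#' @param seed Integer seed controlling the jitter; same seed, same assembly.
#' @param ligand_code Component code written on the pseudo-bilin ligands.
#' @return A `synthetic_params` list.
#' @export
synthetic_params <- function(n_hexamers = 2,
                             packing = c("chain", "rod"),
                             toroid_radius = 35,
                             axial_spacing = 30,
                             lateral_offset = c(2 * toroid_radius + 37, 0, 0),
                             stagger_angle = 0,
                             chromophores_per_protomer = 3,
                             dipole_mode = c("tangent", "radial", "axial"),
                             jitter_sd = 0,
                             seed = 1L,
                             ligand_code = "CYC") {
  packing <- match.arg(packing)
  dipole_mode <- match.arg(dipole_mode)
  stopifnot(n_hexamers >= 1, toroid_radius > 0,
            chromophores_per_protomer >= 1, jitter_sd >= 0,
            length(lateral_offset) == 3L)
  if (packing == "rod" && axial_spacing <= 0) {
    abort("axial_spacing must be positive for rod packing")
  }
  if (packing == "chain" && n_hexamers > 1 &&
      sqrt(sum(lateral_offset^2)) == 0) {
    abort("lateral_offset must be non-zero for chain packing")
  }
  if (n_hexamers > 52L) abort("at most 52 hexamers (one chain id each)")
  structure(
    list(n_hexamers = as.integer(n_hexamers), packing = packing,
         toroid_radius = toroid_radius, axial_spacing = axial_spacing,
         lateral_offset = as.numeric(lateral_offset),
         stagger_angle = stagger_angle,
         chromophores_per_protomer = as.integer(chromophores_per_protomer),
         dipole_mode = dipole_mode, jitter_sd = jitter_sd,
         seed = as.integer(seed), ligand_code = toupper(ligand_code)),
    class = "synthetic_params")
}

# pseudo-bilin atom names: axis-start, anchor (C10), axis-end
synthetic_ligand_config <- function(code) {
  ligand_config(codes = code, anchor_atom = "C10",
                ring_atoms = c("C05", "C10", "C15"),
                reference_atom = "C15")
}

#' Generate a synthetic hexamer assembly
#'
#' Builds the chromophore sites of [synthetic_params()] together with full
#' ground truth: the per-junction nearest cross-hexamer pair and distance,
#' every site's true dipole vector, the hexamer label map (`H1`, `H2`, ...
#' one chain per hexamer) and the matching assembly schema.
#'
#' @param params A [synthetic_params()] object.
#' @return A `synthetic_assembly`: list with `model` (an in-memory
#'   `pbs_model`), `params` and `ground_truth` (list: `junctions` tibble with
#'   `group_a`, `group_b`, `site_a`, `site_b`, `min_distance`,
#'   `n_min_pairs`; `dipoles` tibble; `label_map`; `schema`).
#' @export
make_assembly <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  p <- params
  chains <- c(LETTERS, letters)[seq_len(p$n_hexamers)]
  deg <- pi / 180
  set.seed(p$seed)

  rows <- list()
  for (h in seq_len(p$n_hexamers)) {
    center <- if (p$packing == "rod") {
      c(0, 0, (h - 1) * p$axial_spacing)
    } else {
      (h - 1) * p$lateral_offset
    }
    rot <- (h - 1) * p$stagger_angle
    for (j in seq_len(6L)) {
      for (k in seq_len(p$chromophores_per_protomer)) {
        radius <- p$toroid_radius - 8 * (k - 1)
        if (radius <= 0) abort("chromophores_per_protomer too large for toroid_radius")
        ang <- ((j - 1) * 60 + rot + 20 * (k - 1)) * deg
        pos <- center + c(radius * cos(ang), radius * sin(ang), 0)
        if (p$jitter_sd > 0) pos <- pos + stats::rnorm(3, sd = p$jitter_sd)
        dip <- switch(p$dipole_mode,
          tangent = c(-sin(ang), cos(ang), 0),
          radial = c(cos(ang), sin(ang), 0),
          axial = c(0, 0, 1))
        rows[[length(rows) + 1L]] <- tibble(
          hexamer = h, chain_id = chains[h],
          resno = (j - 1L) * 10L + k,
          role = if (k == 1L) "alpha" else "beta",
          x = pos[1], y = pos[2], z = pos[3],
          dx = dip[1], dy = dip[2], dz = dip[3])
      }
    }
  }
  sites <- dplyr::bind_rows(rows)
  sites$site_id <- paste(p$ligand_code, sites$chain_id, sites$resno, sep = "_")

  junctions <- junction_ground_truth(sites, p)
  if (p$n_hexamers > 1L && any(junctions$min_distance <= 0)) {
    abort("overlapping hexamer placement: zero inter-hexamer anchor distance")
  }

  chrom <- tibble(
    site_id = sites$site_id,
    ligand_code = p$ligand_code,
    chain_id = sites$chain_id,
    resno = sites$resno,
    x = sites$x, y = sites$y, z = sites$z,
    subunit_role = sites$role,
    group_label = paste0("H", sites$hexamer),
    dx = NA_real_, dy = NA_real_, dz = NA_real_,
    dipole_source = NA_character_)

  atoms <- synthetic_ligand_atoms(sites, p)
  label_map <- tibble(group_label = paste0("H", seq_len(p$n_hexamers)),
                      chain_id = chains)
  schema <- assembly_schema(tibble(
    name = paste0("H", seq_len(p$n_hexamers)),
    compartment = "periphery",
    copies = 1L, protomers_per_copy = 6L,
    chromophores_per_alpha = 1L,
    chromophores_per_beta = p$chromophores_per_protomer - 1L,
    extra_chromophores = 0L,
    polypeptides_per_copy = 12L))

  model <- new_pbs_model(
    path = "<synthetic>", chromophores = chrom, atoms = atoms,
    chains = chains,
    warnings = tibble(site_id = character(), message = character()),
    label_map = label_map,
    config = synthetic_ligand_config(p$ligand_code))

  structure(
    list(model = model, params = p,
         ground_truth = list(
           junctions = junctions,
           dipoles = tibble(site_id = sites$site_id, dx = sites$dx,
                            dy = sites$dy, dz = sites$dz),
           label_map = label_map,
           schema = schema)),
    class = "synthetic_assembly")
}

# nearest cross-hexamer pair per adjacent junction, by direct arithmetic
junction_ground_truth <- function(sites, p) {
  if (p$n_hexamers < 2L) {
    return(tibble(group_a = character(), group_b = character(),
                  site_a = character(), site_b = character(),
                  min_distance = double(), n_min_pairs = integer()))
  }
  purrr::map(seq_len(p$n_hexamers - 1L), function(h) {
    a <- sites[sites$hexamer == h, ]
    b <- sites[sites$hexamer == h + 1L, ]
    cross <- tidyr::crossing(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
    d <- sqrt((a$x[cross$i] - b$x[cross$j])^2 +
                (a$y[cross$i] - b$y[cross$j])^2 +
                (a$z[cross$i] - b$z[cross$j])^2)
    mn <- min(d)
    at_min <- abs(d - mn) <= 1e-9
    ord <- order(round(d, 6), a$site_id[cross$i], b$site_id[cross$j])
    k <- ord[1L]
    tibble(group_a = paste0("H", h), group_b = paste0("H", h + 1L),
           site_a = a$site_id[cross$i[k]], site_b = b$site_id[cross$j[k]],
           min_distance = mn, n_min_pairs = sum(at_min))
  }) |> dplyr::bind_rows()
}

# three heavy atoms per pseudo-bilin: axis-start, anchor, axis-end, spanning
# the true dipole so axis fitting can recover it
synthetic_ligand_atoms <- function(sites, p) {
  half <- 1.8
  purrr::map(seq_len(nrow(sites)), function(i) {
    s <- sites[i, ]
    mu <- c(s$dx, s$dy, s$dz)
    anchor <- c(s$x, s$y, s$z)
    tibble(
      atom_name = c("C05", "C10", "C15"),
      element = "C",
      x = c(anchor[1] - half * mu[1], anchor[1], anchor[1] + half * mu[1]),
      y = c(anchor[2] - half * mu[2], anchor[2], anchor[2] + half * mu[2]),
      z = c(anchor[3] - half * mu[3], anchor[3], anchor[3] + half * mu[3]),
      occupancy = 1, alt_loc = "",
      residue_name = p$ligand_code,
      residue_seq = s$resno,
      chain_id = s$chain_id,
      model_number = 1L,
      record_type = "HETATM",
      site_id = s$site_id)
  }) |> dplyr::bind_rows()
}

#' @export
print.synthetic_assembly <- function(x, ...) {
  p <- x$params
  cat("<synthetic_assembly> ", p$packing, " packing, ", p$n_hexamers,
      " hexamers, ", nrow(x$model$chromophores), " chromophores\n", sep = "")
  if (nrow(x$ground_truth$junctions)) {
    cat("  junction min distances: ",
        paste(sprintf("%.1f", x$ground_truth$junctions$min_distance),
              collapse = ", "), " A\n", sep = "")
  }
  invisible(x)
}

#' @export
tidy.synthetic_assembly <- function(x, ...) x$ground_truth$junctions

#' @export
glance.synthetic_assembly <- function(x, ...) {
  tibble(
    packing = x$params$packing,
    n_hexamers = x$params$n_hexamers,
    n_chromophores = nrow(x$model$chromophores),
    n_junctions = nrow(x$ground_truth$junctions),
    min_junction_distance = if (nrow(x$ground_truth$junctions))
      min(x$ground_truth$junctions$min_distance) else NA_real_)
}

#' Write a synthetic assembly as a coordinate fixture with sidecars
#'
#' Writes the pseudo-bilin ligands as a PDB or mmCIF file (3 heavy atoms per
#' chromophore: axis-start, C10 anchor, axis-end) plus sidecar files: the
#' hexamer label map (TSV), the true dipole table (TSV), the matching
#' assembly schema (TSV) and the ground-truth junction table (TSV).
#' [read_structure()] round-trips the coordinates to within PDB fixed-width
#' rounding (1e-3 Angstrom).
#'
#' @param assembly A `synthetic_assembly` from [make_assembly()].
#' @param dir Output directory (created if needed).
#' @param format `"pdb"` or `"mmcif"`.
#' @return Named list of written paths: `structure`, `label_map`, `dipoles`,
#'   `schema`, `junctions`.
#' @export
write_fixture <- function(assembly, dir, format = c("pdb", "mmcif")) {
  stopifnot(inherits(assembly, "synthetic_assembly"))
  format <- match.arg(format)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) abort(paste0("cannot create directory: ", dir))
  }
  atoms <- assembly$model$atoms
  structure_path <- file.path(
    dir, if (format == "pdb") "structure.pdb" else "structure.cif")
  if (format == "pdb") {
    write_pdb_fixture(atoms, structure_path)
  } else {
    write_mmcif_fixture(atoms, structure_path)
  }
  gt <- assembly$ground_truth
  paths <- list(
    structure = structure_path,
    label_map = file.path(dir, "label_map.tsv"),
    dipoles = file.path(dir, "dipoles.tsv"),
    schema = file.path(dir, "schema.tsv"),
    junctions = file.path(dir, "junctions.tsv"))
  write.table(gt$label_map, paths$label_map, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(gt$dipoles, paths$dipoles, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(gt$schema, paths$schema, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(gt$junctions, paths$junctions, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

write_pdb_fixture <- function(atoms, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("REMARK   1 synthetic hexamer assembly fixture", con)
  serial <- 0L
  lines <- character(nrow(atoms))
  for (i in seq_len(nrow(atoms))) {
    serial <- serial + 1L
    lines[i] <- sprintf(
      "HETATM%5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      serial, sprintf(" %-3s", atoms$atom_name[i]), atoms$residue_name[i],
      atoms$chain_id[i], atoms$residue_seq[i],
      atoms$x[i], atoms$y[i], atoms$z[i], atoms$occupancy[i], 0,
      atoms$element[i])
  }
  writeLines(lines, con)
  writeLines("END", con)
  invisible(path)
}

write_mmcif_fixture <- function(atoms, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "data_synthetic",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.auth_asym_id",
    "_atom_site.label_seq_id",
    "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.pdbx_PDB_model_num"), con)
  lines <- sprintf(
    "HETATM %d %s %s . %s %s %s %d %d %.3f %.3f %.3f %.2f 1",
    seq_len(nrow(atoms)), atoms$element, atoms$atom_name,
    atoms$residue_name, atoms$chain_id, atoms$chain_id,
    atoms$residue_seq, atoms$residue_seq,
    atoms$x, atoms$y, atoms$z, atoms$occupancy)
  writeLines(lines, con)
  writeLines("#", con)
  invisible(path)
}
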