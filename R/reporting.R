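#' Configuration for an analysis run
#'
#' Bundles the inputs of a full chromophore-network analysis: coordinate
#' files, ligand configuration, label map, optional dipole table and schema,
#' graph parameters, and an output directory.
#'
#' @param structures Character vector of coordinate file paths (PDB/mmCIF);
#'   multiple files are assumed co-registered in one frame and are merged.
#' @param config A [ligand_config()] or path to a ligand config file.
#' @param label_map Optional path to a label-map TSV (or a data frame).
#' @param dipole_table Optional path to a dipole TSV.
#' @param schema Optional path to an assembly schema TSV (or a data frame).
#' @param label_pairs Optional list of 2-element character vectors: group
#'   label pairs whose minimal inter-group distances the report lists.
#' @param sources,terminals Optional group labels naming pathway sources and
#'   terminal emitters.
#' @param cutoff Graph cutoff in Angstrom (default 45).
#' @param objective Pathway objective (see [shortest_pathways()]).
#' @param estimate_dipoles Estimate geometric dipole axes when no dipole
#'   table is supplied?
#' @param out_dir Output directory for reports.
#' @param seed Integer seed (recorded in the report; the analyses themselves
#'   are deterministic).
#' @return A `run_config` list.
#' @export
run_config <- function(structures, config = ligand_config(),
                       label_map = NULL, dipole_table = NULL, schema = NULL,
                       label_pairs = NULL, sources = NULL, terminals = NULL,
                       cutoff = 45, objective = "min_total",
                       estimate_dipoles = FALSE,
                       out_dir = tempfile("pbsnet_run_"), seed = 1L) {
  if (is.character(config)) config <- read_ligand_config(config)
  stopifnot(inherits(config, "ligand_config"), cutoff > 0,
            length(structures) >= 1L)
  missing <- structures[!file.exists(structures)]
  if (length(missing)) {
    abort(paste0("input structure(s) not found: ",
                 paste(missing, collapse = ", ")))
  }
  for (p in c(label_map, dipole_table, schema)) {
    if (is.character(p) && !file.exists(p)) {
      abort(paste0("input file not found: ", p))
    }
  }
  structure(
    list(structures = structures, config = config, label_map = label_map,
         dipole_table = dipole_table, schema = schema,
         label_pairs = label_pairs, sources = sources,
         terminals = terminals, cutoff = cutoff, objective = objective,
         estimate_dipoles = estimate_dipoles, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "run_config")
}

# merge co-registered models into one (chains must not clash)
merge_models <- function(models) {
  if (length(models) == 1L) return(models[[1L]])
  chains <- unlist(purrr::map(models, "chains"))
  if (anyDuplicated(chains)) {
    abort(paste0("chain id(s) shared between input files: ",
                 paste(unique(chains[duplicated(chains)]), collapse = ", "),
                 "; co-registered inputs must use distinct chains"))
  }
  base <- models[[1L]]
  base$chromophores <- dplyr::bind_rows(purrr::map(models, "chromophores"))
  base$atoms <- dplyr::bind_rows(purrr::map(models, "atoms"))
  base$chains <- chains
  base$warnings <- dplyr::bind_rows(purrr::map(models, "warnings"))
  base$source_path <- paste(purrr::map_chr(models, "source_path"),
                            collapse = ";")
  base
}

load_run_model <- function(cfg) {
  models <- purrr::map(cfg$structures, function(p) {
    m <- read_structure(p, config = cfg$config)
    message("pbsnet: ", nrow(chromophores(m)), " chromophores in ", p)
    m
  })
  model <- merge_models(models)
  if (!is.null(cfg$label_map)) model <- apply_label_map(model, cfg$label_map)
  if (!is.null(cfg$dipole_table)) {
    model <- apply_dipole_table(model, cfg$dipole_table)
  } else if (isTRUE(cfg$estimate_dipoles)) {
    model <- estimate_dipoles(model)
  }
  model
}

#' Extract chromophores for an analysis run
#'
#' Thin orchestration: reads every configured structure, applies the label
#' map, and writes one chromophore table (TSV) into the output directory.
#'
#' @param cfg A [run_config()].
#' @return The chromophore tibble, invisibly-written to
#'   `file.path(cfg$out_dir, "chromophores.tsv")`.
#' @export
run_extract <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  model <- load_run_model(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_chromophore_table(model, file.path(cfg$out_dir, "chromophores.tsv"))
  chromophores(model)
}

round1 <- function(x) round(x, 1)

#' Assemble the full analysis report
#'
#' Runs the configured analyses on the merged, labeled model and writes a
#' machine-readable `report.json` plus a human-readable `report.txt` into the
#' output directory. Sections without the needed inputs (no label pairs, no
#' terminals, no dipoles, no schema) are marked `"skipped"` rather than
#' failing. Distances in the text report are printed to 0.1 Angstrom; the
#' JSON carries both full precision and the printed value.
#'
#' @param cfg A [run_config()].
#' @return The report list, invisibly; side effect: files under
#'   `cfg$out_dir`.
#' @export
run_report <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  model <- load_run_model(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  graph <- build_graph(model, cutoff = cfg$cutoff)

  report <- list(
    inputs = list(structures = cfg$structures, cutoff = cfg$cutoff,
                  objective = cfg$objective, seed = cfg$seed),
    n_chromophores = nrow(chromophores(model)))

  report$inter_group_distances <- if (length(cfg$label_pairs)) {
    purrr::map(cfg$label_pairs, function(pr) {
      r <- inter_group_min_distance(model, pr[1L], pr[2L])
      r$distance_printed <- round1(r$distance)
      r
    }) |> dplyr::bind_rows()
  } else "skipped"

  report$pathways <- if (!is.null(cfg$sources) && !is.null(cfg$terminals)) {
    paths <- shortest_pathways(
      graph,
      sources = unlist(purrr::map(cfg$sources, sites_in_group,
                                  model = model)),
      terminals = unlist(purrr::map(cfg$terminals, sites_in_group,
                                    model = model)),
      objective = cfg$objective)
    paths |>
      dplyr::mutate(
        total_length_printed = round1(.data$total_length),
        max_step_printed = round1(.data$max_step))
  } else "skipped"

  has_dipoles <- any(!is.na(chromophores(model)$dx))
  report$kappa_table <- if (has_dipoles) {
    kt <- pair_orientation_table(model, cutoff = cfg$cutoff)
    kt$distance_printed <- round1(kt$distance)
    kt
  } else "skipped"

  report$census <- if (!is.null(cfg$schema)) {
    sch <- if (is.character(cfg$schema)) read_assembly_schema(cfg$schema)
           else assembly_schema(cfg$schema)
    cen <- census(sch)
    list(totals = glance(cen), by_component = cen$components,
         model_check = validate_against_model(sch, model))
  } else "skipped"

  json_path <- file.path(cfg$out_dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  writeLines(format_report_text(report), file.path(cfg$out_dir, "report.txt"))
  invisible(report)
}

format_report_text <- function(report) {
  out <- c("pbsnet analysis report",
           paste0("chromophores: ", report$n_chromophores), "")
  igd <- report$inter_group_distances
  out <- c(out, "inter-group minimal bilin distances:")
  if (is.character(igd)) {
    out <- c(out, "  skipped")
  } else {
    out <- c(out, sprintf("  %s - %s: %.1f A (%s to %s)",
                          igd$group_a, igd$group_b, igd$distance_printed,
                          igd$site_a, igd$site_b))
  }
  out <- c(out, "", "EET pathways:")
  pw <- report$pathways
  if (is.character(pw)) {
    out <- c(out, "  skipped")
  } else {
    out <- c(out, sprintf(
      "  %s -> %s: %d steps, total %.1f A, longest step %.1f A",
      pw$source, ifelse(pw$reached, pw$terminal, "(unreachable)"),
      ifelse(pw$reached, pw$n_steps, 0L),
      ifelse(pw$reached, pw$total_length_printed, NA),
      ifelse(pw$reached, pw$max_step_printed, NA)))
  }
  out <- c(out, "", "orientation factors (kappa^2):")
  kt <- report$kappa_table
  if (is.character(kt)) {
    out <- c(out, "  skipped")
  } else {
    shown <- head(dplyr::arrange(kt, .data$distance), 20L)
    out <- c(out, sprintf("  %s - %s: D = %.1f A, kappa^2 = %.2f",
                          shown$donor_id, shown$acceptor_id,
                          shown$distance_printed, round(shown$kappa_sq, 2)))
    if (nrow(kt) > 20L) {
      out <- c(out, paste0("  ... (", nrow(kt), " pairs in report.json)"))
    }
  }
  out <- c(out, "", "assembly census:")
  cen <- report$census
  if (is.character(cen)) {
    out <- c(out, "  skipped")
  } else {
    tot <- cen$totals
    out <- c(out, sprintf(
      "  chromophores: %d total (%d core, %d periphery); protomers: %d; polypeptides: %d",
      tot$chromophore_total, tot$chromophores_core,
      tot$chromophores_periphery, tot$protomer_total, tot$polypeptide_total))
  }
  out
}
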