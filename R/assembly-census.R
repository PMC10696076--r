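#' Declare an assembly stoichiometry schema
#'
#' A schema lists the components of a phycobilisome model — hexamers of
#' (alpha beta) protomers and linker polypeptides — with copy numbers and
#' per-subunit chromophore counts, so protomer, polypeptide and bilin tallies
#' follow by pure arithmetic.
#'
#' @param components A data frame with columns `name`, `compartment`
#'   (`core`, `periphery` or `linker`), `copies`, `protomers_per_copy`,
#'   `chromophores_per_alpha`, `chromophores_per_beta`,
#'   `extra_chromophores`, `polypeptides_per_copy` (all counts non-negative
#'   integers).
#' @return An `assembly_schema` tibble.
#' @examples
#' pc <- assembly_schema(data.frame(
#'   name = "pc_hexamer", compartment = "periphery", copies = 1,
#'   protomers_per_copy = 6, chromophores_per_alpha = 1,
#'   chromophores_per_beta = 2, extra_chromophores = 0,
#'   polypeptides_per_copy = 12))
#' census(pc)$chromophore_total  # 6 * (1 + 2) = 18
#' @export
assembly_schema <- function(components) {
  tab <- as_tibble(components)
  need <- c("name", "compartment", "copies", "protomers_per_copy",
            "chromophores_per_alpha", "chromophores_per_beta",
            "extra_chromophores", "polypeptides_per_copy")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    abort(paste0("schema lacks column(s): ", paste(missing, collapse = ", ")))
  }
  count_cols <- need[-(1:2)]
  for (cc in count_cols) {
    v <- tab[[cc]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) ||
        any(v != as.integer(v))) {
      abort(paste0("schema column '", cc,
                   "' must hold non-negative integers"))
    }
    tab[[cc]] <- as.integer(v)
  }
  bad_comp <- setdiff(unique(tab$compartment),
                      c("core", "periphery", "linker"))
  if (length(bad_comp)) {
    abort(paste0("unknown compartment(s): ",
                 paste(bad_comp, collapse = ", "),
                 " (use core, periphery or linker)"))
  }
  out <- tab[, need]
  class(out) <- c("assembly_schema", class(out))
  out
}

#' Read an assembly schema from a TSV file
#' @param path Tab-separated file with the [assembly_schema()] columns as
#'   header. Lines starting with `#` are ignored.
#' @return An `assembly_schema`.
#' @export
read_assembly_schema <- function(path) {
  if (!file.exists(path)) abort(paste0("schema file not found: ", path))
  tab <- read.delim(path, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  assembly_schema(tab)
}

#' Write an assembly schema as TSV
#' @param schema An `assembly_schema`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly_schema <- function(schema, path) {
  write.table(schema, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tally an assembly schema
#'
#' Pure arithmetic: per component, chromophores =
#' `copies * (protomers_per_copy * (chromophores_per_alpha +
#' chromophores_per_beta) + extra_chromophores)`; protomers and polypeptides
#' scale with `copies`. Tallies are exact integers, order-independent in the
#' components, and linear in copy numbers.
#'
#' @param schema An [assembly_schema()] (or a data frame coercible to one).
#' @return A `census_result`: list with `components` (per-component tallies),
#'   `protomers_by_compartment`, `chromophores_by_compartment`,
#'   `chromophore_total`, `protomer_total`, `polypeptide_total`.
#' @export
census <- function(schema) {
  if (!inherits(schema, "assembly_schema")) schema <- assembly_schema(schema)
  comp <- schema |>
    dplyr::mutate(
      protomers = .data$copies * .data$protomers_per_copy,
      chromophores = .data$copies *
        (.data$protomers_per_copy *
           (.data$chromophores_per_alpha + .data$chromophores_per_beta) +
           .data$extra_chromophores),
      polypeptides = .data$copies * .data$polypeptides_per_copy) |>
    dplyr::select("name", "compartment", "copies", "protomers",
                  "chromophores", "polypeptides")
  by_comp <- function(col) {
    comp |>
      dplyr::group_by(.data$compartment) |>
      dplyr::summarise(n = sum(.data[[col]]), .groups = "drop") |>
      dplyr::arrange(.data$compartment)
  }
  structure(
    list(
      components = as_tibble(comp),
      protomers_by_compartment = by_comp("protomers"),
      chromophores_by_compartment = by_comp("chromophores"),
      chromophore_total = sum(comp$chromophores),
      protomer_total = sum(comp$protomers),
      polypeptide_total = sum(comp$polypeptides)),
    class = "census_result")
}

compartment_count <- function(result, table, compartment) {
  tab <- result[[table]]
  i <- match(compartment, tab$compartment)
  if (is.na(i)) 0L else tab$n[i]
}

#' @export
print.census_result <- function(x, ...) {
  cat("<census_result>\n")
  cat("  chromophores: ", x$chromophore_total, " total (",
      compartment_count(x, "chromophores_by_compartment", "core"), " core, ",
      compartment_count(x, "chromophores_by_compartment", "periphery"),
      " periphery)\n", sep = "")
  cat("  protomers:    ", x$protomer_total, " (",
      compartment_count(x, "protomers_by_compartment", "core"), " core, ",
      compartment_count(x, "protomers_by_compartment", "periphery"),
      " periphery)\n", sep = "")
  cat("  polypeptides: ", x$polypeptide_total, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.census_result <- function(x, ...) x$components

#' @export
glance.census_result <- function(x, ...) {
  tibble(
    chromophore_total = x$chromophore_total,
    chromophores_core = compartment_count(x, "chromophores_by_compartment",
                                          "core"),
    chromophores_periphery = compartment_count(
      x, "chromophores_by_compartment", "periphery"),
    protomer_total = x$protomer_total,
    protomers_core = compartment_count(x, "protomers_by_compartment", "core"),
    protomers_periphery = compartment_count(x, "protomers_by_compartment",
                                            "periphery"),
    polypeptide_total = x$polypeptide_total)
}

#' Write a census report as JSON
#' @param result A `census_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_census_report <- function(result, path) {
  stopifnot(inherits(result, "census_result"))
  jsonlite::write_json(
    list(
      components = result$components,
      protomers_by_compartment = result$protomers_by_compartment,
      chromophores_by_compartment = result$chromophores_by_compartment,
      totals = list(chromophores = result$chromophore_total,
                    protomers = result$protomer_total,
                    polypeptides = result$polypeptide_total)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Cross-check a schema against coordinate models
#'
#' Compares the schema's per-compartment chromophore counts with the
#' chromophores actually present in one or more labeled coordinate models.
#' Disagreement is a report, not an error: deposited models legitimately omit
#' components that are too dynamic to build (e.g. the distal chain hexamers
#' of a paddle-shaped phycobilisome).
#'
#' @param schema An [assembly_schema()].
#' @param models A `pbs_model` or list of them, labeled via
#'   [apply_label_map()].
#' @param group_compartments Optional tibble (`group_label`, `compartment`)
#'   assigning each model group label to a schema compartment. By default a
#'   group label is matched to the schema component of the same `name` (and
#'   inherits its compartment).
#' @return A tibble: `compartment`, `schema_count`, `model_count`,
#'   `difference` (model minus schema), plus an `unassigned` attribute with
#'   the number of chromophores whose labels matched no compartment.
#' @export
validate_against_model <- function(schema, models, group_compartments = NULL) {
  if (!inherits(schema, "assembly_schema")) schema <- assembly_schema(schema)
  if (inherits(models, "pbs_model")) models <- list(models)
  sites <- dplyr::bind_rows(purrr::map(models, chromophores))
  map <- group_compartments %||%
    tibble(group_label = schema$name, compartment = schema$compartment)
  sites$compartment <- map$compartment[match(sites$group_label,
                                             map$group_label)]
  unassigned <- sum(is.na(sites$compartment))
  found <- sites |>
    dplyr::filter(!is.na(.data$compartment)) |>
    dplyr::count(.data$compartment, name = "model_count")
  want <- census(schema)$chromophores_by_compartment |>
    dplyr::rename(schema_count = "n")
  out <- dplyr::full_join(want, found, by = "compartment") |>
    dplyr::mutate(
      schema_count = dplyr::coalesce(.data$schema_count, 0L),
      model_count = dplyr::coalesce(.data$model_count, 0L),
      difference = .data$model_count - .data$schema_count) |>
    dplyr::arrange(.data$compartment)
  attr(out, "unassigned") <- unassigned
  out
}
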