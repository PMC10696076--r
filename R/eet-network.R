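#' Build the chromophore excitation-energy-transfer graph
#'
#' Nodes are chromophore sites; an undirected edge joins every pair of sites
#' whose anchor-anchor distance is at or below `cutoff`. Edges may be
#' weighted by plain distance (the shortest-bilin-distance rule used to
#' deduce EET pathways) or by the Forster-style geometric coupling
#' kappa^2 / D^6 (inverted so that stronger coupling means lower path cost).
#'
#' @param model A `pbs_model` (or chromophore tibble) with at least 2 sites.
#' @param cutoff Edge distance cutoff in Angstrom. The default 45 sits
#'   comfortably above the longest functional inter-hexamer bilin step
#'   reported in paddle-shaped phycobilisomes (37 Angstrom) while pruning the
#'   quadratic pair set.
#' @param weighting `"distance"` (edge cost = distance) or `"forster"`
#'   (edge cost = 1 / (kappa^2 / D^6), kappa^2 from site dipoles when both
#'   ends carry them, else the isotropic 2/3).
#' @return An `eet_graph`: list with `nodes` (site tibble), `edges`
#'   (`site_a`, `site_b`, `distance`, `kappa_sq`, `weight`), `cutoff`,
#'   `weighting`. If no pair falls under the cutoff a
#'   `pbsnet_disconnected` warning is raised and the edge table is empty.
#' @export
build_graph <- function(model, cutoff = 45,
                        weighting = c("distance", "forster")) {
  weighting <- match.arg(weighting)
  if (cutoff <= 0) abort("cutoff must be positive")
  sites <- if (inherits(model, "pbs_model")) chromophores(model) else as_tibble(model)
  if (nrow(sites) < 2L) abort("graph construction needs at least 2 chromophores")
  edges <- pairwise_distances(sites, cutoff = cutoff)
  if (nrow(edges) == 0L) {
    warn(paste0("no chromophore pairs within cutoff ", cutoff,
                " Angstrom; graph is fully disconnected"),
         class = "pbsnet_disconnected")
    edges$kappa_sq <- double()
    edges$weight <- double()
    return(new_eet_graph(sites, edges, cutoff, weighting))
  }
  if (weighting == "forster") {
    ia <- match(edges$site_a, sites$site_id)
    ib <- match(edges$site_b, sites$site_id)
    both <- !is.na(sites$dx[ia]) & !is.na(sites$dx[ib])
    ksq <- rep(2 / 3, nrow(edges))
    if (any(both)) {
      orr <- orientation_factor(
        as.matrix(sites[ia[both], c("x", "y", "z")]),
        as.matrix(sites[ia[both], c("dx", "dy", "dz")]),
        as.matrix(sites[ib[both], c("x", "y", "z")]),
        as.matrix(sites[ib[both], c("dx", "dy", "dz")]))
      ksq[both] <- orr$kappa_sq
    }
    edges$kappa_sq <- ksq
    coupling <- forster_edge_weight(edges$distance, pmax(ksq, 1e-12))
    edges$weight <- 1 / coupling
  } else {
    edges$kappa_sq <- NA_real_
    edges$weight <- edges$distance
  }
  new_eet_graph(sites, edges, cutoff, weighting)
}

new_eet_graph <- function(nodes, edges, cutoff, weighting) {
  structure(list(nodes = nodes, edges = edges, cutoff = cutoff,
                 weighting = weighting),
            class = "eet_graph")
}

#' Convert an EET graph to igraph
#' @param graph An `eet_graph`.
#' @return An undirected [igraph::graph] with `distance` and `weight` edge
#'   attributes.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "eet_graph"))
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("site_a", "site_b", "distance", "weight")],
    directed = FALSE,
    vertices = data.frame(name = graph$nodes$site_id))
  g
}

#' @export
print.eet_graph <- function(x, ...) {
  cat("<eet_graph> ", nrow(x$nodes), " chromophores, ", nrow(x$edges),
      " edges (cutoff ", x$cutoff, " A, ", x$weighting, "-weighted)\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.eet_graph <- function(x, ...) x$edges

#' @export
glance.eet_graph <- function(x, ...) {
  g <- as_igraph(x)
  tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    cutoff = x$cutoff,
    weighting = x$weighting,
    n_components = igraph::count_components(g),
    min_distance = if (nrow(x$edges)) min(x$edges$distance) else NA_real_,
    max_distance = if (nrow(x$edges)) max(x$edges$distance) else NA_real_)
}

#' Deduce EET pathways from source chromophores to terminal emitters
#'
#' For each source site, finds the optimal route through the chromophore
#' graph to any of the designated terminal-emitter sites. Terminal emitters
#' are always user-designated (e.g. the ApcE-bound bilins): in organisms
#' lacking the specialised ApcD/ApcF subunits they cannot be inferred from
#' sequence.
#'
#' Two objectives expose the ambiguity in "shortest distances among bilin
#' pairs": `min_total` minimises the summed step distance (standard
#' shortest-path search on the chosen edge weights); `min_max_step` minimises
#' the longest single hop (bottleneck search; among routes attaining the
#' optimal bottleneck the summed-distance-shortest one is reported).
#'
#' @param graph An `eet_graph`.
#' @param sources,terminals Character vectors of site ids present in the
#'   graph (see [sites_in_group()]).
#' @param objective `"min_total"` or `"min_max_step"`.
#' @return A tibble with one row per source: `source`, `terminal`,
#'   `reached`, `n_steps`, `total_length`, `max_step`, `objective` and a
#'   list-column `path` of ordered site ids (with per-step distances in the
#'   list-column `steps`). An unreachable source yields `reached = FALSE`
#'   with `NA` metrics, not an error.
#' @export
shortest_pathways <- function(graph, sources, terminals,
                              objective = c("min_total", "min_max_step")) {
  objective <- match.arg(objective)
  stopifnot(inherits(graph, "eet_graph"))
  if (length(sources) == 0L || length(terminals) == 0L) {
    abort("sources and terminals must be non-empty")
  }
  known <- graph$nodes$site_id
  bad <- setdiff(c(sources, terminals), known)
  if (length(bad)) {
    abort(paste0("site(s) not in graph: ", paste(bad, collapse = ", ")))
  }
  sources <- sort(unique(sources))
  terminals <- sort(unique(terminals))
  g <- as_igraph(graph)
  rows <- purrr::map(sources, function(src) {
    if (objective == "min_total") {
      path_min_total(graph, g, src, terminals)
    } else {
      path_min_max_step(graph, g, src, terminals)
    }
  })
  out <- dplyr::bind_rows(rows)
  out$objective <- objective
  out
}

path_min_total <- function(graph, g, src, terminals) {
  d <- igraph::distances(g, v = src, to = terminals, weights = NULL,
                         algorithm = "dijkstra")[1L, ]
  if (all(!is.finite(d))) return(no_path_row(src))
  # deterministic tie-break: smallest distance (rounded), then terminal id
  ord <- order(round(d, 6), terminals)
  best <- terminals[ord[1L]]
  vp <- igraph::shortest_paths(g, from = src, to = best,
                               weights = NULL, output = "vpath")$vpath[[1L]]
  describe_path(graph, names(vp), src, best)
}

path_min_max_step <- function(graph, g, src, terminals) {
  edges <- graph$edges
  if (nrow(edges) == 0L) return(no_path_row(src))
  thresholds <- sort(unique(round(edges$distance, 9)))
  reachable_under <- function(d) {
    keep <- which(round(edges$distance, 9) <= d)
    if (length(keep) == 0L) return(FALSE)
    sg <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
    any(is.finite(igraph::distances(sg, v = src, to = terminals)[1L, ]))
  }
  if (!reachable_under(thresholds[length(thresholds)])) return(no_path_row(src))
  lo <- 1L; hi <- length(thresholds)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (reachable_under(thresholds[mid])) hi <- mid else lo <- mid + 1L
  }
  keep <- which(round(edges$distance, 9) <= thresholds[lo])
  sg <- igraph::subgraph_from_edges(g, keep, delete.vertices = FALSE)
  d <- igraph::distances(sg, v = src, to = terminals)[1L, ]
  ord <- order(round(d, 6), terminals)
  best <- terminals[ord[1L]]
  vp <- igraph::shortest_paths(sg, from = src, to = best,
                               output = "vpath")$vpath[[1L]]
  describe_path(graph, names(vp), src, best)
}

no_path_row <- function(src) {
  tibble(source = src, terminal = NA_character_, reached = FALSE,
         n_steps = NA_integer_, total_length = NA_real_, max_step = NA_real_,
         path = list(character()), steps = list(double()))
}

describe_path <- function(graph, ids, src, terminal) {
  if (length(ids) < 2L) {
    # source is itself a terminal
    return(tibble(source = src, terminal = terminal, reached = TRUE,
                  n_steps = 0L, total_length = 0, max_step = 0,
                  path = list(ids), steps = list(double())))
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  lut <- setNames(graph$edges$distance,
                  key(graph$edges$site_a, graph$edges$site_b))
  steps <- lut[key(ids[-length(ids)], ids[-1L])]
  tibble(source = src, terminal = terminal, reached = TRUE,
         n_steps = length(steps),
         total_length = sum(steps), max_step = max(steps),
         path = list(ids), steps = list(unname(steps)))
}

#' Minimal inter-group bilin distance
#'
#' The minimum anchor-anchor distance over all chromophore pairs crossing two
#' labeled groups, with the attaining pair. This is the quantity printed on
#' EET-pathway figures as the bilin step between a peripheral hexamer and the
#' core. Ties are broken lexicographically on (distance rounded to 1e-6,
#' site-id pair).
#'
#' @param model A labeled `pbs_model`.
#' @param group_a,group_b Group labels; their site sets must not overlap.
#' @return One-row tibble: `group_a`, `group_b`, `site_a`, `site_b`,
#'   `distance`.
#' @export
inter_group_min_distance <- function(model, group_a, group_b) {
  ids_a <- sites_in_group(model, group_a)
  ids_b <- sites_in_group(model, group_b)
  if (length(intersect(ids_a, ids_b))) {
    abort(paste0("groups '", group_a, "' and '", group_b,
                 "' share chromophores; cross-group distance is undefined"))
  }
  sites <- chromophores(model)
  sa <- sites[match(ids_a, sites$site_id), ]
  sb <- sites[match(ids_b, sites$site_id), ]
  cross <- tidyr::crossing(i = seq_len(nrow(sa)), j = seq_len(nrow(sb)))
  dx <- sa$x[cross$i] - sb$x[cross$j]
  dy <- sa$y[cross$i] - sb$y[cross$j]
  dz <- sa$z[cross$i] - sb$z[cross$j]
  if (any(is.na(dx) | is.na(dy) | is.na(dz))) {
    abort("group members without anchor coordinates")
  }
  d <- sqrt(dx^2 + dy^2 + dz^2)
  ord <- order(round(d, 6), sa$site_id[cross$i], sb$site_id[cross$j])
  k <- ord[1L]
  tibble(group_a = group_a, group_b = group_b,
         site_a = sa$site_id[cross$i[k]], site_b = sb$site_id[cross$j[k]],
         distance = d[k])
}

#' Compare hexamer packing between two assemblies
#'
#' For each inter-hexamer junction (a pair of group labels) in each model,
#' reports the minimal inter-group bilin distance, the number of cross-group
#' contacts under the cutoff, and kappa^2 for the minimal pair when both
#' sites carry dipole vectors. A junction with exactly one sub-cutoff contact
#' is flagged `"single-pathway"` (the laterally staggered chain packing); two
#' or more contacts flag `"network"` (the coaxially stacked rod packing).
#'
#' @param model_a,model_b Labeled `pbs_model`s.
#' @param junctions_a,junctions_b Junctions per model: a list of 2-element
#'   character vectors (group-label pairs); `junctions_b` defaults to
#'   `junctions_a`.
#' @param cutoff Contact cutoff in Angstrom (default 45).
#' @param model_names Length-2 character vector naming the models in the
#'   report.
#' @return A `packing_report` tibble: `model`, `junction`, `group_a`,
#'   `group_b`, `site_a`, `site_b`, `min_distance`, `n_contacts`,
#'   `kappa_sq`, `classification`.
#' @export
compare_packings <- function(model_a, model_b, junctions_a,
                             junctions_b = junctions_a, cutoff = 45,
                             model_names = c("model_a", "model_b")) {
  stopifnot(length(model_names) == 2L)
  report_one <- function(model, junctions, name) {
    purrr::map(junctions, function(jn) {
      if (length(jn) != 2L) abort("each junction must be a pair of group labels")
      labs <- chromophores(model)$group_label
      for (lab in jn) {
        if (!any(!is.na(labs) & labs == lab)) {
          abort(paste0("junction label '", lab, "' not present in ", name))
        }
      }
      mind <- inter_group_min_distance(model, jn[1L], jn[2L])
      n_contacts <- count_cross_contacts(model, jn[1L], jn[2L], cutoff)
      ksq <- junction_kappa_sq(model, mind)
      tibble(
        model = name,
        junction = paste(jn[1L], jn[2L], sep = "-"),
        group_a = jn[1L], group_b = jn[2L],
        site_a = mind$site_a, site_b = mind$site_b,
        min_distance = mind$distance,
        n_contacts = n_contacts,
        kappa_sq = ksq,
        classification = if (n_contacts >= 2L) "network"
                         else if (n_contacts == 1L) "single-pathway"
                         else "disconnected")
    }) |> dplyr::bind_rows()
  }
  out <- dplyr::bind_rows(
    report_one(model_a, junctions_a, model_names[1L]),
    report_one(model_b, junctions_b, model_names[2L]))
  class(out) <- c("packing_report", class(out))
  out
}

count_cross_contacts <- function(model, group_a, group_b, cutoff) {
  sites <- chromophores(model)
  ids_a <- sites_in_group(model, group_a)
  ids_b <- sites_in_group(model, group_b)
  sa <- as.matrix(sites[match(ids_a, sites$site_id), c("x", "y", "z")])
  sb <- as.matrix(sites[match(ids_b, sites$site_id), c("x", "y", "z")])
  d2 <- outer(rowSums(sa^2), rep(1, nrow(sb))) +
    outer(rep(1, nrow(sa)), rowSums(sb^2)) - 2 * sa %*% t(sb)
  sum(sqrt(pmax(d2, 0)) <= cutoff)
}

junction_kappa_sq <- function(model, mind) {
  sites <- chromophores(model)
  a <- sites[sites$site_id == mind$site_a, ]
  b <- sites[sites$site_id == mind$site_b, ]
  if (is.na(a$dx) || is.na(b$dx)) return(NA_real_)
  orientation_factor(c(a$x, a$y, a$z), c(a$dx, a$dy, a$dz),
                     c(b$x, b$y, b$z), c(b$dx, b$dy, b$dz))$kappa_sq
}

#' @export
glance.packing_report <- function(x, ...) {
  x |>
    dplyr::group_by(.data$model) |>
    dplyr::summarise(
      n_junctions = dplyr::n(),
      min_distance = min(.data$min_distance),
      mean_contacts = mean(.data$n_contacts),
      all_single_pathway = all(.data$classification == "single-pathway"),
      any_network = any(.data$classification == "network"),
      .groups = "drop")
}

#' Write the edge table of an EET graph as TSV
#' @param graph An `eet_graph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(graph, path) {
  stopifnot(inherits(graph, "eet_graph"))
  write.table(graph$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an EET graph in GraphML or DOT format
#' @param graph An `eet_graph`.
#' @param path Output path.
#' @param format `"graphml"` or `"dot"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(as_igraph(graph), path, format = format)
  invisible(path)
}
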