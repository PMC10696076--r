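collinear_sites <- function(zs) {
  tibble::tibble(site_id = sprintf("S%d", seq_along(zs)),
                 x = 0, y = 0, z = zs)
}

test_that("graph construction keeps exactly the sub-cutoff pairs", {
  g <- build_graph(collinear_sites(c(0, 20, 40)), cutoff = 25)
  expect_equal(nrow(g$edges), 2L)
  expect_setequal(paste(g$edges$site_a, g$edges$site_b),
                  c("S1 S2", "S2 S3"))
  # cutoff at or above the largest pair distance: complete graph
  full <- build_graph(collinear_sites(c(0, 20, 40)), cutoff = 40)
  expect_equal(nrow(full$edges), 3L)
  n <- 9
  sites <- random_site_cloud(n, box = 30)
  expect_equal(nrow(build_graph(sites, cutoff = 1000)$edges),
               n * (n - 1) / 2)
  expect_error(build_graph(sites, cutoff = -1), "positive")
  expect_error(build_graph(sites[1, ], cutoff = 10), "at least 2")
})

test_that("no pairs under the cutoff signals a disconnected graph", {
  expect_warning(g <- build_graph(collinear_sites(c(0, 100)), cutoff = 10),
                 class = "pbsnet_disconnected")
  expect_equal(nrow(g$edges), 0L)
})

test_that("graph edges equal the brute-force O(n^2) pair scan", {
  set.seed(11)
  asm <- make_assembly(synthetic_params(n_hexamers = 3, packing = "rod"))
  sites <- chromophores(asm$model)
  g <- build_graph(sites, cutoff = 45)
  oracle <- brute_force_edges(sites, 45)
  got <- as.data.frame(g$edges[order(g$edges$site_a, g$edges$site_b),
                               c("site_a", "site_b", "distance")])
  expect_equal(got, oracle, ignore_attr = TRUE)

  cloud <- random_site_cloud(80, box = 100)
  g2 <- build_graph(cloud, cutoff = 35)
  o2 <- brute_force_edges(cloud, 35)
  expect_equal(nrow(g2$edges), nrow(o2))
  expect_equal(sort(g2$edges$distance), sort(o2$distance))
})

test_that("a single source-terminal edge is a one-step path", {
  g <- build_graph(collinear_sites(c(0, 25.1)), cutoff = 30)
  p <- shortest_pathways(g, "S1", "S2")
  expect_true(p$reached)
  expect_equal(p$n_steps, 1L)
  expect_equal(p$total_length, 25.1)
  expect_equal(p$max_step, 25.1)
  expect_equal(p$path[[1]], c("S1", "S2"))
})

test_that("objectives split on the diamond: direct 15 vs two 10s", {
  sites <- tibble::tibble(
    site_id = c("S", "A", "T"),
    x = c(0, 7.5, 15), y = c(0, sqrt(100 - 56.25), 0), z = 0)
  g <- build_graph(sites, cutoff = 16)
  total <- shortest_pathways(g, "S", "T", objective = "min_total")
  expect_equal(total$total_length, 15)
  expect_equal(total$n_steps, 1L)
  bottleneck <- shortest_pathways(g, "S", "T", objective = "min_max_step")
  expect_equal(bottleneck$max_step, 10)
  expect_equal(bottleneck$n_steps, 2L)
  # the enumeration oracle agrees with both optima
  enum <- enumerate_paths(g$edges, "S", "T")
  expect_equal(min(enum$total), total$total_length)
  expect_equal(min(enum$maxstep), bottleneck$max_step)
})

test_that("a disconnected source yields a no-path record, not an error", {
  sites <- tibble::tibble(site_id = c("S1", "S2", "S3"),
                          x = c(0, 5, 500), y = 0, z = 0)
  g <- build_graph(sites, cutoff = 10)
  p <- shortest_pathways(g, "S3", "S1")
  expect_false(p$reached)
  expect_true(is.na(p$total_length))
  expect_error(shortest_pathways(g, character(), "S1"), "non-empty")
  expect_error(shortest_pathways(g, "S9", "S1"), "S9")
})

test_that("chain fixtures route hexamer by hexamer with 4 junction steps", {
  asm <- make_assembly(synthetic_params(n_hexamers = 5, packing = "chain"))
  paths <- write_fixture(asm, withr::local_tempdir())
  model <- apply_label_map(read_structure(paths$structure), paths$label_map)
  g <- build_graph(model, cutoff = 45)
  p <- shortest_pathways(g, sites_in_group(model, "H1")[1],
                         sites_in_group(model, "H5"))
  expect_true(p$reached)
  route_chains <- chromophores(model)$group_label[
    match(p$path[[1]], chromophores(model)$site_id)]
  expect_equal(rle(route_chains)$values, paste0("H", 1:5))
  expect_equal(sum(route_chains[-1] != route_chains[-length(route_chains)]),
               4L)
  expect_equal(p$total_length, sum(p$steps[[1]]))
})

test_that("both objectives match exhaustive enumeration on random graphs", {
  set.seed(123)
  for (i in 1:120) {
    n <- sample(2:8, 1)
    sites <- random_site_cloud(n, box = 40)
    cutoff <- stats::runif(1, 20, 55)
    g <- suppressWarnings(build_graph(sites, cutoff = cutoff))
    src <- sites$site_id[1]
    dst <- sites$site_id[n]
    enum <- if (nrow(g$edges)) enumerate_paths(g$edges, src, dst) else NULL
    total <- shortest_pathways(g, src, dst, objective = "min_total")
    bottleneck <- shortest_pathways(g, src, dst, objective = "min_max_step")
    if (is.null(enum)) {
      expect_false(total$reached)
      expect_false(bottleneck$reached)
    } else {
      expect_equal(total$total_length, min(enum$total), tolerance = 1e-9)
      expect_equal(bottleneck$max_step, min(enum$maxstep), tolerance = 1e-9)
      # bottleneck of min_max_step never exceeds min_total's largest step
      expect_lte(bottleneck$max_step, total$max_step + 1e-9)
    }
  }
})

test_that("inter-group minimal distance is symmetric and guards overlap", {
  asm <- make_assembly(synthetic_params(n_hexamers = 2, packing = "chain"))
  model <- asm$model
  ab <- inter_group_min_distance(model, "H1", "H2")
  ba <- inter_group_min_distance(model, "H2", "H1")
  expect_equal(ab$distance, ba$distance)
  expect_setequal(c(ab$site_a, ab$site_b), c(ba$site_a, ba$site_b))
  expect_equal(ab$distance, asm$ground_truth$junctions$min_distance)
  expect_error(inter_group_min_distance(model, "H1", "H1"), "share")
  expect_error(inter_group_min_distance(model, "H1", "H9"), "H9")
})

test_that("packing comparison separates chain from rod junctions", {
  chain <- make_assembly(synthetic_params(n_hexamers = 3, packing = "chain"))
  rod <- make_assembly(synthetic_params(n_hexamers = 3, packing = "rod"))
  junctions <- list(c("H1", "H2"), c("H2", "H3"))
  rep <- compare_packings(chain$model, rod$model, junctions,
                          model_names = c("chain", "rod"))
  chain_rows <- rep[rep$model == "chain", ]
  rod_rows <- rep[rep$model == "rod", ]
  expect_true(all(chain_rows$classification == "single-pathway"))
  expect_true(all(chain_rows$n_contacts == 1L))
  expect_true(all(rod_rows$classification == "network"))
  expect_true(all(rod_rows$n_contacts >= 2L))
  expect_equal(chain_rows$min_distance,
               chain$ground_truth$junctions$min_distance)
  # identical models give identical reports
  twin <- compare_packings(chain$model, chain$model, junctions)
  expect_equal(twin[twin$model == "model_a", -1],
               twin[twin$model == "model_b", -1])
  expect_error(compare_packings(chain$model, rod$model,
                                list(c("H1", "H9"))), "H9")
  sm <- glance(rep)
  expect_true(sm$all_single_pathway[sm$model == "chain"])
  expect_true(sm$any_network[sm$model == "rod"])
})

test_that("graphs export to TSV, GraphML and DOT", {
  g <- build_graph(collinear_sites(c(0, 10, 20)), cutoff = 15)
  dir <- withr::local_tempdir()
  write_edge_table(g, file.path(dir, "edges.tsv"))
  export_graph(g, file.path(dir, "g.graphml"), "graphml")
  export_graph(g, file.path(dir, "g.dot"), "dot")
  expect_equal(nrow(utils::read.delim(file.path(dir, "edges.tsv"))), 2L)
  expect_true(any(grepl("graphml",
                        readLines(file.path(dir, "g.graphml"), n = 5))))
  expect_gt(file.size(file.path(dir, "g.dot")), 0)
  gl <- glance(g)
  expect_equal(gl$n_edges, 2L)
  expect_equal(gl$n_components, 1)
  expect_equal(tidy(g), g$edges)
})
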