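test_that("anchor coordinates read back identically from a handcrafted PDB", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_handmade_pdb(tmp, rbind(
    hand_atoms("C05", 0.5, 1.5, 2.5),
    hand_atoms("C10", 1.0, 2.0, 3.0),
    hand_atoms("C15", 1.5, 2.5, 3.5)))
  model <- read_structure(tmp)
  sites <- chromophores(model)
  expect_equal(nrow(sites), 1L)
  expect_equal(c(sites$x, sites$y, sites$z), c(1, 2, 3))
  expect_equal(sites$ligand_code, "CYC")
  expect_equal(sites$chain_id, "X")
})

test_that("synthetic fixtures round-trip with the expected site count", {
  asm <- make_assembly(synthetic_params(n_hexamers = 2, packing = "rod"))
  for (fmt in c("pdb", "mmcif")) {
    paths <- write_fixture(asm, withr::local_tempdir(), format = fmt)
    model <- read_structure(paths$structure)
    sites <- chromophores(model)
    expect_equal(nrow(sites), 2L * 6L * 3L)
    truth <- chromophores(asm$model)
    idx <- match(truth$site_id, sites$site_id)
    expect_false(anyNA(idx))
    expect_lt(max(abs(sites$x[idx] - truth$x)), 1e-3)
    expect_lt(max(abs(sites$y[idx] - truth$y)), 1e-3)
    expect_lt(max(abs(sites$z[idx] - truth$z)), 1e-3)
  }
})

test_that("site count equals an independent ligand-instance line scan", {
  paths <- write_fixture(
    make_assembly(synthetic_params(n_hexamers = 3, packing = "chain")),
    withr::local_tempdir())
  lines <- readLines(paths$structure)
  het <- lines[startsWith(lines, "HETATM") &
                 substr(lines, 18, 20) == "CYC"]
  instances <- unique(paste(substr(het, 22, 22), substr(het, 23, 26)))
  model <- read_structure(paths$structure)
  expect_equal(nrow(chromophores(model)), length(instances))
})

test_that("alt-locs collapse to highest occupancy, ties alphabetical", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_handmade_pdb(tmp, rbind(
    hand_atoms("C10", 0, 0, 0, occ = 0.4, alt = "A"),
    hand_atoms("C10", 9, 9, 9, occ = 0.6, alt = "B")))
  sites <- chromophores(read_structure(tmp))
  expect_equal(c(sites$x, sites$y, sites$z), c(9, 9, 9))

  tmp2 <- withr::local_tempfile(fileext = ".pdb")
  write_handmade_pdb(tmp2, rbind(
    hand_atoms("C10", 5, 5, 5, occ = 0.5, alt = "B"),
    hand_atoms("C10", 1, 1, 1, occ = 0.5, alt = "A")))
  sites2 <- chromophores(read_structure(tmp2))
  expect_equal(c(sites2$x, sites2$y, sites2$z), c(1, 1, 1))
})

test_that("a ligand missing its anchor atom is reported, not dropped", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_handmade_pdb(tmp, rbind(
    hand_atoms("C05", 0, 0, 0),
    hand_atoms("C15", 1, 0, 0)))
  model <- read_structure(tmp)
  sites <- chromophores(model)
  expect_equal(nrow(sites), 1L)
  expect_true(is.na(sites$x))
  expect_equal(model$warnings$site_id, sites$site_id)
  expect_match(model$warnings$message, "anchor")
  expect_error(pair_distance(sites[1, ], c(0, 0, 0)), "anchor")
})

test_that("zero matching ligands yields an explicit empty-result signal", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_handmade_pdb(tmp, hand_atoms("C10", 0, 0, 0, resname = "HEM"))
  expect_warning(model <- read_structure(tmp), class = "pbsnet_empty_model")
  expect_equal(nrow(chromophores(model)), 0L)
})

test_that("hydrogens are ignored for site extraction", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_handmade_pdb(tmp, rbind(
    hand_atoms("C10", 1, 1, 1),
    hand_atoms("H10", 2, 2, 2, element = "H")))
  model <- read_structure(tmp)
  expect_equal(nrow(model$atoms), 1L)
})

test_that("multi-model files use the first block and attach a warning", {
  tmp <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL     1",
    "HETATM    1  C10 CYC A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL     2",
    "HETATM    2  C10 CYC A   1       9.000   9.000   9.000  1.00  0.00           C",
    "ENDMDL", "END"), tmp)
  model <- read_structure(tmp)
  expect_true(any(grepl("model blocks", model$warnings$message)))
  sites <- chromophores(model)
  expect_equal(nrow(sites), 1L)
  expect_equal(c(sites$x, sites$y, sites$z), c(1, 2, 3))
})

test_that("unreadable input raises a parse error naming the file", {
  bad <- withr::local_tempfile(fileext = ".cif")
  writeLines("not a coordinate file", bad)
  expect_error(read_structure(bad), "atom_site")
  expect_error(read_structure("/nonexistent/file.pdb"), "not found")
})

test_that("label maps attach groups without changing coordinates or counts", {
  asm <- make_assembly(synthetic_params(n_hexamers = 2, packing = "chain"))
  paths <- write_fixture(asm, withr::local_tempdir())
  model <- read_structure(paths$structure)
  before <- chromophores(model)
  labeled <- apply_label_map(model, paths$label_map)
  after <- chromophores(labeled)
  expect_equal(after[, c("site_id", "x", "y", "z")],
               before[, c("site_id", "x", "y", "z")])
  expect_equal(unname(table(after$group_label)[c("H1", "H2")]),
               c(18L, 18L), ignore_attr = TRUE)
})

test_that("label map edge cases behave per contract", {
  asm <- make_assembly(synthetic_params(n_hexamers = 1))
  paths <- write_fixture(asm, withr::local_tempdir())
  model <- read_structure(paths$structure)

  # single-chain map labels the only chain
  one <- apply_label_map(model, data.frame(group_label = "Rb'I",
                                           chain_id = "A"))
  expect_true(all(chromophores(one)$group_label == "Rb'I"))

  # empty mapping file returns the model unchanged
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("group_label\tchain_id", empty)
  expect_equal(chromophores(apply_label_map(model, empty)),
               chromophores(model))

  # absent chain errors, naming the offender
  expect_error(
    apply_label_map(model, data.frame(group_label = "Rt1", chain_id = "Z")),
    "Z")
  # duplicate rows rejected
  expect_error(
    apply_label_map(model, data.frame(group_label = c("A1", "A1"),
                                      chain_id = c("A", "A"))),
    "duplicate")
})

test_that("ligand configuration round-trips through a key-value file", {
  cfgfile <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# bilin extraction settings",
               "codes = CYC, PCB",
               "anchor_atom = CHC",
               "ring_atoms = C05, C10, C15",
               "reference_atom = C15"), cfgfile)
  cfg <- read_ligand_config(cfgfile)
  expect_equal(cfg$codes, c("CYC", "PCB"))
  expect_equal(cfg$anchor_atom, "CHC")
  expect_equal(cfg$ring_atoms, c("C05", "C10", "C15"))
  expect_error(read_ligand_config(withr::local_tempfile()), "not found")
})

test_that("model accessors and broom methods summarise the model", {
  asm <- make_assembly(synthetic_params(n_hexamers = 2))
  paths <- write_fixture(asm, withr::local_tempdir())
  model <- apply_label_map(read_structure(paths$structure), paths$label_map)
  expect_equal(tidy(model), chromophores(model))
  g <- glance(model)
  expect_equal(g$n_chromophores, 36L)
  expect_equal(g$n_labeled, 36L)
  expect_length(sites_in_group(model, "H1"), 18L)
  expect_error(sites_in_group(model, "H9"), "H9")
  out <- withr::local_tempfile(fileext = ".tsv")
  write_chromophore_table(model, out)
  expect_equal(nrow(utils::read.delim(out)), 36L)
})
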