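fixture_pdb <- function(path) {
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA AGLY A   2       2.000   0.000   0.000  0.40  0.00           C",
    "ATOM      4  CA BGLY A   2       2.500   0.000   0.000  0.60  0.00           C",
    "ATOM      5  HA  GLY A   2       2.100   1.000   0.000  1.00  0.00           H",
    "ATOM      6  CA  SER A   3       3.000   0.000   0.000  1.00  0.00           C",
    "HETATM    7  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O",
    "ATOM      8  CA  LEU A   7       9.000   0.000   0.000  1.00  0.00           C",
    "ATOM      9  CA  VAL A   8      10.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   ALA A   1      90.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      91.000   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   2      92.000   0.000   0.000  1.00  0.00           C",
    "ATOM      4  CA  SER A   3      93.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "END"), path)
  path
}

test_that("PDB parsing uses model 1, top-occupancy alt-locs, keeps H, drops water, splits breaks", {
  path <- fixture_pdb(withr::local_tempfile(fileext = ".pdb"))
  s <- load_structure(path)
  expect_s3_class(s, "fr_structure")
  # residues 1-3 and 7-8 are split at the numbering gap into two chains
  expect_length(s$chains, 2L)
  expect_equal(vapply(s$chains, function(ch) ch$N, 0L), c(3L, 2L))
  ch1 <- s$chains[[1L]]
  # model 1 coordinates only
  expect_equal(ch1$ca[1L, ], c(1, 0, 0))
  # alt-loc resolved to the higher-occupancy B copy
  expect_equal(ch1$ca[2L, ], c(2.5, 0, 0))
  # hydrogen retained with element H
  res2 <- chain_residue(ch1, 2L)
  expect_true("H" %in% res2$element)
  # water dropped entirely
  expect_false(any(vapply(s$chains, function(ch) "HOH" %in% ch$aa, TRUE)))
})

test_that("mmCIF parsing yields the same chain as the PDB writer round trip", {
  cif <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 2 C CA . GLY A 1 2 ? 3.800 0.000 0.000 1.00 0.00 ? 2 GLY A CA 1",
    "ATOM 3 C CA . SER A 1 3 ? 3.800 3.800 0.000 1.00 0.00 ? 3 SER A CA 1"),
    cif)
  s <- load_structure(cif)
  expect_length(s$chains, 1L)
  expect_equal(s$chains[[1L]]$aa, c("ALA", "GLY", "SER"))
  expect_equal(s$chains[[1L]]$ca[2L, ], c(3.8, 0, 0))
})

test_that("load_structure rejects missing, garbled and protein-free files", {
  expect_error(load_structure(file.path(tempdir(), "nope.pdb")), "not found")
  bad <- withr::local_tempfile(fileext = ".xyz")
  writeLines("hello", bad)
  expect_error(load_structure(bad), "format")
  water_only <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A   1       0.000   0.000   0.000  1.00  0.00           O",
    "END"), water_only)
  expect_error(load_structure(water_only))
})

test_that("atom_selection picks 1 CA, heavy atoms, and all atoms per level", {
  r <- residue_5atom()
  expect_equal(nrow(atom_selection(r, "CA")), 1L)
  expect_equal(nrow(atom_selection(r, "HV")), 4L)
  expect_equal(nrow(atom_selection(r, "HH")), 5L)
  no_ca <- make_residue(c(0, 0, 0), name = "CB", element = "C")
  expect_error(atom_selection(no_ca, "CA"), "CA")
  h_only <- make_residue(c(0, 0, 0), name = "H1", element = "H")
  expect_error(atom_selection(h_only, "HV"), "heavy")
})

test_that("HV selection is a subset of HH selection for random residues", {
  set.seed(11)
  for (k in 1:20) {
    r <- random_residue(sample(2:8, 1L))
    hv <- atom_selection(r, "HV")
    hh <- atom_selection(r, "HH")
    expect_true(all(apply(hv, 1L, function(row)
      any(colSums(abs(t(hh) - row)) == 0))))
  }
})

test_that("radius of gyration matches the direct formula and is rigid-motion invariant", {
  two <- new_chain(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(radius_of_gyration(two), 1.0)
  same <- new_chain(rbind(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(radius_of_gyration(same), 0.0)

  set.seed(5)
  cloud <- matrix(rnorm(300), ncol = 3L)
  ch <- new_chain(cloud)
  ctr <- colMeans(cloud)
  brute <- sqrt(sum(apply(cloud, 1L, function(r) sum((r - ctr)^2))) / 100)
  expect_equal(radius_of_gyration(ch), brute, tolerance = 1e-12)

  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0, 0, 0, 1), 3L, byrow = TRUE)
  moved <- sweep(cloud %*% rot, 2L, c(10, -4, 2), "+")
  expect_equal(radius_of_gyration(new_chain(moved)),
               radius_of_gyration(ch), tolerance = 1e-9)
})

test_that("HH collection is refused when the ensemble carries no hydrogens", {
  ch <- atomful_chain(N = 6L, with_h = FALSE)
  expect_error(collect_distances(list(ch), m_range = c(2L, 2L), level = "HH"),
               "hydrogen")
  ch_h <- atomful_chain(N = 6L, with_h = TRUE)
  expect_silent(collect_distances(list(ch_h), m_range = c(2L, 2L),
                                  level = "HH"))
})
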