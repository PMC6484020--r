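test_that("PDB coordinates are converted from Angstrom to nm on read", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      10.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       0.000   5.000   0.000  1.00  0.00           C",
    "ATOM      3  N   GLY A   2       1.000   2.000   3.000  1.00  0.00           N",
    "END"
  ), tmp)
  s <- read_structure(tmp)
  expect_equal(nrow(s$atoms), 3)
  expect_equal(s$atoms$atom_name, c("CA", "CB", "N"))  # file order kept
  expect_equal(s$coords[1, ], c(1, 0, 0))
  expect_equal(s$coords[3, ], c(0.1, 0.2, 0.3))
  expect_equal(s$atoms$element, c("C", "C", "N"))
})

test_that("malformed and unsupported PDB records are rejected with context", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      10.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  ALA A   1       xx.000   5.000   0.000  1.00  0.00           C"
  ), tmp)
  expect_error(read_structure(tmp), "line 2")

  writeLines(
    "ATOM      1  CA  ALA     1      10.000   0.000   0.000  1.00  0.00           C",
    tmp)
  expect_error(read_structure(tmp), "chain")

  writeLines(
    "ATOM      1  CA  ALA A   1A     10.000   0.000   0.000  1.00  0.00           C",
    tmp)
  expect_error(read_structure(tmp), "insertion")
})

test_that("structure round trip preserves identity and coordinates to 1e-3 nm", {
  s <- random_structure(n_atoms = 50, seed = 42)
  for (fmt in c("pdb", "xyz")) {
    tmp <- tempfile(fileext = paste0(".", fmt))
    write_structure(s, tmp)
    s2 <- read_structure(tmp)
    expect_equal(nrow(s2$atoms), 50)
    expect_lt(max(abs(s2$coords - s$coords)), 1e-3)
    if (fmt == "pdb") {
      expect_equal(s2$atoms$atom_name, s$atoms$atom_name)
      expect_equal(s2$atoms$residue_number, s$atoms$residue_number)
      expect_equal(s2$atoms$chain_id, s$atoms$chain_id)
    }
  }
})

test_that("multi-model PDB and XYZ-dialect ensembles round trip", {
  ref <- build_reference_complex()
  frames <- lapply(1:3, function(k) ref$coords + 0.01 * k)
  ens <- trajectory_ensemble(
    annotated_structure(ref$atoms, ref$coords, regions = ref$regions),
    frames, times = c(0, 1, 2))

  pdb <- tempfile(fileext = ".pdb")
  write_ensemble(ens, pdb)
  ens_pdb <- read_ensemble(pdb)
  expect_equal(n_frames(ens_pdb), 3)
  expect_lt(max(abs(ens_pdb$frames[[3]] - frames[[3]])), 1e-3)

  xyz <- tempfile(fileext = ".xyz")
  write_ensemble(ens, xyz)
  ens_xyz <- read_ensemble(xyz)
  expect_equal(n_frames(ens_xyz), 3)
  expect_equal(ens_xyz$times, c(0, 1, 2))
  expect_lt(max(abs(ens_xyz$frames[[2]] - frames[[2]])), 1e-5)
})

test_that("XYZ reading tolerates trailing whitespace and blank lines", {
  xyz <- tempfile(fileext = ".xyz")
  writeLines(c("2", "t=0", "C 0 0 0", "C 1 0 0  ", "",
               "2", "t=1.5", "C 0 0 0\t", "C 2 0 0", "", ""), xyz)
  ens <- read_ensemble(xyz)
  expect_equal(n_frames(ens), 2)
  expect_equal(ens$times, c(0, 1.5))
  expect_equal(ens$frames[[2]][2, 1], 2)
})

test_that("frame-count mismatches and empty inputs are format errors", {
  xyz <- tempfile(fileext = ".xyz")
  writeLines(c("2", "t=0", "C 0 0 0", "C 1 0 0",
               "3", "t=1", "C 0 0 0", "C 1 0 0", "C 2 0 0"), xyz)
  expect_error(read_ensemble(xyz), "inconsistent atom count")
  writeLines(character(0), xyz)
  expect_error(read_ensemble(xyz), "empty input")
  pdb <- tempfile(fileext = ".pdb")
  writeLines("END", pdb)
  expect_error(read_ensemble(pdb), "empty input")
})

test_that("atom selection honours chain, range and atom class", {
  ref <- build_reference_complex()
  helix_all <- select_atoms(ref, "E", c(143, 153), "all")
  expect_setequal(unique(ref$atoms$residue_number[helix_all]), 143:153)
  expect_true(all(ref$atoms$chain_id[helix_all] == "E"))

  # all = heavy + hydrogens, and disjoint ranges give disjoint selections
  heavy <- select_atoms(ref, "E", c(143, 153), "heavy")
  hydro <- setdiff(helix_all, heavy)
  expect_true(all(ref$atoms$element[hydro] == "H"))
  expect_setequal(helix_all, union(heavy, hydro))
  loop <- select_atoms(ref, "E", c(136, 142), "all")
  expect_length(intersect(helix_all, loop), 0)

  # glycine has no side-chain atoms
  expect_error(select_atoms(ref, "E", c(139, 139), "side_chain"),
               "empty selection")
  # named-set selection
  ca_only <- select_atoms(ref, "E", c(143, 153), "CA")
  expect_length(ca_only, 11)
})

test_that("heavy-atom selection counts elements, not names", {
  atoms <- data.frame(
    atom_name = c("N", "CA", "C", "O", "CB", "CG", "H", "HA", "HB1", "HB2"),
    element = c("N", "C", "C", "O", "C", "C", "H", "H", "H", "H"),
    chain_id = "A", residue_number = 1, residue_name = "ABU",
    stringsAsFactors = FALSE
  )
  s <- annotated_structure(atoms, matrix(rnorm(30), 10, 3))
  expect_length(select_atoms(s, "A", c(1, 1), "heavy"), 6)
  expect_length(select_atoms(s, "A", c(1, 1), "side_chain"), 2)
})

test_that("region annotations validate and select atoms", {
  ref <- build_reference_complex()
  expect_error(set_regions(ref, list(bad = list(chain = "Z", start = 1,
                                                end = 2))),
               "selects no atoms")
  expect_length(region_atoms(ref, "srm_helix", "CA"), 11)
  expect_error(region_atoms(ref, "nonexistent"), "not annotated")

  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("srm_helix:", "  chain: E", "  start: 143", "  end: 153"), cfg)
  regions <- read_regions(cfg)
  expect_equal(regions$srm_helix$start, 143L)
})

test_that("structure invariants reject bad input", {
  atoms <- data.frame(atom_name = c("CA", "CA"), element = "C",
                      chain_id = "A", residue_number = 1,
                      residue_name = "ALA", stringsAsFactors = FALSE)
  expect_error(annotated_structure(atoms, matrix(0, 2, 3)), "duplicate")
  atoms$atom_name <- c("CA", "CB")
  expect_error(annotated_structure(atoms, matrix(c(0, Inf), 2, 3)), "finite")
  expect_error(trajectory_ensemble(random_structure(5), list(matrix(0, 5, 3)),
                                   times = numeric(0)), "length mismatch")
  expect_error(trajectory_ensemble(random_structure(5),
                                   list(matrix(0, 5, 3), matrix(0, 5, 3)),
                                   times = c(1, 1)), "strictly increasing")
})
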