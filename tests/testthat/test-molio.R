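test_that("multi-model PDB entries contribute model 1 coordinates only", {
  mols <- parse_structure(two_model_pdb(), "pdb")
  all_xyz <- do.call(rbind, lapply(mols, coords))
  expect_equal(sum(vapply(mols, n_atoms, integer(1))), 3L)
  expect_true(all(all_xyz[, "x"] < 6))   # model 2 lives at x ~ 8-9.5
  # polymer chain and hetero ligand split into separate molecules
  kinds <- lapply(mols, function(m) unique(m$atoms$record_kind))
  expect_setequal(unlist(kinds), c("polymer", "hetero"))
})

test_that("a single hetero residue parses into one molecule, intact", {
  path <- write_pdb_fixture(hetero_residue_pdb(20))
  mols <- parse_structure(path, "pdb")
  expect_length(mols, 1)
  expect_equal(n_atoms(mols[[1]]), 20L)
  expect_equal(mols[[1]]$atoms$serial, 1:20)
})

test_that("hetero residues merge into one molecule only when covalently linked", {
  # residues 1.2 A apart at the junction: covalent (C-C range)
  linked <- write_pdb_fixture(c(hetero_residue_pdb(3, resno = 1),
                                hetero_residue_pdb(3, resno = 2,
                                                   start_x = 3 * 1.2,
                                                   serial0 = 3)))
  expect_length(parse_structure(linked, "pdb"), 1)
  # residues 8 A apart: separate molecules
  apart <- write_pdb_fixture(c(hetero_residue_pdb(3, resno = 1),
                               hetero_residue_pdb(3, resno = 2,
                                                  start_x = 8, serial0 = 3)))
  expect_length(parse_structure(apart, "pdb"), 2)
})

test_that("splitting loses no atom and duplicates none", {
  lines <- c(pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, "N"),
             pdb_atom_line(2, "CA", "ALA", "A", 1, 1.45, 0, 0, "C"),
             pdb_atom_line(3, "N", "GLY", "B", 1, 20, 0, 0, "N"),
             hetero_residue_pdb(4, resno = 50, start_x = 40, serial0 = 3),
             hetero_residue_pdb(5, resno = 60, start_x = 60, serial0 = 7))
  mols <- parse_structure(write_pdb_fixture(lines), "pdb")
  serials <- sort(unlist(lapply(mols, function(m) m$atoms$serial)))
  expect_equal(serials, sort(c(1, 2, 3, 3 + 1:4, 7 + 1:5)))
})

test_that("MOL2 parsing carries partial charges (sum conserved)", {
  path <- file.path(peoe_fixture_dir(), "methanol.mol2")
  mol <- parse_structure(path, "mol2")[[1]]
  expect_equal(n_atoms(mol), 6L)
  expect_lt(abs(sum(charges(mol))), 1e-6 + 1e-3)  # obabel prints 4 decimals
  expect_equal(mol$atoms$element[1:2], c("C", "O"))
  expect_equal(nrow(mol$bonds), 5L)
})

test_that("PQR charges land on the atoms", {
  path <- tempfile(fileext = ".pqr")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000 -0.3000 1.5000",
    "ATOM      2  CA  ALA A   1       1.450   0.000   0.000  0.2000 1.7000",
    "END"), path)
  mol <- parse_structure(path, "pqr")[[1]]
  expect_equal(charges(mol), c(-0.3, 0.2))
})

test_that("unparseable files and unknown elements raise informative errors", {
  bad <- tempfile(fileext = ".xyz")
  writeLines("not a structure", bad)
  expect_error(parse_structure(bad), "format")
  expect_error(parse_structure(tempfile(fileext = ".pdb")), "not found")
  unk <- write_pdb_fixture(
    pdb_atom_line(1, "Q1", "LIG", "A", 1, 0, 0, 0, "Qq", "HETATM"))
  expect_error(parse_structure(unk, "pdb"), "element")
})

test_that("highest-occupancy altloc wins, ties to the first code", {
  path <- write_pdb_fixture(c(
    pdb_atom_line(1, "C1", "LIG", "A", 1, 0, 0, 0, "C", "HETATM",
                  occ = 0.4, alt = "A"),
    pdb_atom_line(2, "C1", "LIG", "A", 1, 5, 0, 0, "C", "HETATM",
                  occ = 0.6, alt = "B"),
    pdb_atom_line(3, "C2", "LIG", "A", 1, 1.4, 0, 0, "C", "HETATM",
                  occ = 0.5, alt = "A"),
    pdb_atom_line(4, "C2", "LIG", "A", 1, 6.4, 0, 0, "C", "HETATM",
                  occ = 0.5, alt = "B")))
  mol <- parse_structure(path, "pdb")[[1]]
  expect_equal(n_atoms(mol), 2L)
  expect_equal(mol$atoms$serial, c(2L, 3L))  # 0.6 beats 0.4; tie -> first
})

test_that("metal stripping removes coordination cores and preserves order", {
  mol <- iron_complex_mol(42)
  out <- strip_metal_atoms(mol)
  expect_equal(n_atoms(out), 42L)
  expect_false("Fe" %in% out$atoms$element)
  expect_equal(out$atoms$serial, mol$atoms$serial[-1])  # order preserved
  # all-organic molecule untouched
  org <- random_mol(12, seed = 3)
  expect_identical(strip_metal_atoms(org)$atoms, org$atoms)
  # a lone cation strips to an empty molecule
  na <- molecule(data.frame(element = "Na", x = 0, y = 0, z = 0))
  expect_equal(n_atoms(strip_metal_atoms(na)), 0L)
  # B and Si are retained
  bsi <- molecule(data.frame(element = c("B", "Si", "C"),
                             x = c(0, 3, 6), y = 0, z = 0))
  expect_equal(n_atoms(strip_metal_atoms(bsi)), 3L)
})

test_that("ligand size filters keep exactly the 10..485 atom range", {
  sizes <- c(9, 10, 485, 486)
  mols <- lapply(sizes, function(n) random_mol(n, seed = n))
  kept <- filter_ligands(mols)
  expect_equal(vapply(kept, n_atoms, integer(1)), c(10L, 485L))
  expect_equal(filter_ligands(list()), list())
  # 3-atom waters all removed
  waters <- lapply(1:5, function(i) random_mol(3, seed = i))
  expect_equal(filter_ligands(waters), list())
  expect_error(filter_ligands(mols, min_atoms = 20, max_atoms = 10),
               "exceeds")
})

test_that("pocket extraction honors both modes and their cutoffs", {
  lig <- molecule(data.frame(element = "C", x = 0, y = 0, z = 0),
                  mol_id = "lig")
  prot <- data.frame(
    serial = 11:13, element = "C",
    x = c(4.0, 7.0, 4.9), y = 0, z = 0, charge = NA_real_,
    record_kind = "polymer", resname = "ALA", chain = "A",
    resno = c(1L, 2L, 3L), insert = "", stringsAsFactors = FALSE)
  atom_level <- extract_pocket(prot, lig, pocket_spec("atom_level", 6.5))
  expect_equal(atom_level$atoms$serial, c(11L, 13L))  # 7.0 A atom excluded

  # residue-complete: one atom at 4.9 A pulls its 8 A siblings in
  res3 <- rbind(prot,
                data.frame(serial = 14L, element = "C", x = 8, y = 0, z = 0,
                           charge = NA_real_, record_kind = "polymer",
                           resname = "ALA", chain = "A", resno = 3L,
                           insert = "", stringsAsFactors = FALSE))
  rc <- extract_pocket(res3, lig, pocket_spec("residue_complete", 5.0))
  expect_setequal(rc$atoms$serial, c(11L, 13L, 14L))

  # no protein atom within cutoff -> empty, flagged
  far <- prot; far$x <- far$x + 100
  empty <- extract_pocket(far, lig, pocket_spec("atom_level", 6.5))
  expect_equal(n_atoms(empty), 0L)
  expect_true(isTRUE(attr(empty, "empty_pocket")))

  expect_error(extract_pocket(prot, molecule(prot[0, ]), pocket_spec()),
               "empty")
})

test_that("atom-level pockets are subsets of residue-complete pockets", {
  set.seed(42)
  lig <- random_mol(8, seed = 99)
  prot <- data.frame(
    serial = 100 + 1:60, element = "C",
    x = stats::rnorm(60, sd = 6), y = stats::rnorm(60, sd = 6),
    z = stats::rnorm(60, sd = 6), charge = NA_real_,
    record_kind = "polymer", resname = "ALA", chain = "A",
    resno = rep(1:12, each = 5), insert = "", stringsAsFactors = FALSE)
  for (cutoff in c(4, 5, 6.5)) {
    al <- extract_pocket(prot, lig, pocket_spec("atom_level", cutoff))
    rc <- extract_pocket(prot, lig, pocket_spec("residue_complete", cutoff))
    expect_true(all(al$atoms$serial %in% rc$atoms$serial))
  }
})

test_that("pocket extraction is invariant under a joint rigid transform", {
  set.seed(7)
  lig <- random_mol(6, seed = 5)
  prot <- data.frame(
    serial = 1:40, element = "C",
    x = stats::rnorm(40, sd = 5), y = stats::rnorm(40, sd = 5),
    z = stats::rnorm(40, sd = 5), charge = NA_real_,
    record_kind = "polymer", resname = "ALA", chain = "A",
    resno = rep(1:8, each = 5), insert = "", stringsAsFactors = FALSE)
  rot <- topotier:::random_rotation()
  tr <- c(12, -5, 3)
  prot_mol <- molecule(prot)
  prot_t <- as.data.frame(rigid_transform(prot_mol, rot, tr))
  lig_t <- rigid_transform(lig, rot, tr)
  for (mode in c("atom_level", "residue_complete")) {
    p1 <- extract_pocket(prot, lig, pocket_spec(mode))
    p2 <- extract_pocket(prot_t, lig_t, pocket_spec(mode))
    expect_equal(p1$atoms$serial, p2$atoms$serial)
  }
})

test_that("written structures round-trip through parse_structure", {
  mol <- random_mol(15, seed = 11)
  pdb <- tempfile(fileext = ".pdb")
  write_structure(mol, pdb, "pdb")
  back <- parse_structure(pdb, "pdb")[[1]]
  expect_equal(coords(back), coords(mol), tolerance = 1e-3)
  mol2 <- tempfile(fileext = ".mol2")
  write_structure(mol, mol2, "mol2")
  back2 <- parse_structure(mol2, "mol2")[[1]]
  expect_equal(coords(back2), coords(mol), tolerance = 1e-4)
  expect_equal(charges(back2), charges(mol), tolerance = 1e-6)
})
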