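# Fixtures are built in code at test time; only the PEOE reference MOL2
# files (charges frozen from an external toolkit) live under extdata.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element, record = "ATOM", occ = 1, alt = "") {
  sprintf("%-6s%5d %-4s%1s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resname, chain, resno, x, y, z, occ, 0,
          element)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Two-model NMR-style entry whose models differ in every coordinate.
two_model_pdb <- function() {
  write_pdb_fixture(c(
    "MODEL        1",
    pdb_atom_line(1, "N", "ALA", "A", 1, 0, 0, 0, "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 1.45, 0, 0, "C"),
    pdb_atom_line(3, "C1", "LIG", "A", 101, 5, 0, 0, "C", "HETATM"),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "N", "ALA", "A", 1, 9, 9, 9, "N"),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 9.45, 9, 9, "C"),
    pdb_atom_line(3, "C1", "LIG", "A", 101, 8, 9, 9, "C", "HETATM"),
    "ENDMDL"))
}

# A hetero residue of n carbon atoms spaced 1.2 A apart (no covalent link
# to anything else at that spacing within the residue chain direction).
hetero_residue_pdb <- function(n, resno = 101, start_x = 0, serial0 = 0,
                               chain = "A") {
  vapply(seq_len(n), function(i) {
    pdb_atom_line(serial0 + i, paste0("C", i), "LIG", chain, resno,
                  start_x + 1.2 * (i - 1), 0, 0, "C", "HETATM")
  }, character(1))
}

# Porphyrin-like fixture: one Fe center plus n_organic carbons on a ring.
iron_complex_mol <- function(n_organic = 42) {
  th <- 2 * pi * seq_len(n_organic) / n_organic
  molecule(data.frame(
    element = c("Fe", rep("C", n_organic)),
    x = c(0, 2 * cos(th)), y = c(0, 2 * sin(th)), z = 0,
    stringsAsFactors = FALSE), mol_id = "porph")
}

# Random charged blob via the package generator with charges covering all
# default tiers.
random_mol <- function(n, seed) {
  make_molecule(n, "gaussian_blob", charge_profile = "tiers", seed = seed)
}

# Brute-force double-loop evaluation of the five printed moment formulas:
# the independent oracle for compute_moments()/fingerprint().
brute_moments <- function(xyz) {
  n <- nrow(xyz)
  if (n <= 1) return(c(0, 0, 0, 0, 0))
  s1 <- 0; xs <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    xs <- c(xs, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
  }
  c2 <- sum(xs) / (n * n - n)
  c1 <- sum(xs) / n^3
  c3 <- sum((xs - c2)^2) / n^2
  if (c3 > 0) {
    c4 <- (sum((xs - c2)^3) / n^2) / c3^1.5
    c5 <- (sum((xs - c2)^4) / n^2) / c3^2 - 3
  } else { c4 <- 0; c5 <- 0 }
  c(c1, c2, c3, c4, c5)
}

# Independent fingerprint oracle for the default tripartite scheme:
# literal interval rule (< -0.1 | [-0.1, 0.1] | > +0.1), brute-force moments.
brute_fingerprint <- function(mol) {
  q <- charges(mol)
  xyz <- coords(mol)
  tier_of <- ifelse(q < -0.1, 1L, ifelse(q <= 0.1, 2L, 3L))
  unlist(lapply(1:3, function(t) {
    brute_moments(xyz[tier_of == t, , drop = FALSE])
  }), use.names = FALSE)
}

set_coords_for_test <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

peoe_fixture_dir <- function() {
  system.file("extdata", "peoe_ref", package = "topotier")
}
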