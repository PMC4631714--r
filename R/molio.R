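#' Parse a structure file into its constituent molecules
#'
#' Reads a PDB, MOL2 or PQR file and splits the entry into molecules. For
#' multi-model PDB files only the first model contributes atoms. Polymer
#' (ATOM) records form one molecule per chain; hetero (HETATM) records are
#' grouped by residue and groups whose atoms lie within covalent-bonding
#' distance (sum of covalent radii + 0.45 Angstrom) are merged, so multi-residue
#' ligands such as bound peptides stay whole. MOL2 and PQR partial charges are
#' carried onto the atoms. When alternate locations are present, the
#' highest-occupancy altloc is kept (ties broken by first altloc code).
#'
#' @param path file path.
#' @param format one of `"auto"`, `"pdb"`, `"mol2"`, `"pqr"`; `"auto"` decides
#'   from the file extension.
#' @return list of [molecule()] objects.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mol2", "pqr")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("parse_structure(): file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pdb = "pdb", ent = "pdb", mol2 = "mol2",
                     ml2 = "mol2", pqr = "pqr",
                     stop("parse_structure(): cannot infer format from '.",
                          ext, "'; pass format explicitly"))
  }
  switch(format,
         pdb = parse_pdb_like(path, pqr = FALSE),
         pqr = parse_pdb_like(path, pqr = TRUE),
         mol2 = parse_mol2(path))
}

parse_pdb_like <- function(path, pqr = FALSE) {
  reader <- if (pqr) bio3d::read.pqr else bio3d::read.pdb
  pdb <- tryCatch(
    suppressWarnings(reader(path, multi = FALSE, rm.alt = FALSE,
                            verbose = FALSE)),
    error = function(e) stop("parse_structure(): unparseable ",
                             if (pqr) "PQR" else "PDB", " file '", path,
                             "': ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("parse_structure(): no ATOM/HETATM records in ", path)
  }
  at <- resolve_altloc(at)
  element <- at$elesy
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    element[missing_el] <- suppressWarnings(
      bio3d::atom2ele(at$elety[missing_el]))
  }
  element <- normalize_element(element)
  bad <- is.na(element) | !(element %in% element_table$symbol)
  if (any(bad)) {
    stop("parse_structure(): unknown element for record(s) ",
         paste(utils::head(at$eleno[bad], 5), collapse = ", "),
         " (atom name ", paste(utils::head(at$elety[bad], 5), collapse = ", "),
         ") in ", path)
  }
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    element = element,
    x = at$x, y = at$y, z = at$z,
    charge = if (pqr) as.numeric(at$o) else NA_real_,
    record_kind = ifelse(at$type == "ATOM", "polymer", "hetero"),
    resname = at$resid,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", at$insert),
    stringsAsFactors = FALSE)
  entry <- tools::file_path_sans_ext(basename(path))
  split_molecules(atoms, entry = entry, source = path)
}

# Keep the highest-occupancy alternate location per atom site; ties go to the
# first altloc code in the file.
resolve_altloc <- function(at) {
  alt <- at$alt
  if (all(is.na(alt) | alt == "")) return(at)
  site <- paste(at$type, at$chain, at$resno, at$insert, at$elety, sep = "\r")
  occ <- ifelse(is.na(at$o), 1, at$o)
  keep <- rep(TRUE, nrow(at))
  for (s in unique(site[!is.na(alt) & alt != ""])) {
    idx <- which(site == s)
    if (length(idx) < 2) next
    best <- idx[which.max(occ[idx])]  # which.max takes the first on ties
    keep[setdiff(idx, best)] <- FALSE
  }
  at[keep, , drop = FALSE]
}

parse_mol2 <- function(path) {
  # a missing @<TRIPOS>BOND block is legal (bonds are optional downstream)
  m <- tryCatch(suppressWarnings(bio3d::read.mol2(path)),
                error = function(e) stop("parse_structure(): unparseable ",
                                         "MOL2 file '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  at <- m$atom
  element <- sub("\\..*$", "", at$elety)
  element <- normalize_element(element)
  bad <- !(element %in% element_table$symbol)
  if (any(bad)) {
    stop("parse_structure(): unknown element in MOL2 record(s) ",
         paste(utils::head(at$eleno[bad], 5), collapse = ", "), " in ", path)
  }
  atoms <- data.frame(
    serial = as.integer(at$eleno),
    element = element,
    x = at$x, y = at$y, z = at$z,
    charge = if (is.null(at$charge)) NA_real_ else as.numeric(at$charge),
    record_kind = "hetero",
    resname = if (is.null(at$resid)) "LIG" else at$resid,
    chain = "A",
    resno = if (is.null(at$resno)) 1L else as.integer(at$resno),
    insert = "",
    stringsAsFactors = FALSE)
  mol <- molecule(atoms,
                  mol_id = paste0(tools::file_path_sans_ext(basename(path)),
                                  "_1"),
                  source = path)
  mol$sybyl_type <- at$elety
  if (!is.null(m$bond) && nrow(m$bond)) {
    mol$bonds <- data.frame(i = as.integer(m$bond$origin),
                            j = as.integer(m$bond$target),
                            order = as.character(m$bond$type),
                            stringsAsFactors = FALSE)
  }
  list(mol)
}

# Split an atom table into molecules: one per polymer chain; hetero residues
# merged by covalent proximity between residue groups.
split_molecules <- function(atoms, entry, source) {
  mols <- list()
  pol <- atoms[atoms$record_kind == "polymer", , drop = FALSE]
  if (nrow(pol)) {
    for (ch in unique(pol$chain)) {
      mols[[length(mols) + 1L]] <- pol[pol$chain == ch, , drop = FALSE]
    }
  }
  het <- atoms[atoms$record_kind == "hetero", , drop = FALSE]
  if (nrow(het)) {
    grp <- paste(het$chain, het$resno, het$insert, sep = "\r")
    comp <- merge_covalent_groups(het, match(grp, unique(grp)))
    for (g in sort(unique(comp))) {
      mols[[length(mols) + 1L]] <- het[comp == g, , drop = FALSE]
    }
  }
  lapply(seq_along(mols), function(i) {
    molecule(mols[[i]], mol_id = paste0(entry, "_", i), source = source)
  })
}

# Union-find over residue groups: two groups join when any inter-group atom
# pair is within covalent range (r_i + r_j + 0.45 A).
merge_covalent_groups <- function(atoms, group) {
  n_grp <- max(group)
  parent <- seq_len(n_grp)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n_grp > 1) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    rad <- covalent_radius(atoms$element)
    dd <- as.matrix(stats::dist(xyz))
    thr <- outer(rad, rad, "+") + 0.45
    linked <- which(dd <= thr & outer(group, group, "!="), arr.ind = TRUE)
    if (nrow(linked)) {
      for (k in seq_len(nrow(linked))) {
        a <- find(group[linked[k, 1]]); b <- find(group[linked[k, 2]])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  roots <- vapply(seq_len(n_grp), find, integer(1))
  match(roots, sort(unique(roots)))[group]
}

#' Remove metal and metalloid atoms from a molecule
#'
#' Strips atoms classified as metals (plus the metalloids Ge, As, Sb, Te, Po;
#' B and Si are retained) so that organometallic complexes lose their
#' coordination cores before charge assignment and fingerprinting. The order
#' of the remaining atoms is preserved; an empty result is permitted (it will
#' be removed downstream by the size filter).
#'
#' @param mol a [molecule()].
#' @return the molecule without metal atoms.
#' @export
strip_metal_atoms <- function(mol) {
  keep <- !is_strippable_metal(mol$atoms$element)
  mol$atoms <- mol$atoms[keep, , drop = FALSE]
  rownames(mol$atoms) <- NULL
  mol
}

#' Apply the ligand size filters
#'
#' Retains molecules whose atom count (after metal stripping, hydrogens
#' included when present) lies within `[min_atoms, max_atoms]`. The defaults
#' remove small fragments such as solvent molecules and monoatomic ions
#' (fewer than 10 atoms) and cap ligand size at 485 atoms.
#'
#' @param mols list of [molecule()] objects.
#' @param min_atoms minimum atom count (default 10).
#' @param max_atoms maximum atom count (default 485).
#' @return filtered list, input order preserved.
#' @export
filter_ligands <- function(mols, min_atoms = 10L, max_atoms = 485L) {
  if (min_atoms > max_atoms) {
    stop("filter_ligands(): min_atoms (", min_atoms,
         ") exceeds max_atoms (", max_atoms, ")")
  }
  n <- vapply(mols, n_atoms, integer(1))
  mols[n >= min_atoms & n <= max_atoms]
}

#' Binding-pocket definition
#'
#' @param mode `"residue_complete"` (every atom of every polymer residue with
#'   at least one atom within the cutoff of the ligand) or `"atom_level"`
#'   (polymer atoms individually within the cutoff).
#' @param cutoff distance cutoff in Angstrom; defaults to 5.0 for
#'   residue-complete and 6.5 for atom-level pockets.
#' @return object of class `pocket_spec`.
#' @export
pocket_spec <- function(mode = c("residue_complete", "atom_level"),
                        cutoff = NULL) {
  mode <- match.arg(mode)
  if (is.null(cutoff)) cutoff <- if (mode == "residue_complete") 5.0 else 6.5
  if (!is.numeric(cutoff) || length(cutoff) != 1 || cutoff <= 0) {
    stop("pocket_spec(): cutoff must be a positive number")
  }
  structure(list(mode = mode, cutoff = cutoff), class = "pocket_spec")
}

#' Extract the binding pocket around a ligand
#'
#' Selects polymer atoms of the complex near the ligand. In
#' `residue_complete` mode every atom of every polymer residue having at
#' least one atom within `spec$cutoff` of any ligand atom is kept; in
#' `atom_level` mode only the polymer atoms individually within the cutoff
#' are kept. Ligand atoms are always excluded. Distances are Euclidean
#' between atom centers.
#'
#' @param complex_atoms a [molecule()] or atom data.frame holding the full
#'   complex (or its polymer part).
#' @param ligand a [molecule()]; must be non-empty.
#' @param spec a [pocket_spec()].
#' @return a [molecule()]; if no polymer atom lies within the cutoff the
#'   result is empty and carries attribute `empty_pocket = TRUE`.
#' @export
extract_pocket <- function(complex_atoms, ligand, spec = pocket_spec()) {
  if (inherits(complex_atoms, "topo_mol")) complex_atoms <- complex_atoms$atoms
  if (!inherits(spec, "pocket_spec")) stop("extract_pocket(): spec must be a pocket_spec")
  if (n_atoms(ligand) == 0) stop("extract_pocket(): ligand is empty")
  pol <- complex_atoms[complex_atoms$record_kind == "polymer", , drop = FALSE]
  lig_serial <- ligand$atoms$serial
  pol <- pol[!(pol$serial %in% lig_serial), , drop = FALSE]
  pocket_id <- paste0(ligand$mol_id, "_pocket_", spec$mode, spec$cutoff)
  if (nrow(pol) == 0) {
    out <- molecule(pol, mol_id = pocket_id, source = "extract_pocket")
    attr(out, "empty_pocket") <- TRUE
    return(out)
  }
  pxyz <- as.matrix(pol[, c("x", "y", "z")])
  lxyz <- coords(ligand)
  # min distance from each polymer atom to any ligand atom
  d2min <- rep(Inf, nrow(pxyz))
  for (k in seq_len(nrow(lxyz))) {
    d2 <- (pxyz[, 1] - lxyz[k, 1])^2 + (pxyz[, 2] - lxyz[k, 2])^2 +
      (pxyz[, 3] - lxyz[k, 3])^2
    d2min <- pmin(d2min, d2)
  }
  within <- d2min <= spec$cutoff^2
  keep <- if (spec$mode == "atom_level") {
    within
  } else {
    res <- paste(pol$chain, pol$resno, pol$insert, sep = "\r")
    res %in% unique(res[within])
  }
  out <- molecule(pol[keep, , drop = FALSE], mol_id = pocket_id,
                  source = "extract_pocket")
  if (n_atoms(out) == 0) attr(out, "empty_pocket") <- TRUE
  out
}

#' Write a molecule to a PDB or MOL2 file
#'
#' PDB output goes through [bio3d::write.pdb()]; MOL2 output writes a minimal
#' `@<TRIPOS>` file carrying coordinates and partial charges (bond block
#' included when the molecule holds perceived or parsed bonds).
#'
#' @param mol a [molecule()].
#' @param path output path.
#' @param format `"pdb"` or `"mol2"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(mol, path, format = c("pdb", "mol2")) {
  format <- match.arg(format)
  a <- mol$atoms
  if (format == "pdb") {
    xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
    bio3d::write.pdb(file = path, xyz = xyz,
                     type = ifelse(a$record_kind == "polymer", "ATOM", "HETATM"),
                     resno = a$resno, resid = a$resname, eleno = a$serial,
                     elety = make.unique(paste0(a$element, seq_len(nrow(a)))),
                     chain = a$chain, insert = ifelse(a$insert == "", NA, a$insert),
                     o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                     elesy = a$element, verbose = FALSE)
  } else {
    bonds <- mol$bonds
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("@<TRIPOS>MOLECULE", mol$mol_id,
                 sprintf("%d %d 1", nrow(a),
                         if (is.null(bonds)) 0L else nrow(bonds)),
                 "SMALL", "USER_CHARGES", "", "@<TRIPOS>ATOM"), con)
    ch <- ifelse(is.na(a$charge), 0, a$charge)
    writeLines(sprintf("%6d %-4s %10.4f %10.4f %10.4f %-5s %3d %-6s %10.6f",
                       seq_len(nrow(a)), paste0(a$element, seq_len(nrow(a))),
                       a$x, a$y, a$z,
                       if (!is.null(mol$sybyl_type)) mol$sybyl_type else a$element,
                       a$resno, a$resname, ch), con)
    if (!is.null(bonds) && nrow(bonds)) {
      writeLines("@<TRIPOS>BOND", con)
      writeLines(sprintf("%5d %5d %5d %s", seq_len(nrow(bonds)),
                         bonds$i, bonds$j, bonds$order), con)
    }
  }
  invisible(path)
}
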