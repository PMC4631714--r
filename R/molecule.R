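#' Construct a molecule object
#'
#' A `topo_mol` is the atomic container used throughout the package: an
#' ordered table of atoms with Cartesian coordinates (Angstrom) and, once
#' assigned or read from file, per-atom partial charges (elementary-charge
#' units). It is the sole input to fingerprinting.
#'
#' @param atoms data.frame with columns `serial` (integer), `element`
#'   (element symbol), `x`, `y`, `z` (Angstrom), `charge` (partial charge or
#'   `NA` when not yet assigned), `record_kind` ("polymer" or "hetero"),
#'   `resname`, `chain`, `resno`, `insert`. Missing annotation columns are
#'   filled with defaults.
#' @param mol_id identifier string (source entry id + molecule index).
#' @param source provenance string (file path or generator description).
#' @return object of class `topo_mol`.
#' @export
molecule <- function(atoms, mol_id = "mol", source = "constructed") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  defaults <- list(serial = if (nrow(atoms)) seq_len(nrow(atoms)) else integer(),
                   charge = NA_real_, record_kind = "hetero",
                   resname = "UNK", chain = "A", resno = 1L, insert = "")
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) {
      atoms[[nm]] <- rep(defaults[[nm]], length.out = nrow(atoms))
    }
  }
  required <- c("element", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("molecule(): atoms is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) && !all(is.finite(xyz))) {
    stop("molecule(): non-finite coordinates")
  }
  atoms$element <- normalize_element(atoms$element)
  unknown <- !(atoms$element %in% element_table$symbol)
  if (any(unknown)) {
    stop("molecule(): unrecognized element symbol(s): ",
         paste(unique(atoms$element[unknown]), collapse = ", "))
  }
  rownames(atoms) <- NULL
  structure(list(mol_id = mol_id, atoms = atoms, source = source),
            class = "topo_mol")
}

#' @export
print.topo_mol <- function(x, ...) {
  ch <- x$atoms$charge
  cat(sprintf("<topo_mol> %s: %d atoms (%s)\n", x$mol_id, nrow(x$atoms),
              if (nrow(x$atoms) == 0) "empty"
              else if (anyNA(ch)) "charges unset"
              else sprintf("net charge %+.3f e", sum(ch))))
  if (nrow(x$atoms)) {
    elements <- sort(table(x$atoms$element), decreasing = TRUE)
    cat("  composition:", paste(names(elements), elements, sep = "",
                                collapse = " "), "\n")
  }
  cat("  source:", x$source, "\n")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `topo_mol`.
#' @return integer atom count.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' Coordinate matrix of a molecule
#' @param mol a `topo_mol`.
#' @return numeric n x 3 matrix (Angstrom).
#' @export
coords <- function(mol) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}

#' Per-atom partial charges
#' @param mol a `topo_mol`.
#' @return numeric vector, `NA` where unassigned.
#' @export
charges <- function(mol) mol$atoms$charge

set_coords <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]
  mol$atoms$y <- xyz[, 2]
  mol$atoms$z <- xyz[, 3]
  mol
}

# Case-normalize an element symbol: first letter upper, rest lower.
normalize_element <- function(el) {
  el <- trimws(as.character(el))
  out <- paste0(toupper(substr(el, 1, 1)), tolower(substring(el, 2)))
  out[el == ""] <- ""
  out
}

#' @export
as.data.frame.topo_mol <- function(x, ...) x$atoms
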