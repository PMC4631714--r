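#' Parameters for iterative partial-equalization charge assignment
#'
#' Classic Gasteiger--Marsili electronegativity polynomial coefficients
#' (chi = a + b q + c q^2, in eV) keyed by element/hybridization type, with
#' the damping schedule of the original method: at iteration t only a
#' fraction `damping^t` of the indicated charge is transferred across each
#' bond, and the series is truncated after `max_iter` iterations (6, as
#' classically done) or once the largest per-atom update drops below `tol`.
#'
#' @param damping per-iteration attenuation factor in (0, 1); default 0.5.
#' @param max_iter maximum number of iterations; default 6.
#' @param tol convergence threshold on the largest absolute charge update.
#' @return object of class `peoe_params`.
#' @export
peoe_parameters <- function(damping = 0.5, max_iter = 6L, tol = 1e-6) {
  if (damping <= 0 || damping >= 1) stop("peoe_parameters(): damping must be in (0,1)")
  if (max_iter < 1) stop("peoe_parameters(): max_iter must be >= 1")
  if (tol <= 0) stop("peoe_parameters(): tol must be > 0")
  coef <- rbind(
    H     = c(7.17,  6.24, -0.56),
    C.3   = c(7.98,  9.18,  1.88),
    C.2   = c(8.79,  9.32,  1.51),
    C.1   = c(10.39, 9.45,  0.73),
    N.3   = c(11.54, 10.82, 1.36),
    N.2   = c(12.87, 11.15, 0.85),
    N.1   = c(15.68, 11.70, -0.27),
    O.3   = c(14.18, 12.92, 1.39),
    O.2   = c(17.07, 13.79, 0.47),
    F     = c(14.66, 13.85, 2.31),
    Cl    = c(11.00, 9.69,  1.35),
    Br    = c(10.08, 8.47,  1.16),
    I     = c(9.90,  7.96,  0.96),
    S.3   = c(10.14, 9.13,  1.38),
    S.2   = c(10.88, 9.49,  1.33),
    P.3   = c(8.90,  8.24,  0.96))
  colnames(coef) <- c("a", "b", "c")
  # electronegativity of the cation, the transfer denominator; H is special
  chi_plus <- rowSums(coef)
  chi_plus["H"] <- 20.02
  structure(list(coef = coef, chi_plus = chi_plus, damping = damping,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "peoe_params")
}

# Bond list from the covalent-radius rule (r_i + r_j + 0.45 A). Returns a
# two-column integer matrix of atom index pairs (i < j).
perceive_bonds <- function(mol) {
  if (!is.null(mol$bonds)) {
    b <- mol$bonds
    return(cbind(pmin(b$i, b$j), pmax(b$i, b$j)))
  }
  n <- n_atoms(mol)
  if (n < 2) return(matrix(integer(), ncol = 2))
  dd <- as.matrix(stats::dist(coords(mol)))
  rad <- covalent_radius(mol$atoms$element)
  thr <- outer(rad, rad, "+") + 0.45
  hits <- which(dd <= thr & upper.tri(dd) & dd > 1e-6, arr.ind = TRUE)
  unname(hits)
}

# PEOE atom type: from the parsed SYBYL type when the molecule came from
# MOL2, otherwise from a heavy-atom degree heuristic (degree = number of
# perceived bonds): C 4->sp3, 3->sp2, <=2->sp1; N >=3->sp3, 2->sp2, 1->sp1;
# O 2->sp3 (ether/hydroxyl), 1->sp2 (carbonyl-like); S/P -> S.3/P.3.
peoe_type <- function(mol, bonds) {
  el <- mol$atoms$element
  n <- length(el)
  if (!is.null(mol$sybyl_type)) {
    ty <- mol$sybyl_type
    map <- c(C.3 = "C.3", C.2 = "C.2", C.ar = "C.2", C.cat = "C.2",
             C.1 = "C.1", N.3 = "N.3", N.4 = "N.3", N.2 = "N.2",
             N.ar = "N.2", N.am = "N.2", N.pl3 = "N.2", N.1 = "N.1",
             O.3 = "O.3", O.2 = "O.2", O.co2 = "O.2", S.3 = "S.3",
             S.2 = "S.2", S.o = "S.3", S.o2 = "S.3", P.3 = "P.3",
             H = "H", F = "F", Cl = "Cl", Br = "Br", I = "I")
    out <- unname(map[ty])
    if (!anyNA(out)) return(out)
    # fall through to heuristic for unmapped entries
    heur <- peoe_type(structure(list(atoms = mol$atoms), class = "topo_mol"),
                      bonds)
    out[is.na(out)] <- heur[is.na(out)]
    return(out)
  }
  deg <- tabulate(c(bonds[, 1], bonds[, 2]), nbins = n)
  vapply(seq_len(n), function(i) {
    switch(el[i],
           H = "H", F = "F", Cl = "Cl", Br = "Br", I = "I",
           C = if (deg[i] >= 4) "C.3" else if (deg[i] == 3) "C.2" else "C.1",
           N = if (deg[i] >= 3) "N.3" else if (deg[i] == 2) "N.2" else "N.1",
           O = if (deg[i] >= 2) "O.3" else "O.2",
           S = "S.3",
           P = "P.3",
           el[i])  # unparameterized elements keep their symbol
  }, character(1))
}

#' Assign Gasteiger-type (PEOE) partial charges
#'
#' Iterative partial equalization of orbital electronegativities: charges
#' start from the formal charges (zero unless an `formal` column is present
#' on the atom table), each iteration computes per-atom electronegativities
#' chi = a + b q + c q^2 and transfers charge across every bond from the
#' less to the more electronegative atom, scaled by `damping^t` and the
#' donor's cation electronegativity. Total charge is conserved exactly.
#' Elements without PEOE parameters keep their formal charge and take no
#' part in transfers (with a warning), or raise an error when
#' `strict = TRUE`.
#'
#' @param mol a [molecule()]; elements must be known and coordinates set
#'   (bonds are perceived from covalent radii unless the molecule carries a
#'   parsed bond table).
#' @param params a [peoe_parameters()] object.
#' @param strict error (rather than warn) on elements without parameters.
#' @return the molecule with `charge` filled for every atom.
#' @export
assign_gasteiger <- function(mol, params = peoe_parameters(), strict = FALSE) {
  n <- n_atoms(mol)
  if (n == 0) return(mol)
  bonds <- perceive_bonds(mol)
  type <- peoe_type(mol, bonds)
  known <- type %in% rownames(params$coef)
  if (any(!known)) {
    offenders <- unique(mol$atoms$element[!known])
    msg <- paste0("no PEOE parameters for element(s): ",
                  paste(offenders, collapse = ", "))
    if (strict) stop("assign_gasteiger(): ", msg)
    warning("assign_gasteiger(): ", msg,
            "; those atoms keep their formal charge")
  }
  formal <- mol$atoms$formal
  if (is.null(formal)) formal <- rep(0, n)
  formal[is.na(formal)] <- 0
  q <- formal
  if (nrow(bonds)) {
    active <- known[bonds[, 1]] & known[bonds[, 2]]
    bonds <- bonds[active, , drop = FALSE]
  }
  if (nrow(bonds)) {
    a <- params$coef[, "a"]; b <- params$coef[, "b"]; cc <- params$coef[, "c"]
    ti <- type
    for (t in seq_len(params$max_iter)) {
      chi <- rep(0, n)
      chi[known] <- a[ti[known]] + b[ti[known]] * q[known] +
        cc[ti[known]] * q[known]^2
      scale <- params$damping^t
      dq <- rep(0, n)
      for (k in seq_len(nrow(bonds))) {
        i <- bonds[k, 1]; j <- bonds[k, 2]
        if (chi[i] == chi[j]) next
        lo <- if (chi[i] < chi[j]) i else j
        hi <- if (chi[i] < chi[j]) j else i
        move <- (chi[hi] - chi[lo]) / params$chi_plus[[ti[lo]]] * scale
        dq[lo] <- dq[lo] + move   # donor becomes more positive
        dq[hi] <- dq[hi] - move
      }
      q <- q + dq
      if (max(abs(dq)) < params$tol) break
    }
  }
  mol$atoms$charge <- q
  mol
}

#' Guarantee that every atom carries a partial charge
#'
#' Returns the molecule unchanged when charges are already present (e.g.
#' parsed from MOL2 or PQR); otherwise runs [assign_gasteiger()]. Downstream
#' fingerprinting always sees charged atoms after this call.
#'
#' @param mol a [molecule()].
#' @param params a [peoe_parameters()] object, used only when assignment is
#'   needed.
#' @return a charged molecule.
#' @export
ensure_charges <- function(mol, params = peoe_parameters()) {
  if (n_atoms(mol) == 0 || !anyNA(mol$atoms$charge)) return(mol)
  assign_gasteiger(mol, params)
}
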